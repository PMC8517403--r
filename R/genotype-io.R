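#' Construct a genotype matrix object
#'
#' Bundles an additive-coded dosage matrix with its marker map. Dosages count
#' copies of the "A" allele, so `"aa" = 0`, `"Aa" = 1`, `"AA" = 2`; missing
#' calls are `NA`.
#'
#' @param dosages Numeric `n x m` matrix with values in `{0, 1, 2, NA}`.
#'   Row names are sample IDs, column names are marker IDs (supplied names
#'   win over `map$id` being absent).
#' @param map Data frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   one row per marker, in column order of `dosages`. If `NULL`, a map with
#'   all markers on chromosome `"1"` at consecutive positions is created.
#' @return An object of class `"genotype_matrix"`: a list with elements
#'   `dosages` (numeric matrix) and `map` (data frame).
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
#'                             dimnames = list(paste0("s", 1:3), c("m1", "m2"))))
#' dim(g$dosages)
#' @export
genotype_matrix <- function(dosages, map = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (n < 2L) stop("genotype matrix needs at least 2 samples", call. = FALSE)
  if (m < 1L) stop("genotype matrix needs at least 1 marker", call. = FALSE)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("sample", seq_len(n))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("marker", seq_len(m))
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad))
    stop("invalid dosage code(s): ",
         paste(unique(dosages[bad]), collapse = ", "),
         " (allowed: 0, 1, 2, NA)", call. = FALSE)
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate sample IDs", call. = FALSE)
  if (anyDuplicated(colnames(dosages)))
    stop("duplicate marker IDs", call. = FALSE)
  if (is.null(map)) {
    map <- data.frame(id = colnames(dosages), chrom = "1",
                      pos = seq_len(m), stringsAsFactors = FALSE)
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(map)))
    stop("marker map must have columns id, chrom, pos", call. = FALSE)
  map <- map[, need]
  map$id <- as.character(map$id)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (nrow(map) != m)
    stop("marker map has ", nrow(map), " rows but genotype matrix has ",
         m, " markers", call. = FALSE)
  if (!identical(map$id, colnames(dosages)))
    stop("marker map IDs do not match dosage column names", call. = FALSE)
  if (any(map$pos < 1L))
    stop("marker positions must be >= 1 (1-based bp)", call. = FALSE)
  structure(list(dosages = dosages, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "markers;",
      sum(is.na(x$dosages)), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read genotypes from PLINK binary or tab-separated text
#'
#' Two layouts are supported. `format = "tsv"`: `path` is a tab-separated
#' table, samples in rows, first column `sample_id`, remaining header cells
#' marker IDs; `map_path` is a companion tab-separated marker map with header
#' `id`, `chrom`, `pos`. `format = "plink"`: `path` is a PLINK file-set
#' prefix; `<prefix>.bed` (SNP-major binary), `<prefix>.bim` and
#' `<prefix>.fam` are read, dosages counting copies of the A1 allele.
#'
#' Missing calls are preserved as `NA`; no imputation happens here.
#'
#' @param path File path (tsv) or PLINK prefix.
#' @param format `"tsv"` or `"plink"`.
#' @param map_path Marker-map path, required for `format = "tsv"`.
#' @return A [genotype_matrix()].
#' @seealso [write_genotypes()], [filter_markers()], [impute_missing()]
#' @export
read_genotypes <- function(path, format = c("tsv", "plink"), map_path = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (is.null(map_path))
      stop("map_path is required for tsv genotypes", call. = FALSE)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (names(tab)[1] != "sample_id")
      stop("tsv genotype file must start with a 'sample_id' column",
           call. = FALSE)
    dos <- as.matrix(tab[, -1, drop = FALSE])
    rownames(dos) <- as.character(tab$sample_id)
    map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    genotype_matrix(dos, map)
  } else {
    read_plink(path)
  }
}

# Decode a SNP-major PLINK .bed byte stream: per marker ceil(n/4) bytes,
# 2 bits per sample, LSB first. 00 = A1/A1 (2), 10 = A1/A2 (1),
# 11 = A2/A2 (0), 01 = missing.
decode_bed_bytes <- function(raw_bytes, n, m) {
  bytes_per_marker <- (n + 3L) %/% 4L
  if (length(raw_bytes) != bytes_per_marker * m)
    stop("bed payload has ", length(raw_bytes), " bytes; expected ",
         bytes_per_marker * m, " for ", n, " samples x ", m, " markers",
         call. = FALSE)
  ints <- as.integer(raw_bytes)
  # all four 2-bit fields of every byte, samples varying fastest
  codes2 <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                  (ints %/% 16L) %% 4L, ints %/% 64L)
  lookup <- c(2, NA, 1, 0)  # indices 1..4 for 2-bit values 0..3
  full <- matrix(lookup[codes2 + 1L], nrow = 4L * bytes_per_marker, ncol = m)
  full[seq_len(n), , drop = FALSE]
}

read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing PLINK file: ", f, call. = FALSE)
  bim_tab <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  fam_tab <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam_tab)
  m <- nrow(bim_tab)
  payload <- readBin(bed, what = "raw", n = file.info(bed)$size)
  if (length(payload) < 3L ||
      payload[1] != as.raw(0x6c) || payload[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic number)", call. = FALSE)
  if (payload[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported", call. = FALSE)
  dos <- decode_bed_bytes(payload[-(1:3)], n, m)
  rownames(dos) <- as.character(fam_tab[[2]])
  colnames(dos) <- as.character(bim_tab[[2]])
  map <- data.frame(id = as.character(bim_tab[[2]]),
                    chrom = as.character(bim_tab[[1]]),
                    pos = as.integer(bim_tab[[4]]),
                    stringsAsFactors = FALSE)
  genotype_matrix(dos, map)
}

#' Write a genotype matrix to tab-separated files
#'
#' Writes the dosage table (samples in rows, `sample_id` first column) and
#' the marker map, in the layout accepted by [read_genotypes()] with
#' `format = "tsv"`. Missing calls are written as `NA`.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path for the dosage table.
#' @param map_path Output path for the marker map.
#' @export
write_genotypes <- function(g, path, map_path) {
  tab <- data.frame(sample_id = rownames(g$dosages),
                    g$dosages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(g$map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(g)
}

#' Read a phenotype vector keyed by sample ID
#'
#' Expects a tab-separated file with header `sample_id<TAB><trait>`; the
#' second column is the trait value.
#'
#' @param path File path.
#' @return Named numeric vector (names are sample IDs).
#' @export
read_phenotype <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id" || ncol(tab) < 2L)
    stop("phenotype file must have header sample_id<TAB>value", call. = FALSE)
  y <- as.numeric(tab[[2]])
  if (any(!is.finite(y))) stop("phenotype values must be finite", call. = FALSE)
  names(y) <- as.character(tab$sample_id)
  y
}

#' Read a covariate matrix keyed by sample ID
#'
#' Tab-separated, header `sample_id<TAB>cov1<TAB>...`. An intercept column of
#' ones is prepended unless the first covariate column is already constant 1.
#'
#' @param path File path.
#' @return Numeric matrix, rows named by sample ID, first column the
#'   intercept.
#' @export
read_covariates <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id")
    stop("covariate file must start with a 'sample_id' column", call. = FALSE)
  x <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- as.character(tab$sample_id)
  if (ncol(x) == 0L || !all(x[, 1] == 1))
    x <- cbind(intercept = 1, x)
  if (qr(x)$rank < ncol(x))
    stop("covariate matrix is rank deficient", call. = FALSE)
  x
}

#' Per-marker minor allele frequency and missing rate
#'
#' @param g A [genotype_matrix()].
#' @return Data frame with columns `id`, `maf`, `missing_rate`.
#' @export
marker_maf <- function(g) {
  p <- colMeans(g$dosages, na.rm = TRUE) / 2
  data.frame(id = g$map$id,
             maf = pmin(p, 1 - p),
             missing_rate = colMeans(is.na(g$dosages)),
             stringsAsFactors = FALSE)
}

#' Filter markers on minor allele frequency and missing rate
#'
#' Keeps markers whose MAF is strictly greater than `maf_min` and whose
#' missing rate is strictly below `missing_max` (so markers at exactly 5%
#' MAF are removed and markers at exactly 20% missingness are removed, the
#' usual GWAS quality-control convention). Marker order is preserved.
#'
#' @param g A [genotype_matrix()].
#' @param maf_min MAF threshold (default 0.05); markers at or below it drop.
#' @param missing_max Missing-rate threshold (default 0.20); markers at or
#'   above it drop.
#' @return Filtered [genotype_matrix()].
#' @export
filter_markers <- function(g, maf_min = 0.05, missing_max = 0.20) {
  stat <- marker_maf(g)
  keep <- stat$maf > maf_min & stat$missing_rate < missing_max
  keep[is.na(keep)] <- FALSE
  if (!any(keep))
    stop("no markers pass the MAF/missing-rate filters", call. = FALSE)
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  g$map[keep, , drop = FALSE])
}

#' Mean-impute missing genotype calls
#'
#' Each missing cell is replaced by its marker's mean observed dosage, which
#' preserves per-marker allele-frequency information. Markers with no
#' observed calls are an error (they should have been filtered first).
#'
#' @param g A [genotype_matrix()].
#' @return A [genotype_matrix()] with no missing values.
#' @export
impute_missing <- function(g) {
  dos <- g$dosages
  miss <- is.na(dos)
  if (!any(miss)) return(g)
  mu <- colMeans(dos, na.rm = TRUE)
  if (any(!is.finite(mu)))
    stop("marker(s) entirely missing: ",
         paste(g$map$id[!is.finite(mu)], collapse = ", "), call. = FALSE)
  idx <- which(miss, arr.ind = TRUE)
  dos[idx] <- mu[idx[, 2]]
  out <- g
  out$dosages <- dos
  out
}

# Align phenotype (named vector) and optional covariates to the genotype
# sample order; errors on unmatched IDs.
align_samples <- function(g, y, x_cov = NULL) {
  ids <- rownames(g$dosages)
  if (is.null(names(y))) {
    if (length(y) != length(ids))
      stop("unnamed phenotype length does not match sample count",
           call. = FALSE)
    names(y) <- ids
  }
  if (!all(ids %in% names(y)))
    stop("phenotype missing for sample(s): ",
         paste(setdiff(ids, names(y)), collapse = ", "), call. = FALSE)
  y <- y[ids]
  if (is.null(x_cov)) {
    x_cov <- matrix(1, length(ids), 1, dimnames = list(ids, "intercept"))
  } else {
    if (!all(ids %in% rownames(x_cov)))
      stop("covariates missing for some samples", call. = FALSE)
    x_cov <- x_cov[ids, , drop = FALSE]
  }
  list(y = y, x_cov = x_cov)
}
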