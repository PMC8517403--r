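#' Marker-inferred genetic relatedness matrix
#'
#' Computes the kinship (genomic relationship) matrix
#' \deqn{K = \frac{1}{m}\sum_{i=1}^m x_i x_i^T = \frac{1}{m} G G^T}
#' from the additive dosage matrix G. By default the raw 0/1/2 codes are
#' used; `centered = TRUE` subtracts the per-marker mean dosage first, which
#' makes K invariant to which allele is counted (the raw form is
#' allele-coding dependent).
#'
#' @param g A [genotype_matrix()] with no missing values (impute first).
#' @param centered Center each marker at its mean dosage before the Gram
#'   product? Default `FALSE`.
#' @return An `n x n` symmetric positive semi-definite matrix of class
#'   `"kinship_matrix"`, dimnames set to the sample IDs.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 2, 1, 1), 2,
#'                             dimnames = list(c("a", "b"), c("m1", "m2"))))
#' compute_kinship(g)
#' @export
compute_kinship <- function(g, centered = FALSE) {
  G <- g$dosages
  if (anyNA(G))
    stop("genotypes contain missing values; run impute_missing() first",
         call. = FALSE)
  m <- ncol(G)
  if (m == 0L) stop("no markers", call. = FALSE)
  if (centered) G <- sweep(G, 2L, colMeans(G), "-")
  K <- tcrossprod(G) / m
  K <- (K + t(K)) / 2  # defend symmetry against BLAS rounding
  dimnames(K) <- list(rownames(g$dosages), rownames(g$dosages))
  class(K) <- c("kinship_matrix", "matrix")
  K
}

#' Write a kinship matrix as tab-separated text
#'
#' Square layout with a `sample_id` header column, so kinship can be cached
#' between runs and read back with [read_kinship()].
#'
#' @param k Kinship matrix.
#' @param path Output path.
#' @export
write_kinship <- function(k, path) {
  tab <- data.frame(sample_id = rownames(k), unclass(k),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(k)
}

#' Read a kinship matrix written by [write_kinship()]
#'
#' @param path File path.
#' @return A `"kinship_matrix"`.
#' @export
read_kinship <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  k <- as.matrix(tab[, -1, drop = FALSE])
  rownames(k) <- as.character(tab$sample_id)
  if (nrow(k) != ncol(k) || !identical(rownames(k), colnames(k)))
    stop("kinship file is not a square sample-ID-labelled matrix",
         call. = FALSE)
  k <- (k + t(k)) / 2
  class(k) <- c("kinship_matrix", "matrix")
  k
}
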