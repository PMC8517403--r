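#' Leading principal components of the genotype matrix
#'
#' Top-k left singular vectors of the column-centered dosage matrix,
#' returned as orthonormal covariate columns for population-structure
#' correction.
#'
#' @param g A [genotype_matrix()], imputed.
#' @param k_components Number of components; 0 returns `NULL` (intercept
#'   only downstream).
#' @return `n x k` matrix of orthonormal scores (columns `PC1`, ...), or
#'   `NULL`.
#' @export
make_pcs <- function(g, k_components) {
  if (k_components == 0L) return(NULL)
  n <- nrow(g$dosages)
  m <- ncol(g$dosages)
  if (k_components >= min(n, m))
    stop("k_components must be < min(n, m)", call. = FALSE)
  Gc <- sweep(g$dosages, 2L, colMeans(g$dosages), "-")
  sv <- svd(Gc, nu = k_components, nv = 0)
  pcs <- sv$u[, seq_len(k_components), drop = FALSE]
  dimnames(pcs) <- list(rownames(g$dosages),
                        paste0("PC", seq_len(k_components)))
  pcs
}

# Deterministic per-stage child seeds from one global seed, so stages can
# be re-run in isolation; kept below 2^31.
stage_seeds <- function(seed) {
  base <- as.integer(seed) %% 1000000L
  c(genotypes = base * 2L + 11L,
    phenotype = base * 2L + 12L,
    cv = base * 2L + 13L)
}

#' Run the full two-stage association scan
#'
#' Orchestrates the pipeline: marker QC filter, mean imputation, kinship,
#' null mixed-model fit, genome-wide score scan, lenient screening,
#' empirical-Bayes multi-locus fit, likelihood-ratio testing, and LOD-based
#' QTN calling. An empty screen set short-circuits to an empty (valid)
#' call table.
#'
#' @param g A [genotype_matrix()] (may contain missing calls).
#' @param y Phenotype vector named by sample ID (or in sample order).
#' @param x_cov Optional covariate matrix (intercept added if `NULL`).
#' @param maf_min,missing_max Marker QC thresholds (see [filter_markers()]).
#' @param screen_p Stage-1 screening p-value cutoff (default 0.005).
#' @param lod_threshold Stage-2 LOD call threshold (default 3.0).
#' @param tau,omega EB prior hyperparameters (default Jeffreys, 0/0).
#' @param pcs Number of genotype principal components appended to the
#'   covariates (default 0).
#' @param pcg PCG solver settings ([pcg_settings()]).
#' @param eb Optional full [eb_config()]; overrides `tau`/`omega`.
#' @param exact_quadform Exact per-marker x'Px in the scan (default TRUE).
#' @param verbose Print per-stage progress (default FALSE).
#' @return List of class `"ebscan_result"`: `calls` (QTN table: id, chrom,
#'   pos, effect, lr, lod, p_value), `scan` (per-marker score-test table),
#'   `screen` (selected markers), `eb_fit` (or NULL), `null_fit`,
#'   `kinship`, and `log` (stage parameters and notes).
#' @examples
#' g <- simulate_genotypes(n = 120, m = 300, seed = 7)
#' des <- derive_design(simulation_design(n = 120, m = 300,
#'   qtns = data.frame(h2 = 0.25, maf = 0.3), sigma_k2 = 0))
#' y <- simulate_phenotype(g, des, seed = 8)
#' res <- ebscan(g, y)
#' res$calls
#' @export
ebscan <- function(g, y, x_cov = NULL, maf_min = 0.05, missing_max = 0.20,
                   screen_p = 0.005, lod_threshold = 3.0,
                   tau = 0, omega = 0, pcs = 0L,
                   pcg = pcg_settings(), eb = NULL,
                   exact_quadform = TRUE, verbose = FALSE) {
  stopifnot(maf_min >= 0, maf_min < 0.5, missing_max > 0, missing_max <= 1,
            screen_p > 0, screen_p <= 1, lod_threshold >= 0)
  say <- function(...) if (verbose) message("[ebscan] ", ...)
  log <- list(params = list(maf_min = maf_min, missing_max = missing_max,
                            screen_p = screen_p,
                            lod_threshold = lod_threshold,
                            tau = tau, omega = omega, pcs = pcs),
              notes = character())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  say("filtering markers")
  g <- stage("filter", filter_markers(g, maf_min, missing_max))
  g <- stage("impute", impute_missing(g))
  al <- stage("align", align_samples(g, y, x_cov))
  y <- al$y
  X <- al$x_cov
  if (pcs > 0L) {
    say("computing ", pcs, " genotype PCs")
    X <- cbind(X, stage("pcs", make_pcs(g, pcs)))
  }
  say("kinship over ", ncol(g$dosages), " markers")
  K <- stage("kinship", compute_kinship(g))
  say("null model fit")
  nf <- stage("null_model", fit_null_model(y, X, K, pcg))
  log$notes <- c(log$notes, sprintf("sigma_k2=%.6g sigma_e2=%.6g",
                                    nf$sigma_k2, nf$sigma_e2))
  say("score scan over ", ncol(g$dosages), " markers")
  scan <- stage("scan", score_scan(g, y, X, K, nf,
                                   exact_quadform = exact_quadform))
  screen <- screen_markers(scan, screen_p)
  say("screened q = ", nrow(screen), " markers at p <= ", screen_p)
  eb_cfg <- if (is.null(eb)) eb_config(tau = tau, omega = omega) else eb
  if (nrow(screen) == 0L) {
    log$notes <- c(log$notes, "empty screen set; no EB stage run")
    calls <- data.frame(id = character(), chrom = character(),
                        pos = integer(), effect = numeric(), lr = numeric(),
                        lod = numeric(), p_value = numeric(),
                        stringsAsFactors = FALSE)
    fit <- NULL
  } else {
    g_sel <- g$dosages[, screen$index, drop = FALSE]
    say("EB fit on q = ", ncol(g_sel))
    fit <- stage("eb", eb_fit(y, X, g_sel, eb_cfg))
    lrt <- stage("lrt", eb_lrt_all(fit))
    calls <- call_qtns(fit, lrt, lod_threshold, map = g$map)
  }
  structure(list(calls = calls, scan = scan, screen = screen,
                 eb_fit = fit, null_fit = nf, kinship = K,
                 genotypes = g, log = log),
            class = "ebscan_result")
}

#' @export
print.ebscan_result <- function(x, ...) {
  cat("two-stage scan:", nrow(x$scan), "markers,",
      nrow(x$screen), "screened,", nrow(x$calls), "QTN call(s)\n")
  if (nrow(x$calls) > 0) print(utils::head(x$calls, 10))
  invisible(x)
}
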