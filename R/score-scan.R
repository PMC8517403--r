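#' Project the phenotype through the null model
#'
#' Computes Py where P = M0^-1 - M0^-1 X (X' M0^-1 X)^-1 X' M0^-1 is the
#' null-model projection. P annihilates the covariate columns, and Py is
#' obtained as M0^-1 (y - X b_hat) through the fit's solver; P itself is
#' never formed.
#'
#' @param y Phenotype vector.
#' @param x_cov Covariate matrix.
#' @param null_fit A [fit_null_model()].
#' @param k Kinship matrix (unused directly; kept for interface symmetry).
#' @return Numeric n-vector Py.
#' @export
project_phenotype <- function(y, x_cov, null_fit, k = NULL) {
  r <- y - drop(as.matrix(x_cov) %*% null_fit$b_hat)
  py <- null_fit$solver(r)
  attributes(py) <- NULL
  py
}

#' Score-test statistics for one marker
#'
#' Given the projected phenotype Py and the quadratic form x'Px, returns the
#' raw score statistic `t_score = (1/2) (x'Py)^2`, its standardized form
#' `t_std = (x'Py)^2 / (x'Px)` — whose null distribution is exactly
#' chi-square with 1 df because Var(x'Py) = x'Px — and the upper-tail
#' chi-square p-value of `t_std`. A marker with `x'Px <= 1e-12`
#' (monomorphic after projection) is flagged degenerate with p = 1.
#'
#' @param x Marker dosage n-vector (imputed).
#' @param py Projected phenotype from [project_phenotype()].
#' @param px_quadform The scalar x'Px (>= 0).
#' @return List with `t_score`, `t_std`, `p_value`, `degenerate`.
#' @export
score_statistic <- function(x, py, px_quadform) {
  xpy <- sum(x * py)
  t_score <- 0.5 * xpy^2
  if (!is.finite(px_quadform) || px_quadform <= 1e-12) {
    return(list(t_score = t_score, t_std = 0, p_value = 1, degenerate = TRUE))
  }
  t_std <- xpy^2 / px_quadform
  list(t_score = t_score, t_std = t_std,
       p_value = stats::pchisq(t_std, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Genome-wide score-test scan
#'
#' Applies the single-marker score test to every marker. Py and b_hat come
#' from the null fit and are computed once; the per-marker quadratic form
#' x'Px = x'M0^-1 x - (x'M0^-1 X) (X'M0^-1 X)^-1 (X'M0^-1 x) is exact by
#' default, with all M0^-1 G products solved in one multi-right-hand-side
#' PCG call. `exact_quadform = FALSE` replaces M0 by sigma_e2*I in the
#' quadratic form only (a documented speed/accuracy trade; the numerator
#' x'Py is always exact).
#'
#' @param g A [genotype_matrix()], imputed.
#' @param y Phenotype vector aligned to `g`.
#' @param x_cov Covariate matrix.
#' @param k Kinship matrix.
#' @param null_fit A [fit_null_model()].
#' @param exact_quadform Use exact x'Px (default `TRUE`).
#' @return Data frame with one row per marker: `id`, `chrom`, `pos`,
#'   `index` (column in `g`), `t_score`, `t_std`, `p_value`, `degenerate`.
#' @export
score_scan <- function(g, y, x_cov, k, null_fit, exact_quadform = TRUE) {
  G <- g$dosages
  if (anyNA(G)) stop("genotypes contain missing values; impute first",
                     call. = FALSE)
  X <- as.matrix(x_cov)
  n <- nrow(G)
  m <- ncol(G)
  py <- project_phenotype(y, X, null_fit)
  xpy <- drop(crossprod(G, py))
  if (exact_quadform) {
    W <- as.matrix(null_fit$solver(G))        # M0^-1 G
    M0iX <- as.matrix(null_fit$solver(X))     # M0^-1 X
    S <- crossprod(X, M0iX)
    S <- (S + t(S)) / 2
    C <- crossprod(M0iX, G)                   # X' M0^-1 G  (c x m)
    xm0ix <- .colSums(G * W, n, m)
    corr <- .colSums(C * solve(S, C), nrow(C), m)
    xpx <- xm0ix - corr
  } else {
    # K-free approximation: M0 ~ sigma_e2 * I in the quadratic form
    se2 <- null_fit$sigma_e2
    xtx <- .colSums(G * G, n, m)
    XtG <- crossprod(X, G)
    xpx <- (xtx - .colSums(XtG * solve(crossprod(X), XtG), ncol(X), m)) / se2
  }
  xpx <- pmax(xpx, 0)
  degenerate <- xpx <= 1e-12
  t_std <- ifelse(degenerate, 0, xpy^2 / xpx)
  out <- data.frame(
    id = g$map$id, chrom = g$map$chrom, pos = g$map$pos,
    index = seq_len(m),
    t_score = 0.5 * xpy^2,
    t_std = t_std,
    p_value = ifelse(degenerate, 1,
                     stats::pchisq(t_std, df = 1, lower.tail = FALSE)),
    degenerate = degenerate,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Screen scan records with a lenient p-value cutoff
#'
#' Keeps markers with p-value at or below the threshold (inclusive; the
#' deliberately lenient pre-selection of a two-stage multi-locus method — no
#' Bonferroni correction at this stage). Records are ordered by ascending
#' p-value, ties broken by chromosome then position.
#'
#' @param records Scan data frame from [score_scan()].
#' @param p_threshold Screening cutoff (default 0.005).
#' @return Data frame of selected records with attribute `q` (the count);
#'   zero rows is a valid, empty screen set.
#' @export
screen_markers <- function(records, p_threshold = 0.005) {
  sel <- records[records$p_value <= p_threshold, , drop = FALSE]
  ord <- order(sel$p_value, sel$chrom, sel$pos)
  sel <- sel[ord, , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "q") <- nrow(sel)
  sel
}

#' Write scan results as tab-separated text
#'
#' Columns: `snp_id chrom pos t_score t_std p_value`.
#'
#' @param records Scan data frame.
#' @param path Output path.
#' @export
write_scan <- function(records, path) {
  out <- data.frame(snp_id = records$id, chrom = records$chrom,
                    pos = records$pos, t_score = records$t_score,
                    t_std = records$t_std, p_value = records$p_value,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(records)
}
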