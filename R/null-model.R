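#' Settings for the preconditioned conjugate gradient solver
#'
#' @param rel_tol Relative residual threshold (default `1e-8`).
#' @param max_iter Iteration cap; `NULL` means `10 * n`, chosen when the
#'   system size is known.
#' @param preconditioner `"jacobi"` (diagonal of M0) or `"none"`.
#' @return A list of class `"pcg_settings"`.
#' @export
pcg_settings <- function(rel_tol = 1e-8, max_iter = NULL,
                         preconditioner = c("jacobi", "none")) {
  stopifnot(rel_tol > 0, is.null(max_iter) || max_iter >= 1)
  structure(list(rel_tol = rel_tol, max_iter = max_iter,
                 preconditioner = match.arg(preconditioner)),
            class = "pcg_settings")
}

#' Apply the null covariance operator M0
#'
#' M0 = sigma_k2 * K + sigma_e2 * I, applied to a vector or to each column
#' of a matrix without forming M0.
#'
#' @param fit A [fit_null_model()] result, or a list with elements
#'   `sigma_k2` and `sigma_e2`.
#' @param k Kinship matrix.
#' @param v Numeric vector (length n) or n-row matrix.
#' @return `sigma_k2 * K %*% v + sigma_e2 * v`, same shape as `v`.
#' @export
apply_m0 <- function(fit, k, v) {
  v <- as.matrix(v)
  if (nrow(v) != nrow(k)) stop("shape mismatch between K and v", call. = FALSE)
  out <- fit$sigma_k2 * (k %*% v) + fit$sigma_e2 * v
  dimnames(out) <- NULL
  if (ncol(out) == 1L) drop(out) else out
}

#' Solve M0 w = v by preconditioned conjugate gradients
#'
#' Solves the symmetric positive-definite system (sigma_k2*K + sigma_e2*I) w
#' = v iteratively, using only matrix-vector products with K. Multiple
#' right-hand sides (a matrix `v`) are iterated simultaneously with
#' per-column step sizes, which keeps genome-wide solves fast.
#'
#' @param k Kinship matrix.
#' @param fit List with `sigma_k2`, `sigma_e2` (e.g. a [fit_null_model()]).
#' @param v Right-hand side vector or matrix.
#' @param settings A [pcg_settings()].
#' @return Solution of the same shape as `v`, with attributes `iterations`
#'   and `rel_resid` (the largest per-column relative residual).
#' @export
pcg_solve <- function(k, fit, v, settings = pcg_settings()) {
  was_vec <- is.null(dim(v))
  B <- as.matrix(v)
  n <- nrow(k)
  if (nrow(B) != n) stop("shape mismatch between K and v", call. = FALSE)
  max_iter <- if (is.null(settings$max_iter)) 10L * n else settings$max_iter
  if (fit$sigma_e2 <= 0)
    stop("sigma_e2 must be > 0 for an SPD M0", call. = FALSE)
  d <- if (settings$preconditioner == "jacobi")
    fit$sigma_k2 * diag(k) + fit$sigma_e2 else rep(1, n)
  if (any(d <= 0)) d <- pmax(d, .Machine$double.eps)

  amul <- function(M) fit$sigma_k2 * (k %*% M) + fit$sigma_e2 * M
  bnorm <- sqrt(.colSums(B * B, n, ncol(B)))
  X <- matrix(0, n, ncol(B))
  active <- bnorm > 0
  iters <- 0L
  if (any(active)) {
    R <- B
    Z <- R / d
    P <- Z
    rz <- .colSums(R * Z, n, ncol(B))
    for (it in seq_len(max_iter)) {
      AP <- amul(P)
      pap <- .colSums(P * AP, n, ncol(B))
      alpha <- ifelse(active & pap > 0, rz / pap, 0)
      X <- X + sweep(P, 2L, alpha, "*")
      R <- R - sweep(AP, 2L, alpha, "*")
      iters <- it
      res <- sqrt(.colSums(R * R, n, ncol(B)))
      active <- bnorm > 0 & res > settings$rel_tol * bnorm
      if (!any(active)) break
      Z <- R / d
      rz_new <- .colSums(R * Z, n, ncol(B))
      beta <- ifelse(rz > 0, rz_new / rz, 0)
      P <- Z + sweep(P, 2L, beta, "*")
      rz <- rz_new
    }
    rel <- max(ifelse(bnorm > 0,
                      sqrt(.colSums(R * R, n, ncol(B))) / pmax(bnorm, 1e-300),
                      0))
    if (any(active)) {
      cond <- simpleError(sprintf(
        "PCG did not converge in %d iterations (relative residual %.3g)",
        iters, rel))
      cond$best_iterate <- X
      cond$rel_resid <- rel
      class(cond) <- c("pcg_convergence_error", class(cond))
      stop(cond)
    }
  } else {
    rel <- 0
  }
  out <- if (was_vec) drop(X) else X
  attr(out, "iterations") <- iters
  attr(out, "rel_resid") <- rel
  out
}

#' Method-of-moments estimation of null variance components
#'
#' MINQUE(0) / Haseman–Elston-type estimator. With Q = I - X(X'X)^-1 X' and
#' e = Qy, the two moment equations
#' \deqn{tr(QKQK)\,\sigma_k^2 + tr(QK)\,\sigma_e^2 = e'Ke}
#' \deqn{tr(QK)\,\sigma_k^2 + (n-c)\,\sigma_e^2 = e'e}
#' are solved for (sigma_k2, sigma_e2). Negative solutions are truncated at
#' zero and the remaining one-dimensional moment equation re-solved; a
#' numerically singular system falls back to spectral REML. sigma_e2 is
#' floored at `1e-8 * var(y)` so that M0 stays positive definite.
#'
#' @param y Phenotype vector (aligned to `k`).
#' @param x_cov Covariate matrix including the intercept.
#' @param k Kinship matrix.
#' @return List with `sigma_k2`, `sigma_e2`, and a `diagnostics` list
#'   recording truncation and any REML fallback.
#' @export
estimate_null_variances <- function(y, x_cov, k) {
  n <- length(y)
  X <- as.matrix(x_cov)
  c_ <- ncol(X)
  xtx <- crossprod(X)
  if (rcond(xtx) < 1e-12)
    stop("covariate matrix is (near) rank deficient", call. = FALSE)
  beta_ols <- solve(xtx, crossprod(X, y))
  e <- y - drop(X %*% beta_ols)
  ete <- sum(e * e)
  if (ete <= 1e-12 * max(1, sum(y * y)))
    stop("phenotype has no residual variance after covariate adjustment",
         call. = FALSE)
  Ke <- drop(k %*% e)
  # QK = K - X (X'X)^-1 (X'K); traces of QK and (QK)^2 without any n^3 step
  XtK <- crossprod(X, k)
  QK <- k - X %*% solve(xtx, XtK)
  tr_qk <- sum(diag(QK))
  tr_qkqk <- sum(QK * t(QK))
  A <- matrix(c(tr_qkqk, tr_qk, tr_qk, n - c_), 2, 2)
  rhs <- c(sum(e * Ke), ete)
  diagnostics <- list(truncated = FALSE, fallback_reml = FALSE)
  if (abs(det(A)) < 1e-10 * max(1, tr_qkqk * (n - c_))) {
    est <- reml_null_variances(y, X, k)
    diagnostics$fallback_reml <- TRUE
    sig <- c(est$sigma_k2, est$sigma_e2)
  } else {
    sig <- solve(A, rhs)
    if (sig[1] < 0) {
      sig <- c(0, ete / (n - c_))
      diagnostics$truncated <- TRUE
    } else if (sig[2] < 0) {
      sig <- c(rhs[1] / tr_qkqk, 0)
      diagnostics$truncated <- TRUE
    }
  }
  floor_e <- 1e-8 * stats::var(y)
  if (sig[2] < floor_e) {
    sig[2] <- floor_e
    diagnostics$floored_sigma_e2 <- TRUE
  }
  list(sigma_k2 = max(sig[1], 0), sigma_e2 = sig[2],
       diagnostics = diagnostics)
}

#' Spectral REML estimation of the null variance components
#'
#' Exact restricted maximum likelihood by one eigendecomposition of the
#' kinship matrix and a one-dimensional profile over the variance ratio.
#' Used as a cross-check oracle for [estimate_null_variances()] and as its
#' fallback for singular moment systems; O(n^3), so intended for moderate n.
#'
#' @inheritParams estimate_null_variances
#' @return List with `sigma_k2`, `sigma_e2`, `loglik_restricted`.
#' @export
reml_null_variances <- function(y, x_cov, k) {
  n <- length(y)
  X <- as.matrix(x_cov)
  c_ <- ncol(X)
  # restrict to the residual space of X via QR, then diagonalize the
  # restricted kinship: covariance becomes sigma_k2*diag(lam) + sigma_e2*I
  qr_x <- qr(X)
  Qc <- qr.Q(qr_x, complete = TRUE)[, (c_ + 1L):n, drop = FALSE]
  Kr <- crossprod(Qc, k %*% Qc)
  eg <- eigen((Kr + t(Kr)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  z <- drop(crossprod(eg$vectors, crossprod(Qc, y)))
  nr <- n - c_
  neg_restricted_ll <- function(log_ratio) {
    r <- exp(log_ratio)           # sigma_k2 / sigma_e2
    w <- r * lam + 1
    s2 <- sum(z^2 / w) / nr       # profiled sigma_e2
    0.5 * (nr * log(s2) + sum(log(w)) + nr)
  }
  opt <- stats::optimize(neg_restricted_ll, c(-20, 20), tol = 1e-10)
  r <- exp(opt$minimum)
  w <- r * lam + 1
  sigma_e2 <- sum(z^2 / w) / nr
  list(sigma_k2 = r * sigma_e2, sigma_e2 = sigma_e2,
       loglik_restricted = -opt$objective - 0.5 * nr * log(2 * pi))
}

#' Generalized least squares fixed effects under M0
#'
#' Computes b_hat = (X' M0^-1 X)^-1 X' M0^-1 y, with every M0^-1 product
#' obtained from the supplied solver.
#'
#' @param y Phenotype vector.
#' @param x_cov Covariate matrix.
#' @param solver Function mapping an n-vector or n-row matrix v to M0^-1 v.
#' @return Named numeric vector of fixed-effect estimates.
#' @export
gls_bhat <- function(y, x_cov, solver) {
  X <- as.matrix(x_cov)
  M0iX <- as.matrix(solver(X))
  S <- crossprod(X, M0iX)
  S <- (S + t(S)) / 2
  if (rcond(S) < 1e-12)
    stop("X' M0^-1 X is singular (rank-deficient covariates)", call. = FALSE)
  drop(solve(S, crossprod(M0iX, y)))
}

#' Gaussian log-likelihood with a general covariance
#'
#' Evaluates -(n/2) log(2 pi) - (1/2) log|Sigma| - (1/2) r' Sigma^-1 r with
#' r = y - X b, for a dense positive-definite covariance matrix.
#'
#' @param y Phenotype vector.
#' @param x_cov Covariate matrix.
#' @param b Fixed-effect vector.
#' @param sigma Dense `n x n` positive-definite covariance matrix.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(y, x_cov, b, sigma) {
  n <- length(y)
  r <- y - drop(as.matrix(x_cov) %*% b)
  ch <- tryCatch(chol(sigma),
                 error = function(e) stop("covariance is not positive definite",
                                          call. = FALSE))
  quad <- sum(backsolve(ch, r, transpose = TRUE)^2)
  -(n / 2) * log(2 * pi) - sum(log(diag(ch))) - quad / 2
}

#' Fit the null linear mixed model
#'
#' Estimates (sigma_k2, sigma_e2) by the method of moments
#' ([estimate_null_variances()]), builds the M0 = sigma_k2*K + sigma_e2*I
#' solver contract (PCG), and computes the GLS fixed effects.
#'
#' @param y Phenotype vector, aligned to the kinship sample order.
#' @param x_cov Covariate matrix including the intercept.
#' @param k Kinship matrix.
#' @param settings A [pcg_settings()].
#' @return Object of class `"null_model_fit"`: `sigma_k2`, `sigma_e2`,
#'   `b_hat`, `solver` (function v -> M0^-1 v), and `diagnostics`
#'   (variance-component notes plus PCG iteration counts).
#' @export
fit_null_model <- function(y, x_cov, k, settings = pcg_settings()) {
  vc <- estimate_null_variances(y, x_cov, k)
  fit <- list(sigma_k2 = vc$sigma_k2, sigma_e2 = vc$sigma_e2)
  solver <- function(v) pcg_solve(k, fit, v, settings)
  b_hat <- gls_bhat(y, x_cov, solver)
  structure(list(sigma_k2 = vc$sigma_k2, sigma_e2 = vc$sigma_e2,
                 b_hat = b_hat, solver = solver, settings = settings,
                 diagnostics = vc$diagnostics),
            class = "null_model_fit")
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat("null LMM fit: sigma_k2 =", signif(x$sigma_k2, 5),
      " sigma_e2 =", signif(x$sigma_e2, 5), "\n")
  cat("fixed effects:", paste(signif(x$b_hat, 5), collapse = ", "), "\n")
  invisible(x)
}
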