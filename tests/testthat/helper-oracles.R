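# Independent dense oracles and small fixture builders. Everything here is
# deliberately written the slow, literal way (explicit inverses, per-marker
# loops) so the package's fast paths are checked against a separate route.

random_spd <- function(n, seed) {
  set.seed(seed)
  a <- matrix(rnorm(n * n), n)
  crossprod(a) / n + diag(n)
}

random_psd_kinship <- function(n, seed) {
  set.seed(seed)
  g <- matrix(rbinom(n * (2 * n), 2, 0.3), n)
  k <- tcrossprod(g) / ncol(g)
  dimnames(k) <- list(paste0("s", 1:n), paste0("s", 1:n))
  class(k) <- c("kinship_matrix", "matrix")
  k
}

small_geno <- function(dos, chrom = NULL, pos = NULL) {
  dos <- as.matrix(dos)
  if (is.null(rownames(dos))) rownames(dos) <- paste0("s", seq_len(nrow(dos)))
  if (is.null(colnames(dos))) colnames(dos) <- paste0("m", seq_len(ncol(dos)))
  map <- data.frame(id = colnames(dos),
                    chrom = if (is.null(chrom)) "1" else chrom,
                    pos = if (is.null(pos)) seq_len(ncol(dos)) * 1000L else pos,
                    stringsAsFactors = FALSE)
  genotype_matrix(dos, map)
}

dense_m0 <- function(k, sigma_k2, sigma_e2) {
  sigma_k2 * unclass(k) + sigma_e2 * diag(nrow(k))
}

# Explicit projection P = M0^-1 - M0^-1 X (X'M0^-1X)^-1 X'M0^-1
dense_projection <- function(m0, x) {
  m0i <- solve(m0)
  m0i - m0i %*% x %*% solve(t(x) %*% m0i %*% x) %*% t(x) %*% m0i
}

# Per-marker score statistics through the explicit dense P
dense_scan_oracle <- function(G, y, x, k, sigma_k2, sigma_e2) {
  P <- dense_projection(dense_m0(k, sigma_k2, sigma_e2), x)
  py <- P %*% y
  t(apply(G, 2, function(g1) {
    xpy <- drop(t(g1) %*% py)
    xpx <- drop(t(g1) %*% P %*% g1)
    c(t_score = 0.5 * xpy^2, t_std = xpy^2 / xpx,
      p_value = pchisq(xpy^2 / xpx, 1, lower.tail = FALSE))
  }))
}

# Literal-equation EM for the multi-locus shrinkage model, coded
# independently of the package: explicit solve() of the working covariance,
# per-marker loops, no Cholesky reuse. Runs a fixed number of cycles.
eb_em_oracle <- function(y, X, G, tau = 0, omega = 0, n_iter = 25) {
  n <- length(y)
  q <- ncol(G)
  b <- solve(t(X) %*% X) %*% t(X) %*% y
  se2 <- drop(t(y - X %*% b) %*% (y - X %*% b)) / n
  se2 <- max(se2, 1e-8 * var(y))
  s2 <- numeric(q)
  r0 <- y - X %*% b
  for (i in 1:q) {
    xi <- G[, i]
    s2[i] <- (drop(t(xi) %*% r0) / sum(xi^2))^2 + se2 / sum(xi^2)
  }
  eb <- numeric(q)
  for (it in 1:n_iter) {
    Sig <- diag(se2, n)
    for (i in 1:q) Sig <- Sig + G[, i] %*% t(G[, i]) * s2[i]
    Sigi <- solve(Sig)
    r <- y - X %*% b
    eb <- numeric(q)
    vb <- numeric(q)
    for (i in 1:q) {
      xi <- G[, i]
      eb[i] <- s2[i] * drop(t(xi) %*% Sigi %*% r)
      vb[i] <- max(s2[i] - s2[i] * drop(t(xi) %*% Sigi %*% xi) * s2[i], 0)
    }
    b <- solve(t(X) %*% Sigi %*% X) %*% t(X) %*% Sigi %*% y
    rn <- y - X %*% b
    fitted_g <- G %*% eb
    se2 <- max(drop(t(rn) %*% (rn - fitted_g)) / n, 1e-8 * var(y))
    for (i in 1:q) s2[i] <- (eb[i]^2 + vb[i] + omega) / (tau + 3)
  }
  # effect estimates evaluated at the final parameter values
  Sig <- diag(se2, n)
  for (i in 1:q) Sig <- Sig + G[, i] %*% t(G[, i]) * s2[i]
  Sigi <- solve(Sig)
  r <- y - X %*% b
  for (i in 1:q) eb[i] <- s2[i] * drop(t(G[, i]) %*% Sigi %*% r)
  list(b = drop(b), sigma_e2 = se2, sigma_i2 = s2, beta = eb)
}

# Draw a polygenic + noise phenotype under known variance components
draw_null_phenotype <- function(k, sigma_k2, sigma_e2, mu = 10, seed = 1) {
  set.seed(seed)
  n <- nrow(k)
  eg <- eigen(unclass(k), symmetric = TRUE)
  u <- drop(eg$vectors %*% (sqrt(pmax(eg$values, 0) * sigma_k2) * rnorm(n)))
  mu + u + rnorm(n, 0, sqrt(sigma_e2))
}
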