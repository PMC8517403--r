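test_that("apply_m0 reduces to the identity in its limits and matches dense", {
  k5 <- random_psd_kinship(5, 11)
  v <- c(1, 0, 0, 0, 0)
  expect_equal(apply_m0(list(sigma_k2 = 0, sigma_e2 = 1), k5, v), v)
  expect_equal(apply_m0(list(sigma_k2 = 1, sigma_e2 = 0),
                        diag(5), 5:1), 5:1)
  fit <- list(sigma_k2 = 2, sigma_e2 = 10)
  expect_equal(apply_m0(fit, k5, v),
               unname(drop(dense_m0(k5, 2, 10) %*% v)), tolerance = 1e-12)
})

test_that("PCG solves diagonal systems in <= 2 iterations and zero rhs in 0", {
  kd <- diag(c(1, 2, 3, 4))
  fit <- list(sigma_k2 = 1, sigma_e2 = 0.5)
  v <- c(4, 3, 2, 1)
  w <- pcg_solve(kd, fit, v)
  expect_equal(unname(as.numeric(w)), v / (diag(kd) + 0.5), tolerance = 1e-10)
  expect_lte(attr(w, "iterations"), 2L)
  z <- pcg_solve(kd, fit, rep(0, 4))
  expect_equal(unname(as.numeric(z)), rep(0, 4))
  expect_equal(attr(z, "iterations"), 0L)
})

test_that("PCG agrees with dense solves on random SPD systems", {
  for (seed in 1:8) {
    n <- sample(5:50, 1)
    k <- random_spd(n, seed)
    fit <- list(sigma_k2 = runif(1, 0.5, 3), sigma_e2 = runif(1, 0.5, 3))
    b <- rnorm(n)
    w <- pcg_solve(k, fit, b)
    w_dense <- solve(dense_m0(k, fit$sigma_k2, fit$sigma_e2), b)
    expect_lt(max(abs(w - w_dense)), 1e-8)
  }
})

test_that("PCG handles matrix right-hand sides column-consistently", {
  k <- random_spd(20, 77)
  fit <- list(sigma_k2 = 2, sigma_e2 = 10)
  B <- matrix(rnorm(20 * 6), 20)
  B[, 3] <- 0  # a zero column must come back zero
  W <- pcg_solve(k, fit, B)
  W_dense <- solve(dense_m0(k, 2, 10), B)
  expect_lt(max(abs(W - W_dense)), 1e-8)
  expect_equal(unname(W[, 3]), rep(0, 20))
})

test_that("PCG reports non-convergence with the best iterate attached", {
  k <- random_spd(30, 5)
  fit <- list(sigma_k2 = 1, sigma_e2 = 1)
  err <- tryCatch(
    pcg_solve(k, fit, rnorm(30), pcg_settings(rel_tol = 1e-14, max_iter = 1L)),
    pcg_convergence_error = function(e) e)
  expect_s3_class(err, "pcg_convergence_error")
  expect_length(err$best_iterate, 30)
  expect_true(is.finite(err$rel_resid))
})

test_that("GLS fixed effects match weighted-mean arithmetic", {
  # identity covariance: OLS mean
  id_solver <- function(v) v
  expect_equal(unname(gls_bhat(c(1, 2, 3), matrix(1, 3, 1), id_solver)), 2)
  # diag(1,1,4) covariance: weights (1,1,1/4) -> (1 + 2 + 6/4)/(2.25) = 2
  d_solver <- function(v) v / c(1, 1, 4)
  expect_equal(unname(gls_bhat(c(1, 2, 6), matrix(1, 3, 1), d_solver)), 2,
               tolerance = 1e-12)
  # duplicated covariate column -> rank error
  X_bad <- cbind(1, c(0, 1, 2), c(0, 1, 2))
  expect_error(gls_bhat(c(1, 2, 3), X_bad, id_solver), "singular")
})

test_that("GLS is invariant to rescaling the covariance", {
  k <- random_spd(12, 9)
  X <- cbind(1, rnorm(12))
  y <- rnorm(12)
  b1 <- gls_bhat(y, X, function(v) solve(dense_m0(k, 2, 10), v))
  b2 <- gls_bhat(y, X, function(v) solve(dense_m0(k, 2, 10) * 7, v))
  expect_equal(b1, b2, tolerance = 1e-9)
})

test_that("Gaussian log-likelihood matches closed forms", {
  expect_equal(log_likelihood(c(1, 2), matrix(1, 2, 1), 0, diag(2)),
               -log(2 * pi) - 0.5 * sum(c(1, 2)^2))
  # zero residual, identity covariance, n = 2
  expect_equal(log_likelihood(c(3, 4), cbind(c(3, 4)), 1, diag(2)),
               -log(2 * pi), tolerance = 1e-12)
  # n = 1, variance 4, residual 2
  expect_equal(log_likelihood(2, matrix(0, 1, 1), 0, matrix(4)),
               -0.5 * log(2 * pi) - 0.5 * log(4) - 0.5,
               tolerance = 1e-12)
  expect_error(log_likelihood(c(1, 2), matrix(1, 2, 1), 0,
                              matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("scaling the covariance traces the 1-D profile optimum", {
  set.seed(4)
  n <- 8
  y <- rnorm(n)
  X <- matrix(1, n, 1)
  sig <- random_spd(n, 21)
  quad <- drop(t(y - mean(y)) %*% solve(sig, y - mean(y)))
  ll <- function(t) log_likelihood(y, X, mean(y), t * sig)
  t_star <- quad / n
  expect_gt(ll(t_star), ll(t_star * 1.3))
  expect_gt(ll(t_star), ll(t_star / 1.3))
  # concavity along the ray near the optimum
  ts <- t_star * c(0.8, 1, 1.25)
  vals <- vapply(ts, ll, numeric(1))
  expect_true(vals[2] > vals[1] && vals[2] > vals[3])
})

test_that("moment estimator recovers variance components on average", {
  est <- sapply(1:12, function(s) {
    g <- simulate_genotypes(300, 600, seed = 400 + s)
    k <- compute_kinship(g)
    y <- draw_null_phenotype(k, sigma_k2 = 2, sigma_e2 = 10, seed = 700 + s)
    vc <- estimate_null_variances(y, matrix(1, 300, 1), k)
    c(vc$sigma_k2, vc$sigma_e2)
  })
  mu <- rowMeans(est)
  expect_lt(abs(mu[2] - 10) / 10, 0.25)
  expect_lt(abs(mu[1] - 2), 2.5)  # high-variance component at this n
})

test_that("pure-noise phenotypes give near-zero polygenic variance", {
  hits <- sapply(1:20, function(s) {
    g <- simulate_genotypes(1000, 500, seed = 900 + s)
    k <- compute_kinship(g)
    set.seed(1300 + s)
    y <- rnorm(1000)
    vc <- estimate_null_variances(y, matrix(1, 1000, 1), k)
    vc$sigma_k2
  })
  expect_gte(mean(hits <= 0.1), 0.9)
})

test_that("degenerate phenotypes and REML cross-check behave", {
  k <- random_psd_kinship(20, 2)
  X <- cbind(1, rnorm(20))
  expect_error(estimate_null_variances(drop(X %*% c(2, 3)), X, k),
               "no residual variance")
  # REML oracle close to moment estimates on a well-posed draw
  g <- simulate_genotypes(250, 500, seed = 31)
  kk <- compute_kinship(g)
  y <- draw_null_phenotype(kk, 2, 10, seed = 32)
  mom <- estimate_null_variances(y, matrix(1, 250, 1), kk)
  reml <- reml_null_variances(y, matrix(1, 250, 1), kk)
  expect_lt(abs(mom$sigma_e2 - reml$sigma_e2), 3)
  expect_true(is.finite(reml$loglik_restricted))
})

test_that("fit_null_model's solver contract inverts M0", {
  g <- simulate_genotypes(60, 120, seed = 8)
  k <- compute_kinship(g)
  y <- draw_null_phenotype(k, 2, 10, seed = 9)
  fit <- fit_null_model(y, matrix(1, 60, 1), k)
  v <- rnorm(60)
  w <- fit$solver(v)
  back <- apply_m0(fit, k, as.numeric(w))
  expect_lt(sqrt(sum((back - v)^2)) / sqrt(sum(v^2)), 1e-6)
})
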