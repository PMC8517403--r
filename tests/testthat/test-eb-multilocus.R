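test_that("EB initial values follow the least-squares formulas", {
  y <- c(1, 2, 3)
  X <- matrix(1, 3, 1)
  G <- cbind(m1 = c(0, 1, 2))
  init <- eb_initialize(y, X, G)
  expect_equal(unname(init$b), 2)
  expect_equal(init$sigma_e2, 2 / 3)
  expect_equal(unname(init$sigma_i2), (2 / 5)^2 + (1 / 5) * (2 / 3),
               tolerance = 1e-12)
  # perfect fit -> floored residual variance
  init2 <- eb_initialize(c(2, 2, 2), X, G)
  expect_gt(init2$sigma_e2, 0)
  # all-zero marker dropped with a warning
  expect_warning(init3 <- eb_initialize(y, X, cbind(z = c(0, 0, 0), G)),
                 "dropped")
  expect_identical(unname(init3$keep), c(FALSE, TRUE))
})

test_that("EM trajectory matches the literal-equation oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(10:20, 1)
    q <- sample(2:5, 1)
    G <- matrix(rbinom(n * q, 2, 0.35), n, q)
    G <- G[, colSums(G) > 0, drop = FALSE]
    q <- ncol(G)
    X <- cbind(rep(1, n))
    y <- rnorm(n, 1 + G %*% rnorm(q, 0, 0.5), 1)
    n_iter <- 25L
    oracle <- eb_em_oracle(y, X, G, n_iter = n_iter)
    fit <- suppressWarnings(
      eb_fit(y, X, G, eb_config(conv_tol = 1e-300, max_iter = n_iter)))
    expect_lt(abs(fit$sigma_e2 - oracle$sigma_e2), 1e-8)
    expect_lt(max(abs(fit$b - oracle$b)), 1e-8)
    expect_lt(max(abs(unname(fit$sigma_i2) - oracle$sigma_i2)), 1e-8)
    expect_lt(max(abs(unname(fit$beta_hat) - oracle$beta)), 1e-8)
  }
})

test_that("a converged fit is a fixed point of one extra EM cycle", {
  set.seed(10)
  n <- 60
  G <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
  y <- rnorm(n, 2 + G[, 1] * 1.5, 1)
  X <- matrix(1, n, 1)
  cfg <- eb_config(conv_tol = 1e-8, max_iter = 2000)
  fit <- eb_fit(y, X, G, cfg)
  expect_true(fit$converged)
  refit <- suppressWarnings(
    eb_fit(y, X, G, eb_config(conv_tol = 1e-300,
                              max_iter = fit$iterations + 1L)))
  expect_lt(max(abs(refit$sigma_i2 - fit$sigma_i2) /
                (fit$sigma_i2 + 1e-10)), 1e-5)
  expect_lt(abs(refit$sigma_e2 - fit$sigma_e2) / fit$sigma_e2, 1e-5)
})

test_that("a strong single-QTN effect is recovered", {
  hits <- sapply(1:20, function(s) {
    set.seed(3000 + s)
    n <- 500
    x <- rbinom(n, 2, 0.3)
    y <- 10 + 2 * x + rnorm(n, 0, 1)
    fit <- eb_fit(y, matrix(1, n, 1), cbind(q1 = x))
    abs(fit$beta_hat[["q1"]] - 2)
  })
  expect_gte(mean(hits < 0.2), 0.9)
})

test_that("pure-noise phenotypes shrink all effects toward zero", {
  frac_ok <- sapply(1:10, function(s) {
    set.seed(4000 + s)
    n <- 200
    G <- matrix(rbinom(n * 20, 2, 0.3), n, 20)
    y <- rnorm(n)
    fit <- eb_fit(y, matrix(1, n, 1), G)
    all(abs(fit$beta_hat) < 0.05)
  })
  expect_gte(mean(frac_ok), 0.9)
})

test_that("inflating the noise variance never strengthens shrunken effects", {
  set.seed(20)
  n <- 80
  G <- matrix(rbinom(n * 4, 2, 0.3), n, 4)
  base <- 5 + drop(G %*% c(1, 0.5, 0, 0))
  noise <- rnorm(n)
  f_small <- eb_fit(base + 0.5 * noise, matrix(1, n, 1), G)
  f_big <- eb_fit(base + 4 * noise, matrix(1, n, 1), G)
  expect_lt(mean(abs(f_big$beta_hat)), mean(abs(f_small$beta_hat)) + 1e-8)
})

test_that("with a diffuse prior the single-marker fit approaches GLS", {
  set.seed(30)
  n <- 40
  x <- rbinom(n, 2, 0.4)
  y <- 1 + 0.8 * x + rnorm(n, 0, 0.5)
  X <- matrix(1, n, 1)
  # fixed-effect (OLS) estimate of the marker given the intercept
  ols <- coef(lm(y ~ x))[["x"]]
  # one E-step with an enormous prior variance
  s2 <- 1e8
  Sig <- tcrossprod(x) * s2 + diag(n) * 0.25
  b <- drop(solve(t(X) %*% solve(Sig, X), t(X) %*% solve(Sig, y)))
  beta_limit <- s2 * drop(t(x) %*% solve(Sig, y - X %*% b))
  expect_lt(abs(beta_limit - ols), 0.05)
})

test_that("likelihood-ratio statistics obey the LOD scaling and edge cases", {
  set.seed(40)
  n <- 100
  x <- rbinom(n, 2, 0.3)
  y <- 10 + 1.2 * x + rnorm(n, 0, 1)
  fit <- eb_fit(y, matrix(1, n, 1), cbind(q1 = x))
  lrt <- eb_likelihood_ratio(fit, 1)
  expect_equal(lrt$lod, lrt$lr / 4.605)
  expect_equal(lrt$p_value, pchisq(lrt$lr, 1, lower.tail = FALSE))
  expect_gte(lrt$lr, 0)
  # LR = 13.815 corresponds exactly to LOD = 3.0
  expect_equal(13.815 / 4.605, 3.0, tolerance = 1e-12)
})

test_that("a perfect single-marker fit triggers the documented LR cap", {
  n <- 4
  r <- c(1, -1, 1, -1)
  # build a fit object around the degenerate geometry by hand
  fit <- structure(list(
    b = 0, sigma_e2 = 1e-8,
    beta_hat = c(q1 = 1), sigma_i2 = c(q1 = 1), iterations = 1L,
    converged = TRUE, config = eb_config(),
    y = r, x_cov = matrix(1, n, 1), g_sel = cbind(q1 = r)),
    class = "eb_model_fit")
  expect_warning(lrt <- eb_likelihood_ratio(fit, 1), "capped")
  expect_equal(lrt$lr, n * log(1e12), tolerance = 1e-6)
})

test_that("QTN calling enforces both the effect floor and the LOD cutoff", {
  fit <- structure(list(
    beta_hat = c(a = 1e-5, b = 0.5, c = 0.4),
    config = eb_config()), class = "eb_model_fit")
  lrt <- data.frame(id = c("b", "c"), effect = c(0.5, 0.4),
                    lr = c(3.1, 2.9) * 4.605, lod = c(3.1, 2.9),
                    p_value = c(1e-4, 2e-4), stringsAsFactors = FALSE)
  calls <- call_qtns(fit, lrt, lod_threshold = 3.0)
  expect_identical(calls$id, "b")
  # marker "a" is below the effect floor: never eligible for testing
  fit2 <- structure(list(
    b = 0, sigma_e2 = 1, beta_hat = c(a = 1e-5), sigma_i2 = c(a = 1),
    iterations = 1L, converged = TRUE, config = eb_config(),
    y = rnorm(5), x_cov = matrix(1, 5, 1), g_sel = cbind(a = rep(1, 5))),
    class = "eb_model_fit")
  expect_error(eb_likelihood_ratio(fit2, 1), "effect_floor")
  expect_equal(nrow(eb_lrt_all(fit2)), 0L)
  expect_equal(nrow(call_qtns(fit2)), 0L)
})

test_that("cross-validation picks the exhaustive-grid optimum, ties to (0,0)", {
  set.seed(50)
  n <- 120
  G <- matrix(rbinom(n * 4, 2, 0.3), n, 4)
  colnames(G) <- paste0("g", 1:4)
  y <- 5 + drop(G %*% c(1, 0, 0.5, 0)) + rnorm(n)
  X <- matrix(1, n, 1)
  single <- cv_select_hyperparams(y, X, G, list(c(0, 0)), seed = 7)
  expect_equal(c(single$tau, single$omega), c(0, 0))
  grid <- list(c(0, 0), c(0.5, 0), c(1, 0))
  res <- cv_select_hyperparams(y, X, G, grid, seed = 7)
  expect_equal(unname(res$cv_errors[paste0("tau=", res$tau, ",omega=",
                                           res$omega)]),
               min(res$cv_errors))
  expect_length(res$cv_errors, 3L)
})
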