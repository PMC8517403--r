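#' Specify a simulation design
#'
#' Describes a synthetic quantitative-trait experiment: n individuals,
#' m independent biallelic markers, a set of QTNs with per-QTN
#' heritabilities, a grand mean, residual variance, and an optional
#' polygenic background with covariance `sigma_k2 * K`.
#'
#' The default QTN set mirrors a standard benchmarking layout: six QTNs at
#' MAF 0.30 with heritabilities 0.10, 0.15, 0.05, 0.05, 0.05, 0.05 (total
#' 0.45), grand mean 10, residual variance 10, polygenic variance 2
#' (`sigma_k2 = 0` disables the polygene).
#'
#' @param n Number of individuals.
#' @param m Number of markers.
#' @param qtns Data frame with columns `h2` and `maf` (optionally `index`,
#'   `effect`); defaults to the six-QTN layout above.
#' @param mu Grand mean (default 10).
#' @param sigma_e2 Residual variance (default 10).
#' @param sigma_k2 Polygenic variance (default 2; 0 disables).
#' @param spacing_bp Base-pair spacing between adjacent markers (default
#'   5000, so a +/-1000 bp evaluation window isolates single markers).
#' @return A list of class `"simulation_design"`.
#' @seealso [derive_design()], [simulate_genotypes()],
#'   [simulate_phenotype()]
#' @export
simulation_design <- function(n, m,
                              qtns = data.frame(
                                h2 = c(0.10, 0.15, 0.05, 0.05, 0.05, 0.05),
                                maf = 0.30),
                              mu = 10.0, sigma_e2 = 10.0, sigma_k2 = 2.0,
                              spacing_bp = 5000L) {
  qtns <- as.data.frame(qtns)
  stopifnot(n >= 2, m >= 1, sigma_e2 >= 0, sigma_k2 >= 0,
            all(qtns$h2 > 0), all(qtns$h2 < 1),
            all(qtns$maf > 0), all(qtns$maf <= 0.5))
  if (sum(qtns$h2) >= 1)
    stop("summed QTN heritability must be < 1", call. = FALSE)
  if (is.null(qtns$index)) qtns$index <- NA_integer_
  if (is.null(qtns$effect)) qtns$effect <- NA_real_
  structure(list(n = as.integer(n), m = as.integer(m), qtns = qtns,
                 mu = mu, sigma_e2 = sigma_e2, sigma_k2 = sigma_k2,
                 spacing_bp = as.integer(spacing_bp)),
            class = "simulation_design")
}

#' Fill in the derived quantities of a simulation design
#'
#' From the heritability identity `h_t2 = sigma_g2 / (sigma_g2 + sigma_e2 +
#' sigma_k2)` with `h_t2 = sum(h_i2)`, solves for the total genetic variance
#' `sigma_g2` and the polygenic heritability `h_k2 = sigma_k2 / (sigma_g2 +
#' sigma_e2 + sigma_k2)`, and derives each QTN's true additive effect
#' \deqn{\beta_i = \sqrt{\left[\frac{h_t^2(\sigma_e^2+\sigma_k^2)}{1-h_t^2}
#'   + \sigma_e^2 + \sigma_k^2\right] \frac{h_i^2}{4\eta_i(1-\eta_i)}}}
#' where `eta_i` is the QTN's MAF. Effects already present in `qtns$effect`
#' are kept (so externally tabulated effects can be replayed exactly).
#' QTN marker indices, if unset, are placed evenly across the panel.
#'
#' All outputs are deterministic functions of the design.
#'
#' @param design A [simulation_design()].
#' @return The design with `sigma_g2`, `h_t2`, `h_k2` filled and
#'   `qtns$effect`, `qtns$index` completed.
#' @export
derive_design <- function(design) {
  h_t2 <- sum(design$qtns$h2)
  if (h_t2 >= 1) stop("summed QTN heritability must be < 1", call. = FALSE)
  s_ek <- design$sigma_e2 + design$sigma_k2
  sigma_g2 <- h_t2 * s_ek / (1 - h_t2)
  total_var <- sigma_g2 + s_ek
  eta <- design$qtns$maf
  eff <- sqrt(total_var * design$qtns$h2 / (4 * eta * (1 - eta)))
  missing_eff <- is.na(design$qtns$effect)
  design$qtns$effect[missing_eff] <- eff[missing_eff]
  if (anyNA(design$qtns$index)) {
    k <- nrow(design$qtns)
    design$qtns$index <- as.integer(round(seq(1, design$m,
                                              length.out = k + 2)))[2:(k + 1)]
  }
  if (any(design$qtns$index < 1 | design$qtns$index > design$m))
    stop("QTN index out of marker range", call. = FALSE)
  design$sigma_g2 <- sigma_g2
  design$h_t2 <- h_t2
  design$h_k2 <- design$sigma_k2 / total_var
  design
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("simulation design:", x$n, "samples x", x$m, "markers,",
      nrow(x$qtns), "QTNs (total h2 =", sum(x$qtns$h2), ")\n")
  cat("mu =", x$mu, " sigma_e2 =", x$sigma_e2, " sigma_k2 =", x$sigma_k2, "\n")
  invisible(x)
}

#' Simulate an independent-marker genotype panel
#'
#' Dosages are Binomial(2, p) per marker under Hardy-Weinberg, with p drawn
#' from `maf_sampler` (a fixed number, a numeric vector recycled over
#' markers, or a `function(m)`). Markers sit on one chromosome at evenly
#' spaced positions. `ld_rho > 0` adds a first-order Markov dependence
#' between adjacent markers: each haplotype allele copies its left
#' neighbour with probability `ld_rho`, otherwise draws fresh, inducing
#' adjacent-marker correlation of about `ld_rho` when frequencies are
#' similar.
#'
#' @param n Samples.
#' @param m Markers.
#' @param maf_sampler Allele frequency specification (default 0.30).
#' @param seed Integer seed (reproducible draws).
#' @param spacing_bp Position spacing (default 5000).
#' @param ld_rho Adjacent-marker copy probability in `[0, 1)` (default 0,
#'   i.e. linkage-equilibrium markers).
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, m, maf_sampler = 0.30, seed = 1L,
                               spacing_bp = 5000L, ld_rho = 0) {
  set.seed(seed)
  p <- if (is.function(maf_sampler)) maf_sampler(m)
       else rep_len(as.numeric(maf_sampler), m)
  stopifnot(all(p > 0), all(p < 1), ld_rho >= 0, ld_rho < 1)
  if (ld_rho == 0) {
    dos <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
  } else {
    hap <- function() {
      h <- matrix(0L, n, m)
      h[, 1] <- stats::rbinom(n, 1L, p[1])
      for (j in seq_len(m)[-1]) {
        copy <- stats::runif(n) < ld_rho
        h[, j] <- ifelse(copy, h[, j - 1], stats::rbinom(n, 1L, p[j]))
      }
      h
    }
    dos <- hap() + hap()
  }
  rownames(dos) <- paste0("s", seq_len(n))
  colnames(dos) <- paste0("m", seq_len(m))
  map <- data.frame(id = colnames(dos), chrom = "1",
                    pos = as.integer(seq_len(m)) * as.integer(spacing_bp),
                    stringsAsFactors = FALSE)
  genotype_matrix(dos, map)
}

#' Simulate a phenotype from a derived design
#'
#' Generates `y = mu + sum_i x_i beta_i + u + e` on the raw 0/1/2 dosages,
#' with polygenic effect `u ~ MVN(0, sigma_k2 * K)` (omitted when
#' `sigma_k2 = 0`) and residual `e ~ MVN(0, sigma_e2 * I)`. The polygenic
#' draw factorizes K by eigendecomposition with negative eigenvalues
#' clamped at zero, so any positive semi-definite kinship is accepted.
#'
#' @param g A [genotype_matrix()] holding the QTN columns.
#' @param design A derived [simulation_design()] (see [derive_design()]).
#' @param k Kinship matrix; required when `design$sigma_k2 > 0`.
#' @param seed Integer seed.
#' @return Named numeric phenotype vector with attribute `genetic_values`
#'   (the noiseless QTN part `sum_i x_i beta_i`).
#' @export
simulate_phenotype <- function(g, design, k = NULL, seed = 1L) {
  if (is.null(design$sigma_g2))
    design <- derive_design(design)
  qt <- design$qtns
  if (any(qt$index > ncol(g$dosages)))
    stop("QTN index out of range for this genotype panel", call. = FALSE)
  n <- nrow(g$dosages)
  gv <- drop(g$dosages[, qt$index, drop = FALSE] %*% qt$effect)
  set.seed(seed)
  u <- 0
  if (design$sigma_k2 > 0) {
    if (is.null(k))
      stop("a kinship matrix is required when sigma_k2 > 0", call. = FALSE)
    eg <- eigen(unclass(k), symmetric = TRUE)
    scale_ <- sqrt(pmax(eg$values, 0) * design$sigma_k2)
    u <- drop(eg$vectors %*% (scale_ * stats::rnorm(n)))
  }
  e <- if (design$sigma_e2 > 0)
    stats::rnorm(n, 0, sqrt(design$sigma_e2)) else 0
  y <- design$mu + gv + u + e
  names(y) <- rownames(g$dosages)
  attr(y, "genetic_values") <- gv
  y
}
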