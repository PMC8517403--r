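---
title: "Two-stage multi-locus association mapping: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage multi-locus association mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebscan)
```

## The model

`ebscan` maps quantitative trait nucleotides (QTNs) in two stages. Stage
one works under the single-marker linear mixed model

$$y = Xb + x\beta + u + \varepsilon,\qquad
u \sim \mathrm{MVN}(0,\ \sigma_k^2 K),\quad
\varepsilon \sim \mathrm{MVN}(0,\ \sigma_e^2 I_n),$$

where $y$ is the $n$-vector of trait values, $X$ the $n\times c$ fixed
covariates (intercept, optionally population-structure covariates or
genotype principal components), $x$ the additive dosage of the focal
marker (0/1/2 copies of the counted allele), and $u$ a polygenic effect
whose covariance is proportional to the marker-inferred relatedness
matrix $K = \tfrac1m GG^{\mathsf T}$. Treating $\beta$ as random,
$\beta\sim N(0,\sigma_g^2)$, marker association is the variance-component
hypothesis $\sigma_g^2>0$, which a score test assesses using only the
null-model fit:

$$T_{\text{score}} = \tfrac12 (x^{\mathsf T} P y)^2, \qquad
P = M_0^{-1} - M_0^{-1}X(X^{\mathsf T}M_0^{-1}X)^{-1}X^{\mathsf T}M_0^{-1},
\qquad M_0 = \hat\sigma_k^2 K + \hat\sigma_e^2 I.$$

Because $\operatorname{Var}(x^{\mathsf T}Py) = x^{\mathsf T}Px$ under the
null, the standardized statistic
$t_{\text{std}} = (x^{\mathsf T}Py)^2 / (x^{\mathsf T}Px)$ is exactly
$\chi^2_1$; this is the single-weight case of the weighted-$\chi^2$
distribution of the raw statistic (whose weight is
$\tfrac12 x^{\mathsf T}Px$), so no general mixture algorithm is needed.
Both forms are reported per marker; p-values come from $t_{\text{std}}$.
Markers with $p \le 0.005$ (inclusive) are screened into stage two — a
deliberately lenient cut with no multiplicity correction, because stage
two, not the screen, decides significance.

Stage two places all $q$ screened markers in one model,
$y = Xb + \sum_{i=1}^q x_i\beta_i + \varepsilon$, with a hierarchical
prior $\beta_i \sim N(0, \sigma_i^2)$ and
$p(\sigma_i^2\mid\tau,\omega) \propto
(\sigma_i^2)^{-(\tau+2)/2}\exp(-\omega/2\sigma_i^2)$. An EM algorithm
estimates every $\sigma_i^2$ from the data (empirical Bayes):

* initialisation: $b=(X^{\mathsf T}X)^{-1}X^{\mathsf T}y$,
  $\sigma_e^2=\tfrac1n\lVert y-Xb\rVert^2$,
  $\sigma_i^2=[(x_i^{\mathsf T}x_i)^{-1}x_i^{\mathsf T}(y-Xb)]^2
  +(x_i^{\mathsf T}x_i)^{-1}\sigma_e^2$;
* E-step: $\mathrm E(\beta_i)=\sigma_i^2 x_i^{\mathsf T}\Sigma^{-1}(y-Xb)$
  with $\Sigma=\sum_i x_i x_i^{\mathsf T}\sigma_i^2+I\sigma_e^2$;
* M-step: GLS update of $b$, residual update of $\sigma_e^2$, and
  $\sigma_i^2 \leftarrow (\mathrm E(\beta_i^2)+\omega)/(\tau+3)$, where
  $\mathrm E(\beta_i^2)$ adds the posterior variance
  $\sigma_i^2-\sigma_i^2 x_i^{\mathsf T}\Sigma^{-1}x_i\sigma_i^2$.

With the Jeffreys prior $(\tau,\omega)=(0,0)$ — the default, and the
choice a five-fold cross-validation over a user grid can revisit via
`cv_select_hyperparams()` — the update drives weakly supported
$\sigma_i^2$ to zero, so most chance-screened markers leave the model.
Markers with $|\hat\beta_i| \le 10^{-4}$ are excluded; the rest are
tested by a likelihood-ratio test and called at LOD $= \mathrm{LR}/4.605
\ge 3$, equivalent to a $\chi^2_1$ tail probability of about
$2\times10^{-4}$.

## Algorithmic choices

**Variance components by the method of moments.** The null components
$(\sigma_k^2,\sigma_e^2)$ come from the MINQUE(0)/Haseman–Elston linear
system in `estimate_null_variances()`: with $Q = I - X(X^{\mathsf T}
X)^{-1}X^{\mathsf T}$ and $e=Qy$, solve
$\{tr(QKQK)\sigma_k^2 + tr(QK)\sigma_e^2 = e^{\mathsf T}Ke;\;
tr(QK)\sigma_k^2 + (n-c)\sigma_e^2 = e^{\mathsf T}e\}$, truncating
negative solutions at zero. It is closed-form, deterministic, unbiased,
and needs no eigendecomposition ($tr(QKQK)$ is computed from $QK$ alone,
so the cost is $O(n^2 c)$ beyond one $n\times n$ product). Exact spectral
REML (`reml_null_variances()`) is provided as a cross-check and as the
fallback for numerically singular moment systems. $\sigma_e^2$ is floored
at $10^{-8}\operatorname{Var}(y)$ so $M_0$ stays positive definite.

**Conjugate gradients.** All $M_0^{-1}v$ products use Jacobi-preconditioned
CG (`pcg_solve()`): $M_0$ is symmetric positive definite and diagonally
dominated by $\sigma_e^2$, so the diagonal preconditioner is cheap and
effective. Defaults: relative residual $10^{-8}$, cap $10n$ iterations;
non-convergence raises a typed condition carrying the best iterate.
Matrix right-hand sides are iterated simultaneously with per-column step
sizes, which is what makes the exact per-marker quadratic form
$x^{\mathsf T}Px$ affordable genome-wide (one multi-column solve of
$M_0^{-1}G$). A documented fast mode replaces $M_0$ by
$\sigma_e^2 I$ in the quadratic form only; it is off by default because
exactness is cheap at the package's target sizes.

**EM convergence.** The EM stops when the maximum relative change of
$(b, \sigma_e^2, \text{all } \sigma_i^2)$ falls below $10^{-6}$
(cap 1000 iterations) — tight enough that reported LOD scores are stable
to three decimals on the package's fixtures. $\Sigma$ is built and
Cholesky-factorized once per iteration and reused across markers, giving
the $O(t\,q\,n^2)$ second stage its expected cost. Posterior effect
means are re-evaluated at the final parameter values. Exact zeros of
$\sigma_i^2$ are allowed: they implement the shrinkage-to-exclusion the
method relies on.

**The likelihood-ratio test is evaluated at the shrunken estimate.** The
LOD for marker $i$ compares the covariate-adjusted residual sum of
squares of $y$ with that of $y - x_i\hat\beta_i$, fixed effects refit
under both hypotheses and the error variance profiled out:
$\mathrm{LR} = n\log(\mathrm{RSS}_0/\mathrm{RSS}_1)$, clamped at 0 and
capped (RSS$_1$ floored at $10^{-12}\mathrm{RSS}_0$) for degenerate
perfect fits. Two alternatives were considered and rejected during
design. Refitting $\beta_i$ by least squares inside the test discards
the shrinkage exactly where it matters, and conditioning the baseline on
the other retained (jointly overfit) screened effects deflates
$\mathrm{RSS}_0$; either way markers screened by chance acquire inflated
LOD scores, and permuted-phenotype panels acquire spurious calls. With
the shrunken-estimate construction the permutation null yields a median
of zero calls (the acceptance suite computes this), which is the
property that justifies running stage two without any multiple-testing
correction. Re-absorbing the marker's allele-frequency mean component
into the intercept under both hypotheses matters because dosages enter
uncentered.

**Kinship coding.** `compute_kinship()` defaults to the raw-code Gram
matrix $GG^{\mathsf T}/m$. Raw 0/1/2 Gram matrices are allele-coding
dependent, so a mean-centered option is provided, but it is off by
default to match the method's published form. With independent markers
the raw $K$ approaches $\alpha I + \beta J$ as $m$ grows; its difference
from a scaled identity — which is what identifies $\sigma_k^2$ — lives in
the $O(\sqrt{n/m})$ spectral spread, so variance-component estimates on
simulated LD-free panels are noisy at large $m/n$ even though the score
test (which needs only $M_0$) is unaffected. The parameter-recovery
checks therefore use $n=1000$ with $m=2000$ markers, a ratio at which
the components are comfortably identified.

## What the simulator emulates — and what it does not

`simulate_genotypes()` draws independent Binomial(2, p) dosages under
Hardy–Weinberg at configurable allele frequencies, on one chromosome at
5,000 bp spacing (so the ±1,000 bp true-positive window of the evaluator
isolates single markers). An optional first-order Markov haplotype chain
adds adjacent-marker LD for sensitivity studies. Real panels differ in
ways the generator deliberately ignores: block LD structure, allele-
frequency spectra, population stratification, and missingness patterns.
Passing the synthetic benchmarks therefore demonstrates the estimator's
statistical behaviour under its own model assumptions, not performance
on any particular species panel.

`derive_design()` implements the benchmark bookkeeping: total QTN
heritability $h_t^2=\sum h_i^2$ fixes the total genetic variance through
$\sigma_g^2 = h_t^2(\sigma_e^2+\sigma_k^2)/(1-h_t^2)$ (the default
six-QTN design at $\sigma_e^2=10$, $\sigma_k^2=2$ gives
$\sigma_g^2 = 9.82$ and polygenic heritability 0.092), and each QTN's
effect is

$$\beta_i = \sqrt{\left[\frac{h_t^2(\sigma_e^2+\sigma_k^2)}{1-h_t^2}
+ \sigma_e^2 + \sigma_k^2\right]\frac{h_i^2}{4\eta_i(1-\eta_i)}},$$

with $\eta_i$ the QTN's minor allele frequency. One property of this
convention deserves emphasis: since
$\operatorname{Var}(x_i) = 2\eta_i(1-\eta_i)$ under Hardy–Weinberg, the
$4\eta_i(1-\eta_i)$ divisor means each QTN's *realized* variance
contribution is $h_i^2 \cdot \text{(total variance)}/2$ — half its
nominal share. The formula is kept as the authoritative default because
it is the convention the benchmark designs were published under (its
$\sqrt{h_i^2}$ ratios are exact), and externally tabulated effects can
be supplied verbatim through `qtns$effect` for exact replication runs.
The consequence is visible in the package's own end-to-end benchmark: at
$n=200$, $m=5{,}000$, the $h^2=0.15$ QTN's score statistic clears the
LOD-3-equivalent threshold in only about three runs in five, an
information ceiling no stage-two construction can beat, so detection
rates at these sizes should be read against that ceiling rather than
against the nominal heritability.

Phenotypes are $y = \mu + \sum_i x_i\beta_i + u + \varepsilon$ on raw
dosages, with $u$ drawn from the eigendecomposition of $\sigma_k^2 K$
(negative eigenvalues clamped at zero) and $\mu = 10$,
$\sigma_e^2 = 10$, $\sigma_k^2 = 2$ by default; $\sigma_k^2 = 0$
reproduces the polygene-free design.

## Evaluation conventions

A call is a true positive when it falls within ±1,000 bp of a true QTN
on the same chromosome; each QTN is credited at most once per replicate
(closest call wins, distance ties to the larger |effect|). The false
positive rate divides false calls by the number of markers outside every
QTN window — the "QTN area" makes the verbal definition set-theoretic.
Per-QTN MSE averages $(\hat\beta_{is}-\beta_i)^2$ over the replicates
that detected QTN $i$, and the summary MSE is the unweighted mean over
QTNs detected at least once. Power–FDR and power–Type-I-error curves
sweep the LOD threshold over its observed range; the area under the
curve is trapezoidal, reported both raw on the observed x-range and
normalized by that range's width, since the integration convention is
not standardized in the literature this benchmark style comes from.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` size their simulations for a
single CPU: calibration pools 2,500 null score statistics over ten
independent phenotype draws (a single draw shares a common
$\lVert Py\rVert$ scale fluctuation that a pooled test must not
conflate with miscalibration); parameter recovery uses 50 panels of
$n=1000$, $m=2000$; the end-to-end operating characteristics use 50
seeded replicates of $n=200$, $m=5{,}000$ with three QTNs, plus 50
permuted-phenotype replicates; and the acceptance script runs the full
six-QTN designs at $n=199$, $m=5{,}000$, 60 replicates per design.
These are the package's own benchmark sizes; the published full-scale
designs (hundreds of thousands of markers, 1,000 replicates) differ
only in marker count and replication, not in per-individual signal
structure.

## Known limitations

* Dense $n\times n$ kinship and working covariance limit the package to
  panels of a few thousand individuals; the method family's own
  applicability statement ($n < 3{,}000$) applies.
* Quantitative traits only; binary traits would need a link-function
  extension of both stages.
* Stage two deliberately omits the polygenic term, as the method
  prescribes; residual stratification not captured by screening-stage
  kinship control can therefore reach the effect estimates. Genotype
  principal components (`make_pcs()`, `pcs =` argument) are the provided
  mitigation.
* The raw-coding kinship identifiability caveat above: on LD-free
  synthetic panels with $m \gg n$, moment estimates of
  $(\sigma_k^2, \sigma_e^2)$ are individually noisy even though their
  $M_0$ combination — all the score test needs — is stable.
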