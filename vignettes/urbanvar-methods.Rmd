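---
title: "Models and methods behind urbanvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind urbanvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanvar)
```

## The scientific problem

Urban bird populations are routinely compared to adjacent non-urban
populations of the same species through per-habitat summary statistics:
a mean, a standard deviation and a sample size per habitat for traits such
as first-clutch laying date (day-of-year, 1 January = 1), clutch size and
number of fledglings. Two questions drive the analysis this package
implements: whether urbanisation shifts *mean* life-history traits, and —
less commonly asked — whether it changes their *variation*, within and
across breeding seasons, and whether landscape heterogeneity around the
study sites predicts those changes.

`urbanvar` provides the full pipeline: schema-validated ingestion of paired
comparison records, logged exclusion filtering, ratio-based effect sizes
for means and variation, among-season pooling, a from-scratch multilevel
phylogenetic meta-analytic engine, landscape quantification on categorical
land-cover grids, and a synthetic-data generator with known truth used to
validate every estimator in the package.

## Effect sizes

For a comparison with urban arm $(\bar{x}_u, s_u, n_u)$ and non-urban arm
$(\bar{x}_n, s_n, n_n)$, with the urban arm always in the numerator:

* **lnRR** $= \ln(\bar{x}_u/\bar{x}_n)$, sampling variance
  $s_u^2/(n_u\bar{x}_u^2) + s_n^2/(n_n\bar{x}_n^2)$. The plain log-ratio is
  the default (a Taylor-corrected variant sits behind `bias_correct`);
  reproducibility with the conventional tooling of this literature takes
  precedence over the newest estimator.
* **lnCVR** $= \ln(CV_u/CV_n) + \tfrac{1}{2(n_u-1)} - \tfrac{1}{2(n_n-1)}$
  with $CV = s/\bar{x}$, sampling variance
  $CV_u^2/n_u + \tfrac{1}{2(n_u-1)} + CV_n^2/n_n + \tfrac{1}{2(n_n-1)}$.
  The mean-variance correlation term is zero by default (supply `mvcor` to
  include it).
* **lnVR** $= \ln(s_u/s_n)$ with the same $1/(2(n-1))$ corrections and
  variance $\tfrac{1}{2(n_u-1)} + \tfrac{1}{2(n_n-1)}$.
* **SMDH**: standardised mean difference with heteroscedastic population
  variances, $d = (\bar{x}_u - \bar{x}_n)/s$, $s^2 = (s_u^2 + s_n^2)/2$,
  multiplied by the exact gamma-function small-sample correction
  $J(m) = \Gamma(m/2)/(\sqrt{m/2}\,\Gamma((m-1)/2))$ at $m = n_u+n_n-2$.

All four agree with `metafor::escalc` to $10^{-9}$ on random records (a
cross-check in the test suite; the implementation itself is independent).
Magnitudes are reported as $100(e^{|y|}-1)$ percent, with the sign carried
alongside: a laying-date lnCVR of 0.176 back-transforms to 19.2% more
variation in the urban habitat.

`effective_sample_size()` uses the two-group form $4n_un_n/(n_u+n_n)$;
the source literature for the small-study moderator cites its methods
rather than printing a formula, so this conventional choice is a
documented default.

## Season pooling

Sources that report one summary per breeding season are pooled into an
among-season record by the n-weighted identities

$$\bar{x} = \sum_i \frac{n_i}{N}\bar{x}_i, \qquad
S^2 = \sum_i \frac{n_i}{N}s_i^2 +
      \sum_i \frac{n_i}{N}(\bar{x}_i - \bar{x})^2 .$$

When the $s_i^2$ are population variances (denominator $n_i$) of raw
samples these identities reproduce the concatenated-sample statistics
*exactly* — the package's pooling oracle test exploits this. Literature
SDs are sample SDs (denominator $n_i-1$), for which the same formulas are
the standard close approximation; we apply them verbatim either way. The
pooled record re-enters the effect-size module with $SD = \sqrt{S^2}$ and
$n = N$: the source data do not state what n a pooled record should carry,
and $\sum n_i$ is the weight already implied by the pooled mean. Arms must
cover the same seasons to be pooled; mismatched groups are skipped with a
warning rather than silently mixed.

## The multilevel phylogenetic meta-analytic model

Effect sizes $y_i$ with known sampling variances $v_i$ follow

$$y \sim \mathcal{N}\!\big(X\beta,\; V(\theta)\big), \qquad
V(\theta) = \sum_u \sigma_u^2 Z_u G_u Z_u^\top + \mathrm{diag}(v_i),$$

with random terms for study-by-trait deviations (with a structured
among-trait variance-covariance matrix), population pair, phylogeny
($G = A$, the species correlation matrix), species (non-phylogenetic) and
observation-level deviations (one variance per trait in multi-trait fits;
observation-level deviations cannot covary across traits because each
observation carries exactly one trait). The fixed part is an overall
intercept, one mean per trait, or trait means plus continuous moderators.

Five constraints on the study-by-trait block are supported, with 1, 2, 4,
3 and 6 free parameters for three traits: a single variance with zero
covariance; compound symmetry; heteroscedastic compound symmetry; a
diagonal matrix; and a fully unstructured matrix. `compare_vcv_structures()`
fits all five by maximum likelihood and tabulates $\Delta$AIC; ties below
$10^{-6}$ go to the structure with fewer parameters.

### Estimation choices

* Final estimates use **REML** (the convention of this literature's
  tooling); structure comparison uses **ML**, because REML likelihoods are
  not comparable across different fixed parts — the engine counts fixed
  effects in AIC only under ML, and the comparison function never varies
  the fixed part. Both are exposed as options.
* Variances are optimised on the log scale; the common correlation of the
  compound-symmetric structures through a logistic transform bounded to
  $(-1/(m-1), 1)$ (its positive-semidefiniteness region); the unstructured
  correlation matrix through a spherical (angle-based Cholesky)
  parameterisation that is positive definite for any unconstrained value.
* The fixed effects are profiled out by GLS at each likelihood evaluation;
  a single Cholesky factorisation per evaluation serves the determinant
  and all solves.
* Optimisation is quasi-Newton (`nlminb`) with relative logLik tolerance
  $10^{-8}$ and up to five dispersed multi-starts (log-variances shifted by
  $\pm 2, \pm 4$); non-convergence is flagged in the returned object,
  never silent. Log-variances are bounded at $-25$ so boundary components
  are representable as numerically-zero without degenerate matrices.
* Confidence intervals are Wald z intervals ($\pm 1.959964\,SE$) by
  default, matching the symmetric intervals this literature prints. Two
  alternatives sit behind `meta_spec(ci = ...)`: a Knapp-Hartung-style
  residual scaling with $t_{k-p}$ quantiles, and a small-sample
  `"adjusted"` interval that combines the Kackar-Harville first-order
  inflation of the coefficient covariance (adding
  $G\,\widehat{\mathrm{Cov}}(\hat\theta)\,G^\top$, with $G$ the
  sensitivity of $\hat\beta$ to the variance parameters and
  $\widehat{\mathrm{Cov}}(\hat\theta)$ from the curvature of the profiled
  restricted likelihood) with Satterthwaite degrees of freedom per
  coefficient. The adjustment matters here because the shared
  species-level and phylogenetic effects are informed by only a few dozen
  species: their variance estimates carry few effective degrees of
  freedom, so plain z intervals are noticeably heavy-tailed relative to
  their stated level in simulation. The recovery experiment therefore
  reports the adjusted intervals — calibration is its whole point — while
  reported fits default to the conventional z form.

The REML log-likelihood follows the Harville form without the
$\tfrac{1}{2}\ln|X^\top X|$ constant some implementations add; REML
log-likelihoods therefore differ from `metafor`'s by that constant while
all estimates, standard errors and ML log-likelihoods agree (verified in
the tests to $5\times10^{-4}$ and $10^{-5}$ respectively).

### Heterogeneity and moderator summaries

`i2_decomposition()` uses the typical sampling variance
$\tilde{v} = (k-1)\sum w_i / \big((\sum w_i)^2 - \sum w_i^2\big)$,
$w_i = 1/v_i$, and reports each component as
$\sigma_u^2/(\sum_u \sigma_u^2 + \tilde{v})$ in percent, so components sum
to the total by construction. `r2_marginal()` is
$\mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) + \sum_u\sigma_u^2)$.
Publication-bias screens are two uni-moderator fits: $\sqrt{1/\tilde{n}}$
(small-study effect) and mean-centred publication year (decline effect).

### The arm-based lnSD model

As a sensitivity analysis that does not form contrasts at all,
`fit_arm_based()` models each habitat arm's $\ln SD$ with known sampling
variance $1/(2(n-1))$, fixed effects for habitat and $\ln(\text{mean})$
(the mean-variance slope is estimated, not assumed), the same study /
population / phylogeny / species intercepts, and an effect-size-level
random term whose entries within a study share an estimated correlation —
arms from the same study are never treated as independent. The
within-study correlation is bounded below by $-1/(m_{\max}-1)$, the PSD
limit for the largest within-study block.

## Phylogeny

Trees come in as Newick; Grafen heights (each node at descendant-tip
count minus one, scaled to unit root height, exponent `rho = 1` — the
method's default, used here without modification) give an ultrametric tree
without dated branch lengths, and the species correlation is the shared
root-to-MRCA depth fraction. Polytomies are handled natively — node
heights depend only on descendant tip counts, so no random resolution is
introduced. These steps are delegated to `ape` (`compute.brlen`, `vcv`),
whose conventions reproduce the hand-derived three- and four-tip cases in
the test suite; tree retrieval from online taxonomy services is out of
scope (all tests are network-free).

## Landscape quantification

Land-cover input is any single-band categorical grid in ESRI ASCII format
with planar (metres) or geographic georeference. Buffer extraction uses
the **pixel-centre-in-circle** rule — the source literature does not state
an inclusion rule, so we fix one and verify it against brute-force
containment in the tests. On geographic grids the circle is geodesic: each
pixel centre's great-circle distance to the site is compared to the
radius, which avoids choosing a projection altogether (the stated CRS of
the original analysis is a datum ensemble, not a projected CRS, so there
is no projection to replicate). Profiles run from 250 m to 5000 m in
250 m steps by default. Heterogeneity is the Hill number of order 1
(`exp` of the Shannon-Wiener index); the urban index is the urban-category
pixel share, with the urban category set configurable. Pair distances are
haversine distances on a 6371.0088 km sphere.

## The synthetic-data generator

`simulate_dataset()` runs the meta-analytic model in the generative
direction, so every estimator in the package can be checked against known
truth: species effects drawn from $\mathcal{N}(0, \sigma_a^2 A)$ on a
simulated pure-birth tree plus i.i.d. species effects, population-pair and
study-by-trait deviations (with the true among-trait structure), and
observation-level noise — independently for lnRR and lnCVR, which are the
estimands and are therefore made exactly identifiable: the non-urban arm
sits at the baseline mean and CV, the urban arm at
$\text{mean}\cdot e^{\ln RR}$ and $CV\cdot e^{\ln CVR}$. Individuals are
normal within arms; per-arm records keep only (mean, SD, n), as the
literature does. Laying-date individuals are rounded into day-of-year
$[1, 366]$.

Defaults mirror the compiled literature dataset's structure: 35 species,
68 studies, three traits with ~80–85% study coverage each, 31% of studies
spanning 2–12 seasons, log-normal per-arm samples around n ≈ 25, true
per-trait effects at the published magnitudes (laying-date lnCVR 0.176,
etc.), and variance components chosen so the implied heterogeneity profile
matches the published one (high total I² for lnRR with a visible species
share; moderate I² for lnCVR dominated by observation-level variance).
This yields around 400 comparisons per replicate. A multi-season
study-trait either reports per-season rows or (with probability 0.25) one
source-pooled row; in the latter case the observation-level deviation is
drawn once for the row — it belongs to the effect size, not to the
season — so source-pooled rows estimate the same quantity as per-season
rows rather than absorbing season-to-season effect fluctuations into
their SDs.

What the generator deliberately does *not* emulate: literature search
bias (beyond the optional funnel-asymmetry injection used in the
publication-bias tests), non-normal phenotype distributions, reporting
errors, and correlation between the lnRR and lnCVR hierarchies. Passing
recovery tests therefore demonstrate estimator correctness under the
model's own assumptions, not robustness to their violation.

`recovery_experiment()` wraps simulate → filter → effect sizes → fit and
reports bias, RMSE and CI coverage. The package's acceptance checks run
200 replicates at roughly 400 comparisons each; at that size the
Monte-Carlo standard error of the bias estimate for the laying-date
variation effect is about 0.005, comfortably resolving the 0.02 bias
bound being checked. Recovery fits use a single optimiser start and a
$10^{-6}$ relative tolerance — the generator's truth lies in a benign
region where dispersed restarts change estimates by far less than the
Monte-Carlo noise.

## Numerical and degenerate-input behaviour

* Exclusion rules apply in a fixed order (missing n, missing SD, n = 1,
  SD = 0) and each record is tallied once under the first rule that
  matches, so a sequentially reported exclusion breakdown is reproduced
  exactly; how multiply-flawed records were tallied in the original
  bookkeeping is not stated anywhere, and the sequential assumption is
  ours.
* Quartile-only sources are converted with the three-number-summary
  estimators (quartile-weighted mean; IQR over the sample-size-adjusted
  normal quantile). Which scenario variant the original extraction used is
  unstated; the three-number variant is the default. A degenerate
  $q_1 = q_3$ yields SD 0 and is caught by the exclusion filter.
* Missing cells, `NA` and `NaN` all read as missing — hand-extracted
  tables deserve tolerant ingestion.
* Log-ratio measures require positive arm means and refuse records that
  violate this, naming the record. In the recovery loop a tiny simulated
  arm of a high-CV count trait can occasionally sample a non-positive
  mean — a summary no real study could report — and such records are
  screened out before effect sizes are computed (well under one record per
  hundred thousand at the default study conditions).
* Variance components truly at zero are estimated at the numerical
  boundary ($e^{-25}$) and reported as such; I² terms then contribute 0.
* Single-trait datasets only admit the single-variance study structure;
  multi-trait structures error early with a clear message.
* An empty buffer or a site outside the raster extent is a per-site
  collected error in `multiscale_profile()` and a hard error in
  `buffer_extract()`.

## Scope and limitations

The package deliberately excludes: literature search and screening
machinery, live phylogeny retrieval, download clients for land-cover
products, Bayesian estimation, robust/cluster variance estimators, and
orchard-style graphics. Model 7 (the spatial meta-regression) requires
user-supplied coordinates and a categorical grid; the reproduction mode
(`reproduce_analysis()`) requires the user to supply a deposited dataset
and reports "n/a" reference columns otherwise.
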