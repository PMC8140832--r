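---
title: "Center-level sparse FPCA of rapid lung-function decline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Center-level sparse FPCA of rapid lung-function decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In cystic fibrosis (CF), lung function — measured as FEV~1~ percent
predicted — declines progressively, with the steepest losses typically
during adolescence. The *timing* and *severity* of this "rapid decline"
vary strongly between patients, and CF care and registry reporting are
organised by care center, so clinically useful benchmarking requires
(1) a patient-level characterisation of decline from noisy, irregularly
timed clinic measurements, and (2) aggregation of those
characterisations to the center level.

This package implements that pipeline: a synthetic registry generator
with known latent structure, cohort filtering, sparse functional
principal components analysis (FPCA), quartile-based phenotype
classification, center-level functional aggregation with size-category
comparisons, and a static/animated dashboard. Because real CF registry
data cannot be redistributed, every stage is exercised on synthetic
cohorts whose ground truth is known, which is what makes the pipeline
testable.

## The model

Each patient's latent lung-function trajectory is modelled as a smooth
random function of age $t \in [6, 21]$:

$$ Y_{ij} = \mu(t_{ij}) + \sum_{k=1}^{K} \xi_{ik}\,\phi_k(t_{ij}) + \varepsilon_{ij},
\qquad \xi_{ik} \sim N(0, \lambda_k), \quad \varepsilon_{ij} \sim N(0, \sigma^2), $$

where $\mu$ is the population mean curve, $\phi_k$ are orthonormal
eigenfunctions of the between-patient covariance function, $\xi_{ik}$
are per-patient scores, and $\varepsilon_{ij}$ is spirometry
measurement error. Patients are observed at irregular, patient-specific
ages ("sparse" functional data), so scores cannot be computed by direct
integration; they are predicted by the Gaussian conditional mean (BLUP)

$$ \hat\xi_i = \Lambda \Phi_i^\top\,(\Phi_i \Lambda \Phi_i^\top + \sigma^2 I)^{-1} (Y_i - \mu_i), $$

with $\Phi_i$ the eigenfunctions evaluated at patient $i$'s visit ages
and $\Lambda = \mathrm{diag}(\lambda_1,\dots,\lambda_K)$. This
shrinkage-based scoring is what lets sparsely observed patients borrow
strength from the population fit.

The first component is oriented so that a **higher first score means
faster decline**. Phenotypes are defined from the cohort-wide first and
third quartiles of $\hat\xi_{i1}$: *late* decliners below Q1, *early*
(rapid) decliners above Q3, *middle* decliners in between — so the
middle group always holds half the cohort by construction.

## Estimation pipeline

The package implements the smoothing-based sparse-FPCA pathway:

1. **Mean.** A penalised cubic smoothing spline is fitted to the pooled
   (age, FEV~1~) scatter, with smoothness chosen by generalised
   cross-validation (a fixed `spar` may be supplied for strict
   reproducibility). Evaluation is on a fixed grid of 61 equally spaced
   ages on [6, 21] (0.25-year step); all curves in the package live on
   this grid.
2. **Covariance surface.** Raw covariances are products of
   within-patient residual pairs at *distinct* ages; same-age pairs are
   excluded so white measurement error cannot contaminate the surface.
   The pair cloud is smoothed with a tensor-product spline surface
   (REML smoothness; the fast discretised fit is used for large pair
   sets), predicted on the grid, and symmetrised.
3. **Error variance.** The raw diagonal (a 1-d smooth of squared
   residuals over age) estimates signal variance *plus* noise, while
   the smoothed surface's diagonal estimates signal alone; $\hat\sigma^2$
   is the average gap over the central half of the age window,
   truncated at zero. Restricting to the central half avoids the
   boundary regions where both smooths are least reliable.
4. **Eigenanalysis.** Trapezoid-rule quadrature weights turn the
   continuous eigenproblem into a symmetric matrix eigendecomposition;
   eigenfunctions are normalised to unit $L^2$ norm on the grid and
   negative eigenvalues (possible after smoothing) are truncated to
   zero. The number of components is the smallest $K$ whose cumulative
   eigenvalue fraction reaches 0.90 (overridable).
5. **Scores and curves.** Scores come from the conditional-expectation
   formula above, with $\sigma^2$ floored at $10^{-8}$ in the solve and
   a small ridge (with a warning) if the system is still numerically
   singular. The fitted curve is the exact reconstruction
   $\hat\mu + \sum_k \hat\xi_{ik}\hat\phi_k$ on the grid; the
   rate-of-change curve is the derivative of a natural-spline
   interpolant of that reconstruction.

An estimation detail worth stating: the fitting grid spans [6, 21] but
a cohort's earliest and latest visits rarely land exactly on those
boundaries, so the mean smoother tolerates up to one year of spline
extrapolation at the window edges before refusing to fit. A grid
genuinely outside the observed range is an error.

### Why this estimation flavour

The same model is often fitted by reduced-rank restricted maximum
likelihood. The smoothing-based pathway was chosen here because every
stage has a closed, testable contract: the mean and covariance smooths
can be checked against generator truth, the eigenproblem against
analytic rank-1 surfaces, and the scoring formula against a brute-force
joint-Gaussian conditional mean — which the test suite does. The
scoring formula, not the smoothing machinery, is the behavioural
contract.

## The synthetic registry generator

The generator emulates the structure of encounter-level CF registry
data on the percent-predicted scale:

- **Mean curve** $\mu(t) = 95 - 25/(1+e^{-(t-14)})$: a smooth logistic
  decline from ≈95 at age 6 to ≈70 at age 21, steepest at age 14 where
  the loss rate is $-25/4 = -6.25$ percent predicted per year. The
  logistic scale of 1 year was chosen so that the implied peak decline
  matches the magnitudes registry analyses report (around −6 percent
  predicted per year); a much broader transition would make the age of
  maximal decline nearly unidentifiable because the rate curve would be
  almost flat.
- **Components.** $\phi_1$ is (the orthonormalised version of) a
  downward logistic step centred at age 12.5: a patient with a large
  positive $\xi_1$ loses lung function earlier and more steeply.
  $\phi_2$ is a Gaussian bump near age 14.5 that tilts depth against
  timing. Raw shapes are orthonormalised by Gram–Schmidt under
  trapezoid quadrature on a fine grid.
- **Score scale** `score_sds = c(25, 10)`. With the unit-norm step
  shape, quartile-representative patients ($\xi_1 \approx \pm 32$)
  differ by roughly 20 percent predicted in late adolescence — the
  order of heterogeneity seen between early and late decliners in CF
  cohorts. This scale also keeps individual decline signal comfortably
  above the measurement noise, which is what makes quartile membership
  recoverable from noisy sparse data at all.
- **Noise** `noise_sd = 5` percent predicted, i.i.d. across visits —
  the conventional magnitude of within-session spirometry variability.
- **Visits.** Patients enter at ages 6–8 and are followed 11–15 years
  (truncated at age 21), with Poisson per-year visit counts (mean 1.0)
  jittered uniformly within the year — roughly one spirometry
  measurement per year, giving mostly 8–14 measurements per patient.
  This is a desk-scale thinning of real quarterly CF encounter
  schedules; it preserves the irregular, patient-specific timing that
  sparse FPCA exists to handle.
- **Centers.** The number of centers per size class follows the
  configured mix as closely as the patient budget allows; per-center
  target patient counts are drawn to straddle the 30 and 150
  boundaries that define small/medium/large categories, with headroom
  so that downstream filtering does not flip categories. Center
  designation is recorded annually; each year a patient transfers with
  probability 0.02, with destination probability proportional to
  center size (large programmes receive more transfers). Scenario
  cohorts can shift entry ages and the mean first score per size class
  — this is how the "small centers see older, more mildly declining
  patients" pattern is constructed for testing.

What the generator does **not** emulate: pulmonary exacerbations,
treatment effects, death or attrition, informative (non-random)
missingness, secular birth-cohort trends, and within-patient serial
correlation beyond what the smooth latent curve induces. Passing tests
therefore demonstrate that the pipeline recovers the latent structure
it models — not that real registry data satisfy that model.

## Classification and aggregation conventions

- **Quantile convention.** Quartiles use linear interpolation of the
  empirical distribution (R's default type 7); the convention is
  recorded in the labels output because label boundaries depend on it.
  Scores exactly equal to Q1 or Q3 are middle decliners.
- **Quartiles are cohort-wide**, not within-center: between-center
  prevalence differences are only meaningful against a common
  threshold.
- **Primary center** is the center with the most distinct designated
  years; ties break to the earliest-attended center, then
  lexicographically — determinism is required for testability.
- **Duplicate (patient, age) records** keep the first occurrence.
- **The ≥7-measurement filter** is applied after the age-window
  restriction, since measurement counts are only meaningful within the
  analysis window.
- **Baseline** is each patient's earliest in-window encounter.
- **Peak decline** is the minimum of the rate-of-change curve and the
  first grid age attaining it (ties go to the youngest age).
- **Category summaries** weight centers equally: Table-1-style rows are
  means (SD) across centers of center-level means; peak-decline
  summaries average patient-level values within center first. Pairwise
  Welch t-tests (two-sided, unequal variance) compare the three size
  categories with a Bonferroni factor of 3; a category with a single
  center has no dispersion and is reported without an SD.
- **Component orientation.** The first component is flipped, if needed,
  so that the correlation between $\hat\xi_1$ and the fitted total
  change $\hat f_i(21) - \hat f_i(6)$ is negative. Higher-order
  components get a nonnegative-integral convention so refits are
  byte-reproducible. Reconstructions are invariant to all such flips.

## The dashboard

The rendered dashboard is plain static HTML, PNG and animated GIF — no
server. The landing page has five links: center-level FPCA animations,
center-level rate-of-change animations, mean predicted trajectories,
mean predicted rates of change, and a placeholder for additional
displays. Nine centers are shown (a seeded random draw of three per
size category). Animations follow a fixed grammar: phenotypes in the
order late → middle → early, and within each phenotype the phases
highlight (observed trajectories coloured), smooth (observed
trajectories morph into fitted curves) and collapse (fitted curves
merge into the cell mean). Colours never vary: early = red, middle =
yellow, late = green; a center with no patients of some phenotype
simply lacks that colour's curve. Frame counts per phase and the GIF
frame delay are configuration values.

GIFs are written by a small self-contained GIF89a encoder (shared
global palette with bit-depth reduction beyond 256 colours, standard
variable-width LZW code stream, looping extension); its output is
validated against an independent decoder in development.

## Problem sizes and numerical tolerances used in testing

The test suite exercises the pipeline on cohorts of 150–2000 patients:
n = 500 at the default study conditions for recovery checks (eigenvalue
relative error < 15%, first-eigenfunction principal angle < 10°, error
variance within 20%, ≥ 85% label agreement with the generator's true
quartile classes), n = 300 at low noise for curve and peak-decline
recovery, n = 700 for the size-category ordering scenario, n = 900 for
center aggregation and dashboard structure, and n = 1000 for the
quartile-split computation. Score predictions are checked against a
brute-force joint-Gaussian conditional mean to 10⁻⁸; aggregation
conservation holds to 10⁻⁹; Welch statistics match a hand-coded
textbook formula to 10⁻⁹.

Derivatives deserve one note: the natural-spline derivative is
cross-checked against central finite differences of the interpolant at
a 0.05-year step. Differences taken directly on the 0.25-year grid
carry $O(h^2)$ truncation error that is visible (up to ≈0.3 percent
predicted per year) for the steepest fitted curves, so the coarse-grid
comparison is not used as a correctness criterion.

## Known limitations

- **Boundary bias.** Eigenfunction estimates are least reliable near
  the window edges; fitted curves for patients with extreme scores can
  err by several percent predicted at ages 20–21 even at low noise.
  Recovery guarantees in the tests are therefore stated over the
  interior of the age window.
- **Flat rate curves.** For patients whose true rate-of-change curve is
  nearly flat, the age of maximal decline is intrinsically
  ill-determined; the half-year recovery guarantee applies to the
  generator's default, well-localised decline shapes.
- **Sampling variability.** At n = 500, eigenvalue estimates vary by
  roughly ±10–20% across generator seeds; the recovery tests are
  seed-fixed statements at the study conditions, not distribution-free
  guarantees.
- **No covariate adjustment, no uncertainty bands.** Supervised or
  covariate-adjusted FPCA and bootstrap confidence bands around the
  fitted curves are out of scope.
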