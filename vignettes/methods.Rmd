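---
title: "Models and methods in nutgeom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in nutgeom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`nutgeom` analyses how a wild frugivore's daily macronutrient intake tracks
habitat fruit availability, and how urinary biomarkers of metabolic state
respond to intake. This vignette is the package's own account of the models
it fits, the choices behind them, and what its synthetic-data tests do and
do not establish.

## The scientific setting

Orangutans in peat-swamp forest face irregular alternation of fruit-scarce
and fruit-rich periods. The habitat-level predictor is the **fruit
availability index (FAI)**: the monthly percentage of monitored phenology
trees bearing fruit (0.5 to 14% in this habitat). Intake is accounted in
kcal per full nest-to-nest follow day, split into protein, total
nonstructural carbohydrates (TNC), lipid, and neutral detergent fiber
(NDF). **Non-protein energy (NPe)** is TNC + NDF + lipid. Urinary
biomarkers index metabolic state: C-peptide (insulin production, positive
energy balance), ketone bodies (fat catabolism), urea (amino-acid
catabolism / ureagenesis), and the nitrogen stable-isotope ratio
delta-15-N (catabolism of endogenous body protein). Concentration analytes
are diluted by hydration; specific gravity (SG) measures that dilution.

## Protein prioritization and the power law

If an animal defends absolute protein intake while letting non-protein
energy float, the percentage of energy from protein must fall as total
energy rises: with protein intake constant, %P is proportional to 1/E. The
degree of regulation is summarized by the exponent L in

  %P = a * E^L,

estimated on the log-log scale where the power law is exactly linear:

  log(%P_ij) = c + alpha_j + L * log(E_ij) + eps_ij,

with Gaussian residuals and Gaussian random intercepts `alpha_j` per
individual. L = -1 is complete prioritization, L = 0 is a constant protein
proportion (no prioritization of absolute protein). `fit_power_function()`
samples this model by MCMC (JAGS); priors are weakly informative and
overridable (`c ~ N(0, 5^2)`, `L ~ N(0, 2^2)`, half-normal(1) SDs). Total
energy is centered on the log scale internally, which only shifts the
intercept. Because the raw intercept and the random intercepts are only
sum-identified, the package monitors the sum-to-zero-constrained versions;
the reported `c` is `c + mean(alpha)` and the `alpha` are deviations from
their mean. Fit quality is summarized by a Bayesian R-squared: per draw,
var(fitted) / (var(fitted) + residual variance).

## Hierarchical robust correlation

Before fitting single-predictor smooth models, intake variables are
screened for concurvity with a hierarchical robust correlation: each
observation vector follows a multivariate Student-t around
individual-specific locations,

  y_ij ~ MVT(nu, mu + alpha_j, S),   S = diag(sigma) R diag(sigma),

with variable-specific random intercepts per individual. The t tails
(degrees of freedom `nu`, Gamma(2, 0.1) prior truncated above 2) absorb
gross outliers so the correlation estimate is not dragged by them; on
clean data the posterior for `nu` drifts high and the estimate approaches
the Gaussian/Pearson one. The correlation matrix is parametrized by its
Cholesky factor in spherical coordinates (one angle per lower-triangular
entry, uniform priors on the angles), which guarantees every posterior
draw is symmetric, unit-diagonal, and positive definite in any dimension.
This parametrization was chosen over the common LKJ prior because the
MCMC engine available to the package has no LKJ density and its conjugate
Wishart sampler cannot operate under a Student-t likelihood; the angle
parametrization is exact, general, and imposes only a weakly informative
prior whose marginals are close to uniform on each correlation. Inputs are
standardized per column (correlations are scale-invariant). Whether the
study's random intercepts were shared across variables or
variable-specific is not determinable from the source; the package
implements them variable-specific.

## Penalized-spline GAMMs

Each response (an intake variable against FAI, or a biomarker against a
single intake variable) is modeled with one penalized low-rank thin-plate
smooth; one nutritional predictor per model avoids concurvity. Families
follow the empirical distributions of the responses: Gaussian for
delta-15-N, log-normal for C-peptide, gamma (log link) for urea, Bernoulli
(logit) for ketone presence. `select_family()` reproduces the screening
step: Gaussian and log-normal candidates by maximum likelihood, gamma by
the method of moments (shape = mean^2/var, rate = mean/var), compared by
AIC.

The smooth basis comes from `mgcv::smoothCon` with the penalty
diagonalized: penalized coefficients then carry an exchangeable normal
prior whose standard deviation is the smoothing parameter (half-normal
prior), and the linear null space is unpenalized (vague normal). Basis
dimension defaults to k = 10. For sampler efficiency the penalized block
is additionally centered, projected orthogonal to the null-space columns,
and rotated to its principal axes in data space; the identity penalty is
invariant under the rotation and the same affine map is applied at
prediction time, so the represented function space, the prior, and the
fitted smooth are unchanged while coefficient posteriors decorrelate and
mix well under Gibbs/slice sampling.

Random effects are per-individual intercepts plus (optionally, default on)
random slopes on the standardized predictor. A random slope on sex within
individual is not included by default: sex is constant within individual,
so such a slope is absorbed by the intercept and only inflates
non-identifiability. Random-effect means are swept into the fixed part
(sum-to-zero post-sweeping), which identifies the population intercept.
Dispersion parameters are constant (location-only models); the source
never states which distributional parameters beyond location were modeled,
and a constant-dispersion model is the conservative reading.

Sampler profiles: `"test"` runs 4 chains x 1000 iterations (500 of them
post-warmup); `"paper"` runs 4 chains x 7000 iterations (3500 post-warmup),
matching the original analysis settings. Initial values are 0 for
gamma-family models and uniform in (-2, 2) otherwise, reproducing the
stated initialization rule. Convergence is gated at split-Rhat < 1.01 for
every monitored parameter; a fit failing the gate is returned but flagged.
The engine's Gibbs/slice samplers have no divergent transitions, so the
divergence count reported by `diagnostics()` is structurally zero; it is
reported to keep the convergence checklist explicit. Overfitting is
screened with pointwise PSIS-LOO Pareto-k values (own implementation:
generalized Pareto tail fit by the Zhang-Stephens estimator), with k > 0.7
counted as unreliable.

## Derivative regions

To say *where* a smooth is credibly rising or falling,
`finite_difference_slopes()` evaluates each posterior draw of the smooth
on a grid and at the grid shifted forward by a small step
(eps = 1e-4 x the grid range by default, forward difference), and
divides by the step. `detect_nonflat_regions()` computes the pointwise
central 95% interval of the slope draws at each grid point and reports
contiguous runs whose interval excludes zero, signed increasing or
decreasing. Intervals are pointwise — matching the per-point exclusion
rule — not simultaneous bands; on a flat truth about 5% of grid points are
flagged at the 95% level by construction. The default grid is 200 evenly
spaced points over the observed predictor range; boundaries are therefore
localized to within one grid step. The forward-difference truncation error
is O(eps x |f''|), far below posterior uncertainty at the default step.

## The synthetic-data generator

Every downstream stage is validated against a generator whose defaults
encode the study conditions the analyses assume:

* **Phenology / FAI**: a 12-month sinusoid (midpoint 4.56%, amplitude
  3.45) with AR(1) noise (SD 0.6, lag-1 correlation 0.6) and rare
  high-fruit spikes, clipped to 0.5-14%; the low/high period means land
  near 2.44% and 6.68% and the overall median near 4.56%. Fruiting trees
  per month are assigned exactly, so the realized FAI respects the range.
* **Intake**: expected NPe is a saturating logistic in FAI (1800 to 2420
  kcal, inflection at the habitat-mean FAI), giving a ~20% caloric and
  ~22% NPe increase from low to high periods. Daily total energy is the
  deterministic FAI-implied value times log-normal noise (~40% CV) and a
  per-individual random intercept (SD 0.10 on the log scale); percent
  protein then follows the scenario's power law in *observed* energy with
  its own per-individual intercept (SD 0.10, the power model's alpha) and
  multiplicative noise (~25% CV), so the hierarchical log-log model is
  exactly correctly specified and parameter recovery is a clean test of
  the estimator. Individual heterogeneity is generated at every level the
  downstream models assume — without it, the models' variance components
  sit on the zero boundary, where their posteriors are degenerate and the
  convergence gate is unattainable. Protein share at the pivot energy (2525 kcal) is
  10.4%, landing the realized protein share at ~10.1% of calories. NPe is
  split into TNC/NDF/lipid (62/27/11) with logistic-normal jitter.
* **Scenarios**: `complete_prioritization` (L = -1, protein noise 2%),
  `partial_prioritization` (L = -0.73 by default), `no_prioritization`
  (L = 0), and `flat_null` (flat FAI link and flat biomarker links, for
  null calibration).
* **Urine**: C-peptide log-normal, urea gamma (shape 6), delta-15-N
  Gaussian, with locations given by smooth monotone links in the prior
  day's TNC intake plus per-individual random intercepts on each
  biomarker's link scale (urea and delta-15-N elevated at low TNC; the
  C-peptide link flat, matching the absence of a detectable response in
  the field data). Ketone positivity is Bernoulli with a steep negative
  logit in standardized TNC, calibrated to ~9.2% positivity overall with
  positives concentrated in low-fruit periods. Concentrations are
  multiplied by (SG - 1)/(SG_ref - 1) with SG ~ Normal(1.023, 0.005)
  truncated above 1.000, so `sg_correct()` inverts the dilution exactly;
  the isotope ratio is not dilution-scaled. Assay CVs include a small
  fraction above the 15% threshold, and a few samples are dated so that no
  prior-day follow exists, exercising the exclusion accounting.

What the generator does *not* emulate: the small observed *decrease* in
period-mean protein intake between low and high fruit periods (a clean
power-law generator ties protein positively to energy; adding a
FAI-linked protein term would misspecify the estimated model and bias
exponent recovery), the corresponding upper reach of the NPe:P period
contrast, within-individual day-to-day autocorrelation of intake (an
optional AR(1) hook exists but defaults to off, since no value is
determinable from the source), fruit-biomass weighting of the FAI,
masting dynamics, and social/behavioral structure. Passing tests
therefore establish that the estimators recover the generating process at
study scale — not that every descriptive of the field data is
reproducible from this process.

## Numerical and design choices

* Quality filters follow the stated boundary conventions strictly:
  samples with SG < 1.002 are excluded (SG correction diverges as SG
  approaches 1), exclusion happens *before* correction; analyte values
  with assay CV > 15% are censored to missing ("rerun or not included"
  collapses to "not included" — no re-assay is possible in software);
  months exactly at the median FAI are labeled low (deterministic,
  conservative toward scarcity). Trace ketone readings count as positive
  by default (the strips detect only acetoacetate and miss mild ketosis,
  so any color change is treated as a positive with a switch to require
  at least "+").
* Urine samples are matched to the follow day exactly one day before
  collection, and only full nest-to-nest days are eligible; unmatched and
  partial-day samples are counted in a structured exclusion log.
* Ratios with a zero denominator are flagged missing, never infinite.
* kcal conversion factors are configuration (4/4/9 kcal per g for
  protein/TNC/lipid and 1.6 for NDF under the fermentable-fiber
  convention) since the exact NDF convention is not restated in the
  source and must be overridable.
* Seeds: one master integer seed; every table and every sampler chain
  derives its own stream deterministically, so identical configurations
  are byte-identical on disk and refits reproduce draws exactly.
* Problem sizes in the test suite are desk-scale by design: the study
  scale (40 individuals x 40 follow-days) is used for exponent recovery
  (20 replicates) and the end-to-end descriptive check, while the
  expensive Student-t correlation fits run at n = 150-300 with 10
  replicates and the smooth-recovery checks at n ≈ 350 with 5 replicates;
  the pipeline's test profile also fits the correlation stage on a row
  subsample. The `"paper"` profile exists for full-scale runs.

## Known limitations

* The exact supplementary model equations of the source analysis are not
  reproduced here; the models are built from their stated structure
  (families, link choices, maximal random effects, spline type, sampler
  settings). Whether FAI enters the biomarker models as a second smooth
  or a linear covariate is not stated; the package uses a linear fixed
  covariate with the spec'd option of adding it, and fits biomarkers
  against one nutritional predictor at a time.
* Pointwise (not simultaneous) credible intervals on derivatives imply a
  ~5% per-point false-flag rate on flat truths; simultaneous bands would
  be the natural extension.
* The Student-t correlation model is the slowest component; for large n
  one should expect minutes, and the pipeline's test profile subsamples.
* The smoothing standard deviation of a penalized smooth is weakly
  identified at small n (a few hundred observations) and can hold a
  split-Rhat near 1.02 however long the chain runs, without visibly
  moving the fitted smooth; the all-parameters convergence gate is
  strict about this, so consult the per-parameter Rhat table before
  discarding a fit.
* Recovery tests at reduced replicate counts bound coverage loosely; they
  detect gross miscalibration, not percentage-point deviations from
  nominal coverage.
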