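# nutgeom

Nutritional geometry and metabolic biomarker modelling for wild-primate
feeding studies.

`nutgeom` is for field ecologists and biological anthropologists who
collect full-day feeding follows, phenology-plot records, and urine
samples from wild frugivores, and want to answer two questions with one
reproducible pipeline:

1. **How is macronutrient intake regulated as fruit availability
   fluctuates?** The package computes the monthly fruit availability
   index (FAI, the percentage of monitored trees in fruit), daily intakes
   of protein, nonstructural carbohydrate (TNC), lipid, and fiber (NDF)
   in kcal, non-protein energy (NPe = TNC + NDF + lipid), and intake
   ratios such as NPe:P — and estimates the **protein-prioritization
   exponent L** from the hierarchical power law

   &nbsp;&nbsp;&nbsp;&nbsp;log(%P<sub>ij</sub>) = c + α<sub>j</sub> + L·log(E<sub>ij</sub>) + ε<sub>ij</sub>

   where %P is the percent of total energy E from protein and α<sub>j</sub>
   are per-individual random intercepts. L = −1 means absolute protein
   intake is fixed whatever the energy intake (complete prioritization);
   L = 0 means a fixed protein *proportion*.

2. **How does metabolic state respond to intake?** Urinary biomarkers
   (C-peptide, urea, δ¹⁵N, ketone bodies) are specific-gravity corrected,
   quality-filtered, matched to the previous day's full-day intake, and
   modeled with Bayesian penalized-spline GAMMs under
   family-appropriate likelihoods (Gaussian, log-normal, gamma,
   Bernoulli), with per-individual random intercepts and slopes.
   Predictor regions where a fitted smooth is credibly rising or falling
   are located by posterior finite-difference derivatives. Concurvity
   among intake variables is screened with a hierarchical robust
   correlation under a multivariate Student-t likelihood.

A synthetic-data generator with known ground truth (scenarios from
complete prioritization to flat nulls) makes every stage testable without
field data. MCMC runs on JAGS via `rjags`; spline bases come from `mgcv`.

## Worked example

Simulate a 20-individual study, estimate the prioritization exponent,
match urine to prior-day intake, and model urea against carbohydrate
intake:

```r
library(nutgeom)

truth <- make_truth("partial_prioritization", seed = 42)  # L_true = -0.73
cfg <- sim_config(n_individuals = 20, follows_per_individual = 30)
phenology <- simulate_phenology(cfg, truth)
follows <- add_derived_intakes(simulate_follows(cfg, truth, phenology))
urine <- simulate_urine(follows, truth, cfg)

fai <- classify_fruit_periods(compute_fai(phenology))
cat("median FAI:", round(attr(fai, "fai_median"), 2), "%\n")
#> median FAI: 4.72 %
cat("mean NPe:P:", round(mean(follows$npe_p), 2), "\n")
#> mean NPe:P: 9.27

fit <- fit_power_function(follows[follows$full_day, ], seed = 1)
print(fit)
#> <power_fit> L = -0.753 (95% CI -0.807 to -0.697), converged
r2 <- bayes_r_squared(fit)
cat(sprintf("Bayesian r2 = %.2f (%.2f to %.2f)\n", r2$mean, r2$ci[1], r2$ci[2]))
#> Bayesian r2 = 0.61 (0.56 to 0.65)
cat(prioritization_interpretation(fit)$label, "\n")
#> strong but not complete prioritization
```

The 95% interval for L covers the generating value −0.73 and excludes
both −1 and 0: protein intake is strongly, but not completely, defended.
The Bayesian r² is the posterior fitted-variance ratio of the log-log
model.

```r
matched <- match_urine_to_intake(filter_cv(urine, "urea_mg_ml"),
                                 follows, fai)
print(matched$log)
#>                  rule n_excluded
#> 1          sg < 1.002          0
#> 2 no prior-day follow         13
#> 3  prior day not full          0

f_urea <- fit_gamm(gamm_spec("urea_mg_ml", "kcal_tnc", "gamma",
                             random_slope = FALSE),
                   matched$matched, iter = 3500, warmup = 1500, seed = 2)
# a few minutes of MCMC
round(diagnostics(f_urea, pareto = FALSE)$max_rhat, 3)
#> [1] 1.019
grid <- seq(min(matched$matched$kcal_tnc), max(matched$matched$kcal_tnc),
            length.out = 200)
regions <- detect_nonflat_regions(finite_difference_slopes(f_urea, grid))
print(as.data.frame(regions))
#>    x_start    x_end       sign
#> 1 1587.401 2752.532 decreasing
#> 2 2812.797 3194.478 decreasing
#> 3 3294.920 3435.539 decreasing
```

Urea concentration falls credibly as carbohydrate intake rises through
the mid-range — the signature of amino-acid gluconeogenesis easing off
as exogenous carbohydrate becomes available — and is flat elsewhere
(the brief gaps between regions are grid points where the pointwise
interval just touches zero). The `regions` table gives the predictor
interval(s) where the posterior 95% interval of the smooth's first
derivative excludes zero, with the slope sign. At this sample size
the only parameter above the 1.01 convergence gate is the smoothing
standard deviation (Rhat 1.019) — a weakly identified hyperparameter
whose slow mixing does not propagate to the smooth itself; every
coefficient and the dispersion clear the gate, and `diagnostics()`
reports the full per-parameter picture so the call is yours.

The whole chain — simulate, clean, match, fit, detect, report — runs as
one call:

```r
bundle <- run_pipeline(run_config(scenario = "partial_prioritization",
                                  seed = 1, out_dir = "runs/demo"))
write_report(bundle)   # runs/demo/report.md + persisted tables and fits
```

or from a shell via `inst/scripts/nutgeom-pipeline.R`.

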