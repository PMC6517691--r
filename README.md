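# microage

Age- and sex-dependent patterns of gut microbiota diversity in adults.

`microage` is an R package for asking two linked questions of a
cross-sectional adult gut-microbiome cohort:

1. **How does alpha diversity change with age, and does it differ by sex?**
   Sequence-variant (SV) richness and the Shannon index are computed on a
   rarefied SV count table and modelled against age with both a simple
   linear model and a linear-spline model whose slope may change at a knot
   (45 years by default) — the comparison of the two by AIC tells you
   whether the age trend is one line or two. Age-group-stratified models
   (young adults, 20–45; middle-aged adults, 46–69) estimate the per-group
   age slope and the adjusted men-minus-women difference, with
   Benjamini–Hochberg adjustment across the reported terms. Sensitivity
   analyses rerun everything within antibiotic-consumer subsets and on
   diversity residualised against a composite cardiometabolic risk scale
   (the sum of within-cohort z-scores of five log-transformed clinical
   covariates).

2. **Does gut microbial *composition* carry an age signal that differs by
   sex?** A random-forest regression (ntree configurable, `mtry = p/3`) is
   trained on the relative abundances of the SVs shared between the sexes
   to predict chronological age — the prediction is the sample's
   *microbiota age*. The model is trained on one sex and applied to the
   other; a smoothing-spline calibration of predicted-versus-chronological
   age in the training sex defines the expected microbiota age at each
   chronological age, and the *relative microbiota age* of a sample is its
   microbiota age minus that expectation. Wilcoxon rank-sum tests compare
   relative microbiota age between women and men, overall and within age
   groups; 10-fold cross-validation error as a function of the number of
   top-importance SVs shows how far the model can be simplified.

Because real cohort SV tables are large external downloads, the package
ships a **synthetic cohort generator** (`cohort_scenario()`,
`simulate_cohort()`) that reproduces the statistical structure the analysis
assumes — a piecewise-linear age–richness trend with a knot, a sex offset in
richness, age-informative SV abundances with an optional sex-specific age
shift, an antibiotic-associated richness deficit, and log-normal
cardiometabolic covariates — so every stage is testable end to end on a
laptop.

## The model in brief

For diversity metric $y_i$ and age $a_i$, the spline model is

$$y_i = \beta_0 + \beta_1 a_i + \beta_2 (a_i - k)_+ + \varepsilon_i,\qquad k = 45,$$

so the young-adult slope is $\beta_1$ and the middle-aged slope
$\beta_1 + \beta_2$; the simple model sets $\beta_2 = 0$ and the two are
compared by Gaussian-likelihood AIC. Stratified models are
$y_i = \beta_0 + \beta_1 a_i + \gamma\,\mathrm{I}(\text{male}_i) + \varepsilon_i$
within each age group, with $\gamma$ reported as the men − women
difference. Relative microbiota age is
$\Delta_i = \hat f_{RF}(x_i) - s(a_i)$, where $\hat f_{RF}$ is the
cross-sex random forest (out-of-bag predictions for training-sex samples)
and $s$ the calibration spline.

## Worked example

```r
library(microage)
library(dplyr)

cohort   <- simulate_cohort(cohort_scenario(n_subjects = 600, seed = 1))
rarefied <- rarefy(cohort$features, depth = 1250, seed = 2)
d        <- alpha_diversity(rarefied) |>
  inner_join(cohort$metadata, by = "sample_id")

simple <- fit_age_trend(d, "richness", "simple")
spline <- fit_age_trend(d, "richness", "spline", knot = 45)
select_model(simple, spline)
#> <age_trend_fit> spline model of richness (stratum all): n=600, R2=0.320, AIC=4542.5
#>   slopes: young 1.014 (SE 0.068), middle -0.180 (SE 0.068)

fit_stratified(d, "richness", group = "young")
#> <age_trend_fit> stratified model of richness (stratum young): n=329, R2=0.466, AIC=2440.2
#>   slopes: young 0.943 (SE 0.074)
#>   delta men - women: -9.920 (SE 1.092)

fit  <- fit_microbiota_age(rarefied, cohort$metadata,
                           training_sex = "female", n_trees = 400, seed = 3)
pred <- predict_microbiota_age(fit, rarefied, cohort$metadata)
compare_sexes(pred)[, c("delta_women_minus_men", "wilcoxon_W", "p.value", "direction")]
#>   delta_women_minus_men wilcoxon_W  p.value    direction
#> 1                 0.995      52885 0.000167 women_higher
```

Reading the output: AIC prefers the spline — richness rises by about one SV
per year across young adulthood and is flat afterwards. Within the young
group, men average ~9.9 fewer SVs than same-age women (the scenario planted
a −10 SV offset). The woman-trained random forest applied to men finds
women about one year "older" on the microbiota clock, reflecting the
scenario's planted 3-year female shift in the compositional age signal,
attenuated by the regression's shrinkage toward the mean age.

The whole analysis — rarefaction through microbiota age, with TSV outputs,
a run log and a Table-1-style descriptive summary — is one call:

```r
run <- run_pipeline(pipeline_config(scenario = cohort_scenario(), seed = 1),
                    output_dir = "results/run1")
```

A thin CLI wrapper with `simulate`, `diversity`, `age-model`, `cardio`,
`microbiota-age` and `run` subcommands is installed at
`system.file("cli/microage", package = "microage")`.

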