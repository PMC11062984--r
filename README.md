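# isoniche

Stable-isotope niche analysis for multi-site predator communities:
baseline standardisation, Bayesian standard-ellipse areas, niche overlap and
individual specialisation, and site-level driver models — with a
study-shaped synthetic data generator for end-to-end validation.

## The science

Carbon and nitrogen stable-isotope ratios (δ¹³C, δ¹⁵N) in animal tissue
integrate diet over time, so the scatter of a population in δ¹³C–δ¹⁵N space
is a quantitative proxy for its trophic niche. Whiskers grow over months;
sectioning a whisker gives a time series of diet for a single individual,
which lets us separate *population* niche width from *individual*
specialisation.

The pipeline follows a comparative study of Tasmanian marsupial carnivores
(Tasmanian devil, spotted-tailed quoll, eastern quoll) across five sites
that differ in habitat modification and history of devil facial tumour
disease (DFTD):

1. **Standardise baselines.** Raw δ-values differ between sites because the
   plants at the base of the food web differ. Herbivorous prey (Bennett's
   wallaby, Tasmanian pademelon) sampled at every site provide a common
   anchor: each site's pooled prey mean is shifted onto the reference
   site's, and all samples at that site are translated by the same offset
   (`site_baseline_offsets()`, `standardize_samples()`). Translation leaves
   areas and overlaps untouched.
2. **Quantify niches.** The standard ellipse area
   `SEA = π√det(Σ)` with small-sample correction `SEA_C`, plus a Bayesian
   version `SEA_B` with a vague Normal–Inverse-Wishart prior, summarised by
   the posterior mode and a 95% highest-density interval
   (`sea()`, `sea_c()`, `sea_b()`, `niche_metrics()`).
3. **Compare niches.** Ellipse overlap with a Jaccard (intersection over
   union) default (`overlap_proportion()`, `bayesian_overlap()`), and a
   relative niche index per individual — the individual's ellipse as a
   proportion of the union of all individuals' ellipses
   (`relative_niche_index()`).
4. **Explain niches.** Camera-trap detections deduplicated with a
   20-minute independence filter feed a Shannon prey-diversity index
   (`dedupe_detections()`, `shannon_diversity()`); six candidate drivers
   are screened with single-predictor linear models under a Bonferroni
   family-wise threshold of 0.05/6 ≈ 0.008 (`driver_models()`). Individual
   proportions are modelled with an in-package beta regression
   (`beta_regression()`), positive areas with an identity-link Gamma GLM
   (`gamma_glm_identity()`).
5. **Validate everything.** `generate_isotope_study()` simulates a full
   study with known truths attached; `simulate_from_reference_means()`
   reproduces published group means exactly at zero noise. The test suite
   cross-checks every estimator against closed forms, independent fitters
   (`mgcv`, `stats::glm`) or Monte Carlo oracles.

See `vignettes/isotopic-niche-methods.Rmd` for the modelling details and
the reasoning behind each design choice.

## Worked example

```r
library(isoniche)
library(dplyr)

# a full synthetic study: 5 sites, 3 predators, prey, whisker sections
samples <- generate_isotope_study(scenario_config(seed = 42))

# anchor every site to the Wilmot prey baseline
prey    <- filter(samples, species %in% iso_prey_species())
offsets <- site_baseline_offsets(prey, baseline_site = "Wilmot")
std     <- standardize_samples(samples, offsets)

# Bayesian niche metrics per site x species
predators <- filter(std, species %in% c("tasmanian_devil",
                                        "spotted_tailed_quoll"))
metrics <- niche_metrics(predators, n_draws = 5000, seed = 1)
print(metrics, n = 3)
#> # A tibble: 10 × 9
#>   site         species          n   SEA SEA_C SEAB_mode SEAB_low SEAB_high  seed
#>   <chr>        <chr>        <int> <dbl> <dbl>     <dbl>    <dbl>     <dbl> <dbl>
#> 1 Arthur River spotted_tai…    25  2.58  2.69      2.33     1.59      3.53     2
#> 2 Arthur River tasmanian_d…    79  2.43  2.46      2.30     1.89      2.96     3
#> 3 Freycinet    spotted_tai…    19  3.36  3.56      2.79     1.93      4.70     4
#> # ℹ 7 more rows

# which site-level driver explains niche size?
drivers <- driver_models(metrics, study_site_covariates(), "SEAB_mode")
select(drivers, predictor, p_value, significant)
#> # A tibble: 6 × 3
#>   predictor             p_value significant
#>   <chr>                   <dbl> <lgl>
#> 1 species            0.895      FALSE
#> 2 dftd_category      0.299      FALSE
#> 3 human_modified_pct 0.00000538 TRUE
#> 4 road_cover         0.507      FALSE
#> 5 shannon_H          0.432      FALSE
#> 6 prey_seab_mode     0.250      FALSE
attr(drivers, "alpha_display")
#> [1] "0.008"

# individual specialisation within one group, modelled as a proportion
devils <- filter(predators, site == "Freycinet",
                 species == "tasmanian_devil")
cn  <- relative_niche_index(devils)
#> Warning message:
#> 92 individual(s) with < 3 sections excluded
fit <- beta_regression(mutate(cn$members,
                              y = squeeze_proportions(relative_index)),
                       y ~ n_sections)
print(fit)
#> Beta regression (logit link), n = 14, logLik = 23.737, phi = 63.265
#>          term estimate std_error statistic   p_value conf_low conf_high
#> 1 (Intercept) -1.51803   0.25756   -5.8939 3.772e-09 -2.02284  -1.01322
#> 2  n_sections -0.01834   0.02675   -0.6856 4.929e-01 -0.07077   0.03409
#> 3       (phi) 63.26533  23.84904        NA        NA 30.21966 132.44696
```

The generator's habitat effect is negative by default, and the driver screen
recovers exactly that: niche size tracks habitat modification, not DFTD —
the study's headline contrast. (The warning is expected: most simulated
individuals contribute a single whisker section and only fully sectioned
animals support an individual ellipse.)

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "isoniche",
                               load_package = "installed")'
```

The suite covers unit behaviour, property-based checks (symmetry,
invariance, monotonicity), oracle comparisons and end-to-end acceptance
checks (`tests/testthat/test-acceptance.R`).

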