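# isomanure

Inference of **manuring intensity** from charred cereal-grain nitrogen
isotope values, and of **settlement-size effects on manuring**, for
archaeobotanists and quantitative archaeologists studying agricultural
intensification and early urbanism.

## The problem and the model

Crops grown on manured soil are enriched in ¹⁵N, but aridity also raises
plant δ¹⁵N, so raw values cannot be compared across regions. Modern
calibration data give a measurement model with level-specific intercepts
and a common rainfall slope,

    δ¹⁵N_i = β_m + λ · log(rain_i) + ε_i,   ε_i ~ N(0, σ²),
    β_low < β_med < β_high,   m ∈ {low, medium, high},

from which each archaeological sample's ordinal manuring level is imputed
(uniform level prior, uniform rainfall prior over the sample's
past-rainfall range, calibration posterior integrated out). The imputed
levels then enter a mixed-effects proportional-odds regression on
settlement size and date with site random intercepts,

    P(M_i ≤ m) = logit⁻¹( α_m − (γ·x_size + τ·x_date + u_site) ),
    u_site ~ N(0, σ_u²),

so a **negative γ** means less manuring at larger settlements
(extensification). Three inference strategies of increasing fidelity are
provided:

1. **Single imputation** — most-probable level per sample, then a
   maximum-likelihood proportional-odds fit with a one-sided Wald test
   (`fit_po_si()`).
2. **Bayesian multiple imputation** (the *cut posterior*) — full
   uncertainty in levels, but no feedback from the size regression into
   the imputation (`sample_cut_posterior()`).
3. **Semi-modular inference** — an influence parameter η ∈ [0, 1] powers
   the analysis-module likelihood in the imputation stage, interpolating
   between cut (η = 0) and full Bayes (η = 1); η is tuned by maximising
   leave-one-out ELPD of the observed δ¹⁵N values
   (`sample_smi_posterior()`, `elpd_curve()`). This counteracts the
   "dilution" of effect estimates that multiple imputation is prone to.

Evidence for the sign of γ is reported as posterior odds, which under the
symmetric prior on γ equal the one-sided Bayes factor (`bayes_factor()`).

Past-rainfall inputs can be built from present-day rainfall with the two
published adjustment rules: a speleothem δ¹⁸O rule (−1 ‰ ↦ +200 mm/yr,
`speleothem_adjust()`) and a pollen-anomaly rule (six summer + six winter
months, `pollen_anomaly_range()`).

## A worked example

Simulate a study shaped like the northern-Mesopotamia dataset (published
site sizes, dates and rainfall; synthetic grain measurements with a true
size effect γ = −0.5 on the standardised size covariate), then run all
three strategies:

```r
library(isomanure)

truth  <- calibration_params(2, 5, 8, lambda = -1.5, sigma = 1)
modern <- generate_modern(truth, n_per_level = 40, seed = 1)
calib  <- fit_calibration(modern)
tidy(calib)
#>   term      estimate std.error conf.low conf.high  rhat   ess
#> 1 beta_low     2.82      1.20     0.888      4.79  1.00  324.
#> 2 beta_med     5.68      1.20     3.77       7.62  1.00  323.
#> 3 beta_high    8.77      1.20     6.84      10.7   1.00  341.
#> 4 lambda      -1.62      0.192   -1.92      -1.31  1.00  341.
#> 5 sigma        0.991     0.0632   0.895      1.10  1.00  497.

arch <- generate_arch(scenario_spec(preset_table1("nmeso"), calib = truth,
                                    gamma = -0.5, sigma_u = 0.5,
                                    n_per_site = 12, seed = 1))

fit_po_si(arch, calib)        # strategy 1: single imputation + Wald
#> gamma -0.440 (se 0.171), one-sided p (negative) = 0.0051

curve <- elpd_curve(arch, calib, manure_config(eta_grid = c(0, 0.5, 1)))
eta_star(curve)
#> [1] 0.5
smi <- sample_smi_posterior(arch, calib, eta = eta_star(curve))
tidy(smi)
#>   term    estimate std.error conf.low conf.high
#> 1 gamma     -0.514     0.182   -0.801    -0.216
bayes_factor(smi)
#> bf 400 (capped): every posterior draw of gamma is negative
```

The calibration recovers the generating lines; the Wald and SMI routes
both find the negative size effect, with the posterior 90% interval
covering the true −0.5; the Bayes factor saturates at the draw count
because no draw is positive. `autoplot()` methods draw the calibration
lines, the γ posterior, the ELPD-vs-η curve, and cumulative-probability
curves against settlement size with 50%/90% credible bands
(`probability_curves()`).

Real data enter through `read_modern_table()` and `read_arch_table()`
(CSV; see the function help for the required columns).

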