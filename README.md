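# ramupk

Model-based evaluation of monoclonal-antibody infusion duration, built
around ramucirumab (an anti-VEGFR-2 IgG1). The package answers two
linked questions for people working in clinical pharmacology and drug
safety:

1. **Does shortening the infusion from 60 to 30 minutes change systemic
   exposure?** A population-pharmacokinetic simulator implements the
   two-compartment infusion model with sigmoidal time-varying clearance,

   *CL(t) = CL₀ · exp(E_max · t^γ / (T₅₀^γ + t^γ))*,

   allometric body-weight effects on clearance and central volume,
   log-normal between-subject variability with CL–V₁ and CL–E_max
   covariance, and additive/proportional residual error. It simulates
   paired 30- vs 60-minute arms under weight-based dosing across the five
   label regimens, computes Cmax / trough / AUC_τ per dosing interval,
   runs visual predictive checks stratified at 27 days of treatment, and
   recovers population parameters from rich designs with a two-stage fit.

2. **Is a faster infusion *rate* (mg/min) associated with more immediate
   infusion-related reactions (IRRs)?** A statistical pipeline derives
   per-patient rates (dose/duration at the earliest-IRR-day
   administration for patients with an event, the first dose otherwise),
   groups them into empirical quartiles, tabulates incidence by grade and
   SMQ category, and fits the multivariate logistic model of IRR risk on
   rate, age, sex, region, premedication, chemotherapy and regimen — plus
   the sensitivity analysis that assumes a standard 60-minute infusion
   for every patient.

Because the underlying trial data are proprietary, the package ships
synthetic-data generators that emulate both data structures — a pooled
IRR cohort whose generating coefficients are the published odds ratios,
and NONMEM-dialect PK datasets — so the whole pipeline is runnable and
tested end to end out of the box.

## Worked example

```r
library(ramupk)

## --- PK: 30- vs 60-minute infusion, 8 mg/kg Q2W ------------------------
p <- default_poppk_parameters()   # illustrative mAb-scale parameters
pool <- withr::with_seed(11, rlnorm(300, log(65), sqrt(log(1.04))))
arm30 <- simulate_arm(p, regimen(8, "Q2W", 30, n_cycles = 1),
                      n = 100, weight_pool = pool, seed = 3)
arm60 <- simulate_arm(p, regimen(8, "Q2W", 60, n_cycles = 1),
                      n = 100, weight_pool = pool, seed = 3)
exposure_comparison(arm_exposure(arm30), arm_exposure(arm60))$ratios
#> # A tibble: 1 × 3
#>   auc_tau_gmr cmax_gmr cmin_gmr
#>         <dbl>    <dbl>    <dbl>
#> 1        1.00     1.00    0.999

## --- Safety: infusion rate vs immediate IRRs ---------------------------
cohort <- generate_irr_cohort(cohort_spec(n_patients = 3216, seed = 1))
rated  <- quartile_groups(compute_infusion_rate(cohort))
dplyr::filter(incidence_table(rated), outcome == "any_grade", category == "all")
#> # A tibble: 5 × 6
#>   group     N outcome   category     n   pct
#>   <chr> <int> <chr>     <chr>    <int> <dbl>
#> 1 Q1      804 any_grade all         64   8
#> 2 Q2      804 any_grade all         71   8.8
#> 3 Q3      804 any_grade all         64   8
#> 4 Q4      804 any_grade all         49   6.1
#> 5 Total  3216 any_grade all        248   7.7

tidy(logistic_model(rated))[, c("factor", "comparison", "or", "ci_lo", "ci_hi", "p_value")]
#> # A tibble: 10 × 6
#>    factor         comparison                         or  ci_lo ci_hi     p_value
#>  1 Infusion rate  1-unit increase, mg/min         0.989 0.935  1.05  0.704
#>  2 Age            >= 65 vs < 65 years             0.874 0.666  1.15  0.334
#>  3 Sex            Female vs male                  1.14  0.860  1.50  0.368
#>  4 Region         Asia vs rest of the world       2.02  1.56   2.63  0.000000137
#>  5 Premedication  Yes vs no                       0.582 0.401  0.843 0.00417
#>  ...
```

Read the output the way a safety review would: at a pooled incidence of
~7.7% the fitted rate coefficient is compatible with no association
(OR 0.989/mg/min, p = 0.70), the quartile incidences show no monotone
trend, while region (Asia), lack of premedication and chemotherapy carry
the real signal — all mirroring the generating model, whose coefficients
are the published odds ratios (`ramucirumab_irr_odds_ratios()`).

A YAML-driven run of the whole pipeline (cohort generation, IRR analysis,
arm simulation, exposure comparison, with audit sidecars per artifact):

```r
run_pipeline(system.file("extdata", "demo-run.yaml", package = "ramupk"),
             out_dir = "demo-out")
```

Plotting helpers: `plot_profile_bands()` (population concentration
bands), `autoplot()` on a VPC summary, `plot_incidence()` on a quartile
table. `tidy()`/`glance()` methods cover the fitted objects.

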