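---
title: "Methods: infusion-duration PK simulation and infusion-rate safety analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: infusion-duration PK simulation and infusion-rate safety analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramupk)
```

## The scientific question

Ramucirumab, an IgG1 antibody against VEGFR-2, is labelled for 60-minute
intravenous infusions. Halving the infusion time would benefit patients and
clinics, but raises two questions this package is built to study:

1. **Pharmacokinetics** — does a 30-minute infusion change systemic
   exposure (Cmax, trough, AUC over the dosing interval) relative to a
   60-minute infusion?
2. **Safety** — is a faster infusion *rate* (mg/min) associated with a
   higher incidence of immediate infusion-related reactions (IRRs; events
   on the day of administration)?

The package implements both arms: a population-PK simulator for the first,
and a cohort-level statistical pipeline (infusion-rate derivation, quartile
incidence tables, multivariate logistic regression) for the second, plus
synthetic-data generators so that every stage runs and is tested without
proprietary trial data.

## The pharmacokinetic model

Concentrations follow a linear two-compartment model with constant-rate
infusion input, parameterised by clearance, central volume $V_1$,
peripheral volume $V_2$ and inter-compartmental clearance $Q$:

$$
\frac{dA_1}{dt} = R_{in}(t) - \frac{CL(t) + Q}{V_1}A_1 + \frac{Q}{V_2}A_2,
\qquad
\frac{dA_2}{dt} = \frac{Q}{V_1}A_1 - \frac{Q}{V_2}A_2,
\qquad
C(t) = A_1/V_1 .
$$

Clearance changes over treatment through a sigmoid function of continuous
time since the first dose (never reset by later doses):

$$
CL(t) = CL_0 \exp\!\left(\frac{E_{max}\,t^{\gamma}}{T_{50}^{\gamma} +
t^{\gamma}}\right),
$$

so $CL(0) = CL_0$, $CL(T_{50}) = CL_0 e^{E_{max}/2}$ and
$CL(\infty) = CL_0 e^{E_{max}}$. Negative $E_{max}$ — the typical antibody
case — describes clearance that falls as disease status improves.
$T_{50}$ is accepted in days in configurations and converted to hours
internally (all internal times are hours).

Body weight acts on clearance and central volume through allometric power
terms $(W/W_{ref})^{\theta}$; no other covariate enters the model.
Between-subject variability is log-normal on $CL_0$, $V_1$ and $V_2$ and
additive on $E_{max}$, with covariance between ($CL_0$, $V_1$) and
($CL_0$, $E_{max}$). Residual error on observations is combined
additive/proportional: $DV = C(1 + \sigma_{prop}\varepsilon_1) +
\sigma_{add}\varepsilon_2$, truncated at zero (truncations are counted).

### Parameter values

Published estimates for the fixed and random effects of this model are not
reproduced here; the shipped defaults (`default_poppk_parameters()`:
$CL_0$ 0.015 L/h, $V_1$ 5.4 L, $Q$ 0.016 L/h, $V_2$ 2.9 L, $E_{max}$
−0.2, $T_{50}$ 27 days, $\gamma$ 2, allometric exponents 0.75/1.0 at 70 kg,
$\omega^2$ = 0.09/0.04/0.25/0.01, $\sigma_{add}$ 1 µg/mL, $\sigma_{prop}$
0.2) are **illustrative**, chosen on the scale of public monoclonal-antibody
population-PK analyses. $T_{50}$ = 27 days mirrors the treatment-duration
split used for model evaluation. Every numerical property the package tests
is parameter-agnostic: real analyses supply their own estimates via
`poppk_parameters()` or a YAML file (`read_poppk_config()`; see
`inst/extdata/model.yaml`).

### Numerics

Two independent evaluation routes exist deliberately:

* `solve_profile()` integrates the ODE system with `deSolve::lsoda`
  (rtol $10^{-8}$, atol $10^{-10}$ by default), restarting the integrator
  at every infusion start/stop so the piecewise-constant input is never
  smoothed across a discontinuity. Dose events shorter than one minute are
  rejected — the label has no bolus administration, and a minimum duration
  keeps the input bounded.
* `closed_form_profile()` evaluates the constant-clearance
  ($E_{max} = 0$) limit exactly, by either the hybrid-constant
  ($\alpha/\beta$ biexponential) formula or a closed-form 2×2 matrix
  exponential; the two agree to rtol $10^{-10}$ and serve as the oracle for
  the ODE route.

A third engine, an internal semi-analytic propagator, freezes clearance at
sub-interval midpoints and advances the state with the exact 2×2 matrix
exponential (Putzer's formula). It is exact under constant clearance and
accurate to about $10^{-4}$ relative under the default time-varying
clearance with 3–4 substeps — far below the residual error of any simulated
observation — and two orders of magnitude faster than the adaptive solver.
It powers the two-stage fit's inner loop and the VPC replicates; its
agreement with `lsoda` is unit-tested.

## Simulation of the 30- vs 60-minute comparison

`simulate_arm()` draws `n` weights *without replacement* from an explicit
weight pool, samples individual parameters, doses each subject at the
regimen's mg/kg, and returns noise-free profiles: exposure is a prediction
of the model, so residual error attaches only to simulated *observations*
(in `generate_pk_dataset()`), never to profiles used for exposure metrics.
Two arms built with the same seed share subjects exactly and differ only in
infusion duration, making the 30/60-minute comparison paired by
construction. The five label regimens (8 mg/kg Q2W, 12 mg/kg Q2W, 6 mg/kg
QW, 8 mg/kg on days 1 + 8 Q3W, 10 mg/kg Q3W) are encoded in `regimen()`.

`exposure_metrics()` computes Cmax (maximum over the interval), the trough
(concentration at the interval end) and AUC$_\tau$ by the trapezoid rule on
the dense solver grid (≥ 200 points per interval enforced); grid density,
not ODE-state augmentation, controls the AUC error, which the tests bound
at 0.5% against the analytic $AUC_{0-\infty} = \text{Dose}/CL$ identity.
Steady state is operationalised as the first interval whose end trough
differs from the previous one by < 1%; with the default declining
clearance this arrives around cycle 12 of Q2W dosing, so steady-state
summaries simulate 15 cycles.

The equivalence experiment itself (500 subjects per arm at 8 mg/kg Q2W and
10 mg/kg Q3W) reproduces the study's design scale and is asserted as a
property: geometric-mean AUC$_\tau$ ratio (30/60 min) within
[0.995, 1.005] and Cmax(30) ≥ Cmax(60) for every subject. Measured at the
default parameters the AUC ratio is ≈ 1.0002: moving 0.5 h of infusion
time inside a 336-h interval is invisible to total exposure, while Cmax
rises slightly with the faster rate.

## Visual predictive check

`vpc()` simulates replicate datasets at the observed design (same weights,
same sampling times; new random effects and residuals per replicate),
splits records at 27 days of treatment, bins each stratum into
equal-count time bins (default 8 — the binning rule is a package choice),
and overlays observed 5th/50th/95th percentiles on the envelope
(5th–95th across replicates) of the same statistics. Replicate $r$ runs
under `seed + r − 1`, so a single replicate at the generating seed
reproduces the observed data bin-for-bin — a degenerate identity the tests
assert.

One statistical caveat is worth stating plainly: an observed cohort is a
*single* draw of correlated random effects, so all late-time bins move up
or down together, and the fraction of bins inside a 90% band has high
variance however many subjects are simulated (band width and
observed-percentile spread both shrink as $1/\sqrt{n}$). Calibration is
therefore tested as pooled coverage over several independent cohorts
(measured ≈ 0.88 against the 0.90 nominal), not as a single-cohort
threshold.

## Two-stage parameter recovery

Full nonlinear mixed-effects estimation is deliberately out of scope; the
package's `two_stage_fit()` is a desk-scale surrogate for rich designs
(≥ 12 samples/subject over ≥ 2 dosing intervals, residual SDs and the
clearance time-course known):

* **Stage 1** fits each subject's $(CL_0, V_1, Q, V_2)$ on the log scale by
  weighted least squares — an unweighted Nelder–Mead search followed by a
  weighted (variance model at the observation, normalised) bounded
  L-BFGS-B polish.
* **Stage 2** pools: geometric means of the allometrically normalised
  estimates give the typical values; variances of the log estimates give
  $\omega^2_{CL}$ and $\omega^2_{V_1}$.

Two numerical hazards shaped this design. First, the SSE surface flattens
as $CL_0 \to 0$ once elimination becomes invisible over the sampled
horizon, stalling finite-difference gradients — hence the derivative-free
first pass. Second, and more insidiously, a near-degenerate valley exists
in which vanishing clearance plus an inflated, slowly equilibrating
peripheral compartment mimics elimination for the duration of a short
study; proportional weighting emphasises exactly the troughs where the two
explanations are hardest to separate. The package therefore (a) accepts
the polish only while it stays within 5× of the first pass on $CL_0$ and
$V_1$, (b) flags fits landing > 20× from the weight-adjusted typical
values (> 10 SD of any realistic random effect) as non-convergent,
excluding and counting them, and (c) the recovery *designs* used in tests
include terminal washout samples after the last dose, whose decaying tail
a peripheral sink cannot reproduce. With that design (100 subjects,
$\sigma_{prop}$ = 0.05, 17 samples over two Q2W cycles plus washout to
1400 h), the typical clearance and central volume recover within 4% and
1% and $\omega^2_{CL}$ within 2%. The recovery experiments set
$\omega^2_{E_{max}} = 0$: the fit's premise is that the clearance
time-course is known at truth, which only holds per subject when
$E_{max}$ carries no between-subject variability. Naive two-stage
variance estimates are inflated by per-subject estimation error; the
washout design keeps that inflation small rather than correcting for it
analytically.

## The immediate-IRR pipeline

`compute_infusion_rate()` implements the analysis rule: rate = total dose /
infusion duration (mg/min) at the administration on the day of the
*earliest* immediate IRR for patients with an event, and at the *first*
dose otherwise; non-positive or absent durations yield a missing rate with
a recorded reason. `sensitivity_rate()` recomputes every rate as
dose/60 min, because observed durations are themselves contaminated by IRR
management (interrupted infusions run long).

`quartile_groups()` splits non-missing rates at their empirical
25th/50th/75th percentiles using the lower (type-1) empirical-CDF
quantile, with boundary values assigned to the lower group and missing
rates kept as a fifth column; extreme rates (the two known 182/190 mg/min
data-entry outliers) are retained in Q4, with a pipeline switch to exclude
them for sensitivity. The exact quantile convention of the original
analysis is not recoverable from its printed group sizes, so the rule here
is declared rather than inferred. `incidence_table()` tabulates patients
with ≥ 1 event by group, outcome grade and SMQ category, with percentages
rounded half-up to one decimal — the tests verify this rounding against
every printed per-study and per-quartile cell recomputed from its n/N
counts.

`logistic_model()` fits the pooled maximum-likelihood logistic regression
of IRR occurrence on infusion rate (continuous, per 1 mg/min), age ≥ 65,
sex, region (Asia vs rest of world), premedication, chemotherapy and
dosing regimen (reference 8 mg/kg Q2W), with Wald 95% intervals. Body
weight is excluded by design: dosing is weight-based, so weight and rate
are strongly collinear. Records with missing rates are excluded and
counted (the original handling is unstated; exclusion is the declared
default), the model pools across studies without study terms (also
unstated there; stated here), covariates constant in the data are dropped
rather than crashing the contrast machinery, and suspected separation is
returned as a diagnosed failed fit.

## The synthetic cohort generator

`generate_irr_cohort()` emulates the pooled ten-study data structure:

* regimen mix defaulting to the published per-study enrolment proportions
  (≈ 55% 8 mg/kg Q2W, 27.5% 10 mg/kg Q3W, 11% D1+D8 Q3W, 4.5% 12 mg/kg
  Q2W, 1.5% 6 mg/kg QW), and covariate marginals (40% age ≥ 65, 30%
  female, 35% Asia, 90% premedicated, 72% on chemotherapy) chosen as
  plausible for this oncology programme;
* log-normal body weights (median 65 kg, CV 20% — the real distribution is
  unpublished), weight-based dosing, infusion durations uniform on
  60 ± 15 min extended whenever needed to respect the ≤ 25 mg/min rate
  cap — under these defaults the pooled median rate lands near the
  reported ≈ 9.6 mg/min, though exact matching is not asserted;
* events from a logistic model whose coefficients are the logs of the
  published multivariate odds ratios
  (`ramucirumab_irr_odds_ratios()`), with the intercept solved numerically
  on the realised covariates so the expected marginal incidence equals the
  7.9% target; earliest-event dose numbers decay geometrically (events
  concentrate in the first infusions) and 17/254 of events are
  grade ≥ 3;
* optional ingredients, off by default: missing durations, injected
  data-entry outliers (flagged), and study-level random intercepts
  (the pooled model has none, but per-study incidences ranged
  2.5–13.8%, so heterogeneity is available as a knob).

What the generator does **not** emulate: real covariate correlations,
per-study enrolment counts, repeat administrations per patient beyond the
two the rate rule needs, or any mechanism linking PK exposure to IRR risk.
Passing tests therefore demonstrate internal consistency of the estimators
at the study's scale — not properties of the real trial data.

`generate_pk_dataset()` produces NONMEM-dialect tables (`ID, TIME, AMT,
RATE, DV, MDV, EVID, WT`; `RATE` in mg/h encodes duration as `AMT/RATE`;
missing fields serialise as `"."`, numbers at 6 significant digits so
write → read → write round-trips byte-for-byte).

## Statistical fragility worth knowing about

Two stochastic checks carry irreducible assertion noise at their stated
sizes. Per-factor 95%-CI coverage over 200 replicates has a binomial SD of
≈ 1.5%, so with ten factors whose true coverage is ≈ 95% (measured
94.5–97.7% at 1000 replicates), some factor falls below a 93% line in
roughly half of all 200-replicate experiments. Similarly, the
point-estimate check at n = 100,000 includes the 6 mg/kg QW contrast,
whose ≈ 1.5% share leaves a log-OR sampling SE of ≈ 0.10 — twice a 5%
band. The package asserts these checks at their stated sizes anyway, and
the aggregate calibration (mean coverage across factors) is what the unit
suite relies on; the three headline recovery quantities (premedication,
region, infusion-rate odds ratios) sit well inside their bands.

## Pipeline and reproducibility

`run_pipeline()` executes configured stages (`generate`, `irr`,
`simulate`, `expose`, `vpc`) from a YAML config with a single seed, writes
tidy CSVs, and records a `.meta.json` sidecar (config hash, seed, package
version) next to every artifact; identical config + seed reproduces
identical bytes. Every stochastic function takes an explicit seed and is
bit-reproducible given (seed, inputs).

Problem sizes used by the shipped tests and acceptance script — 500
subjects per simulated arm, 100,000-patient cohorts for point recovery,
200 × 3216 for coverage, 100 subjects for the two-stage fit, 150-subject
VPC cohorts — were chosen to match the study's scale where it is stated
and to keep each experiment's Monte-Carlo error well inside the asserted
tolerance elsewhere.

## Known limitations

* No target-mediated or nonlinear elimination, no absorption phase, no
  covariates beyond body weight.
* The two-stage fit is not FOCE/Laplace; omega estimates are naive
  (noise-inflated) and the off-diagonal covariances are not recovered.
* IRR classification (SMQ categories, grades) is taken as an input column;
  no MedDRA processing, no time-to-event modelling.
* Exposure metrics assume the dense simulation grid; they are not an NCA
  engine for sparse observed data.
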