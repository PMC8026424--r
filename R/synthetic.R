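#' Published multivariate odds ratios for immediate-IRR risk
#'
#' The odds ratios from the pooled ten-study multivariate logistic analysis
#' of immediate infusion-related reactions, used throughout the package as
#' the generating truth for synthetic cohorts: infusion rate (per 1 mg/min)
#' 1.014, age >= 65 0.831, female sex 1.127, Asian region 2.151,
#' premedication 0.519, chemotherapy 1.443, and the regimen contrasts against
#' 8 mg/kg Q2W (10 mg/kg Q3W 0.790; 12 mg/kg Q2W 0.456; 6 mg/kg QW 0.922;
#' 8 mg/kg D1D8 Q3W 0.505).
#'
#' @return Tibble: `factor`, `comparison`, `term`, `or`.
#' @export
ramucirumab_irr_odds_ratios <- function() {
  tibble::tibble(
    factor = c("Infusion rate", "Age", "Sex", "Region", "Premedication",
               "Chemotherapy", rep("Dosing regimen", 4)),
    comparison = c("1-unit increase, mg/min", ">= 65 vs < 65 years",
                   "Female vs male", "Asia vs rest of the world",
                   "Yes vs no", "Yes vs no",
                   "10 mg/kg Q3W vs 8 mg/kg Q2W",
                   "12 mg/kg Q2W vs 8 mg/kg Q2W",
                   "6 mg/kg QW vs 8 mg/kg Q2W",
                   "8 mg/kg D1D8 Q3W vs 8 mg/kg Q2W"),
    term = c("rate", "age_ge_65", "sexfemale", "region_asia",
             "premedication", "chemotherapy",
             "regimen10Q3W", "regimen12Q2W", "regimen6QW", "regimen8D1D8Q3W"),
    or = c(1.014, 0.831, 1.127, 2.151, 0.519, 1.443,
           0.790, 0.456, 0.922, 0.505)
  )
}

regimen_dose_per_kg <- c("8Q2W" = 8, "10Q3W" = 10, "12Q2W" = 12,
                         "6QW" = 6, "8D1D8Q3W" = 8)

#' Specify a synthetic immediate-IRR cohort
#'
#' Defaults emulate the pooled phase II/III dataset: ~3216 patients across
#' five weight-based regimens (mix approximating the per-study enrolment),
#' log-normal body weights (median 65 kg, CV 20%), infusions of 60 +/- up to
#' 15 min extended whenever needed to keep the rate at or below 25 mg/min,
#' a 7.9% marginal incidence of immediate IRRs, and generating log-odds
#' equal to the logs of the published multivariate odds ratios.
#'
#' @param n_patients Cohort size.
#' @param incidence_target Target marginal any-grade incidence, in (0, 1).
#' @param odds_ratios Tibble like [ramucirumab_irr_odds_ratios()] giving the
#'   generating odds ratios per model term.
#' @param prop_age_ge_65,prop_female,prop_region_asia,prop_premedication,prop_chemotherapy
#'   Marginal covariate probabilities.
#' @param prob_regimen Named probabilities over the five regimen labels.
#' @param weight_median,weight_cv Log-normal body-weight distribution.
#' @param duration_min_lo,duration_min_hi Uniform range of drawn infusion
#'   durations (minutes) before the rate cap is applied.
#' @param rate_cap_mg_min Infusions are extended so dose/duration never
#'   exceeds this rate (`Inf` disables the cap).
#' @param prop_missing_duration Fraction of records whose recorded duration
#'   is set missing (emulating data-entry gaps).
#' @param prob_grade_ge3 Probability an IRR patient's worst event is
#'   grade >= 3 (default 17/254, the pooled proportion).
#' @param outliers Optional tibble (`dose_mg`, `duration_min`) of
#'   deliberately injected data-entry outliers, flagged `is_outlier`;
#'   default none (clean cohort).
#' @param study_sigma SD of optional study-level random intercepts (log-odds
#'   scale) over `n_studies` studies; 0 (default) reproduces the pooled
#'   no-heterogeneity model.
#' @param n_studies Number of studies when `study_sigma > 0`.
#' @param seed Integer seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 3216,
                        incidence_target = 0.079,
                        odds_ratios = ramucirumab_irr_odds_ratios(),
                        prop_age_ge_65 = 0.40,
                        prop_female = 0.30,
                        prop_region_asia = 0.35,
                        prop_premedication = 0.90,
                        prop_chemotherapy = 0.72,
                        prob_regimen = c("8Q2W" = 0.555, "10Q3W" = 0.275,
                                         "12Q2W" = 0.045, "6QW" = 0.015,
                                         "8D1D8Q3W" = 0.11),
                        weight_median = 65, weight_cv = 0.20,
                        duration_min_lo = 45, duration_min_hi = 75,
                        rate_cap_mg_min = 25,
                        prop_missing_duration = 0,
                        prob_grade_ge3 = 17 / 254,
                        outliers = NULL,
                        study_sigma = 0, n_studies = 10,
                        seed = 1L) {
  stopifnot(n_patients >= 1)
  if (incidence_target <= 0 || incidence_target >= 1) {
    stop("`incidence_target` must lie strictly in (0, 1)", call. = FALSE)
  }
  props <- c(prop_age_ge_65, prop_female, prop_region_asia,
             prop_premedication, prop_chemotherapy, prop_missing_duration)
  if (any(props < 0 | props > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  if (!setequal(names(prob_regimen), names(regimen_dose_per_kg)) ||
      abs(sum(prob_regimen) - 1) > 1e-8 || any(prob_regimen < 0)) {
    stop("`prob_regimen` must be probabilities over the five regimen labels summing to 1",
         call. = FALSE)
  }
  stopifnot(duration_min_lo >= 1, duration_min_hi >= duration_min_lo,
            rate_cap_mg_min > 0, weight_median > 0, weight_cv > 0)
  structure(
    list(n_patients = as.integer(n_patients),
         incidence_target = incidence_target, odds_ratios = odds_ratios,
         prop_age_ge_65 = prop_age_ge_65, prop_female = prop_female,
         prop_region_asia = prop_region_asia,
         prop_premedication = prop_premedication,
         prop_chemotherapy = prop_chemotherapy,
         prob_regimen = prob_regimen[names(regimen_dose_per_kg)],
         weight_median = weight_median, weight_cv = weight_cv,
         duration_min_lo = duration_min_lo,
         duration_min_hi = duration_min_hi,
         rate_cap_mg_min = rate_cap_mg_min,
         prop_missing_duration = prop_missing_duration,
         prob_grade_ge3 = prob_grade_ge3,
         outliers = outliers, study_sigma = study_sigma,
         n_studies = as.integer(n_studies), seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Draw an infusion duration under the 60 +/- 15 min policy, then extend it
# whenever dose/duration would exceed the rate cap.
draw_durations <- function(n, dose_mg, spec) {
  dur <- stats::runif(n, spec$duration_min_lo, spec$duration_min_hi)
  pmax(dur, dose_mg / spec$rate_cap_mg_min)
}

#' Generate a synthetic immediate-IRR cohort
#'
#' Samples covariates and weight-based doses, draws infusion durations under
#' the rate-cap policy, and assigns immediate-IRR events from a logistic
#' model whose linear predictor uses the generating log-odds coefficients.
#' The intercept is solved numerically on the realised covariates so the
#' expected marginal incidence equals the target. IRR patients get an
#' earliest-event dose index drawn from a geometric distribution (events
#' concentrate in the first infusions) and a separate infusion duration for
#' the event-day administration.
#'
#' @param spec A `cohort_spec`.
#' @return Tibble of patient records: identifiers, covariates, `regimen`,
#'   `weight_kg`, `dose_mg`, `duration_min`, event-day dose/duration,
#'   `irr_flag`, `irr_grade_ge3`, `irr_category`,
#'   `earliest_irr_dose_index`, `is_outlier`, `study_id`.
#' @export
generate_irr_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  ors <- stats::setNames(log(spec$odds_ratios$or), spec$odds_ratios$term)

  withr::with_seed(spec$seed, {
    regimen <- sample(names(spec$prob_regimen), n, replace = TRUE,
                      prob = spec$prob_regimen)
    age_ge_65 <- stats::runif(n) < spec$prop_age_ge_65
    female <- stats::runif(n) < spec$prop_female
    region_asia <- stats::runif(n) < spec$prop_region_asia
    premedication <- stats::runif(n) < spec$prop_premedication
    chemotherapy <- stats::runif(n) < spec$prop_chemotherapy
    sdlog <- sqrt(log(1 + spec$weight_cv^2))
    weight <- stats::rlnorm(n, log(spec$weight_median), sdlog)
    dose <- unname(regimen_dose_per_kg[regimen]) * weight
    duration <- draw_durations(n, dose, spec)
    study_id <- sample.int(spec$n_studies, n, replace = TRUE)
    study_eff <- if (spec$study_sigma > 0) {
      stats::rnorm(spec$n_studies, 0, spec$study_sigma)[study_id]
    } else {
      rep(0, n)
    }

    rate <- dose / duration
    reg_terms <- paste0("regimen", regimen)
    lp <- ors[["rate"]] * rate +
      ors[["age_ge_65"]] * age_ge_65 +
      ors[["sexfemale"]] * female +
      ors[["region_asia"]] * region_asia +
      ors[["premedication"]] * premedication +
      ors[["chemotherapy"]] * chemotherapy +
      ifelse(regimen == "8Q2W", 0, ors[reg_terms]) +
      study_eff

    f <- function(b0) mean(stats::plogis(b0 + lp)) - spec$incidence_target
    lo <- -30; hi <- 30
    if (f(lo) > 0 || f(hi) < 0) {
      stop("target incidence infeasible given the generating coefficients ",
           "(mean linear predictor out of range)", call. = FALSE)
    }
    b0 <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    irr_flag <- stats::runif(n) < stats::plogis(b0 + lp)

    n_irr <- sum(irr_flag)
    earliest <- rep(NA_integer_, n)
    earliest[irr_flag] <- stats::rgeom(n_irr, prob = 0.45) + 1L
    irr_day_duration <- rep(NA_real_, n)
    irr_day_duration[irr_flag] <- draw_durations(n_irr, dose[irr_flag], spec)
    grade_ge3 <- irr_flag & stats::runif(n) < spec$prob_grade_ge3
    categories <- c("anaphylactic", "angioedema", "hypersensitivity",
                    "cytokine_release", "irr_pt")
    cat_w <- c(3, 40, 174, 4, 86)  # pooled category mix among IRR patients
    irr_category <- rep(NA_character_, n)
    irr_category[irr_flag] <- sample(categories, n_irr, replace = TRUE,
                                     prob = cat_w / sum(cat_w))

    if (spec$prop_missing_duration > 0) {
      miss <- stats::runif(n) < spec$prop_missing_duration
      duration[miss] <- NA_real_
      irr_day_duration[miss & irr_flag] <- NA_real_
    }

    out <- tibble::tibble(
      patient_id = seq_len(n),
      study_id = study_id,
      regimen = factor(regimen, levels = names(regimen_dose_per_kg)),
      weight_kg = weight,
      dose_mg = dose,
      duration_min = duration,
      irr_flag = irr_flag,
      irr_grade_ge3 = grade_ge3,
      irr_category = irr_category,
      earliest_irr_dose_index = earliest,
      irr_day_dose_mg = ifelse(irr_flag, dose, NA_real_),
      irr_day_duration_min = irr_day_duration,
      age_ge_65 = age_ge_65,
      sex = factor(ifelse(female, "female", "male"),
                   levels = c("male", "female")),
      region_asia = region_asia,
      premedication = premedication,
      chemotherapy = chemotherapy,
      is_outlier = FALSE
    )
    if (!is.null(spec$outliers) && nrow(spec$outliers) > 0) {
      k <- nrow(spec$outliers)
      idx <- seq_len(k)
      out$dose_mg[idx] <- spec$outliers$dose_mg
      out$duration_min[idx] <- spec$outliers$duration_min
      out$irr_day_dose_mg[idx] <- ifelse(out$irr_flag[idx],
                                         spec$outliers$dose_mg, NA_real_)
      out$irr_day_duration_min[idx] <- ifelse(out$irr_flag[idx],
                                              spec$outliers$duration_min,
                                              NA_real_)
      out$is_outlier[idx] <- TRUE
    }
    out
  })
}

#' Specify a synthetic PK observation design
#'
#' @param n_subjects Number of subjects.
#' @param reg A `regimen` (defines doses and the simulated horizon).
#' @param sampling_times_h Sampling times, hours since first dose; all must
#'   lie within the simulated horizon `n_cycles * tau`.
#' @param weight_median,weight_cv Log-normal body-weight distribution.
#' @param seed Integer seed.
#' @return A `pk_design_spec` object.
#' @export
pk_design_spec <- function(n_subjects, reg, sampling_times_h,
                           weight_median = 65, weight_cv = 0.20, seed = 1L) {
  stopifnot(inherits(reg, "regimen"), n_subjects >= 1,
            length(sampling_times_h) >= 1)
  if (any(sampling_times_h < 0)) {
    stop("sampling times must be non-negative", call. = FALSE)
  }
  # the simulated horizon covers the dosing window plus any washout samples
  # after the last dose
  structure(
    list(n_subjects = as.integer(n_subjects), regimen = reg,
         sampling_times_h = sort(sampling_times_h),
         weight_median = weight_median, weight_cv = weight_cv,
         seed = as.integer(seed)),
    class = "pk_design_spec"
  )
}

# Per-subject propagator closures for a fixed design (dose schedule and
# sampling layout). The geometry is replicate-invariant, so VPC replicates
# pay only the evaluation arithmetic.
.design_propagators <- function(pop, reg, subjects, samples) {
  lapply(seq_len(nrow(subjects)), function(i) {
    tt <- samples$time_h[samples$subject_id == subjects$subject_id[i]]
    dos <- dose_schedule(reg, subjects$weight[i])
    .make_propagator(pop, dos, tt, substeps = 4L)
  })
}

# Shared observation simulator: given subjects (subject_id, weight) and a
# sample layout (subject_id, time_h), draw etas and residuals from a single
# seeded stream and return true + observed concentrations. Both
# generate_pk_dataset() and vpc() route through this, so a VPC replicate run
# at the generating seed reproduces the observed dataset exactly. True
# profiles come from the semi-analytic propagator (~1e-4 relative accuracy,
# far below the residual noise applied on top).
.simulate_observations <- function(pop, reg, subjects, samples, seed,
                                   props = NULL) {
  if (is.null(props)) props <- .design_propagators(pop, reg, subjects, samples)
  n_per <- tabulate(match(samples$subject_id, subjects$subject_id),
                    nbins = nrow(subjects))
  if (!identical(as.vector(rep(subjects$subject_id, n_per)),
                 as.vector(samples$subject_id))) {
    stop("`samples` must be grouped by subject in the order of `subjects`",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    eta <- if (all(pop$omega == 0)) {
      matrix(0, nrow(subjects), 4)
    } else {
      MASS::mvrnorm(nrow(subjects), mu = rep(0, 4), Sigma = pop$omega)
    }
    if (is.null(dim(eta))) eta <- matrix(eta, nrow = 1)
    typ <- apply_weight_covariates(pop, subjects$weight)
    inds <- tibble::tibble(
      subject_id = subjects$subject_id, weight = subjects$weight,
      cl0_i = typ$cl0 * exp(eta[, 1]), v1_i = typ$v1 * exp(eta[, 2]),
      v2_i = typ$v2 * exp(eta[, 3]), q_i = typ$q,
      emax_i = pop$emax + eta[, 4]
    )
    conc_true <- unlist(lapply(seq_len(nrow(inds)), function(i) {
      props[[i]](inds$cl0_i[i], inds$v1_i[i], inds$v2_i[i], inds$q_i[i],
                 inds$emax_i[i])
    }), use.names = FALSE)
    obs <- tibble::tibble(
      subject_id = rep(inds$subject_id, n_per),
      weight = rep(inds$weight, n_per),
      time_h = samples$time_h,
      conc_true = conc_true
    )
    eps_prop <- stats::rnorm(nrow(obs), 0, 1)
    eps_add <- stats::rnorm(nrow(obs), 0, 1)
    dv_raw <- obs$conc_true * (1 + pop$sigma_prop * eps_prop) +
      pop$sigma_add * eps_add
    obs$dv <- pmax(dv_raw, 0)
    obs$truncated <- dv_raw < 0
    list(observations = obs, individuals = inds, dv = obs$dv)
  })
}

#' Generate a synthetic NONMEM-style PK dataset
#'
#' Simulates true profiles under the population model, applies the
#' additive/proportional residual-error model
#' `DV = C (1 + sigma_prop * eps1) + sigma_add * eps2`, truncates negative
#' observations at zero (flagged), and emits standard pharmacometrics rows:
#' dosing rows (`EVID = 1` with `AMT` in mg and `RATE` in mg/h) and
#' observation rows (`EVID = 0` with `DV` in ug/mL).
#'
#' @param spec A `pk_design_spec`.
#' @param pop A `poppk_parameters`.
#' @return Tibble with columns `ID`, `TIME`, `AMT`, `RATE`, `DV`, `MDV`,
#'   `EVID`, `WT`; the number of zero-truncated observations is attached as
#'   attribute `"n_truncated"`, the long-format observations (with true
#'   concentrations) as `"observations"` and the individual parameters as
#'   `"individuals"`.
#' @export
generate_pk_dataset <- function(spec, pop) {
  stopifnot(inherits(spec, "pk_design_spec"),
            inherits(pop, "poppk_parameters"))
  subjects <- withr::with_seed(spec$seed + 1000000L, {
    sdlog <- sqrt(log(1 + spec$weight_cv^2))
    tibble::tibble(
      subject_id = seq_len(spec$n_subjects),
      weight = stats::rlnorm(spec$n_subjects, log(spec$weight_median), sdlog)
    )
  })
  samples <- tidyr::expand_grid(subject_id = subjects$subject_id,
                                time_h = spec$sampling_times_h)
  sim <- .simulate_observations(pop, spec$regimen, subjects, samples,
                                seed = spec$seed)
  obs <- sim$observations

  dose_rows <- dplyr::bind_rows(lapply(seq_len(nrow(subjects)), function(i) {
    dos <- dose_schedule(spec$regimen, subjects$weight[i])
    tibble::tibble(
      ID = subjects$subject_id[i], TIME = dos$start_h, AMT = dos$amount_mg,
      RATE = dos$amount_mg / dos$duration_h, DV = NA_real_,
      MDV = 1L, EVID = 1L, WT = subjects$weight[i]
    )
  }))
  obs_rows <- tibble::tibble(
    ID = obs$subject_id, TIME = obs$time_h, AMT = NA_real_, RATE = NA_real_,
    DV = obs$dv, MDV = 0L, EVID = 0L, WT = obs$weight
  )
  out <- dplyr::arrange(dplyr::bind_rows(dose_rows, obs_rows),
                        .data$ID, .data$TIME, dplyr::desc(.data$EVID))
  attr(out, "n_truncated") <- sum(obs$truncated)
  attr(out, "observations") <- obs
  attr(out, "individuals") <- sim$individuals
  out
}
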