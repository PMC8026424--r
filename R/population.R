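#' Draw individual PK parameters for a set of subjects
#'
#' Random effects (eta_cl, eta_v1, eta_v2, eta_emax) are drawn from a
#' multivariate normal with covariance `pop$omega`. Clearance and the two
#' volumes carry exponential (log-normal) between-subject variability on the
#' weight-adjusted typical values; Emax carries an additive term:
#' `cl0_i = typical(weight) * exp(eta_cl)`, `emax_i = emax + eta_emax`.
#'
#' @param pop A `poppk_parameters` object (omega must be PSD).
#' @param weights Vector of body weights, one subject per element.
#' @param seed Integer seed; draws are bit-reproducible given `(seed, inputs)`.
#' @return A tibble: `subject_id`, `weight`, `cl0_i`, `v1_i`, `v2_i`, `q_i`,
#'   `emax_i`.
#' @export
sample_population <- function(pop, weights, seed = 1L) {
  stopifnot(inherits(pop, "poppk_parameters"))
  if (length(weights) == 0L || any(!is.finite(weights)) || any(weights <= 0)) {
    stop("`weights` must be a non-empty vector of positive weights",
         call. = FALSE)
  }
  n <- length(weights)
  eta <- withr::with_seed(seed, {
    if (all(pop$omega == 0)) {
      matrix(0, n, 4)
    } else {
      MASS::mvrnorm(n, mu = rep(0, 4), Sigma = pop$omega)
    }
  })
  if (is.null(dim(eta))) eta <- matrix(eta, nrow = 1)
  typ <- apply_weight_covariates(pop, weights)
  tibble::tibble(
    subject_id = seq_len(n),
    weight = weights,
    cl0_i = typ$cl0 * exp(eta[, 1]),
    v1_i = typ$v1 * exp(eta[, 2]),
    v2_i = typ$v2 * exp(eta[, 3]),
    q_i = typ$q,
    emax_i = pop$emax + eta[, 4]
  )
}

#' Default dense output grid for a regimen
#'
#' At least 200 points per dosing interval, with extra resolution in the
#' first hours after each dose start so the infusion peak is captured.
#'
#' @param reg A `regimen`.
#' @param points_per_interval Minimum grid points per interval.
#' @return Sorted numeric vector of times (h).
#' @export
profile_grid <- function(reg, points_per_interval = 240) {
  tau <- regimen_tau(reg)
  n_int <- ceiling(reg$n_cycles * switch(reg$schedule, D1D8_Q3W = 1, 1))
  horizon <- reg$n_cycles * tau
  base <- seq(0, horizon, length.out = reg$n_cycles * points_per_interval + 1)
  starts <- dose_schedule(reg, weight = 70)$start_h
  fine <- as.vector(outer(c(0, reg$infusion_duration_min / 60 * c(0.5, 1, 1.01),
                            2, 4), starts, `+`))
  sort(unique(round(c(base, fine[fine <= horizon]), 9)))
}

#' Simulate one arm of an infusion-duration comparison
#'
#' Samples `n` weights without replacement from `weight_pool`, draws
#' individual parameters, builds each subject's weight-based dose schedule
#' and integrates the noise-free profiles. Residual error is never added
#' here: exposure is computed from model-predicted ("true") profiles;
#' observation noise belongs to the synthetic-data generator.
#'
#' @param pop A `poppk_parameters` object.
#' @param reg A `regimen` (its `infusion_duration_min` defines the arm).
#' @param n Number of subjects (`n <= length(weight_pool)`).
#' @param weight_pool Pool of body weights sampled without replacement.
#' @param seed Integer seed; weight sampling and eta draws are reproducible.
#'   Two arms differing only in infusion duration share subjects and
#'   parameters when given the same seed.
#' @param times Output grid; defaults to [profile_grid()].
#' @param rtol,atol Solver tolerances passed to [solve_profile()].
#' @return An `arm_simulation` object: list with `profiles` (tibble
#'   `subject_id`, `time_h`, `conc_ug_ml`), `individuals`, `doses`,
#'   `regimen`, `seed`.
#' @export
simulate_arm <- function(pop, reg, n, weight_pool, seed = 1L,
                         times = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(reg, "regimen"))
  if (n > length(weight_pool)) {
    stop("`n` exceeds the size of the weight pool (sampling is without replacement)",
         call. = FALSE)
  }
  weights <- withr::with_seed(seed, sample(weight_pool, n, replace = FALSE))
  inds <- sample_population(pop, weights, seed = seed + 1L)
  if (is.null(times)) times <- profile_grid(reg)

  doses <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    dplyr::mutate(dose_schedule(reg, weights[i]),
                  subject_id = inds$subject_id[i], .before = 1)
  }))
  profiles <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    pr <- solve_profile(inds[i, ], pop,
                        doses[doses$subject_id == inds$subject_id[i],
                              c("start_h", "amount_mg", "duration_h")],
                        times, rtol = rtol, atol = atol)
    dplyr::mutate(pr, subject_id = inds$subject_id[i], .before = 1)
  }))
  structure(
    list(profiles = profiles, individuals = inds, doses = doses,
         regimen = reg, seed = seed),
    class = "arm_simulation"
  )
}

#' @export
print.arm_simulation <- function(x, ...) {
  cat(sprintf(
    "<arm_simulation> %d subjects, %g mg/kg %s, %g-min infusion, %d cycle(s)\n",
    nrow(x$individuals), x$regimen$dose_per_kg, x$regimen$schedule,
    x$regimen$infusion_duration_min, x$regimen$n_cycles))
  invisible(x)
}

#' Exposure metrics over a dosing interval
#'
#' Computes Cmax (maximum over the interval), Cmin (trough, the concentration
#' at the interval end) and AUC_tau (trapezoidal rule on the dense grid) for
#' either the first-dose interval or the steady-state interval. Steady state
#' is operationalised as the first interval whose end-of-interval trough
#' differs from the previous trough by less than `ss_tol` (default 1%).
#'
#' @param profile Tibble `time_h`, `conc_ug_ml` for one subject, covering the
#'   requested interval with at least `min_points` grid points.
#' @param doses The subject's dose-event tibble.
#' @param interval `"first_dose"` or `"steady_state"`.
#' @param tau_h Dosing-interval length in hours (see [regimen_tau()]).
#' @param ss_tol Relative trough-change threshold declaring steady state.
#' @param min_points Minimum grid points required inside the interval.
#' @return One-row tibble: `cmax`, `cmin`, `auc_tau`, `interval_label`,
#'   `interval_start_h`.
#' @export
exposure_metrics <- function(profile, doses, interval = c("first_dose",
                                                          "steady_state"),
                             tau_h, ss_tol = 0.01, min_points = 200) {
  interval <- match.arg(interval)
  stopifnot(all(c("time_h", "conc_ug_ml") %in% names(profile)))
  doses <- validate_doses(doses)
  t0 <- if (nrow(doses)) doses$start_h[1] else 0

  ends <- t0 + seq_len(floor((max(profile$time_h) - t0) / tau_h + 1e-9)) * tau_h
  trough_at <- function(tt) {
    stats::approx(profile$time_h, profile$conc_ug_ml, xout = tt,
                  rule = 2)$y
  }
  start <- if (interval == "first_dose") {
    t0
  } else {
    if (length(ends) < 2) {
      stop("profile too short to locate steady state", call. = FALSE)
    }
    tr <- trough_at(ends)
    rel <- abs(tr[-1] / tr[-length(tr)] - 1)
    k <- which(rel < ss_tol)[1]
    if (is.na(k)) {
      stop("steady state not reached within the simulated horizon",
           call. = FALSE)
    }
    ends[k]  # interval (ends[k], ends[k] + tau) has a stabilised trough
  }
  stop_t <- start + tau_h
  inside <- profile$time_h >= start - 1e-9 & profile$time_h <= stop_t + 1e-9
  if (sum(inside) < min_points) {
    stop(sprintf("interval [%.6g, %.6g] h covered by only %d points (need >= %d)",
                 start, stop_t, sum(inside), min_points), call. = FALSE)
  }
  tt <- profile$time_h[inside]
  cc <- profile$conc_ug_ml[inside]
  auc <- sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
  tibble::tibble(
    cmax = max(cc),
    cmin = trough_at(stop_t),
    auc_tau = auc,
    interval_label = interval,
    interval_start_h = start
  )
}

#' Exposure summary for every subject of a simulated arm
#'
#' @param arm An `arm_simulation`.
#' @param interval `"first_dose"` or `"steady_state"`.
#' @param ... Passed to [exposure_metrics()].
#' @return Tibble with one row per subject: `subject_id`, `cmax`, `cmin`,
#'   `auc_tau`, `interval_label`, `interval_start_h`.
#' @export
arm_exposure <- function(arm, interval = "first_dose", ...) {
  stopifnot(inherits(arm, "arm_simulation"))
  tau <- regimen_tau(arm$regimen)
  arm$profiles |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      exposure_metrics(df,
                       arm$doses[arm$doses$subject_id == key$subject_id,
                                 c("start_h", "amount_mg", "duration_h")],
                       interval = interval, tau_h = tau, ...)
    }) |>
    dplyr::ungroup()
}

#' Compare exposure between two infusion durations
#'
#' Geometric-mean ratios (arm A / arm B) of AUC_tau, Cmax and Cmin across
#' subjects, plus medians, arithmetic and geometric means per arm. With the
#' same seed the two arms share subjects, so the ratio is paired.
#'
#' @param exp_a,exp_b Exposure tibbles from [arm_exposure()] for the two arms.
#' @return A list with `ratios` (one-row tibble of geometric-mean ratios) and
#'   `by_arm` (summary statistics per arm).
#' @export
exposure_comparison <- function(exp_a, exp_b) {
  gm <- function(x) exp(mean(log(x)))
  summarise_arm <- function(e, label) {
    tibble::tibble(
      arm = label,
      metric = c("auc_tau", "cmax", "cmin"),
      mean = c(mean(e$auc_tau), mean(e$cmax), mean(e$cmin)),
      geo_mean = c(gm(e$auc_tau), gm(e$cmax), gm(e$cmin)),
      median = c(stats::median(e$auc_tau), stats::median(e$cmax),
                 stats::median(e$cmin))
    )
  }
  list(
    ratios = tibble::tibble(
      auc_tau_gmr = gm(exp_a$auc_tau) / gm(exp_b$auc_tau),
      cmax_gmr = gm(exp_a$cmax) / gm(exp_b$cmax),
      cmin_gmr = gm(exp_a$cmin) / gm(exp_b$cmin)
    ),
    by_arm = dplyr::bind_rows(summarise_arm(exp_a, "A"),
                              summarise_arm(exp_b, "B"))
  )
}
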