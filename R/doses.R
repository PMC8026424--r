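#' Define a dosing regimen
#'
#' Weight-based regimens matching the five schedules used across the pooled
#' ramucirumab programme: 8 mg/kg Q2W, 12 mg/kg Q2W, 6 mg/kg QW,
#' 8 mg/kg on days 1 and 8 of a 3-week cycle, and 10 mg/kg Q3W.
#'
#' @param dose_per_kg Dose in mg/kg (> 0).
#' @param schedule One of `"Q2W"`, `"Q3W"`, `"QW"`, `"D1D8_Q3W"`.
#' @param infusion_duration_min Infusion length in minutes (30 and 60 are the
#'   headline comparison; any value >= 1 is accepted).
#' @param n_cycles Number of dosing cycles to administer.
#' @return A `regimen` object.
#' @export
regimen <- function(dose_per_kg, schedule = c("Q2W", "Q3W", "QW", "D1D8_Q3W"),
                    infusion_duration_min = 60, n_cycles = 1) {
  schedule <- match.arg(schedule)
  stopifnot(is.numeric(dose_per_kg), length(dose_per_kg) == 1L, dose_per_kg > 0)
  if (infusion_duration_min < 1) {
    stop("infusion duration must be at least 1 minute", call. = FALSE)
  }
  stopifnot(n_cycles >= 1)
  structure(
    list(dose_per_kg = dose_per_kg, schedule = schedule,
         infusion_duration_min = infusion_duration_min,
         n_cycles = as.integer(n_cycles)),
    class = "regimen"
  )
}

#' Dosing-interval (tau) of a regimen, in hours
#'
#' For the D1D8 Q3W schedule the interval is the 3-week cycle.
#' @param reg A `regimen`.
#' @return Interval length in hours.
#' @export
regimen_tau <- function(reg) {
  stopifnot(inherits(reg, "regimen"))
  switch(reg$schedule,
         Q2W = 336, Q3W = 504, QW = 168, D1D8_Q3W = 504)
}

#' Build the dose-event table for one subject
#'
#' @param reg A `regimen`.
#' @param weight Body weight in kg (absolute dose = `dose_per_kg * weight`).
#' @return A tibble of dose events: `start_h`, `amount_mg`, `duration_h`.
#' @export
dose_schedule <- function(reg, weight) {
  stopifnot(inherits(reg, "regimen"), weight > 0)
  tau <- regimen_tau(reg)
  starts <- switch(
    reg$schedule,
    Q2W = (seq_len(reg$n_cycles) - 1) * tau,
    Q3W = (seq_len(reg$n_cycles) - 1) * tau,
    QW  = (seq_len(reg$n_cycles) - 1) * tau,
    D1D8_Q3W = as.vector(vapply(seq_len(reg$n_cycles) - 1,
                                function(k) k * tau + c(0, 168), numeric(2)))
  )
  tibble::tibble(
    start_h = starts,
    amount_mg = reg$dose_per_kg * weight,
    duration_h = reg$infusion_duration_min / 60
  )
}

# Validate a dose-event table: positive durations (>= 1 min, no boluses),
# non-negative amounts, sorted and non-overlapping infusions.
validate_doses <- function(doses) {
  req <- c("start_h", "amount_mg", "duration_h")
  if (!all(req %in% names(doses))) {
    stop("dose events need columns start_h, amount_mg, duration_h",
         call. = FALSE)
  }
  if (nrow(doses) == 0L) return(doses)
  if (any(doses$amount_mg < 0)) stop("dose amounts must be >= 0", call. = FALSE)
  if (any(doses$duration_h < 1 / 60)) {
    stop("infusion durations must be at least 1 minute (no bolus events)",
         call. = FALSE)
  }
  if (is.unsorted(doses$start_h, strictly = FALSE)) {
    stop("dose events must be sorted by start time", call. = FALSE)
  }
  ends <- doses$start_h + doses$duration_h
  if (nrow(doses) > 1L &&
      any(doses$start_h[-1] < ends[-nrow(doses)] - 1e-9)) {
    stop("overlapping infusions are not supported", call. = FALSE)
  }
  doses
}

# Piecewise-constant infusion rate (mg/h) at time t for a dose table.
infusion_rate_at <- function(doses, t) {
  r <- numeric(length(t))
  for (i in seq_len(nrow(doses))) {
    on <- t >= doses$start_h[i] & t < doses$start_h[i] + doses$duration_h[i]
    r[on] <- r[on] + doses$amount_mg[i] / doses$duration_h[i]
  }
  r
}
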