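#' Individual parameter set from the typical values
#'
#' Weight-adjusted typical values with all random effects at zero; convenient
#' for deterministic single-subject work.
#'
#' @param pop A `poppk_parameters` object.
#' @param weight Body weight (kg).
#' @param subject_id Identifier.
#' @return One-row tibble: `subject_id`, `weight`, `cl0_i`, `v1_i`, `v2_i`,
#'   `q_i`, `emax_i`.
#' @export
individual_from_typical <- function(pop, weight, subject_id = 1L) {
  typ <- apply_weight_covariates(pop, weight)
  tibble::tibble(
    subject_id = subject_id, weight = weight,
    cl0_i = typ$cl0, v1_i = typ$v1, v2_i = typ$v2, q_i = typ$q,
    emax_i = pop$emax
  )
}

as_individual <- function(ind) {
  req <- c("cl0_i", "v1_i", "v2_i", "q_i", "emax_i")
  if (is.data.frame(ind)) {
    if (nrow(ind) != 1L) stop("`ind` must be a single subject", call. = FALSE)
    ind <- as.list(ind)
  }
  if (!all(req %in% names(ind))) {
    stop("individual parameters need ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (ind$cl0_i <= 0 || ind$v1_i <= 0 || ind$v2_i <= 0 || ind$q_i < 0) {
    stop("individual clearances/volumes must be positive", call. = FALSE)
  }
  ind
}

#' Numerically integrate a subject's concentration--time profile
#'
#' Integrates the two-compartment infusion system with time-varying clearance
#' \deqn{dA_1/dt = R_{in}(t) - \frac{CL(t)+Q}{V_1}A_1 + \frac{Q}{V_2}A_2,\quad
#'       dA_2/dt = \frac{Q}{V_1}A_1 - \frac{Q}{V_2}A_2,}
#' with \eqn{C(t)=A_1/V_1} and \eqn{R_{in}} piecewise-constant over each
#' infusion. Integration uses an adaptive stiff-capable solver
#' (`deSolve::lsoda`) restarted at every infusion start/stop so the
#' discontinuous input is never smoothed across a breakpoint.
#'
#' @param ind Individual parameters (one-row tibble from
#'   [sample_population()] / [individual_from_typical()], or a named list).
#' @param model A `poppk_parameters` object supplying `t50` and `gamma`.
#' @param doses Dose-event tibble (`start_h`, `amount_mg`, `duration_h`),
#'   sorted and non-overlapping.
#' @param times Output grid, hours since first dose (non-negative).
#' @param rtol,atol Solver tolerances.
#' @return A tibble `time_h`, `conc_ug_ml` (profile of the central
#'   compartment; zero before the first dose).
#' @export
solve_profile <- function(ind, model, doses, times,
                          rtol = 1e-8, atol = 1e-10) {
  ind <- as_individual(ind)
  stopifnot(inherits(model, "poppk_parameters"))
  doses <- validate_doses(doses)
  if (any(times < 0)) stop("`times` must be non-negative", call. = FALSE)

  ord <- order(times)
  tq <- times[ord]
  conc <- numeric(length(tq))
  if (nrow(doses) == 0L || all(doses$amount_mg == 0)) {
    out <- tibble::tibble(time_h = times, conc_ug_ml = 0)
    return(out)
  }

  horizon <- max(tq, doses$start_h + doses$duration_h)
  brk <- sort(unique(c(0, doses$start_h, doses$start_h + doses$duration_h,
                       horizon)))
  brk <- brk[brk <= horizon + 1e-12]

  k21 <- ind$q_i / ind$v2_i
  k12 <- ind$q_i / ind$v1_i
  derivs <- function(t, y, parms) {
    cl <- .cl_sigmoid(t, ind$cl0_i, ind$emax_i, model$t50, model$gamma)
    list(c(
      parms$rate - (cl / ind$v1_i + k12) * y[1] + k21 * y[2],
      k12 * y[1] - k21 * y[2]
    ))
  }

  state <- c(A1 = 0, A2 = 0)
  for (s in seq_len(length(brk) - 1L)) {
    a <- brk[s]; b <- brk[s + 1L]
    rate <- sum(doses$amount_mg[doses$start_h <= a + 1e-12 &
                                  doses$start_h + doses$duration_h >= b - 1e-12] /
                  doses$duration_h[doses$start_h <= a + 1e-12 &
                                     doses$start_h + doses$duration_h >= b - 1e-12])
    sel <- which(tq > a + 1e-12 & tq <= b + 1e-12)
    tt <- sort(unique(c(a, tq[sel], b)))
    sol <- deSolve::lsoda(y = state, times = tt, func = derivs,
                          parms = list(rate = rate),
                          rtol = rtol, atol = atol)
    if (length(sel)) {
      conc[sel] <- unname(sol[match(round(tq[sel], 10),
                                    round(sol[, 1], 10)), 2]) / ind$v1_i
    }
    # deSolve's `[` keeps names; unname so the next segment's state names
    # stay exactly A1/A2
    state <- c(A1 = unname(sol[nrow(sol), 2]), A2 = unname(sol[nrow(sol), 3]))
  }
  conc <- pmax(conc, 0)

  res <- numeric(length(times))
  res[ord] <- conc
  tibble::tibble(time_h = times, conc_ug_ml = res)
}

# 2x2 matrix exponential solution of x' = Ax + u via eigen-decomposition;
# A is the compartmental rate matrix, which has distinct real eigenvalues
# whenever Q > 0.
.expm_step <- function(A, x0, u, dt) {
  eg <- eigen(A)
  V <- eg$vectors
  lam <- eg$values
  Vi <- solve(V)
  z0 <- Vi %*% x0
  w <- Vi %*% u
  # modal solution z_k(dt) = e^{lam dt} z0 + (e^{lam dt}-1)/lam * w
  elam <- exp(lam * dt)
  phi <- ifelse(abs(lam) > 1e-14, (elam - 1) / lam, dt)
  Re(V %*% (elam * z0 + phi * w))
}

#' Closed-form two-compartment infusion profile (constant clearance)
#'
#' Exact biexponential solution for a single constant-rate infusion under
#' constant clearance, used as an oracle for [solve_profile()]. Two
#' independent evaluations are available: the hybrid-constant
#' (alpha/beta) macro formula and a matrix-exponential evaluation of the
#' 2x2 rate matrix.
#'
#' @param ind Individual parameters; `emax_i` must be exactly 0 (constant
#'   clearance) or the call errors.
#' @param dose A single dose event (one-row tibble: `start_h`, `amount_mg`,
#'   `duration_h`).
#' @param times Output times (hours).
#' @param method `"hybrid"` (default) or `"expm"`.
#' @return A tibble `time_h`, `conc_ug_ml`.
#' @export
closed_form_profile <- function(ind, dose, times,
                                method = c("hybrid", "expm")) {
  method <- match.arg(method)
  ind <- as_individual(ind)
  if (ind$emax_i != 0) {
    stop("closed_form_profile requires constant clearance (emax_i == 0)",
         call. = FALSE)
  }
  dose <- validate_doses(dose)
  stopifnot(nrow(dose) == 1L)
  cl <- ind$cl0_i; v1 <- ind$v1_i; v2 <- ind$v2_i; q <- ind$q_i
  tinf <- dose$duration_h
  rate <- dose$amount_mg / tinf
  trel <- times - dose$start_h

  if (method == "expm" && q > 0) {
    # d/dt (A1,A2) = A %*% (A1,A2) + (rate,0) during the infusion
    A <- matrix(c(-(cl + q) / v1, q / v1, q / v2, -q / v2), nrow = 2)
    conc <- vapply(trel, function(t) {
      if (t <= 0) return(0)
      t1 <- min(t, tinf)
      x <- .expm_step(A, c(0, 0), c(rate, 0), t1)
      if (t > tinf) x <- .expm_step(A, x, c(0, 0), t - tinf)
      x[1] / v1
    }, numeric(1))
    return(tibble::tibble(time_h = times, conc_ug_ml = pmax(conc, 0)))
  }

  k10 <- cl / v1; k12 <- q / v1; k21 <- q / v2
  if (q == 0) {
    # one-compartment limit
    conc <- ifelse(
      trel <= 0, 0,
      ifelse(trel <= tinf,
             rate / cl * (1 - exp(-k10 * trel)),
             rate / cl * (1 - exp(-k10 * tinf)) * exp(-k10 * (trel - tinf))))
    return(tibble::tibble(time_h = times, conc_ug_ml = pmax(conc, 0)))
  }
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  Acoef <- (alpha - k21) / (alpha - beta)
  Bcoef <- (k21 - beta) / (alpha - beta)
  inf_part <- function(t) {
    rate / v1 * (Acoef / alpha * (1 - exp(-alpha * t)) +
                   Bcoef / beta * (1 - exp(-beta * t)))
  }
  conc <- ifelse(
    trel <= 0, 0,
    ifelse(trel <= tinf,
           inf_part(pmax(trel, 0)),
           rate / v1 * (Acoef / alpha * (1 - exp(-alpha * tinf)) *
                          exp(-alpha * (trel - tinf)) +
                          Bcoef / beta * (1 - exp(-beta * tinf)) *
                          exp(-beta * (trel - tinf)))))
  tibble::tibble(time_h = times, conc_ug_ml = pmax(conc, 0))
}
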