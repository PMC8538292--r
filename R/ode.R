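#' Right-hand side of the QE-TMDD + FC turnover system
#'
#' Evaluates the time derivative of the six-dimensional state for one subject.
#' The state is `c(a_dep, ctot, a_p, rtot, a_pt, fc)`:
#' SC depot amount (nmol), total central drug concentration (nmol/L), free
#' peripheral drug amount (nmol), total central target concentration (nmol/L),
#' free peripheral target amount (nmol) and fecal calprotectin (mg/kg).
#' Free central concentrations (C, R) are recovered from the totals with
#' [qe_free_concentrations()] at each evaluation; binding takes place in the
#' central compartment only and the complex is internalized at rate `kint`.
#' FC follows an indirect-response model in which the free target stimulates
#' FC production: `dFC/dt = kin * (1 + emax*R/(c50+R)) - kout*FC` with
#' `kin = fc0*kout / (1 + emax*R0/(c50+R0))` and `R0 = ksyn/kdeg`, so the
#' drug-free steady state `(0, 0, 0, R0, R0*vp_t, fc0)` is stationary by
#' construction.
#'
#' @param state numeric state vector `c(a_dep, ctot, a_p, rtot, a_pt, fc)`
#'   (names optional, order fixed).
#' @param t time (days); the system is autonomous, `t` is accepted for solver
#'   compatibility.
#' @param p individual parameters: a one-row data.frame or named list with
#'   fields `ka, cl, vc, q, vp, f, ksyn, kdeg, vc_t, q_t, vp_t, kint, kd,
#'   kout, fc0, emax, c50` (see [individual_parameters()]).
#' @param infusion_rate zero-order IV input rate (nmol/day), default 0.
#' @return numeric vector of derivatives, same order as `state`.
#' @examples
#' p <- individual_parameters(pop_params(), reference_covariates())
#' r0 <- p$ksyn / p$kdeg
#' base <- c(0, 0, 0, r0, r0 * p$vp_t, p$fc0)
#' pkpd_rhs(base, 0, p)   # all zero at the drug-free steady state
#' @export
pkpd_rhs <- function(state, t = 0, p, infusion_rate = 0) {
  if (!is.numeric(state) || length(state) != 6L || anyNA(state) ||
      any(!is.finite(state))) {
    stop("pkpd_rhs: state must be a finite numeric vector of length 6")
  }
  if (any(state < 0)) stop("pkpd_rhs: state must be non-negative")
  p <- as.list(p)
  d <- rhs_blocks(state[1], state[2], state[3], state[4], state[5], state[6],
                  p, infusion_rate)
  out <- c(d$a_dep, d$ctot, d$a_p, d$rtot, d$a_pt, d$fc)
  names(out) <- c("a_dep", "ctot", "a_p", "rtot", "a_pt", "fc")
  out
}

# Vectorised derivative blocks shared by the scalar API and the stacked
# cohort integrator. All of p's fields may be length n.
rhs_blocks <- function(a_dep, ctot, a_p, rtot, a_pt, fc, p, infusion_rate) {
  qe <- qe_free(pmax(ctot, 0), pmax(rtot, 0), p$kd)
  cf <- qe$c_free
  rf <- qe$r_free
  r0 <- p$ksyn / p$kdeg
  kin <- p$fc0 * p$kout / (1 + p$emax * r0 / (p$c50 + r0))
  list(
    a_dep = -p$ka * a_dep,
    ctot  = (p$ka * a_dep + infusion_rate) / p$vc - (p$cl / p$vc) * cf +
            (p$q / p$vc) * (a_p / p$vp - cf) - p$kint * (ctot - cf),
    a_p   = p$q * (cf - a_p / p$vp),
    rtot  = p$ksyn - p$kdeg * rf + (p$q_t / p$vc_t) * (a_pt / p$vp_t - rf) -
            p$kint * (rtot - rf),
    a_pt  = p$q_t * (rf - a_pt / p$vp_t),
    fc    = kin * (1 + p$emax * rf / (p$c50 + rf)) - p$kout * fc
  )
}

#' Simulate one subject under a dose schedule
#'
#' Integrates the QE-TMDD + FC system from the drug-free steady state under a
#' schedule of IV infusions and SC doses, restarting the solver at every dose
#' and infusion boundary so event times are exact. SC doses add
#' `f * amount` (in nmol) to the depot at the dose time; IV doses enter as a
#' zero-order infusion over `infusion_duration` days (overlapping infusions
#' sum their rates).
#'
#' @param p individual parameters (one-row data.frame or named list, see
#'   [individual_parameters()]).
#' @param schedule a dose schedule data.frame with columns `time` (days),
#'   `route` (`"iv"` or `"sc"`), `amount_mg`, and optionally
#'   `infusion_duration` (days, default 1/24 for IV). An empty or NULL
#'   schedule simulates the drug-free baseline.
#' @param times output time grid (days), must start at or after 0.
#' @param control solver options: list with `rtol` (default 1e-8), `atol`
#'   (default 1e-10), `method` (default `"lsoda"`).
#' @param mw molecular weight (g/mol) for the ug/mL output series.
#' @return an object of class `pkpd_sim`: list with `time` and, per subject,
#'   columns in matrices `conc_nmoll` (free drug), `conc_ugml`, `target_nmoll`
#'   (free target), `fc_mgkg`, `ctot`, `rtot`, plus `n`.
#' @examples
#' p <- individual_parameters(pop_params(), reference_covariates())
#' sch <- data.frame(time = 0, route = "iv", amount_mg = 390)
#' sim <- simulate_patient(p, sch, times = 0:112)
#' max(sim$conc_ugml)                       # induction peak
#' sim$fc_mgkg[sim$time == 112]             # pre-dose FC at week 16
#' @export
simulate_patient <- function(p, schedule = NULL, times = 0:224,
                             control = list(), mw = 149000) {
  pars <- as_param_list(p)
  ev <- normalize_schedule(schedule)
  sim_core(pars, ev, times, control, mw)
}

#' Simulate a cohort under per-subject dose schedules
#'
#' Batch version of [simulate_patient()]: all subjects are integrated as one
#' stacked ODE system, which is much faster than a per-subject loop. All
#' schedules must share the same event times, routes and infusion durations
#' (amounts may differ per subject) -- the natural situation for protocolised
#' dosing where only the weight-banded amount varies.
#'
#' @param pars data.frame of individual parameters, one row per subject
#'   (see [individual_parameters()]).
#' @param schedules either a single schedule data.frame applied to every
#'   subject, or a list of n schedule data.frames with identical
#'   `time`/`route`/`infusion_duration` columns.
#' @inheritParams simulate_patient
#' @return a `pkpd_sim` object with one column per subject in each series.
#' @export
simulate_cohort <- function(pars, schedules = NULL, times = 0:224,
                            control = list(), mw = 149000) {
  pl <- as_param_list(pars)
  n <- length(pl$cl)
  if (is.null(schedules) || is.data.frame(schedules)) {
    ev <- normalize_schedule(schedules)
  } else {
    if (length(schedules) != n) {
      stop("simulate_cohort: need one schedule per subject")
    }
    evs <- lapply(schedules, normalize_schedule)
    ev <- evs[[1]]
    for (e in evs[-1]) {
      if (nrow(e) != nrow(ev) || any(e$time != ev$time) ||
          any(e$route != ev$route) ||
          any(e$infusion_duration != ev$infusion_duration)) {
        stop("simulate_cohort: schedules must share event times, routes ",
             "and infusion durations (amounts may differ)")
      }
    }
    if (nrow(ev)) {
      ev$amount_mg <- NULL
      amt <- do.call(cbind, lapply(evs, `[[`, "amount_mg"))
      ev$amount_mg <- I(split(amt, row(amt)))  # list: per event, n amounts
    }
  }
  sim_core(pl, ev, times, control, mw)
}

# --- internals ---------------------------------------------------------------

param_fields <- c("ka", "cl", "vc", "q", "vp", "f", "ksyn", "kdeg", "vc_t",
                  "q_t", "vp_t", "kint", "kd", "kout", "fc0", "emax", "c50")

as_param_list <- function(p) {
  p <- as.list(p)
  miss <- setdiff(param_fields, names(p))
  if (length(miss)) {
    stop("missing individual parameter(s): ", paste(miss, collapse = ", "))
  }
  p <- p[param_fields]
  n <- max(lengths(p))
  p <- lapply(p, function(x) {
    x <- as.numeric(x)
    if (length(x) == 1L) rep(x, n) else x
  })
  if (any(lengths(p) != n)) stop("parameter vectors have unequal lengths")
  # ksyn = 0 is the linear (target-free) limit and is allowed
  bad <- names(p)[vapply(names(p), function(nm) {
    x <- p[[nm]]
    anyNA(x) || any(!is.finite(x)) ||
      (if (nm == "ksyn") any(x < 0) else any(x <= 0))
  }, logical(1))]
  if (length(bad)) {
    stop("individual parameter(s) must be positive and finite: ",
         paste(bad, collapse = ", "))
  }
  if (any(p$f >= 1)) stop("absorbed fraction f must lie in (0, 1)")
  p
}

normalize_schedule <- function(schedule) {
  if (is.null(schedule) || NROW(schedule) == 0L) {
    return(data.frame(time = numeric(0), route = character(0),
                      amount_mg = numeric(0), infusion_duration = numeric(0)))
  }
  stopifnot(is.data.frame(schedule),
            all(c("time", "route", "amount_mg") %in% names(schedule)))
  sch <- schedule
  sch$route <- tolower(as.character(sch$route))
  if (!all(sch$route %in% c("iv", "sc"))) {
    stop("schedule route must be 'iv' or 'sc'")
  }
  if (is.null(sch$infusion_duration)) {
    sch$infusion_duration <- ifelse(sch$route == "iv", 1 / 24, 0)
  }
  sch$infusion_duration[sch$route == "sc"] <- 0
  if (any(sch$time < 0)) stop("dose times must be non-negative")
  amts <- if (is.list(sch$amount_mg)) unlist(sch$amount_mg) else sch$amount_mg
  if (any(amts <= 0)) stop("dose amounts must be positive")
  if (any(sch$route == "iv" & sch$infusion_duration <= 0)) {
    stop("iv doses need a positive infusion_duration")
  }
  sch[order(sch$time), , drop = FALSE]
}

event_amounts <- function(ev_row, n) {
  a <- ev_row$amount_mg
  if (is.list(a)) a <- a[[1]]
  a <- as.numeric(a)
  if (length(a) == 1L) a <- rep(a, n)
  if (length(a) != n) stop("per-event amounts must have length 1 or n")
  a
}

sim_core <- function(p, ev, times, control, mw) {
  ctl <- utils::modifyList(list(rtol = 1e-8, atol = 1e-10, method = "lsoda"),
                           control)
  n <- length(p$cl)
  times <- sort(unique(as.numeric(times)))
  if (anyNA(times) || times[1] < 0) stop("times must be non-negative")
  horizon <- max(times)

  r0 <- p$ksyn / p$kdeg
  y <- c(rep(0, 3 * n), r0, r0 * p$vp_t, p$fc0)

  i1 <- seq_len(n); i2 <- n + i1; i3 <- 2 * n + i1
  i4 <- 3 * n + i1; i5 <- 4 * n + i1; i6 <- 5 * n + i1

  iv <- ev[ev$route == "iv" & ev$time < horizon, , drop = FALSE]
  sc <- ev[ev$route == "sc" & ev$time <= horizon, , drop = FALSE]
  bounds <- sort(unique(c(0, times[1], sc$time, iv$time,
                          pmin(iv$time + iv$infusion_duration, horizon),
                          horizon)))
  bounds <- bounds[bounds <= horizon]

  deriv <- function(t, y, pr) {
    if (min(y) < -1e-6) {
      stop("integration produced a negative state (min ", format(min(y)),
           " at t=", format(t), ")")
    }
    d <- rhs_blocks(y[i1], y[i2], y[i3], y[i4], y[i5], y[i6], p, pr$inf)
    list(c(d$a_dep, d$ctot, d$a_p, d$rtot, d$a_pt, d$fc))
  }

  out_t <- numeric(0)
  out_y <- NULL
  record <- function(tt, mat) {
    keep <- tt %in% times & !(tt %in% out_t)
    if (any(keep)) {
      out_t <<- c(out_t, tt[keep])
      out_y <<- rbind(out_y, mat[keep, , drop = FALSE])
    }
  }

  if (length(bounds) < 2L) {  # degenerate single-instant grid
    record(bounds, matrix(y, nrow = 1))
  }
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    # SC boluses at segment start enter the depot scaled by F
    hit <- which(sc$time == a)
    for (j in hit) {
      y[i1] <- y[i1] + p$f * mg_to_nmol(event_amounts(sc[j, ], n), mw)
    }
    # constant infusion rates active on [a, b): overlapping infusions sum
    inf <- rep(0, n)
    if (nrow(iv)) {
      act <- which(iv$time <= a & (iv$time + iv$infusion_duration) > a)
      for (j in act) {
        inf <- inf + mg_to_nmol(event_amounts(iv[j, ], n), mw) /
          iv$infusion_duration[j]
      }
    }
    tt <- sort(unique(c(a, times[times > a & times < b], b)))
    sol <- deSolve::ode(y = y, times = tt, func = deriv,
                        parms = list(inf = inf), method = ctl$method,
                        rtol = ctl$rtol, atol = ctl$atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE solver failed on segment [", a, ", ", b, "]")
    }
    y <- sol[nrow(sol), -1]
    record(sol[-nrow(sol), 1], sol[-nrow(sol), -1, drop = FALSE])
    if (b == horizon) record(b, matrix(y, nrow = 1))
  }

  ord <- order(out_t)
  out_t <- out_t[ord]
  out_y <- out_y[ord, , drop = FALSE]
  ctot <- pmax(out_y[, i2, drop = FALSE], 0)
  rtot <- pmax(out_y[, i4, drop = FALSE], 0)
  kdm <- matrix(p$kd, nrow(ctot), n, byrow = TRUE)
  qe <- qe_free(ctot, rtot, kdm)
  structure(list(
    time = out_t,
    n = n,
    conc_nmoll = matrix(qe$c_free, ncol = n),
    conc_ugml = matrix(qe$c_free, ncol = n) * mw / 1e6,
    target_nmoll = matrix(qe$r_free, ncol = n),
    fc_mgkg = pmax(out_y[, i6, drop = FALSE], 0),
    ctot = ctot,
    rtot = rtot
  ), class = "pkpd_sim")
}

#' @export
print.pkpd_sim <- function(x, ...) {
  cat(sprintf("PK-PD simulation: %d subject(s), %d time points over %g days\n",
              x$n, length(x$time), max(x$time)))
  cat(sprintf("  peak free drug (ugml): median %.3g; final FC (mg/kg): median %.4g\n",
              stats::median(apply(x$conc_ugml, 2, max)),
              stats::median(x$fc_mgkg[length(x$time), ])))
  invisible(x)
}

#' @export
as.data.frame.pkpd_sim <- function(x, ...) {
  n <- x$n
  nt <- length(x$time)
  data.frame(
    subject_id = rep(seq_len(n), each = nt),
    time_day = rep(x$time, n),
    conc_ugml = as.vector(x$conc_ugml),
    conc_nmolL = as.vector(x$conc_nmoll),
    free_target_nmolL = as.vector(x$target_nmoll),
    fc_mgkg = as.vector(x$fc_mgkg)
  )
}

#' Export simulated trajectories as long-format delimited text
#'
#' Writes columns `subject_id, time_day, conc_ugml, conc_nmolL,
#' free_target_nmolL, fc_mgkg`, tab-separated.
#'
#' @param sim a `pkpd_sim` object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_timeseries <- function(sim, path) {
  stopifnot(inherits(sim, "pkpd_sim"))
  utils::write.table(as.data.frame(sim), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Terminal half-life from a log-linear fit
#'
#' Fits ordinary least squares to `ln(concentration)` against time over a
#' window of the simulated profile and returns `ln(2) / lambda_z`, where
#' `lambda_z` is the negative slope. The window must contain at least two
#' grid points (two points give the exact halving time), strictly positive
#' concentrations, and no dose events.
#'
#' @param sim a `pkpd_sim` object (or any list with `time` and `conc_nmoll`).
#' @param window numeric length-2, `c(t_start, t_end)` in days.
#' @param subject column index of the subject to use (default 1).
#' @return terminal half-life in days.
#' @examples
#' t <- 0:84
#' fake <- structure(list(time = t,
#'                        conc_nmoll = cbind(100 * exp(-0.0391 * t)), n = 1L),
#'                   class = "pkpd_sim")
#' terminal_half_life(fake, c(42, 84))   # ln(2)/0.0391 = 17.7 days
#' @export
terminal_half_life <- function(sim, window = c(42, 84), subject = 1L) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  sel <- sim$time >= window[1] & sim$time <= window[2]
  t <- sim$time[sel]
  conc <- sim$conc_nmoll[sel, subject]
  if (length(t) < 2L) {
    stop("terminal_half_life: need at least 2 points in the window")
  }
  if (any(conc <= 0)) {
    stop("terminal_half_life: concentrations must be positive in the window")
  }
  lz <- -unname(stats::coef(stats::lm(log(conc) ~ t))[2])
  if (lz <= 0) stop("terminal_half_life: profile not declining in the window")
  log(2) / lz
}
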