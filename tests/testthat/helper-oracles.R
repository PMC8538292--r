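# Independent oracles used by the tests. These deliberately do not reuse the
# package's right-hand side or integrator loop.

# Closed-form linear two-compartment profile (first-order absorption depot,
# zero-order IV infusions) via eigendecomposition of the constant-coefficient
# system: x(t0+dt) = E x0 + A^-1 (E - I) b with E = V exp(L dt) V^-1.
# Returns free drug concentration (nmol/L) on `times` for one subject.
linear2cpt_oracle <- function(p, schedule, times, mw = 149000) {
  A <- rbind(c(-p$ka, 0, 0),
             c(p$ka, -(p$cl + p$q) / p$vc, p$q / p$vp),
             c(0, p$q / p$vc, -p$q / p$vp))
  eg <- eigen(A)
  V <- eg$vectors
  Vi <- solve(V)
  propagate <- function(x0, b, dt) {
    E <- V %*% diag(exp(eg$values * dt), 3) %*% Vi
    drop(E %*% x0 + solve(A, (E - diag(3)) %*% b))
  }
  sch <- schedule[order(schedule$time), , drop = FALSE]
  sch$infusion_duration <- ifelse(sch$route == "iv",
                                  ifelse(is.null(sch$infusion_duration), 1 / 24,
                                         sch$infusion_duration), 0)
  horizon <- max(times)
  iv <- sch[sch$route == "iv" & sch$time < horizon, , drop = FALSE]
  sc <- sch[sch$route == "sc" & sch$time <= horizon, , drop = FALSE]
  bounds <- sort(unique(c(0, sc$time, iv$time,
                          pmin(iv$time + iv$infusion_duration, horizon),
                          horizon)))
  x <- c(0, 0, 0)
  out <- numeric(length(times))
  out[times == 0] <- 0
  for (k in seq_len(length(bounds) - 1)) {
    a <- bounds[k]; bnd <- bounds[k + 1]
    for (j in which(sc$time == a)) {
      x[1] <- x[1] + p$f * sc$amount_mg[j] * 1e6 / mw
    }
    rate <- 0
    for (j in seq_len(nrow(iv))) {
      if (iv$time[j] <= a && iv$time[j] + iv$infusion_duration[j] > a) {
        rate <- rate + iv$amount_mg[j] * 1e6 / mw / iv$infusion_duration[j]
      }
    }
    b <- c(0, rate, 0)
    inner <- times[times > a & times <= bnd]
    for (tt in inner) out[times == tt] <- propagate(x, b, tt - a)[2] / p$vc
    x <- propagate(x, b, bnd - a)
  }
  out
}

# Full kinetic-binding TMDD model (mass-action on/off rates instead of the
# quasi-equilibrium closure), concentration-level bookkeeping as in the
# package. Returns free drug, free target and FC on `times`.
kinetic_tmdd_oracle <- function(p, schedule, times, koff = 1000,
                                mw = 149000, rtol = 1e-10, atol = 1e-12) {
  kon <- koff / p$kd
  r0 <- p$ksyn / p$kdeg
  kin <- p$fc0 * p$kout / (1 + p$emax * r0 / (p$c50 + r0))
  rhs <- function(t, y, parms) {
    ad <- y[1]; cf <- y[2]; px <- y[3]; ap <- y[4]; rf <- y[5]; apt <- y[6]
    fc <- y[7]
    bind <- kon * cf * rf - koff * px
    list(c(
      -p$ka * ad,
      (p$ka * ad + parms$rate) / p$vc - (p$cl / p$vc) * cf +
        (p$q / p$vc) * (ap / p$vp - cf) - bind,
      bind - p$kint * px,
      p$q * (cf - ap / p$vp),
      p$ksyn - p$kdeg * rf + (p$q_t / p$vc_t) * (apt / p$vp_t - rf) - bind,
      p$q_t * (rf - apt / p$vp_t),
      kin * (1 + p$emax * rf / (p$c50 + rf)) - p$kout * fc
    ))
  }
  sch <- schedule[order(schedule$time), , drop = FALSE]
  sch$infusion_duration <- ifelse(sch$route == "iv", 1 / 24, 0)
  horizon <- max(times)
  iv <- sch[sch$route == "iv" & sch$time < horizon, , drop = FALSE]
  sc <- sch[sch$route == "sc" & sch$time <= horizon, , drop = FALSE]
  bounds <- sort(unique(c(0, sc$time, iv$time,
                          pmin(iv$time + iv$infusion_duration, horizon),
                          horizon)))
  y <- c(0, 0, 0, 0, r0, r0 * p$vp_t, p$fc0)
  keep_t <- numeric(0)
  keep <- NULL
  for (k in seq_len(length(bounds) - 1)) {
    a <- bounds[k]; bnd <- bounds[k + 1]
    for (j in which(sc$time == a)) {
      y[1] <- y[1] + p$f * sc$amount_mg[j] * 1e6 / mw
    }
    rate <- 0
    for (j in seq_len(nrow(iv))) {
      if (iv$time[j] <= a && iv$time[j] + iv$infusion_duration[j] > a) {
        rate <- rate + iv$amount_mg[j] * 1e6 / mw / iv$infusion_duration[j]
      }
    }
    tt <- sort(unique(c(a, times[times > a & times < bnd], bnd)))
    sol <- deSolve::lsoda(y, tt, rhs, parms = list(rate = rate),
                          rtol = rtol, atol = atol, maxsteps = 2e5)
    y <- sol[nrow(sol), -1]
    sel <- sol[, 1] %in% times & !(sol[, 1] %in% keep_t)
    keep_t <- c(keep_t, sol[sel, 1])
    keep <- rbind(keep, sol[sel, -1, drop = FALSE])
  }
  ord <- order(keep_t)
  list(time = keep_t[ord], conc_nmoll = keep[ord, 2],
       target_nmoll = keep[ord, 5], fc_mgkg = keep[ord, 7])
}

typical_pars <- function(...) {
  p <- individual_parameters(pop_params(), reference_covariates())
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p
}
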