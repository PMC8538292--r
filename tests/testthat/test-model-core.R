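p_typ <- individual_parameters(pop_params(), reference_covariates())

test_that("the drug-free steady state is stationary for the right-hand side", {
  r0 <- p_typ$ksyn / p_typ$kdeg
  base <- c(0, 0, 0, r0, r0 * p_typ$vp_t, p_typ$fc0)
  expect_equal(unname(pkpd_rhs(base, 0, p_typ)), rep(0, 6), tolerance = 1e-14)
})

test_that("derivative signs and the depot term follow the model equations", {
  r0 <- p_typ$ksyn / p_typ$kdeg
  # drug present, target still at baseline: free target < R0, FC must fall
  st <- c(0, 50, 0, r0, r0 * p_typ$vp_t, p_typ$fc0)
  expect_lt(pkpd_rhs(st, 0, p_typ)[["fc"]], 0)
  # depot only: dCtot/dt = ka * A_dep / Vc minus uptake terms evaluated at
  # the QE free concentration (hand-evaluated right-hand side)
  st2 <- c(604.0, 0, 0, r0, r0 * p_typ$vp_t, p_typ$fc0)
  d <- pkpd_rhs(st2, 0, p_typ)
  expect_equal(d[["a_dep"]], -p_typ$ka * 604.0)
  expect_equal(d[["ctot"]], p_typ$ka * 604.0 / p_typ$vc, tolerance = 1e-12)
  expect_error(pkpd_rhs(c(-1, 0, 0, r0, r0 * p_typ$vp_t, p_typ$fc0), 0, p_typ),
               "non-negative")
})

test_that("drug-free simulation stays at baseline over 224 days", {
  sim <- simulate_patient(p_typ, NULL, times = seq(0, 224, by = 7))
  r0 <- p_typ$ksyn / p_typ$kdeg
  expect_true(all(sim$conc_nmoll == 0))
  expect_lt(max(abs(sim$fc_mgkg / p_typ$fc0 - 1)), 1e-6)
  expect_lt(max(abs(sim$target_nmoll / r0 - 1)), 1e-6)
})

test_that("linear limit matches the closed-form two-compartment solution", {
  p_lin <- typical_pars(ksyn = 0)
  times <- sort(unique(c(seq(0, 84, by = 0.5), 1 / 24)))
  for (sch in list(
    data.frame(time = 0, route = "iv", amount_mg = 390),
    data.frame(time = c(0, 14), route = "sc", amount_mg = c(90, 90))
  )) {
    sim <- simulate_patient(p_lin, sch, times)
    ref <- linear2cpt_oracle(p_lin, sch, times)
    sel <- ref > 0
    expect_lt(max(abs(sim$conc_nmoll[sel, 1] - ref[sel]) / ref[sel]), 1e-3)
  }
})

test_that("dose response is linear in the target-free limit", {
  p_lin <- typical_pars(ksyn = 0)
  times <- seq(0, 56, by = 1)
  one <- simulate_patient(p_lin, data.frame(time = 0, route = "sc",
                                            amount_mg = 90), times)
  two <- simulate_patient(p_lin, data.frame(time = 0, route = "sc",
                                            amount_mg = 180), times)
  sel <- one$conc_nmoll[, 1] > 0
  expect_equal(two$conc_nmoll[sel, 1] / one$conc_nmoll[sel, 1],
               rep(2, sum(sel)), tolerance = 1e-6)
})

test_that("stacked cohort integration reproduces per-subject simulation", {
  set.seed(21)
  pop <- pop_params()
  cov <- generate_cohort(population_spec(n = 4, seed = 21))
  pars <- individual_parameters(pop, cov, sample_random_effects(pop, 4))
  schedules <- lapply(cov$weight, function(w) build_schedule("a", w))
  times <- seq(0, 224, by = 7)
  batch <- simulate_cohort(pars, schedules, times)
  for (i in 1:4) {
    solo <- simulate_patient(pars[i, ], schedules[[i]], times)
    expect_equal(batch$conc_nmoll[, i], solo$conc_nmoll[, 1],
                 tolerance = 1e-6)
    expect_equal(batch$fc_mgkg[, i], solo$fc_mgkg[, 1], tolerance = 1e-6)
  }
})

test_that("schedules must share event shapes for batch simulation", {
  pars <- rbind(p_typ, p_typ)
  s1 <- build_schedule("a", 70)
  s2 <- build_schedule("b", 70)
  expect_error(simulate_cohort(pars, list(s1, s2), 0:224), "share event")
  # amounts may differ
  s3 <- build_schedule("a", 90)
  sim <- simulate_cohort(pars, list(s1, s3), seq(0, 224, 28))
  expect_gt(max(sim$conc_nmoll[, 2]), max(sim$conc_nmoll[, 1]))
})

test_that("terminal half-life comes from the log-linear slope", {
  t <- 0:84
  mono <- structure(list(time = t, n = 1L,
                         conc_nmoll = cbind(100 * exp(-0.0391 * t))),
                    class = "pkpd_sim")
  expect_equal(terminal_half_life(mono, c(42, 84)), log(2) / 0.0391,
               tolerance = 1e-10)
  expect_equal(log(2) / 0.0391, 17.7, tolerance = 2e-3)
  two <- structure(list(time = c(0, 17.73), n = 1L,
                        conc_nmoll = cbind(c(100, 50))), class = "pkpd_sim")
  expect_equal(terminal_half_life(two, c(0, 17.73)), 17.73, tolerance = 1e-10)
  expect_error(terminal_half_life(mono, c(100, 120)), "at least 2")
  zero <- structure(list(time = t, n = 1L,
                         conc_nmoll = cbind(rep(0, length(t)))),
                    class = "pkpd_sim")
  expect_error(terminal_half_life(zero, c(42, 84)), "positive")
})

test_that("typical-patient terminal slope matches the eigenvalue formula", {
  # analytic lambda_z of the linear two-compartment system at typical values
  k10 <- 0.277 / 3.57; k12 <- 1.89 / 3.57; k21 <- 1.89 / 3.30
  s <- k10 + k12 + k21
  lz <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
  expect_equal(log(2) / lz, 17.79, tolerance = 1e-3)
  sim <- simulate_patient(p_typ, data.frame(time = 0, route = "iv",
                                            amount_mg = 390), times = 0:84)
  thalf <- terminal_half_life(sim, c(42, 84))
  # TMDD adds a little clearance relative to the linear eigenvalue
  expect_gt(thalf, 15.5)
  expect_lt(thalf, log(2) / lz + 0.5)
})

test_that("residual error reproduces the published variance model", {
  x <- c(10, 50, 100)
  noise_free <- add_residual_error(x, "drug",
                                   pop_params(sigma_add = 0, sigma_prop = 0),
                                   seed = 1)
  expect_equal(noise_free, x)
  expect_equal(add_residual_error(x, "fc", pop_params(sigma_fc = 0), seed = 1),
               x)
  expect_equal(add_residual_error(x, "drug", seed = 42),
               add_residual_error(x, "drug", seed = 42))
  set.seed(5)
  reps <- add_residual_error(rep(67, 1e5), "drug")
  expect_equal(sd(reps), sqrt(4.55^2 + (0.0777 * 67)^2), tolerance = 0.02)
  expect_equal(sd(reps), 6.9, tolerance = 0.01)
  expect_true(all(add_residual_error(rep(0.01, 1000), "drug", seed = 2) >= 0))
  expect_error(add_residual_error(c(1, NA), "drug"), "finite")
})
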