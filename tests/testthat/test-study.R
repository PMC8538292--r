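cfg_small <- run_config(scenarios = c("a", "b", "d", "e", "f"), n = 150,
                        seed = 4)
study_small <- run_study(cfg_small)

test_that("scenario results are well-formed proportions with binomial SEs", {
  for (r in study_small$results) {
    expect_s3_class(r, "scenario_result")
    expect_true(all(r$proportion >= 0 & r$proportion <= 1))
    expect_equal(r$se, sqrt(r$proportion * (1 - r$proportion) / r$n))
    expect_equal(r$weeks, c(8, 16, 24, 32))
  }
  # metrics are computed on the endoscopically active subgroup
  expect_equal(study_small$results$a$n, sum(study_small$cohort$ulcers_baseline))
})

test_that("study runs are deterministic under the configuration seed", {
  again <- run_study(cfg_small)
  expect_identical(study_small$table, again$table)
})

test_that("escalated regimens dominate standard dosing under shared seeds", {
  tab <- study_small$table
  w32 <- function(s) tab$proportion[tab$scenario == s & tab$week == 32]
  expect_gte(w32("b"), w32("a"))
  expect_gte(w32("d"), w32("a"))
  expect_gte(w32("f"), w32("d"))
  # adaptive scenarios share weeks 0-16 with the standard arm
  w8 <- function(s) tab$proportion[tab$scenario == s & tab$week == 8]
  w16 <- function(s) tab$proportion[tab$scenario == s & tab$week == 16]
  for (s in c("d", "e", "f")) {
    expect_identical(w8(s), w8("a"))
    expect_identical(w16(s), w16("a"))
  }
  # transient benefit of reinduction at week 24
  w24 <- function(s) tab$proportion[tab$scenario == s & tab$week == 24]
  expect_gte(w24("e"), w24("a"))
})

test_that("subgroup restriction changes the remission metric", {
  cfg_full <- run_config(scenarios = "a", n = 150, seed = 4,
                         ulcer_subgroup = FALSE)
  full <- run_scenario(cfg_full, "a")
  expect_equal(full$n, 150)
  expect_false(isTRUE(all.equal(full$proportion,
                                study_small$results$a$proportion)))
  # subjects without baseline ulcers start lower and remit more often
  expect_gt(full$proportion[4], study_small$results$a$proportion[4])
})

test_that("remission table is tidy and optionally written to disk", {
  tab <- remission_table(study_small$results)
  expect_equal(nrow(tab), 5 * 4)
  expect_named(tab, c("scenario", "week", "proportion", "se"))
  path <- tempfile(fileext = ".tsv")
  remission_table(study_small$results, path)
  expect_equal(nrow(read.table(path, header = TRUE, sep = "\t")), 20)
  unlink(path)
  expect_error(remission_table(list()), "no scenario results")
})

test_that("Monte-Carlo error of the remission estimate scales as binomial", {
  p1 <- run_study(run_config(scenarios = "a", n = 400, seed = 11))
  p2 <- run_study(run_config(scenarios = "a", n = 400, seed = 12))
  w32 <- function(st) {
    st$table$proportion[st$table$week == 32]
  }
  n <- p1$results$a$n
  p <- (w32(p1) + w32(p2)) / 2
  expect_lt(abs(w32(p1) - w32(p2)), 3 * sqrt(p * (1 - p) * 2 / n))
})

test_that("q4w troughs exceed q8w troughs subject by subject", {
  cfg <- run_config(scenarios = "a", n = 40, seed = 6, trough_week = 48)
  popn <- study_population(cfg)
  day <- 336
  times <- sort(unique(c(seq(0, day, by = 28), day)))
  sim8 <- ustekisim:::simulate_scenario_group(cfg, popn$cohort, popn$pars,
                                              "a", NA, times)
  sim4 <- ustekisim:::simulate_scenario_group(cfg, popn$cohort, popn$pars,
                                              "b", NA, times)
  i <- match(day, times)
  expect_true(all(sim4$conc_ugml[i, ] > sim8$conc_ugml[i, ]))
  expect_equal(median_ss_trough(cfg, "q8w", popn),
               median(sim8$conc_ugml[i, ]))
})

test_that("with IIV disabled the trough median equals the typical trough", {
  pop0 <- pop_params(omega_cl = 0, omega_vc = 0, omega_vp = 0, omega_f = 0,
                     omega_ksyn = 0, omega_fc0 = 0)
  cov <- reference_covariates()
  cov$weight <- 70  # 390 mg band
  pars <- individual_parameters(pop0, cov)
  times <- sort(unique(c(seq(0, 336, by = 28), 336)))
  sim <- simulate_patient(pars, build_schedule("a", 70, horizon = 336), times)
  typical_trough <- sim$conc_ugml[match(336, times), 1]
  # a degenerate cohort of identical typical subjects has that median
  cfg <- run_config(scenarios = "a", n = 5, seed = 1, pop = pop0)
  popn <- study_population(cfg)
  popn$cohort <- cov[rep(1, 5), ]
  popn$pars <- pars[rep(1, 5), ]
  expect_equal(median_ss_trough(cfg, "q8w", popn), typical_trough,
               tolerance = 1e-8)
})

test_that("ksyn sensitivity vanishes at multiplier one and in the linear limit", {
  expect_equal(ksyn_peak_sensitivity(multiplier = 1), 0, tolerance = 1e-9)
})

test_that("remission can optionally be classified on noisy FC", {
  cfg <- run_config(scenarios = "a", n = 80, seed = 5,
                    remission_with_ruv = TRUE)
  r <- run_scenario(cfg, "a")
  expect_true(all(r$proportion >= 0 & r$proportion <= 1))
})

test_that("YAML configuration round-trips through read_run_config", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("scenarios: [a, d]", "n: 25", "seed: 99", "horizon: 224",
               "pop:", "  kd: 0.2", "spec:", "  p_ulcer: 0.9"), path)
  cfg <- read_run_config(path)
  expect_identical(cfg$scenarios, c("a", "d"))
  expect_identical(cfg$n, 25L)
  expect_equal(cfg$pop$kd, 0.2)
  expect_equal(cfg$spec$p_ulcer, 0.9)
  unlink(path)
})

test_that("simulated trajectories export in the documented long format", {
  p <- individual_parameters(pop_params(), reference_covariates())
  sim <- simulate_patient(p, build_schedule("a", 70), times = seq(0, 224, 56))
  path <- tempfile(fileext = ".tsv")
  write_timeseries(sim, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_named(tab, c("subject_id", "time_day", "conc_ugml", "conc_nmolL",
                      "free_target_nmolL", "fc_mgkg"))
  expect_equal(nrow(tab), 5)
  unlink(path)
})
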