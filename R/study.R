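#' Configuration for a virtual dosing study
#'
#' Bundles the run-time choices of a simulated trial: which scenarios to run,
#' cohort size, seed, horizon, assessment weeks, remission cut-off, solver
#' tolerances, the IIV-scale reading and whether remission is classified on
#' the model-predicted FC (default) or on FC perturbed by the proportional
#' residual error.
#'
#' @param scenarios character vector of scenario ids (subset of `"a"`--`"f"`).
#' @param n cohort size (>= 1).
#' @param seed integer seed for cohort generation and random effects.
#' @param horizon simulation horizon in days (>= 224 so week 32 is covered).
#' @param weeks assessment weeks.
#' @param trough_week week at which steady-state troughs are read.
#' @param remission_threshold FC remission cut-off (mg/kg).
#' @param remission_with_ruv classify on FC with proportional residual error.
#' @param ulcer_subgroup restrict remission metrics to subjects with
#'   endoscopically active disease at baseline (as in the study).
#' @param trough_full_cohort compute troughs over the full cohort (PK-only
#'   summary) rather than the ulcer subgroup.
#' @param iiv_scale see [sample_random_effects()].
#' @param rtol,atol solver tolerances.
#' @param pop population parameters ([pop_params()]).
#' @param spec optional [population_spec()]; by default one of size `n` using
#'   the study marginals (its seed is left `NULL`: the config seed governs).
#' @return an object of class `run_config`.
#' @examples
#' cfg <- run_config(scenarios = "a", n = 200, seed = 7)
#' @export
run_config <- function(scenarios = letters[1:6], n = 10000, seed = 1,
                       horizon = 224, weeks = c(8, 16, 24, 32),
                       trough_week = 48, remission_threshold = 100,
                       remission_with_ruv = FALSE, ulcer_subgroup = TRUE,
                       trough_full_cohort = TRUE,
                       iiv_scale = c("cv-derived", "direct-sd"),
                       rtol = 1e-8, atol = 1e-10,
                       pop = pop_params(), spec = NULL) {
  scenarios <- as.character(scenarios)
  bad <- setdiff(scenarios, letters[1:6])
  if (length(bad)) stop("unknown scenario id(s): ", paste(bad, collapse = ","))
  if (n < 1) stop("cohort size must be >= 1")
  if (horizon < 224) stop("horizon must be >= 224 days (week 32)")
  if (is.null(spec)) spec <- population_spec(n = n)
  structure(list(
    scenarios = scenarios, n = as.integer(n), seed = as.integer(seed),
    horizon = horizon, weeks = weeks, trough_week = trough_week,
    remission_threshold = remission_threshold,
    remission_with_ruv = isTRUE(remission_with_ruv),
    ulcer_subgroup = isTRUE(ulcer_subgroup),
    trough_full_cohort = isTRUE(trough_full_cohort),
    iiv_scale = match.arg(iiv_scale),
    rtol = rtol, atol = atol, pop = pop, spec = spec
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file holds top-level `run_config()` arguments plus optional nested
#' sections `pop` (overrides passed to [pop_params()]) and `spec` (overrides
#' passed to [population_spec()]).
#'
#' @param path YAML file path.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configurations requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  # a bare `n:` key is a YAML 1.1 boolean; map it back to the argument name
  names(raw)[names(raw) %in% c("FALSE", "no")] <- "n"
  pop <- do.call(pop_params, as.list(raw$pop))
  raw$pop <- NULL
  spec_over <- as.list(raw$spec)
  raw$spec <- NULL
  cfg <- do.call(run_config, c(raw, list(pop = pop)))
  if (length(spec_over)) {
    cfg$spec <- do.call(population_spec,
                        utils::modifyList(list(n = cfg$n), spec_over))
  }
  cfg
}

#' Generate the virtual study population for a configuration
#'
#' Seeds the RNG from the configuration, generates the cohort, draws random
#' effects and computes the individual parameters. All scenarios of one study
#' share this population, so adaptive regimens are compared on the same
#' virtual subjects.
#'
#' @param config a [run_config()].
#' @return list with elements `cohort`, `eta`, `pars` and `ulcer` (row
#'   indices of the endoscopically active subgroup).
#' @export
study_population <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  spec <- config$spec
  spec$n <- config$n
  cohort <- generate_cohort(spec)
  eta <- sample_random_effects(config$pop, config$n, config$iiv_scale)
  pars <- individual_parameters(config$pop, cohort, eta)
  list(cohort = cohort, eta = eta, pars = pars,
       ulcer = which(cohort$ulcers_baseline))
}

# Simulate a scenario for a set of subjects sharing the event-time shape.
# flags (week-16 remission) are needed for d-f; returns a pkpd_sim.
simulate_scenario_group <- function(config, cohort, pars, scenario,
                                    flag, times) {
  schedules <- lapply(seq_len(nrow(cohort)), function(i) {
    build_schedule(scenario, cohort$weight[i], in_remission_wk16 = flag,
                   horizon = max(times))
  })
  simulate_cohort(pars, schedules, times,
                  control = list(rtol = config$rtol, atol = config$atol))
}

#' Run one dosing scenario
#'
#' Simulates the configured virtual population under one of the six dosing
#' strategies and returns the remission proportions at the assessment weeks,
#' computed over the endoscopically active subgroup (the study's convention)
#' unless `config$ulcer_subgroup` is `FALSE`. For the response-adaptive
#' scenarios d--f, week-16 remission is read pre-dose at day 112 from the
#' standard-schedule simulation; remitters keep their standard trajectories
#' (weeks 0--16 are identical across scenarios by construction) and only the
#' non-remitters are re-simulated under the escalated schedule.
#'
#' @param config a [run_config()].
#' @param scenario scenario id `"a"`--`"f"`.
#' @param context optional cached study context from [run_study()] internals:
#'   list with `popn` (from [study_population()]) and optionally `sim_std`
#'   (standard-schedule simulation of the metric subgroup). Supplying it
#'   reuses the population and standard trajectories across scenarios.
#' @return an object of class `scenario_result`: scenario id, subgroup size,
#'   seed, assessment weeks, remission proportions and Monte-Carlo standard
#'   errors, plus the per-subject FC matrix at the assessment days.
#' @examples
#' cfg <- run_config(scenarios = "a", n = 50, seed = 1)
#' run_scenario(cfg, "a")
#' @export
run_scenario <- function(config, scenario, context = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!scenario %in% letters[1:6]) stop("unknown scenario id: ", scenario)
  if (is.null(context)) context <- study_context(config)
  popn <- context$popn
  idx <- if (config$ulcer_subgroup) popn$ulcer else seq_len(config$n)
  if (!length(idx)) stop("metric subgroup is empty")
  cohort <- popn$cohort[idx, , drop = FALSE]
  pars <- popn$pars[idx, , drop = FALSE]
  times <- context$times

  if (scenario %in% c("a", "b", "c")) {
    sim <- if (scenario == "a") context$sim_std else {
      simulate_scenario_group(config, cohort, pars, scenario, NA, times)
    }
    fc <- sim$fc_mgkg
  } else {
    flags <- assess_remission(context$sim_std, 16, config$remission_threshold)
    fc <- context$sim_std$fc_mgkg
    nr <- which(!flags)
    if (length(nr)) {
      sim_nr <- simulate_scenario_group(config, cohort[nr, , drop = FALSE],
                                        pars[nr, , drop = FALSE], scenario,
                                        FALSE, times)
      fc[, nr] <- sim_nr$fc_mgkg
    }
  }

  day_idx <- match(config$weeks * 7, times)
  if (anyNA(day_idx)) stop("assessment weeks are off the simulation grid")
  fc_w <- fc[day_idx, , drop = FALSE]
  if (config$remission_with_ruv) {
    fc_w <- fc_w * (1 + stats::rnorm(length(fc_w), 0, config$pop$sigma_fc))
    fc_w <- pmax(fc_w, 0)
  }
  prop <- rowMeans(fc_w < config$remission_threshold)
  n <- length(idx)
  structure(list(
    scenario = scenario, n = n, seed = config$seed, weeks = config$weeks,
    proportion = unname(prop),
    se = sqrt(pmax(prop * (1 - prop), 0) / n),
    fc_weeks = fc_w
  ), class = "scenario_result")
}

# Shared per-study cache: population, output grid, and the standard-schedule
# simulation of the metric subgroup (scenario a), which weeks 0-16 of the
# adaptive scenarios reuse.
study_context <- function(config) {
  popn <- study_population(config)
  idx <- if (config$ulcer_subgroup) popn$ulcer else seq_len(config$n)
  times <- sort(unique(c(seq(0, config$horizon, by = 7), config$horizon)))
  sim_std <- simulate_scenario_group(
    config, popn$cohort[idx, , drop = FALSE],
    popn$pars[idx, , drop = FALSE], "a", NA, times)
  list(popn = popn, times = times, sim_std = sim_std)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario (%s): n = %d, seed = %d\n", x$scenario, x$n, x$seed))
  for (i in seq_along(x$weeks)) {
    cat(sprintf("  week %2d remission: %5.1f%% (SE %.1f pp)\n",
                x$weeks[i], 100 * x$proportion[i], 100 * x$se[i]))
  }
  invisible(x)
}

#' Run the configured scenario list
#'
#' Generates the virtual population once, simulates every scenario in
#' `config$scenarios` on it, and assembles the remission table.
#'
#' @param config a [run_config()].
#' @return list with `results` (named list of `scenario_result`), `table`
#'   (the tidy remission table), `cohort` and `pars`.
#' @examples
#' st <- run_study(run_config(scenarios = c("a", "d"), n = 100, seed = 2))
#' st$table
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ctx <- study_context(config)
  results <- lapply(config$scenarios, function(s) run_scenario(config, s, ctx))
  names(results) <- config$scenarios
  list(results = results, table = remission_table(results),
       cohort = ctx$popn$cohort, pars = ctx$popn$pars)
}

#' Tidy remission table across scenarios
#'
#' @param results a list of `scenario_result` objects.
#' @param path optional file path; when given the table is also written as
#'   tab-separated text.
#' @return data.frame with columns `scenario, week, proportion, se`.
#' @export
remission_table <- function(results, path = NULL) {
  if (inherits(results, "scenario_result")) results <- list(results)
  if (!length(results)) stop("remission_table: no scenario results")
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(scenario = r$scenario, week = r$weeks,
               proportion = r$proportion, se = r$se)
  }))
  rownames(tab) <- NULL
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  tab
}

#' Median steady-state trough concentration
#'
#' Simulates the cohort under IV induction plus 90 mg SC maintenance on the
#' chosen calendar (every 8 weeks, or every 4 weeks from week 4) continued to
#' the configured trough week (48 by default, more than four terminal
#' half-lives into maintenance), reads each subject's pre-dose free-drug
#' concentration at that day and returns the cohort median in ug/mL.
#' Troughs are a PK-only summary and are computed over the full cohort by
#' default (`config$trough_full_cohort`).
#'
#' @param config a [run_config()].
#' @param regimen `"q8w"` or `"q4w"`.
#' @param popn optional cached [study_population()] output.
#' @return median trough (ug/mL).
#' @examples
#' cfg <- run_config(scenarios = "a", n = 100, seed = 3)
#' median_ss_trough(cfg, "q8w")
#' @export
median_ss_trough <- function(config, regimen = c("q8w", "q4w"), popn = NULL) {
  regimen <- match.arg(regimen)
  stopifnot(inherits(config, "run_config"))
  day <- config$trough_week * 7
  if (day < 224) stop("trough week too early for steady state")
  if (is.null(popn)) popn <- study_population(config)
  idx <- if (config$trough_full_cohort) seq_len(nrow(popn$cohort)) else
    popn$ulcer
  cohort <- popn$cohort[idx, , drop = FALSE]
  pars <- popn$pars[idx, , drop = FALSE]
  times <- sort(unique(c(seq(0, day, by = 28), day)))
  sim <- simulate_scenario_group(config, cohort, pars,
                                 if (regimen == "q8w") "a" else "b",
                                 NA, times)
  troughs <- sim$conc_ugml[match(day, sim$time), ]
  stats::median(troughs)
}

#' Sensitivity of the induction peak to the target synthesis rate
#'
#' Simulates the typical patient (reference covariates, zero random effects)
#' after a single 390 mg IV dose infused over one hour, once at the typical
#' target synthesis rate and once with `ksyn` multiplied by `multiplier`
#' (baseline target R0 and the peripheral target initial condition scale with
#' it), and returns the drop in peak free-drug concentration in ug/mL.
#'
#' @param pop population parameters.
#' @param multiplier factor on `ksyn` for the second run (default 10).
#' @param control solver options, as in [simulate_patient()].
#' @return `peak(typical) - peak(multiplied)` in ug/mL.
#' @examples
#' \donttest{ksyn_peak_sensitivity(pop_params())}
#' @export
ksyn_peak_sensitivity <- function(pop = pop_params(), multiplier = 10,
                                  control = list()) {
  p1 <- individual_parameters(pop, reference_covariates())
  p2 <- p1
  p2$ksyn <- p1$ksyn * multiplier
  p2$r0 <- p2$ksyn / p2$kdeg
  sch <- data.frame(time = 0, route = "iv", amount_mg = 390,
                    infusion_duration = 1 / 24)
  times <- sort(unique(c(seq(0, 3, by = 1 / 96), seq(3, 28, by = 0.25))))
  peak <- function(p) {
    max(simulate_patient(p, sch, times, control = control)$conc_ugml)
  }
  peak(p1) - peak(p2)
}
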