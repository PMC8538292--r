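#' Weight-banded induction dose
#'
#' The IV induction dose by body weight: 260 mg at or below 55 kg, 390 mg
#' above 55 up to and including 85 kg, 520 mg above 85 kg.
#'
#' @param weight body weight (kg), positive; vectorised.
#' @return dose in mg (260, 390 or 520).
#' @examples
#' induction_dose_mg(c(55, 70, 86))  # 260 390 520
#' @export
induction_dose_mg <- function(weight) {
  if (!is.numeric(weight) || anyNA(weight) || any(weight <= 0)) {
    stop("induction_dose_mg: weight must be positive")
  }
  ifelse(weight <= 55, 260, ifelse(weight <= 85, 390, 520))
}

#' Build a dose schedule for one of the six simulated strategies
#'
#' Scenarios:
#' * `"a"` -- weight-banded IV induction at day 0, then 90 mg SC every 8
#'   weeks (standard treatment);
#' * `"b"` -- IV induction, then 90 mg SC every 4 weeks from week 4;
#' * `"c"` -- weight-banded IV doses every 8 weeks;
#' * `"d"` -- standard treatment; non-remitters at week 16 switch to 90 mg SC
#'   every 4 weeks from week 20;
#' * `"e"` -- standard treatment; non-remitters receive an IV reinduction at
#'   week 16 (replacing the week-16 SC dose) and continue 90 mg SC every 8
#'   weeks (weeks 24, 32, ...);
#' * `"f"` -- as `"e"` but followed by 90 mg SC every 4 weeks from week 20.
#'
#' For scenarios d--f the week-16 remission flag is required; subjects in
#' remission receive the scenario-(a) schedule. Maintenance doses are placed
#' at all multiples of the interval up to and including the horizon; a dose
#' falling exactly on an assessment day cannot influence that day's read-out
#' (SC doses only fill the depot and IV infusions start after the read-out).
#'
#' @param scenario one of `"a"`--`"f"`.
#' @param cov a one-row covariate data.frame (only `weight` is used), or a
#'   numeric weight in kg.
#' @param in_remission_wk16 logical flag, required for scenarios d--f.
#' @param horizon schedule horizon (days), default 224 (32 weeks).
#' @param maintenance_mg SC maintenance dose (mg), default 90.
#' @param infusion_duration IV infusion length (days), default 1/24 (1 h).
#' @return a schedule data.frame with columns `time, route, amount_mg,
#'   infusion_duration`, sorted by time.
#' @examples
#' build_schedule("a", 70)
#' build_schedule("f", 70, in_remission_wk16 = FALSE)
#' @export
build_schedule <- function(scenario, cov, in_remission_wk16 = NA,
                           horizon = 224, maintenance_mg = 90,
                           infusion_duration = 1 / 24) {
  if (!is.character(scenario) || length(scenario) != 1L ||
      !scenario %in% letters[1:6]) {
    stop("unknown scenario id: ", paste(scenario, collapse = ","),
         " (expected one of a-f)")
  }
  weight <- if (is.data.frame(cov)) cov$weight else cov
  ind_mg <- induction_dose_mg(weight)
  if (scenario %in% c("d", "e", "f")) {
    if (is.na(in_remission_wk16)) {
      stop("scenario ", scenario, " requires the week-16 remission flag")
    }
    if (isTRUE(in_remission_wk16)) scenario <- "a"
  }

  ev <- function(time, route, amount) {
    data.frame(time = time, route = route, amount_mg = amount,
               infusion_duration = ifelse(route == "iv", infusion_duration, 0))
  }
  grid <- function(from, by) {
    t <- seq(from, horizon, by = by)
    t[t <= horizon]
  }
  sch <- switch(scenario,
    a = rbind(ev(0, "iv", ind_mg),
              ev(grid(56, 56), "sc", maintenance_mg)),
    b = rbind(ev(0, "iv", ind_mg),
              ev(grid(28, 28), "sc", maintenance_mg)),
    c = ev(grid(0, 56), "iv", ind_mg),
    d = rbind(ev(0, "iv", ind_mg),
              ev(c(56, 112), "sc", maintenance_mg),
              ev(grid(140, 28), "sc", maintenance_mg)),
    e = rbind(ev(0, "iv", ind_mg),
              ev(56, "sc", maintenance_mg),
              ev(112, "iv", ind_mg),
              ev(grid(168, 56), "sc", maintenance_mg)),
    f = rbind(ev(0, "iv", ind_mg),
              ev(56, "sc", maintenance_mg),
              ev(112, "iv", ind_mg),
              ev(grid(140, 28), "sc", maintenance_mg))
  )
  sch <- sch[sch$time <= horizon, , drop = FALSE]
  rownames(sch) <- NULL
  sch[order(sch$time), , drop = FALSE]
}

#' Classify biochemical remission at an assessment week
#'
#' Remission is model-predicted fecal calprotectin strictly below the cut-off
#' (100 mg/kg by default) at the assessment day (`week * 7`). The assessment
#' day must be on the simulated grid; the value there is the pre-dose FC,
#' since same-day doses cannot influence the read-out.
#'
#' @param sim a `pkpd_sim` object.
#' @param week assessment week (scalar).
#' @param threshold remission cut-off (mg/kg).
#' @return logical vector, one flag per subject.
#' @examples
#' p <- individual_parameters(pop_params(), reference_covariates())
#' sim <- simulate_patient(p, build_schedule("a", 70), times = 0:224)
#' assess_remission(sim, 16)
#' @export
assess_remission <- function(sim, week, threshold = 100) {
  stopifnot(inherits(sim, "pkpd_sim"), length(week) == 1L)
  day <- week * 7
  i <- which(sim$time == day)
  if (length(i) != 1L) {
    stop("assessment day ", day, " is not on the simulated grid")
  }
  unname(sim$fc_mgkg[i, ] < threshold)
}

#' Export dose schedules as delimited text
#'
#' Writes one row per dose event with columns `subject_id, time_day, route,
#' amount_mg`, tab-separated, for audit.
#'
#' @param schedules a named list of schedule data.frames (names are subject
#'   ids) or a single schedule.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_schedules <- function(schedules, path) {
  if (is.data.frame(schedules)) schedules <- list(`1` = schedules)
  rows <- do.call(rbind, lapply(names(schedules), function(id) {
    s <- schedules[[id]]
    data.frame(subject_id = id, time_day = s$time, route = s$route,
               amount_mg = s$amount_mg)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
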