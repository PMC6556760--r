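#' Specify the ground truth for one trial arm
#'
#' An `arm_spec` describes one arm of the simulated world: its true outcome
#' distribution, its adherence, its role, and (for platform designs) when it
#' becomes available. Non-adherent patients on a treatment arm cross over to
#' the control distribution but remain analyzed on their assigned arm
#' (intent-to-treat dilution).
#'
#' @param name arm label (unique within a scenario).
#' @param role `"control"` or `"treatment"`. A scenario has exactly one
#'   control.
#' @param true_param true response probability (binary outcome, in (0,1)) or
#'   true mean (continuous outcome).
#' @param true_sd true outcome SD (continuous outcomes only).
#' @param adherence proportion of patients in \[0,1\] who actually receive
#'   the assigned arm; the remainder respond like controls.
#' @param available_from 0 for arms active from the start; a positive patient
#'   count for queued platform arms, which may be admitted once an admission
#'   trigger fires at or after that accrual point.
#' @param secondary_param,secondary_sd true parameters of an optional
#'   secondary (monitoring-only) outcome.
#' @return an object of class `arm_spec`.
#' @export
arm_spec <- function(name, role = c("treatment", "control"), true_param,
                     true_sd = NULL, adherence = 1, available_from = 0,
                     secondary_param = NULL, secondary_sd = NULL) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_field("name", "must be a non-empty string")
  check_scalar_num(true_param, "true_param")
  if (!is.null(true_sd)) check_scalar_num(true_sd, "true_sd", lo = 0, open_lo = TRUE)
  check_scalar_num(adherence, "adherence", lo = 0, hi = 1)
  check_scalar_num(available_from, "available_from", lo = 0)
  if (!is.null(secondary_param)) check_scalar_num(secondary_param, "secondary_param")
  if (!is.null(secondary_sd)) check_scalar_num(secondary_sd, "secondary_sd", lo = 0, open_lo = TRUE)
  structure(list(name = name, role = role, true_param = as.numeric(true_param),
                 true_sd = if (is.null(true_sd)) NULL else as.numeric(true_sd),
                 adherence = as.numeric(adherence),
                 available_from = as.integer(available_from),
                 secondary_param = secondary_param,
                 secondary_sd = secondary_sd),
            class = "arm_spec")
}

#' Define the adaptive design: thresholds, schedule, allocation, platform
#'
#' All thresholds, schedules and platform settings that define an adaptive
#' design. Interim looks are placed at equal increments of accumulated total
#' sample size: look `j` occurs at `ceiling(j * max_n / n_looks)` patients,
#' with the last look coinciding with `max_n` (the final analysis).
#'
#' Decision rules evaluated at each look, in fixed order: (1) stop the trial
#' for superiority when the maximum superiority probability exceeds
#' `superiority_threshold`; (2) drop any treatment arm whose superiority
#' probability falls below `futility_threshold`; (3) drop any treatment arm
#' judged, with certainty `mcid_certainty` or more, to have an effect below
#' `mcid_margin`; (4) if arms were dropped, a platform design admits queued
#' arms to replace them; (5) if no treatment arm remains, stop for futility.
#' The control arm is never dropped.
#'
#' @param outcome `"binary"` or `"continuous"`.
#' @param max_n maximum total sample size of the adaptive design and the
#'   fixed sample size of the conventional comparator.
#' @param n_looks number of interim analyses (the last is the final
#'   analysis at `max_n`).
#' @param direction benefit direction; defaults to `"lower-better"` for
#'   binary outcomes (harmful-event convention, as in a relative risk
#'   reduction) and `"higher-better"` for continuous.
#' @param superiority_threshold posterior probability in (0.5, 1\] above
#'   which the trial stops and declares the leading arm the winner.
#' @param futility_threshold superiority probability in \[0, 0.5) below
#'   which a treatment arm is dropped.
#' @param mcid_margin minimally clinically important effect margin (relative
#'   risk reduction for binary, mean difference for continuous), or `NULL`
#'   to disable the margin rule.
#' @param mcid_certainty certainty in (0.5, 1\] required to drop an arm on
#'   the margin rule.
#' @param burn_in accrued sample size before which allocation stays equal
#'   even under response-adaptive randomization.
#' @param rar_enabled enable response-adaptive randomization (weights
#'   recomputed for every accumulated patient after burn-in).
#' @param platform_enabled allow queued arms to be admitted when active arms
#'   are dropped.
#' @param perpetual with `platform_enabled`, continue the trial into a new
#'   two-arm comparison (winner vs next queued arm) instead of stopping at
#'   superiority, up to `perpetual_cap` patients.
#' @param comparison_mode `"all-arms"` (probability of being best of all
#'   active arms) or `"vs-control"` (pairwise probability of beating
#'   control).
#' @param cost_per_patient linear per-patient cost (currency units).
#' @param accrual_rate constant accrual rate (patients per time unit);
#'   trial duration is `total_n / accrual_rate`.
#' @param decision_draws Monte-Carlo posterior draws per interim decision
#'   (default 10000).
#' @param rar_draws posterior draws for the per-patient allocation update
#'   (default 1000, reduced for tractability).
#' @param rar_floor allocation floor passed to [rar_weights()].
#' @param protect_control pin the control allocation at `1/K` under RAR.
#' @param max_active_arms cap on concurrently active arms; `NULL` means the
#'   number of initially active arms.
#' @param perpetual_cap hard stop for perpetual platform trials (default
#'   `5 * max_n`); trials censored there report `"perpetual-censored"`.
#' @param new_arm_burn_in patients accrued with equal allocation after a new
#'   platform arm is admitted, before RAR resumes (default 50).
#' @param prior named list overriding the diffuse prior: `alpha`, `beta`
#'   (binary; default 1, 1) or `mean`, `scale` (continuous; default 0, 1000).
#' @param planning_sd planning outcome SD for continuous outcomes, used as
#'   the plug-in until the data can estimate a pooled SD.
#' @param secondary_outcome `"binary"` or `"continuous"` if a
#'   monitoring-only secondary outcome is tracked, else `NULL`.
#' @return an object of class `design_rules`.
#' @export
design_rules <- function(outcome = c("binary", "continuous"), max_n,
                         n_looks = 1L, direction = NULL,
                         superiority_threshold = 0.99,
                         futility_threshold = 0.01,
                         mcid_margin = NULL, mcid_certainty = 0.95,
                         burn_in = 0L, rar_enabled = FALSE,
                         platform_enabled = FALSE, perpetual = FALSE,
                         comparison_mode = c("all-arms", "vs-control"),
                         cost_per_patient = 1, accrual_rate = 1,
                         decision_draws = 10000L, rar_draws = 1000L,
                         rar_floor = 0.01, protect_control = FALSE,
                         max_active_arms = NULL, perpetual_cap = NULL,
                         new_arm_burn_in = 50L, prior = NULL,
                         planning_sd = 1, secondary_outcome = NULL) {
  outcome <- match.arg(outcome)
  comparison_mode <- match.arg(comparison_mode)
  if (is.null(direction))
    direction <- if (outcome == "binary") "lower-better" else "higher-better"
  if (!direction %in% c("higher-better", "lower-better"))
    stop_field("direction", "must be \"higher-better\" or \"lower-better\"")
  check_scalar_num(max_n, "max_n", lo = 2)
  check_scalar_num(n_looks, "n_looks", lo = 1)
  check_scalar_num(superiority_threshold, "superiority_threshold",
                   lo = 0.5, hi = 1, open_lo = TRUE)
  check_scalar_num(futility_threshold, "futility_threshold",
                   lo = 0, hi = 0.5, open_hi = TRUE)
  if (!is.null(mcid_margin)) {
    check_scalar_num(mcid_margin, "mcid_margin", lo = 0)
    check_scalar_num(mcid_certainty, "mcid_certainty",
                     lo = 0.5, hi = 1, open_lo = TRUE)
  }
  check_scalar_num(burn_in, "burn_in", lo = 0, hi = max_n)
  check_scalar_num(cost_per_patient, "cost_per_patient", lo = 0)
  check_scalar_num(accrual_rate, "accrual_rate", lo = 0, open_lo = TRUE)
  check_scalar_num(decision_draws, "decision_draws", lo = 1)
  check_scalar_num(rar_draws, "rar_draws", lo = 1)
  check_scalar_num(rar_floor, "rar_floor", lo = 0, hi = 1)
  check_scalar_num(new_arm_burn_in, "new_arm_burn_in", lo = 0)
  check_scalar_num(planning_sd, "planning_sd", lo = 0, open_lo = TRUE)
  if (!is.null(max_active_arms))
    check_scalar_num(max_active_arms, "max_active_arms", lo = 2)
  if (is.null(perpetual_cap)) perpetual_cap <- 5 * max_n
  check_scalar_num(perpetual_cap, "perpetual_cap", lo = max_n)
  if (!is.null(secondary_outcome) &&
      !secondary_outcome %in% c("binary", "continuous"))
    stop_field("secondary_outcome", "must be \"binary\" or \"continuous\"")
  default_prior <- if (outcome == "binary") list(alpha = 1, beta = 1)
                   else list(mean = 0, scale = 1000)
  if (is.null(prior)) prior <- default_prior
  bad <- setdiff(names(prior), names(default_prior))
  if (length(bad)) stop_field("prior", paste("unknown element:", bad[1]))
  prior <- utils::modifyList(default_prior, prior)
  structure(list(outcome = outcome, direction = direction,
                 max_n = as.integer(max_n), n_looks = as.integer(n_looks),
                 superiority_threshold = superiority_threshold,
                 futility_threshold = futility_threshold,
                 mcid_margin = mcid_margin, mcid_certainty = mcid_certainty,
                 burn_in = as.integer(burn_in), rar_enabled = isTRUE(rar_enabled),
                 platform_enabled = isTRUE(platform_enabled),
                 perpetual = isTRUE(perpetual),
                 comparison_mode = comparison_mode,
                 cost_per_patient = cost_per_patient,
                 accrual_rate = accrual_rate,
                 decision_draws = as.integer(decision_draws),
                 rar_draws = as.integer(rar_draws),
                 rar_floor = rar_floor, protect_control = isTRUE(protect_control),
                 max_active_arms = if (is.null(max_active_arms)) NULL else as.integer(max_active_arms),
                 perpetual_cap = as.integer(perpetual_cap),
                 new_arm_burn_in = as.integer(new_arm_burn_in),
                 prior = prior, planning_sd = planning_sd,
                 secondary_outcome = secondary_outcome),
            class = "design_rules")
}

#' Validate a full scenario (arms plus rules) before any simulation
#'
#' @param arms list of [arm_spec()] objects.
#' @param rules a [design_rules()] object.
#' @return invisibly `TRUE`; errors name the offending field.
#' @export
validate_scenario <- function(arms, rules) {
  if (!inherits(rules, "design_rules")) stop_field("rules", "not a design_rules object")
  if (!is.list(arms) || length(arms) < 2L)
    stop_field("arms", "need at least 2 arms")
  if (!all(vapply(arms, inherits, TRUE, "arm_spec")))
    stop_field("arms", "every element must be an arm_spec")
  roles <- vapply(arms, `[[`, "", "role")
  if (sum(roles == "control") != 1L)
    stop_field("arms", "exactly one control arm is required")
  ctl <- which(roles == "control")
  if (arms[[ctl]]$available_from != 0L)
    stop_field("available_from", "the control arm must be active from the start")
  nm <- vapply(arms, `[[`, "", "name")
  if (anyDuplicated(nm)) stop_field("name", "arm names must be unique")
  for (a in arms) {
    if (rules$outcome == "binary") {
      if (a$true_param <= 0 || a$true_param >= 1)
        stop_field("true_param",
                   sprintf("binary response probability for arm \"%s\" must be in (0,1)", a$name))
    } else if (is.null(a$true_sd)) {
      stop_field("true_sd",
                 sprintf("continuous outcome requires true_sd for arm \"%s\"", a$name))
    }
    if (!is.null(rules$secondary_outcome)) {
      if (is.null(a$secondary_param))
        stop_field("secondary_param",
                   sprintf("secondary outcome configured but arm \"%s\" has no secondary_param", a$name))
      if (rules$secondary_outcome == "continuous" && is.null(a$secondary_sd))
        stop_field("secondary_sd",
                   sprintf("continuous secondary outcome requires secondary_sd for arm \"%s\"", a$name))
    }
  }
  n_initial <- sum(vapply(arms, function(a) a$available_from == 0L, TRUE))
  if (n_initial < 2L)
    stop_field("available_from", "at least 2 arms must be active from the start")
  invisible(TRUE)
}
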