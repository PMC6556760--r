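CONFIG_SCHEMA_VERSION <- 1L

config_keys <- list(
  top = c("schema_version", "arms", "rules", "secondary", "simulation"),
  arm = c("name", "role", "true_param", "true_sd", "adherence",
          "available_from", "secondary_param", "secondary_sd"),
  rules = c("outcome", "direction", "max_n", "n_looks",
            "superiority_threshold", "futility_threshold", "mcid_margin",
            "mcid_certainty", "burn_in", "rar_enabled", "platform_enabled",
            "perpetual", "comparison_mode", "cost_per_patient",
            "accrual_rate", "decision_draws", "rar_draws", "rar_floor",
            "protect_control", "max_active_arms", "perpetual_cap",
            "new_arm_burn_in", "prior", "planning_sd"),
  secondary = "outcome",
  simulation = c("n_sims", "time_budget", "seed")
)

reject_unknown <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown key \"%s\" in %s (allowed: %s)",
                 bad[1], where, paste(allowed, collapse = ", ")),
         call. = FALSE)
}

#' Construct a scenario configuration object
#'
#' Bundles the ground-truth arms, the design rules and the simulation block
#' (replicate count or time budget plus master seed) into a validated
#' `hect_config`, the unit that [load_config()] and [save_config()]
#' serialize and that the CLI consumes.
#'
#' @param arms list of [arm_spec()] objects.
#' @param rules a [design_rules()] object.
#' @param n_sims default replicate count for design evaluation.
#' @param time_budget optional wall-clock budget in seconds (overrides
#'   `n_sims` when set).
#' @param seed default master seed.
#' @return an object of class `hect_config`.
#' @export
scenario_config <- function(arms, rules, n_sims = 200L, time_budget = NULL,
                            seed = 1L) {
  validate_scenario(arms, rules)
  if (!is.null(n_sims)) check_scalar_num(n_sims, "n_sims", lo = 1)
  if (!is.null(time_budget)) check_scalar_num(time_budget, "time_budget", lo = 0, open_lo = TRUE)
  check_scalar_num(seed, "seed", lo = 0)
  structure(list(schema_version = CONFIG_SCHEMA_VERSION, arms = arms,
                 rules = rules,
                 sim = list(n_sims = if (is.null(n_sims)) NULL else as.integer(n_sims),
                            time_budget = time_budget,
                            seed = as.integer(seed))),
            class = "hect_config")
}

#' @export
print.hect_config <- function(x, ...) {
  cat(sprintf("Trial scenario (schema v%d): %d arms, %s outcome, max_n %d, %d looks\n",
              x$schema_version, length(x$arms), x$rules$outcome,
              x$rules$max_n, x$rules$n_looks))
  for (a in x$arms)
    cat(sprintf("  %-10s %-9s true_param %-6g adherence %-4g%s\n",
                a$name, a$role, a$true_param, a$adherence,
                if (a$available_from > 0) sprintf(" (queued from %d)", a$available_from) else ""))
  invisible(x)
}

#' Load and validate a JSON scenario configuration
#'
#' Parses, validates and defaults a scenario file. Validation is complete
#' before anything runs: unknown keys are rejected with a message naming the
#' key, and out-of-range values raise errors naming the field and its
#' allowed range. Every field of [design_rules()] that the file omits takes
#' the documented default, and the applied defaults are logged as messages.
#'
#' @param path path to a JSON configuration file.
#' @param quiet suppress the defaulting log.
#' @return an object of class `hect_config`.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  reject_unknown(raw, config_keys$top, "config")
  if (is.null(raw$arms) || !length(raw$arms))
    stop_field("arms", "config must define at least 2 arms")
  if (is.null(raw$rules)) stop_field("rules", "config must define the design rules")
  sv <- raw$schema_version %||% CONFIG_SCHEMA_VERSION
  if (sv != CONFIG_SCHEMA_VERSION)
    stop_field("schema_version",
               sprintf("unsupported version %s (this package reads %d)",
                       sv, CONFIG_SCHEMA_VERSION))
  arms <- lapply(raw$arms, function(a) {
    reject_unknown(a, config_keys$arm, "arms[]")
    do.call(arm_spec, a)
  })
  reject_unknown(raw$rules, config_keys$rules, "rules")
  rules_args <- raw$rules
  if (!is.null(rules_args$prior)) rules_args$prior <- as.list(rules_args$prior)
  if (!is.null(raw$secondary)) {
    reject_unknown(raw$secondary, config_keys$secondary, "secondary")
    rules_args$secondary_outcome <- raw$secondary$outcome
  }
  defaulted <- setdiff(setdiff(names(formals(design_rules)), "secondary_outcome"),
                       names(rules_args))
  rules <- do.call(design_rules, rules_args)
  if (!quiet && length(defaulted))
    message("defaults applied for: ", paste(defaulted, collapse = ", "))
  sim <- raw$simulation %||% list()
  reject_unknown(sim, config_keys$simulation, "simulation")
  cfg <- scenario_config(arms, rules,
                         n_sims = sim$n_sims %||% 200L,
                         time_budget = sim$time_budget,
                         seed = sim$seed %||% 1L)
  cfg
}

#' Serialize a scenario configuration to JSON
#'
#' The written file loads back ([load_config()]) to an identical
#' configuration.
#'
#' @param config an `hect_config`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "hect_config"))
  arm_list <- lapply(config$arms, function(a) Filter(Negate(is.null), unclass(a)))
  rules <- unclass(config$rules)
  secondary <- NULL
  if (!is.null(rules$secondary_outcome))
    secondary <- list(outcome = rules$secondary_outcome)
  rules$secondary_outcome <- NULL
  rules <- Filter(Negate(is.null), rules)
  out <- list(schema_version = config$schema_version, arms = arm_list,
              rules = rules)
  if (!is.null(secondary)) out$secondary <- secondary
  out$simulation <- Filter(Negate(is.null), config$sim)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Canonical scenario fixtures used across the test suite
#'
#' Four fully specified scenarios at the worked example thresholds (99%
#' superiority, 1% probability-of-best futility, and 95% certainty that the
#' relative risk reduction is below 20% for the margin rule):
#'
#' * `null-2arm`: binary harmful-event outcome, control and treatment both
#'   at a 40% event rate (null truth), max_n 2000, 10 looks.
#' * `alt-2arm`: as above with the treatment event rate at 20% (a true 50%
#'   relative risk reduction).
#' * `platform-3arm`: control plus one active treatment at the null and one
#'   queued treatment at a 25% event rate; platform admission enabled with
#'   at most 2 concurrently active arms... the queued arm replaces the
#'   first treatment when it is dropped.
#' * `continuous-2arm`: Gaussian outcome (higher better), control mean 0 and
#'   treatment mean 0.4 at SD 1, mean-difference margin 0.2, max_n 500.
#'
#' @param name fixture name.
#' @return an object of class `hect_config`.
#' @export
make_fixture <- function(name = c("null-2arm", "alt-2arm", "platform-3arm",
                                  "continuous-2arm")) {
  name <- match.arg(name)
  bin_rules <- function(...) design_rules(
    outcome = "binary", max_n = 2000L, n_looks = 10L,
    superiority_threshold = 0.99, futility_threshold = 0.01,
    mcid_margin = 0.20, mcid_certainty = 0.95, burn_in = 200L,
    cost_per_patient = 500, accrual_rate = 10, ...)
  switch(name,
    "null-2arm" = scenario_config(
      list(arm_spec("control", "control", 0.40),
           arm_spec("treat", "treatment", 0.40)),
      bin_rules(), n_sims = 200L, seed = 42L),
    "alt-2arm" = scenario_config(
      list(arm_spec("control", "control", 0.40),
           arm_spec("treat", "treatment", 0.20)),
      bin_rules(), n_sims = 200L, seed = 42L),
    "platform-3arm" = scenario_config(
      list(arm_spec("control", "control", 0.40),
           arm_spec("treat1", "treatment", 0.40),
           arm_spec("treat2", "treatment", 0.25, available_from = 1)),
      bin_rules(platform_enabled = TRUE, max_active_arms = 2L),
      n_sims = 200L, seed = 42L),
    "continuous-2arm" = scenario_config(
      list(arm_spec("control", "control", 0.0, true_sd = 1),
           arm_spec("treat", "treatment", 0.4, true_sd = 1)),
      design_rules(outcome = "continuous", direction = "higher-better",
                   max_n = 500L, n_looks = 10L,
                   superiority_threshold = 0.99, futility_threshold = 0.01,
                   mcid_margin = 0.2, mcid_certainty = 0.95, burn_in = 50L,
                   cost_per_patient = 500, accrual_rate = 10,
                   planning_sd = 1),
      n_sims = 200L, seed = 42L))
}
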