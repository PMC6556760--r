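dist_summary <- function(x, bins = 20L) {
  qs <- stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  lo <- min(x); hi <- max(x)
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  breaks <- seq(lo, hi, length.out = bins + 1L)
  counts <- as.integer(table(cut(x, breaks, include.lowest = TRUE)))
  list(mean = mean(x), median = stats::median(x),
       q05 = qs[1], q25 = qs[2], q75 = qs[4], q95 = qs[5],
       min = min(x), max = max(x),
       hist = list(breaks = breaks, counts = counts))
}

replicate_block <- function(trials, arm_names) {
  winner <- vapply(trials, `[[`, "", "winner")
  declared <- !is.na(winner)
  # per-arm win probability = fraction of all replicates won by that arm;
  # the probabilities sum to prob_winner_declared (remainder = no winner)
  per_arm <- vapply(arm_names, function(a) sum(declared & winner == a) / length(winner), 0)
  list(prob_winner_declared = mean(declared),
       per_arm_win = per_arm,
       stop_reasons = {
         tab <- table(vapply(trials, `[[`, "", "stop_reason"))
         stats::setNames(as.integer(tab), names(tab))
       },
       sample_size = dist_summary(vapply(trials, `[[`, 0, "total_n")),
       cost = dist_summary(vapply(trials, `[[`, 0, "total_cost")),
       duration = dist_summary(vapply(trials, `[[`, 0, "duration")))
}

#' Estimate a design's operating characteristics by Monte Carlo
#'
#' Runs `n_sims` independent seeded replicates of [simulate_trial()] and, on
#' the same per-replicate child seeds, of the conventional fixed-sample
#' comparator [simulate_conventional()], and aggregates both into a
#' `hect_design_summary`: the probability a winner is declared (type I error
#' under a null truth, power under an alternative), per-arm win
#' probabilities, and mean/median/quantile/histogram summaries of final
#' sample size, cost and duration.
#'
#' Replicate `i` uses [child_seed()]`(seed, i)`, so extending `n_sims` never
#' reshuffles earlier replicates. With `time_budget` (seconds) instead of
#' `n_sims`, the wall clock is checked between replicates only — every
#' counted replicate is complete — and the realized count is recorded.
#'
#' @param arms list of [arm_spec()] objects.
#' @param rules a [design_rules()] object.
#' @param n_sims number of replicates, or `NULL` to use `time_budget`.
#' @param time_budget wall-clock budget in seconds (used when `n_sims` is
#'   `NULL`).
#' @param seed master seed for the replicate-splitting scheme.
#' @param progress_every if positive, a log line is emitted every that many
#'   replicates.
#' @return an object of class `hect_design_summary` with `adaptive` and
#'   `conventional` blocks.
#' @export
evaluate_design <- function(arms, rules, n_sims = NULL, time_budget = NULL,
                            seed = 1L, progress_every = 0L) {
  validate_scenario(arms, rules)
  if (is.null(n_sims) && is.null(time_budget))
    stop_field("n_sims", "supply n_sims or time_budget")
  if (!is.null(n_sims)) check_scalar_num(n_sims, "n_sims", lo = 1)
  if (!is.null(time_budget)) check_scalar_num(time_budget, "time_budget", lo = 0, open_lo = TRUE)
  adaptive <- list(); conventional <- list()
  t0 <- Sys.time()
  i <- 0L
  repeat {
    if (!is.null(n_sims) && i >= n_sims) break
    if (is.null(n_sims) &&
        as.numeric(difftime(Sys.time(), t0, units = "secs")) >= time_budget) break
    i <- i + 1L
    s <- child_seed(seed, i)
    adaptive[[i]] <- simulate_trial(arms, rules, seed = s)
    conventional[[i]] <- simulate_conventional(arms, rules, seed = s)
    if (progress_every > 0L && i %% progress_every == 0L)
      message(sprintf("replicate %d done", i))
  }
  if (i == 0L)
    stop("time_budget elapsed before any replicate completed", call. = FALSE)
  arm_names <- vapply(arms, `[[`, "", "name")
  rec <- function(trials, design) data.frame(
    design = design, rep = seq_along(trials),
    seed = vapply(trials, `[[`, 0L, "seed"),
    stop_reason = vapply(trials, `[[`, "", "stop_reason"),
    winner = vapply(trials, `[[`, "", "winner"),
    total_n = vapply(trials, `[[`, 0L, "total_n"),
    total_cost = vapply(trials, `[[`, 0, "total_cost"),
    duration = vapply(trials, `[[`, 0, "duration"),
    stringsAsFactors = FALSE)
  structure(list(n_sims = i, seed = as.integer(seed), arms = arm_names,
                 adaptive = replicate_block(adaptive, arm_names),
                 conventional = replicate_block(conventional, arm_names),
                 replicates = rbind(rec(adaptive, "adaptive"),
                                    rec(conventional, "conventional"))),
            class = "hect_design_summary")
}

#' @export
print.hect_design_summary <- function(x, ...) {
  cat(sprintf("Design operating characteristics (%d simulated trials, seed %d)\n",
              x$n_sims, x$seed))
  fmt <- function(b, label) {
    cat(sprintf("  %-12s winner declared %.3f | E[n] %.1f (median %g) | E[cost] %.1f | E[dur] %.2f\n",
                label, b$prob_winner_declared, b$sample_size$mean,
                b$sample_size$median, b$cost$mean, b$duration$mean))
  }
  fmt(x$adaptive, "adaptive:")
  fmt(x$conventional, "conventional:")
  invisible(x)
}

#' Estimate type I error and power for a design
#'
#' Runs [evaluate_design()] under a null scenario (all true parameters
#' equal; validated) and an alternative scenario, and reports the
#' winner-declared fraction under the null (type I error) and the fraction
#' of replicates declaring the truly best arm under the alternative
#' (power), each with its binomial Monte-Carlo standard error. The
#' conventional comparator's estimates are included.
#'
#' @param null_arms,alt_arms arm lists for the null and alternative truth.
#' @param rules a [design_rules()] object shared by both runs.
#' @param n_sims replicates per run.
#' @param seed master seed (both runs use the same seed sequence).
#' @return an object of class `hect_error_rates`.
#' @export
error_rate_pair <- function(null_arms, alt_arms, rules, n_sims, seed = 1L) {
  tp <- vapply(null_arms, `[[`, 0, "true_param")
  if (length(unique(tp)) != 1L)
    stop_field("null_arms",
               "all arms must share the same true_param in a null configuration")
  s_null <- evaluate_design(null_arms, rules, n_sims = n_sims, seed = seed)
  s_alt <- evaluate_design(alt_arms, rules, n_sims = n_sims, seed = seed)
  alt_tp <- vapply(alt_arms, `[[`, 0, "true_param")
  best <- if (rules$direction == "higher-better") which.max(alt_tp) else which.min(alt_tp)
  best_name <- alt_arms[[best]]$name
  se <- function(p, n) sqrt(p * (1 - p) / n)
  type1 <- s_null$adaptive$prob_winner_declared
  power <- s_alt$adaptive$per_arm_win[[best_name]]
  structure(list(
    type1 = type1, type1_se = se(type1, n_sims),
    power = power, power_se = se(power, n_sims),
    conventional_type1 = s_null$conventional$prob_winner_declared,
    conventional_power = s_alt$conventional$per_arm_win[[best_name]],
    best_arm = best_name, n_sims = n_sims,
    null_summary = s_null, alt_summary = s_alt),
    class = "hect_error_rates")
}

#' @export
print.hect_error_rates <- function(x, ...) {
  cat(sprintf("type I error: %.4f (SE %.4f)   power [%s]: %.4f (SE %.4f)\n",
              x$type1, x$type1_se, x$best_arm, x$power, x$power_se))
  cat(sprintf("conventional: type I %.4f, power %.4f   (%d sims each)\n",
              x$conventional_type1, x$conventional_power, x$n_sims))
  invisible(x)
}

#' Flatten design summaries into a one-row-per-design comparison table
#'
#' Produces the tabular analogue of the bar-chart comparison between the
#' adaptive and conventional design: one row per summary, with the
#' adaptive and conventional operating characteristics side by side.
#' The table round-trips losslessly through CSV.
#'
#' @param summaries a single `hect_design_summary` or a list of them.
#' @param labels optional design labels (default `design1`, `design2`, ...).
#' @return a `data.frame`.
#' @export
summarize_to_table <- function(summaries, labels = NULL) {
  if (inherits(summaries, "hect_design_summary")) summaries <- list(summaries)
  if (!length(summaries)) stop_field("summaries", "need at least one summary")
  if (is.null(labels)) labels <- paste0("design", seq_along(summaries))
  row_of <- function(s, lab) {
    b <- s$adaptive; cv <- s$conventional
    data.frame(
      design = lab, n_sims = s$n_sims, seed = s$seed,
      prob_winner_declared = b$prob_winner_declared,
      mean_n = b$sample_size$mean, median_n = b$sample_size$median,
      mean_cost = b$cost$mean, median_cost = b$cost$median,
      mean_duration = b$duration$mean, median_duration = b$duration$median,
      conv_prob_winner_declared = cv$prob_winner_declared,
      conv_mean_n = cv$sample_size$mean, conv_median_n = cv$sample_size$median,
      conv_mean_cost = cv$cost$mean, conv_median_cost = cv$cost$median,
      conv_mean_duration = cv$duration$mean,
      conv_median_duration = cv$duration$median,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, Map(row_of, summaries, labels))
  rownames(out) <- NULL
  out
}
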