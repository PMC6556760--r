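#' Draw outcomes for patients on one arm, with adherence dilution
#'
#' Patients on a treatment arm receive their assigned treatment with
#' probability `arm$adherence`; non-adherent patients respond like controls
#' (full crossover) but are analyzed as assigned. Control patients always
#' draw from the control distribution.
#'
#' @param arm,control [arm_spec()] objects for the assigned arm and control.
#' @param rules [design_rules()]; supplies the outcome type.
#' @param n number of patients to draw.
#' @param secondary draw the secondary outcome instead of the primary.
#' @return numeric vector of outcomes (0/1 for binary). Uses R's global RNG.
#' @export
draw_outcome <- function(arm, control, rules, n = 1L, secondary = FALSE) {
  if (n <= 0L) return(numeric(0))
  type <- if (secondary) rules$secondary_outcome else rules$outcome
  par_of <- function(a) if (secondary) a$secondary_param else a$true_param
  sd_of <- function(a) if (secondary) a$secondary_sd else a$true_sd
  own <- par_of(arm); ctl <- par_of(control)
  mixed <- arm$role != "control" && arm$adherence < 1
  if (type == "binary") {
    if (!mixed) return(stats::rbinom(n, 1L, own))
    adh <- stats::runif(n) < arm$adherence
    stats::rbinom(n, 1L, ifelse(adh, own, ctl))
  } else {
    if (!mixed) return(stats::rnorm(n, own, sd_of(arm)))
    adh <- stats::runif(n) < arm$adherence
    stats::rnorm(n, ifelse(adh, own, ctl), ifelse(adh, sd_of(arm), sd_of(control)))
  }
}

# Pooled across-arm outcome SD for the continuous plug-in model. Arms with
# fewer than 2 observations contribute nothing; with no usable arm, the
# planning SD is returned.
pooled_sd <- function(n_k, sx, sxx, planning_sd) {
  use <- which(n_k >= 2L)
  if (!length(use)) return(planning_sd)
  ss <- sum(sxx[use] - sx[use]^2 / n_k[use])
  df <- sum(n_k[use] - 1L)
  if (df <= 0 || ss <= 0) return(planning_sd)
  sqrt(ss / df)
}

# Build current posterior states for the given arm indices.
build_posteriors <- function(idx, n_k, succ, sx, sxx, rules, arm_names) {
  if (rules$outcome == "binary") {
    out <- lapply(idx, function(k)
      binary_posterior(rules$prior$alpha + succ[k],
                       rules$prior$beta + (n_k[k] - succ[k])))
  } else {
    sp <- pooled_sd(n_k, sx, sxx, rules$planning_sd)
    out <- lapply(idx, function(k) {
      p <- continuous_posterior(rules$prior$mean, rules$prior$scale,
                                sigma0 = rules$planning_sd)
      p$n <- n_k[k]; p$sx <- sx[k]; p$sxx <- sxx[k]
      p$sigma_fixed <- sp
      p
    })
  }
  names(out) <- arm_names[idx]
  out
}

#' Evaluate the interim adaptation rules on a set of active-arm posteriors
#'
#' Applies, in fixed order, the superiority stop, the probability-of-best
#' futility drop, the margin (MCID) futility drop, and the platform
#' admission count, as described in [design_rules()]. The control arm is
#' never dropped; if every treatment arm is dropped (and no queued arm can
#' replace them) the trial stops for futility.
#'
#' In `"all-arms"` comparison mode the per-arm probability is the chance of
#' being best of all active arms (any arm, including control, can trigger
#' the superiority stop). In `"vs-control"` mode each treatment's
#' probability is the pairwise chance of beating control, and the control
#' entry is `NA`.
#'
#' @param posteriors named list of posterior states, one per active arm.
#' @param rules a [design_rules()] object.
#' @param control index of the control arm within `posteriors`.
#' @param queue_available number of queued platform arms currently eligible
#'   for admission.
#' @return a list with elements `probs` (per-arm decision probabilities),
#'   `stop` (`"none"`, `"superiority"` or `"futility-all"`), `winner`
#'   (index or `NA`), `drop` (indices), `drop_reason` (parallel character
#'   vector, `"futility"` or `"mcid"`), and `admit` (count of arms to
#'   admit). Uses R's global RNG.
#' @export
interim_decision <- function(posteriors, rules, control = 1L,
                             queue_available = 0L) {
  K <- length(posteriors)
  if (K < 2L) stop_field("posteriors", "need at least 2 active arms")
  tr <- setdiff(seq_len(K), control)
  if (rules$comparison_mode == "all-arms") {
    probs <- prob_superior_each(posteriors, rules$direction, rules$decision_draws)
    cand <- seq_len(K)
  } else {
    probs <- rep(NA_real_, K)
    names(probs) <- names(posteriors)
    for (t in tr)
      probs[t] <- prob_superior_each(list(posteriors[[t]], posteriors[[control]]),
                                     rules$direction, rules$decision_draws)[1L]
    cand <- tr
  }
  out <- list(probs = probs, stop = "none", winner = NA_integer_,
              drop = integer(0), drop_reason = character(0), admit = 0L)
  best <- cand[which.max(probs[cand])]
  if (probs[best] > rules$superiority_threshold) {
    out$stop <- "superiority"
    out$winner <- best
    return(out)
  }
  fut <- tr[probs[tr] < rules$futility_threshold]
  drop <- fut
  reason <- rep("futility", length(fut))
  if (!is.null(rules$mcid_margin)) {
    scale <- if (rules$outcome == "binary") "relative-risk-reduction" else "mean-difference"
    for (t in setdiff(tr, fut)) {
      pm <- prob_effect_below_margin(posteriors[[t]], posteriors[[control]],
                                     rules$mcid_margin, scale,
                                     rules$direction, rules$decision_draws)
      if (pm >= rules$mcid_certainty) {
        drop <- c(drop, t)
        reason <- c(reason, "mcid")
      }
    }
  }
  out$drop <- drop
  out$drop_reason <- reason
  if (length(drop) && rules$platform_enabled)
    out$admit <- min(length(drop), queue_available)
  if (length(tr) - length(drop) + out$admit == 0L) {
    out$stop <- "futility-all"
  }
  out
}

new_log <- function() {
  list(look = integer(0), n = integer(0), arm = character(0),
       prob_superior = numeric(0), action = character(0))
}

log_add <- function(log, look, n, arm, prob, action) {
  m <- length(arm)
  log$look <- c(log$look, rep_len(look, m))
  log$n <- c(log$n, rep_len(n, m))
  log$arm <- c(log$arm, arm)
  log$prob_superior <- c(log$prob_superior, rep_len(as.numeric(prob), m))
  log$action <- c(log$action, rep_len(action, m))
  log
}

#' Simulate one adaptive (optionally platform) trial end to end
#'
#' Accrues patients one at a time, assigns them with the allocation module
#' (equal before burn-in or when RAR is off; square-root response-adaptive
#' weights recomputed for every accumulated patient after burn-in), draws
#' outcomes with adherence dilution, updates conjugate posteriors, and
#' evaluates the adaptation rules at each scheduled interim look. The trial
#' ends at a superiority stop, when every treatment arm has been dropped for
#' futility, or at `max_n`; a perpetual platform trial instead rolls the
#' winner into a new two-arm comparison against the next queued arm until
#' the queue or the hard cap is exhausted.
#'
#' Given the same scenario and seed the result is bit-identical across runs.
#' Secondary (monitoring-only) outcomes are drawn from a separate RNG stream
#' derived from the seed, so configuring a secondary outcome never alters
#' the decision path.
#'
#' @param arms list of [arm_spec()] objects (exactly one control).
#' @param rules a [design_rules()] object.
#' @param seed integer seed; `NULL` continues R's current RNG stream (the
#'   determinism and secondary-isolation guarantees require a seed).
#' @return an object of class `hect_trial`: stop reason, winner, per-arm
#'   enrollment and outcome summaries, the decision log (one row per active
#'   arm per look), total sample size, cost (`total_n * cost_per_patient`),
#'   duration (`total_n / accrual_rate`) and final posterior estimates.
#' @export
simulate_trial <- function(arms, rules, seed = NULL) {
  validate_scenario(arms, rules)
  if (!is.null(seed)) set.seed(as.integer(seed))
  K <- length(arms)
  arm_names <- vapply(arms, `[[`, "", "name")
  roles <- vapply(arms, `[[`, "", "role")
  ctl <- which(roles == "control")
  active <- vapply(arms, function(a) a$available_from == 0L, TRUE)
  dropped <- logical(K)
  queue <- setdiff(order(vapply(arms, `[[`, 0L, "available_from"),
                         seq_len(K)), which(active))
  max_active <- rules$max_active_arms %||% sum(active)
  n_k <- integer(K); succ <- numeric(K); sx <- numeric(K); sxx <- numeric(K)
  entered_n <- ifelse(active, 0L, NA_integer_)
  dropped_n <- rep(NA_integer_, K)

  step <- rules$max_n / rules$n_looks
  looks <- unique(as.integer(ceiling(seq_len(rules$n_looks) * step)))
  cap <- if (rules$perpetual && rules$platform_enabled) rules$perpetual_cap else rules$max_n
  if (cap > rules$max_n) {
    extra <- rules$max_n + step * seq_len(ceiling((cap - rules$max_n) / step))
    looks <- sort(unique(c(looks, pmin(as.integer(ceiling(extra)), cap))))
  }

  n <- 0L
  comp <- ctl # comparator for decisions; becomes the stage winner in perpetual mode
  newest_entry <- -Inf # accrual count at the most recent platform admission
  log <- new_log()
  stop_reason <- NA_character_
  winner <- NA_integer_

  for (look_i in seq_along(looks)) {
    target <- looks[look_i]
    while (n < target) {
      act <- which(active & !dropped)
      Ka <- length(act)
      personal_end <- if (is.finite(newest_entry)) newest_entry + rules$new_arm_burn_in else 0L
      use_equal <- !rules$rar_enabled || n < rules$burn_in || n < personal_end
      if (use_equal || Ka < 2L) {
        bnd <- target
        if (rules$rar_enabled) {
          if (n < rules$burn_in) bnd <- min(bnd, rules$burn_in)
          if (n < personal_end) bnd <- min(bnd, as.integer(personal_end))
          bnd <- max(bnd, n + 1L)
        }
        m <- bnd - n
        w <- rep(1 / Ka, Ka)
      } else {
        m <- 1L
        sv <- prob_superior_each(
          build_posteriors(act, n_k, succ, sx, sxx, rules, arm_names),
          rules$direction, rules$rar_draws)
        w <- rar_weights(sv, floor = rules$rar_floor,
                         protect_control = rules$protect_control,
                         control = match(ctl, act))
      }
      assigned <- act[sample.int(Ka, m, replace = TRUE, prob = w)]
      for (k in act) {
        mk <- sum(assigned == k)
        if (mk == 0L) next
        y <- draw_outcome(arms[[k]], arms[[ctl]], rules, mk)
        n_k[k] <- n_k[k] + mk
        if (rules$outcome == "binary") succ[k] <- succ[k] + sum(y)
        sx[k] <- sx[k] + sum(y)
        sxx[k] <- sxx[k] + sum(y^2)
      }
      n <- n + m
    }

    act <- which(active & !dropped)
    post <- build_posteriors(act, n_k, succ, sx, sxx, rules, arm_names)
    eligible_queue <- queue[vapply(arms[queue], `[[`, 0L, "available_from") <= n]
    dec <- interim_decision(post, rules, control = match(comp, act),
                            queue_available = length(eligible_queue))
    action <- rep("", length(act))

    if (dec$stop == "superiority") {
      w_arm <- act[dec$winner]
      can_continue <- rules$perpetual && rules$platform_enabled &&
        length(eligible_queue) > 0L && n < cap
      if (can_continue) {
        # Roll into the next two-arm stage: the winner becomes the comparator
        # and every other arm is retired with its enrollment frozen.
        action[dec$winner] <- "stage-winner"
        losers <- setdiff(act, w_arm)
        for (k in losers) {
          dropped[k] <- TRUE
          dropped_n[k] <- n
          action[match(k, act)] <- "dropped-stage-end"
        }
        comp <- w_arm
        adm <- eligible_queue[1L]
        active[adm] <- TRUE
        entered_n[adm] <- n
        queue <- setdiff(queue, adm)
        newest_entry <- n
        log <- log_add(log, look_i, n, arm_names[act], dec$probs, action)
        log <- log_add(log, look_i, n, arm_names[adm], NA_real_, "admitted")
        next
      }
      action[dec$winner] <- "winner"
      log <- log_add(log, look_i, n, arm_names[act], dec$probs, action)
      stop_reason <- "superiority"
      winner <- w_arm
      break
    }

    if (length(dec$drop)) {
      for (j in seq_along(dec$drop)) {
        k <- act[dec$drop[j]]
        dropped[k] <- TRUE
        dropped_n[k] <- n
        action[dec$drop[j]] <- paste0("dropped-", dec$drop_reason[j])
      }
    }
    log <- log_add(log, look_i, n, arm_names[act], dec$probs, action)
    if (dec$admit > 0L) {
      room <- max_active - sum(active & !dropped)
      adm <- utils::head(eligible_queue, min(dec$admit, room))
      for (k in adm) {
        active[k] <- TRUE
        entered_n[k] <- n
        queue <- setdiff(queue, k)
        newest_entry <- n
        log <- log_add(log, look_i, n, arm_names[k], NA_real_, "admitted")
      }
    }
    if (dec$stop == "futility-all" || sum(active & !dropped) < 2L) {
      stop_reason <- "futility-all"
      break
    }
  }

  if (is.na(stop_reason))
    stop_reason <- if (cap > rules$max_n) "perpetual-censored" else "max-n"

  total_cost <- n * rules$cost_per_patient
  duration <- n / rules$accrual_rate
  decision_log <- data.frame(look = log$look, n = log$n, arm = log$arm,
                             prob_superior = log$prob_superior,
                             action = log$action, stringsAsFactors = FALSE)

  ever <- which(active)
  est <- final_estimates_df(ever, n_k, succ, sx, sxx, rules, arm_names, "primary")
  if (!is.null(rules$secondary_outcome)) {
    sec_seed <- if (is.null(seed)) NULL else child_seed(seed, 999983L)
    if (!is.null(sec_seed)) set.seed(sec_seed)
    sec_draws <- lapply(ever, function(k)
      draw_outcome(arms[[k]], arms[[ctl]], rules, n_k[k], secondary = TRUE))
    names(sec_draws) <- arm_names[ever]
    sec <- track_secondary(sec_draws, rules$secondary_outcome,
                           planning_sd = rules$planning_sd)
    est <- rbind(est, sec)
  }

  structure(list(
    stop_reason = stop_reason,
    winner = if (is.na(winner)) NA_character_ else arm_names[winner],
    arms = arm_names, roles = roles,
    enrolled = stats::setNames(n_k, arm_names),
    events = if (rules$outcome == "binary") stats::setNames(succ, arm_names) else NULL,
    outcome_mean = stats::setNames(ifelse(n_k > 0, sx / pmax(n_k, 1), NA_real_), arm_names),
    entered_at = stats::setNames(entered_n, arm_names),
    dropped_at = stats::setNames(dropped_n, arm_names),
    decision_log = decision_log,
    total_n = n, total_cost = total_cost, duration = duration,
    final_estimates = est,
    max_n = rules$max_n, seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "hect_trial")
}

final_estimates_df <- function(idx, n_k, succ, sx, sxx, rules, arm_names, which_outcome) {
  post <- build_posteriors(idx, n_k, succ, sx, sxx, rules, arm_names)
  data.frame(
    arm = arm_names[idx],
    outcome = which_outcome,
    n = n_k[idx],
    post_mean = vapply(post, post_mean, 0),
    post_sd = vapply(post, post_scale, 0),
    cri_lo = vapply(post, function(p) posterior_quantile(p, 0.025), 0),
    cri_hi = vapply(post, function(p) posterior_quantile(p, 0.975), 0),
    stringsAsFactors = FALSE, row.names = NULL)
}

posterior_quantile <- function(p, q) {
  if (inherits(p, "binary_posterior")) stats::qbeta(q, p$alpha, p$beta)
  else stats::qnorm(q, post_mean(p), post_scale(p))
}

#' Summarize a monitoring-only secondary outcome
#'
#' The secondary outcome accumulates alongside the primary and is summarized
#' with the same diffuse-prior conjugate models, but never feeds any
#' adaptation decision.
#'
#' @param draws_by_arm named list of per-arm outcome vectors (0/1 for
#'   binary).
#' @param outcome `"binary"` or `"continuous"`.
#' @param planning_sd plug-in SD fallback for continuous arms with fewer
#'   than 2 observations.
#' @return a data.frame of per-arm posterior summaries (same columns as the
#'   primary rows of a trial's `final_estimates`).
#' @export
track_secondary <- function(draws_by_arm, outcome = c("binary", "continuous"),
                            planning_sd = 1) {
  outcome <- match.arg(outcome)
  rows <- lapply(names(draws_by_arm), function(nm) {
    y <- draws_by_arm[[nm]]
    if (outcome == "binary") {
      p <- update_binary(binary_posterior(1, 1), sum(y), length(y) - sum(y))
    } else {
      p <- update_continuous(continuous_posterior(0, 1000, sigma0 = planning_sd), y)
    }
    data.frame(arm = nm, outcome = "secondary", n = length(y),
               post_mean = post_mean(p), post_sd = post_scale(p),
               cri_lo = posterior_quantile(p, 0.025),
               cri_hi = posterior_quantile(p, 0.975),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Simulate the conventional fixed-sample comparator trial
#'
#' Equal 1:1 (or 1:...:1) allocation throughout, no interim analyses, and a
#' single final analysis at `max_n`: the arm with the largest superiority
#' probability is declared the winner if and only if that probability
#' exceeds `superiority_threshold`. `total_n` is always `max_n`. Queued
#' platform arms are ignored: the comparator is the fixed design over the
#' initially active arms.
#'
#' @inheritParams simulate_trial
#' @return an object of class `hect_trial` with `stop_reason = "max-n"`.
#' @export
simulate_conventional <- function(arms, rules, seed = NULL) {
  validate_scenario(arms, rules)
  if (!is.null(seed)) set.seed(as.integer(seed))
  K <- length(arms)
  arm_names <- vapply(arms, `[[`, "", "name")
  roles <- vapply(arms, `[[`, "", "role")
  ctl <- which(roles == "control")
  act <- which(vapply(arms, function(a) a$available_from == 0L, TRUE))
  Ka <- length(act)
  n_k <- integer(K); succ <- numeric(K); sx <- numeric(K); sxx <- numeric(K)

  assigned <- act[sample.int(Ka, rules$max_n, replace = TRUE, prob = rep(1 / Ka, Ka))]
  for (k in act) {
    mk <- sum(assigned == k)
    if (mk == 0L) next
    y <- draw_outcome(arms[[k]], arms[[ctl]], rules, mk)
    n_k[k] <- mk
    if (rules$outcome == "binary") succ[k] <- sum(y)
    sx[k] <- sum(y)
    sxx[k] <- sum(y^2)
  }

  post <- build_posteriors(act, n_k, succ, sx, sxx, rules, arm_names)
  if (rules$comparison_mode == "all-arms") {
    probs <- prob_superior_each(post, rules$direction, rules$decision_draws)
    cand <- seq_len(Ka)
  } else {
    probs <- rep(NA_real_, Ka)
    tr <- setdiff(seq_len(Ka), match(ctl, act))
    for (t in tr)
      probs[t] <- prob_superior_each(list(post[[t]], post[[match(ctl, act)]]),
                                     rules$direction, rules$decision_draws)[1L]
    cand <- tr
  }
  best <- cand[which.max(probs[cand])]
  winner <- if (probs[best] > rules$superiority_threshold) act[best] else NA_integer_
  action <- rep("", Ka)
  if (!is.na(winner)) action[best] <- "winner"
  decision_log <- data.frame(look = 1L, n = rules$max_n, arm = arm_names[act],
                             prob_superior = as.numeric(probs), action = action,
                             stringsAsFactors = FALSE)

  est <- final_estimates_df(act, n_k, succ, sx, sxx, rules, arm_names, "primary")
  structure(list(
    stop_reason = "max-n",
    winner = if (is.na(winner)) NA_character_ else arm_names[winner],
    arms = arm_names[act], roles = roles[act],
    enrolled = stats::setNames(n_k[act], arm_names[act]),
    events = if (rules$outcome == "binary") stats::setNames(succ[act], arm_names[act]) else NULL,
    outcome_mean = stats::setNames(ifelse(n_k[act] > 0, sx[act] / pmax(n_k[act], 1), NA_real_),
                                   arm_names[act]),
    entered_at = stats::setNames(rep(0L, Ka), arm_names[act]),
    dropped_at = stats::setNames(rep(NA_integer_, Ka), arm_names[act]),
    decision_log = decision_log,
    total_n = rules$max_n,
    total_cost = rules$max_n * rules$cost_per_patient,
    duration = rules$max_n / rules$accrual_rate,
    final_estimates = est,
    max_n = rules$max_n, seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "hect_trial")
}

#' @export
print.hect_trial <- function(x, ...) {
  cat("Simulated trial\n")
  cat(sprintf("  stop reason : %s\n", x$stop_reason))
  cat(sprintf("  winner      : %s\n", if (is.na(x$winner)) "none" else x$winner))
  cat(sprintf("  total n     : %d (max %d)\n", x$total_n, x$max_n))
  cat(sprintf("  cost        : %g   duration: %g\n", x$total_cost, x$duration))
  cat("  enrollment  :", paste(sprintf("%s=%d", names(x$enrolled), x$enrolled),
                               collapse = ", "), "\n")
  invisible(x)
}
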