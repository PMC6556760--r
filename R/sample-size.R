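ss_object <- function(n1, n2, total, method, inputs) {
  structure(list(n_per_group = n1, n1 = n1, n2 = n2, total = total,
                 method = method, inputs = inputs),
            class = "hect_sample_size")
}

#' @export
print.hect_sample_size <- function(x, ...) {
  cat(sprintf("Sample size (%s)\n", x$method))
  if (x$n1 == x$n2) cat(sprintf("  n per group: %d\n", x$n1))
  else cat(sprintf("  n reference: %d   n comparator: %d\n", x$n1, x$n2))
  cat(sprintf("  total      : %d\n", x$total))
  invisible(x)
}

#' Sample size for a two-arm trial with a continuous outcome
#'
#' Normal-approximation two-sample formula with two-sided alpha:
#' `n1 = (z_{1-alpha/2} + z_{power})^2 * sd^2 * (1 + 1/ratio) / delta^2`,
#' rounded up, with `n2 = ceiling(ratio * n1)`. The returned `n1` is the
#' smallest integer whose normal-approximation power reaches the target.
#'
#' @param delta planning mean difference (nonzero).
#' @param sd planning outcome standard deviation.
#' @param alpha two-sided type I error rate in (0, 0.5\].
#' @param power target power in (alpha, 1).
#' @param ratio allocation ratio `n2/n1` (default 1).
#' @return an object of class `hect_sample_size`.
#' @export
sample_size_continuous <- function(delta, sd, alpha = 0.05, power = 0.80,
                                   ratio = 1) {
  check_scalar_num(delta, "delta")
  if (delta == 0) stop_field("delta", "must be nonzero")
  check_scalar_num(sd, "sd", lo = 0, open_lo = TRUE)
  check_scalar_num(alpha, "alpha", lo = 0, hi = 0.5, open_lo = TRUE)
  check_scalar_num(power, "power", lo = alpha, hi = 1, open_lo = TRUE, open_hi = TRUE)
  check_scalar_num(ratio, "ratio", lo = 0, open_lo = TRUE)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n1 <- ceiling((za + zb)^2 * sd^2 * (1 + 1 / ratio) / delta^2)
  n2 <- ceiling(ratio * n1)
  ss_object(as.integer(n1), as.integer(n2), as.integer(n1 + n2),
            "two-sample continuous, normal approximation, two-sided alpha",
            list(delta = delta, sd = sd, alpha = alpha, power = power, ratio = ratio))
}

#' Sample size for a two-arm trial with a binary outcome
#'
#' Normal-approximation formula with unpooled variance and two-sided alpha:
#' `n1 = (z_{1-alpha/2} + z_{power})^2 * (p1 q1 + p2 q2 / ratio) / (p1 - p2)^2`,
#' rounded up. A Fleiss-type continuity correction can be enabled; it is off
#' by default, matching the dominant planning-calculator convention.
#'
#' @param p1,p2 planning response proportions in (0, 1), `p1 != p2`.
#' @inheritParams sample_size_continuous
#' @param correction apply the continuity correction.
#' @return an object of class `hect_sample_size`.
#' @export
sample_size_binary <- function(p1, p2, alpha = 0.05, power = 0.80, ratio = 1,
                               correction = FALSE) {
  check_scalar_num(p1, "p1", lo = 0, hi = 1, open_lo = TRUE, open_hi = TRUE)
  check_scalar_num(p2, "p2", lo = 0, hi = 1, open_lo = TRUE, open_hi = TRUE)
  if (p1 == p2) stop_field("p1/p2", "planning proportions must differ")
  check_scalar_num(alpha, "alpha", lo = 0, hi = 0.5, open_lo = TRUE)
  check_scalar_num(power, "power", lo = alpha, hi = 1, open_lo = TRUE, open_hi = TRUE)
  check_scalar_num(ratio, "ratio", lo = 0, open_lo = TRUE)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  d <- p1 - p2
  v <- p1 * (1 - p1) + p2 * (1 - p2) / ratio
  n1 <- (za + zb)^2 * v / d^2
  if (correction) n1 <- n1 / 4 * (1 + sqrt(1 + 4 / (n1 * abs(d))))^2
  n1 <- ceiling(n1)
  n2 <- ceiling(ratio * n1)
  ss_object(as.integer(n1), as.integer(n2), as.integer(n1 + n2),
            paste0("two-sample binary, unpooled normal approximation, two-sided alpha",
                   if (correction) ", continuity-corrected" else ""),
            list(p1 = p1, p2 = p2, alpha = alpha, power = power, ratio = ratio,
                 correction = correction))
}

#' Sample size for a multi-arm trial
#'
#' The multi-arm sample size is driven by the hardest relevant pairwise
#' comparison: the difference between the largest and the second-largest
#' planning effect. The per-group size is the two-sample size for that pair
#' at the working alpha — the nominal alpha, or `alpha / (n_arms - 1)` under
#' the Bonferroni adjustment over the treatment-versus-reference
#' comparisons — and the total is `n per group * n_arms`. With two arms the
#' result reduces exactly to the two-sample calculators.
#'
#' @param effects per-arm planning effects: proportions (binary) or means
#'   (continuous), length >= 2. A tie between the largest and second-largest
#'   effect leaves no detectable difference and is an error.
#' @param outcome `"binary"` or `"continuous"`.
#' @param sd planning SD (continuous outcomes).
#' @param alpha nominal two-sided alpha.
#' @param power target power.
#' @param multiplicity `"none"` or `"bonferroni"`.
#' @return an object of class `hect_sample_size` with extra fields
#'   `n_arms`, `working_alpha` and `multiplicity`; `total` is
#'   `n_per_group * n_arms`.
#' @export
sample_size_multiarm <- function(effects, outcome = c("binary", "continuous"),
                                 sd = NULL, alpha = 0.05, power = 0.80,
                                 multiplicity = c("none", "bonferroni")) {
  outcome <- match.arg(outcome)
  multiplicity <- match.arg(multiplicity)
  if (!is.numeric(effects) || length(effects) < 2L)
    stop_field("effects", "need planning effects for at least 2 arms")
  n_arms <- length(effects)
  srt <- sort(effects, decreasing = TRUE)
  if (srt[1] == srt[2])
    stop_field("effects",
               "largest and second-largest effects are tied: no detectable difference")
  working_alpha <- if (multiplicity == "bonferroni") alpha / (n_arms - 1) else alpha
  pair <- if (outcome == "binary") {
    sample_size_binary(srt[1], srt[2], alpha = working_alpha, power = power)
  } else {
    if (is.null(sd)) stop_field("sd", "continuous outcome requires a planning SD")
    sample_size_continuous(srt[1] - srt[2], sd, alpha = working_alpha, power = power)
  }
  out <- ss_object(pair$n1, pair$n1, as.integer(pair$n1 * n_arms),
                   sprintf("multi-arm (%d arms), pairwise largest vs second-largest, multiplicity: %s",
                           n_arms, multiplicity),
                   list(effects = effects, outcome = outcome, sd = sd,
                        alpha = alpha, power = power))
  out$n_arms <- n_arms
  out$working_alpha <- working_alpha
  out$multiplicity <- multiplicity
  out
}
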