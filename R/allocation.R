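#' Equal allocation weights
#'
#' The conventional 1:1 (or 1:1:...:1) randomization used by the fixed-sample
#' comparator, during the burn-in phase, and whenever response-adaptive
#' randomization is disabled.
#'
#' @param n_arms number of active arms (at least 2).
#' @return numeric vector of weights, all `1/n_arms`, summing to 1.
#' @export
equal_weights <- function(n_arms) {
  if (!is.numeric(n_arms) || length(n_arms) != 1L || n_arms < 2 ||
      n_arms != round(n_arms))
    stop_field("n_arms", "must be an integer >= 2")
  rep(1 / n_arms, n_arms)
}

#' Response-adaptive allocation weights from superiority probabilities
#'
#' Allocation ratios proportional to the square roots of the per-arm
#' posterior probabilities of being superior:
#' `w_k = sqrt(p_k) / sum_j sqrt(p_j)`. The square root damps the feedback
#' between allocation and evidence relative to allocating proportionally to
#' the probabilities themselves.
#'
#' A floor is applied to each probability before the square-root transform so
#' that no arm's allocation is ever driven exactly to zero (an absorbing
#' state from which an arm could never recover). The floor is expressed as a
#' fraction of the vector's sum, which keeps the transform scale-free; for a
#' normalized superiority vector this equals an absolute floor of `floor`.
#'
#' @param superiority numeric vector of per-arm superiority probabilities
#'   (non-negative, not all zero), as returned by [prob_superior_each()].
#' @param floor minimum probability, as a fraction of `sum(superiority)`,
#'   imputed to any arm before the square-root transform. Default 0.01.
#' @param protect_control if `TRUE`, the control arm's weight is pinned at
#'   `1/K` and only the treatment arms are re-weighted.
#' @param control index of the control arm within `superiority` (used only
#'   when `protect_control` is `TRUE`).
#' @return numeric vector of allocation weights summing to 1.
#' @export
rar_weights <- function(superiority, floor = 0.01,
                        protect_control = FALSE, control = 1L) {
  if (!is.numeric(superiority) || length(superiority) < 2L ||
      any(!is.finite(superiority)) || any(superiority < 0))
    stop_field("superiority", "must be >= 2 finite non-negative probabilities")
  s <- sum(superiority)
  if (s <= 0) stop_field("superiority", "must not be all zero")
  check_scalar_num(floor, "floor", lo = 0, hi = 1)
  p <- pmax(superiority, floor * s)
  w <- sqrt(p)
  w <- w / sum(w)
  if (protect_control) {
    K <- length(w)
    others <- setdiff(seq_len(K), control)
    w[control] <- 1 / K
    w[others] <- w[others] / sum(w[others]) * (1 - 1 / K)
  }
  w
}

#' Randomize one patient to an arm
#'
#' @param weights allocation weights summing to 1.
#' @return the sampled arm index (1-based). Uses R's global RNG stream.
#' @export
assign_patient <- function(weights) {
  if (!is.numeric(weights) || length(weights) < 1L || any(weights < 0) ||
      sum(weights) <= 0)
    stop_field("weights", "must be non-negative with positive sum")
  sample.int(length(weights), 1L, prob = weights)
}
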