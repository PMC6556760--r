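# Independent numerical oracles used to validate the package's code paths.
# These deliberately use different numerics than the implementation
# (composite Simpson on a fixed grid instead of adaptive quadrature; direct
# normal-approximation power search instead of the inverted formula).

# P(X > Y), X ~ Beta(a1, b1), Y ~ Beta(a2, b2), by composite Simpson.
beta_pair_oracle <- function(a1, b1, a2, b2, n_grid = 4001L) {
  x <- seq(0, 1, length.out = n_grid)
  fx <- dbeta(x, a1, b1) * pbeta(x, a2, b2)
  fx[!is.finite(fx)] <- 0 # integrable edge singularities at shape < 1
  h <- x[2] - x[1]
  w <- rep(c(4, 2), length.out = n_grid - 2L)
  v <- unname(h / 3 * (fx[1] + sum(w * fx[-c(1, n_grid)]) + fx[n_grid]))
  min(max(v, 0), 1)
}

# Normal-approximation power of the two-sample binary test at per-group n
# (unpooled variance, two-sided alpha), matching the planning convention.
power_binary_oracle <- function(n1, p1, p2, alpha = 0.05, ratio = 1) {
  za <- qnorm(1 - alpha / 2)
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / (ratio * n1))
  pnorm(abs(p1 - p2) / se - za)
}

power_continuous_oracle <- function(n1, delta, sd, alpha = 0.05, ratio = 1) {
  za <- qnorm(1 - alpha / 2)
  se <- sd * sqrt(1 / n1 + 1 / (ratio * n1))
  pnorm(abs(delta) / se - za)
}

# Smallest integer per-group n reaching the target power (brute force).
min_n_oracle <- function(power_fn, target, ..., n_max = 100000L) {
  for (n in 1:n_max) if (power_fn(n, ...) >= target) return(n)
  stop("oracle search exhausted")
}

# A small scenario that runs in milliseconds, for engine property loops.
cheap_binary_scenario <- function(p_control = 0.4, p_treat = 0.4,
                                  max_n = 200L, n_looks = 2L, ...) {
  list(arms = list(arm_spec("control", "control", p_control),
                   arm_spec("treat", "treatment", p_treat)),
       rules = design_rules("binary", max_n = max_n, n_looks = n_looks,
                            decision_draws = 2000L, ...))
}
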