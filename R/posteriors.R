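#' Conjugate posterior state for a binary (response/no-response) outcome
#'
#' The beta-binomial model: a Beta(alpha, beta) prior on the arm's response
#' probability with a binomial likelihood. `alpha` and `beta` act as
#' pseudo-counts of responses and non-responses. The package default prior is
#' the flat Beta(1, 1), the diffuse non-informative choice used throughout the
#' trial engine unless overridden.
#'
#' @param alpha positive pseudo-count of responses.
#' @param beta positive pseudo-count of non-responses.
#' @return an object of class `binary_posterior`.
#' @seealso [update_binary()], [prob_superior_each()]
#' @export
binary_posterior <- function(alpha = 1, beta = 1) {
  check_scalar_num(alpha, "alpha", lo = 0, open_lo = TRUE)
  check_scalar_num(beta, "beta", lo = 0, open_lo = TRUE)
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = c("binary_posterior", "hect_posterior"))
}

#' Conjugate Gaussian posterior state for a continuous outcome
#'
#' A conjugate normal model for the arm mean with a plug-in outcome standard
#' deviation: the prior on the mean is N(mean, scale^2) and the outcome SD is
#' treated as known, estimated from the data once at least two observations
#' are available (before that, the user-supplied planning SD `sigma0` is
#' used). Keeping the outcome SD as a plug-in keeps the posterior of the mean
#' Gaussian and interim decisions fast; a full normal-inverse-gamma treatment
#' is deliberately out of scope.
#'
#' Sufficient statistics (n, sum, sum of squares) are stored so that batched
#' updates are associative: updating with the concatenation of two batches
#' equals two sequential updates up to floating-point error.
#'
#' @param mean prior mean of the arm mean (outcome units). Default 0.
#' @param scale prior standard deviation of the arm mean. The default 1000
#'   outcome units is the package's diffuse non-informative choice.
#' @param sigma0 planning outcome SD used until the data can estimate it.
#' @return an object of class `continuous_posterior`.
#' @seealso [update_continuous()], [post_mean()], [post_scale()]
#' @export
continuous_posterior <- function(mean = 0, scale = 1000, sigma0 = 1) {
  check_scalar_num(mean, "mean")
  check_scalar_num(scale, "scale", lo = 0, open_lo = TRUE)
  check_scalar_num(sigma0, "sigma0", lo = 0, open_lo = TRUE)
  structure(list(m0 = as.numeric(mean), s0 = as.numeric(scale),
                 n = 0L, sx = 0, sxx = 0,
                 sigma0 = as.numeric(sigma0), sigma_fixed = NULL),
            class = c("continuous_posterior", "hect_posterior"))
}

#' @export
print.binary_posterior <- function(x, ...) {
  cat(sprintf("Beta posterior: alpha = %g, beta = %g (mean %.4f)\n",
              x$alpha, x$beta, post_mean(x)))
  invisible(x)
}

#' @export
print.continuous_posterior <- function(x, ...) {
  cat(sprintf(
    "Gaussian posterior of the mean: n = %d, mean = %.4f, scale = %.4g (sigma_hat %.4g)\n",
    x$n, post_mean(x), post_scale(x), sigma_hat(x)))
  invisible(x)
}

#' Posterior mean of an arm's outcome parameter
#' @param p a posterior state.
#' @return the posterior mean (response probability for binary, arm mean for
#'   continuous).
#' @export
post_mean <- function(p) UseMethod("post_mean")

#' @export
post_mean.binary_posterior <- function(p) p$alpha / (p$alpha + p$beta)

#' @export
post_mean.continuous_posterior <- function(p) {
  s2 <- sigma_hat(p)^2
  prec0 <- 1 / p$s0^2
  prec <- prec0 + p$n / s2
  (p$m0 * prec0 + p$sx / s2) / prec
}

#' Posterior standard deviation of an arm's outcome parameter
#' @param p a posterior state.
#' @export
post_scale <- function(p) UseMethod("post_scale")

#' @export
post_scale.binary_posterior <- function(p) {
  ab <- p$alpha + p$beta
  sqrt(p$alpha * p$beta / (ab^2 * (ab + 1)))
}

#' @export
post_scale.continuous_posterior <- function(p) {
  1 / sqrt(1 / p$s0^2 + p$n / sigma_hat(p)^2)
}

#' Plug-in outcome standard deviation of a continuous posterior
#'
#' Returns, in order of precedence: an externally fixed value (set by the
#' trial engine to the SD pooled across arms), the sample SD once n >= 2, or
#' the planning SD `sigma0`.
#'
#' @param p a `continuous_posterior`.
#' @export
sigma_hat <- function(p) {
  stopifnot(inherits(p, "continuous_posterior"))
  if (!is.null(p$sigma_fixed)) return(p$sigma_fixed)
  if (p$n >= 2L) {
    v <- (p$sxx - p$sx^2 / p$n) / (p$n - 1)
    if (v > 0) return(sqrt(v))
  }
  p$sigma0
}

#' Update a beta-binomial posterior with a batch of binary outcomes
#'
#' Conjugacy is additive: the posterior is
#' Beta(alpha + responses, beta + failures), so batched updates commute and
#' associate exactly.
#'
#' @param prior a [binary_posterior()].
#' @param responses non-negative count of responses in the batch.
#' @param failures non-negative count of non-responses in the batch.
#' @return the updated `binary_posterior`.
#' @export
update_binary <- function(prior, responses, failures) {
  stopifnot(inherits(prior, "binary_posterior"))
  check_scalar_num(responses, "responses", lo = 0)
  check_scalar_num(failures, "failures", lo = 0)
  binary_posterior(prior$alpha + responses, prior$beta + failures)
}

#' Update a conjugate Gaussian posterior with a batch of observations
#'
#' Standard precision-weighted conjugate normal update of the arm mean; the
#' outcome SD is the plug-in described in [continuous_posterior()]. An empty
#' batch returns the prior unchanged.
#'
#' @param prior a [continuous_posterior()].
#' @param observations numeric vector of finite outcome values (may be empty).
#' @return the updated `continuous_posterior`.
#' @export
update_continuous <- function(prior, observations) {
  stopifnot(inherits(prior, "continuous_posterior"))
  if (length(observations) == 0L) return(prior)
  if (!is.numeric(observations) || !all(is.finite(observations)))
    stop_field("observations", "must be finite numeric values")
  prior$n <- prior$n + length(observations)
  prior$sx <- prior$sx + sum(observations)
  prior$sxx <- prior$sxx + sum(observations^2)
  prior
}

posterior_draws <- function(p, draws) {
  if (inherits(p, "binary_posterior")) {
    stats::rbeta(draws, p$alpha, p$beta)
  } else {
    stats::rnorm(draws, post_mean(p), post_scale(p))
  }
}

#' Monte-Carlo probability that each arm is the best of all active arms
#'
#' Draws each arm's outcome parameter from its posterior `draws` times and
#' returns, per arm, the fraction of joint draws in which that arm is
#' strictly best in the stated benefit direction. These probabilities drive
#' every adaptation decision: early stopping for superiority, futility
#' dropping, and response-adaptive allocation.
#'
#' Ties between continuous draws have probability zero; for degenerate
#' point-mass inputs the deterministic tie-break is the lowest arm index.
#' Entries sum to 1 exactly (each joint draw elects exactly one winner).
#'
#' Randomness is taken from R's global stream; callers seed it ([set.seed()])
#' for reproducibility.
#'
#' @param posteriors list of two or more posterior states (all the same
#'   outcome type).
#' @param direction `"higher-better"` or `"lower-better"`: whether larger
#'   parameter values are the clinical benefit.
#' @param draws number of Monte-Carlo joint draws (default 10000).
#' @return numeric vector of probabilities, one per arm, summing to 1.
#' @export
prob_superior_each <- function(posteriors,
                               direction = c("higher-better", "lower-better"),
                               draws = 10000L) {
  direction <- match.arg(direction)
  K <- length(posteriors)
  if (K < 2L) stop_field("posteriors", "need at least 2 arms")
  check_scalar_num(draws, "draws", lo = 1)
  draws <- as.integer(draws)
  X <- matrix(0, nrow = draws, ncol = K)
  for (k in seq_len(K)) X[, k] <- posterior_draws(posteriors[[k]], draws)
  if (direction == "lower-better") X <- -X
  best <- max.col(X, ties.method = "first")
  p <- tabulate(best, nbins = K) / draws
  names(p) <- names(posteriors)
  p
}

#' Closed-form / quadrature probability that one arm beats another
#'
#' The two-arm oracle used to validate the Monte-Carlo path. For Gaussian
#' posteriors the probability is `pnorm((m_a - m_b) / sqrt(s_a^2 + s_b^2))`;
#' for beta posteriors `P(p_a > p_b)` is computed by adaptive quadrature of
#' the integral of `dbeta_a(x) * pbeta_b(x)`.
#'
#' @inheritParams prob_superior_each
#' @param a,b posterior states of the same outcome type.
#' @return `P(a better than b)` in the stated direction.
#' @export
prob_superior_pair_closed_form <- function(a, b,
                                           direction = c("higher-better", "lower-better")) {
  direction <- match.arg(direction)
  if (inherits(a, "binary_posterior") && inherits(b, "binary_posterior")) {
    p_higher <- stats::integrate(
      function(x) stats::dbeta(x, a$alpha, a$beta) * stats::pbeta(x, b$alpha, b$beta),
      0, 1, rel.tol = 1e-10)$value
    p_higher <- min(max(p_higher, 0), 1)
  } else if (inherits(a, "continuous_posterior") && inherits(b, "continuous_posterior")) {
    p_higher <- stats::pnorm((post_mean(a) - post_mean(b)) /
                               sqrt(post_scale(a)^2 + post_scale(b)^2))
  } else {
    stop_field("a/b", "posteriors must have the same outcome type")
  }
  if (direction == "higher-better") p_higher else 1 - p_higher
}

#' Probability that the treatment effect is below a clinically important margin
#'
#' Monte-Carlo fraction of joint posterior draws in which the
#' treatment-versus-control effect falls strictly below `margin`. Used for
#' the margin-based futility rule: an arm is dropped when this probability
#' reaches the configured certainty (e.g. 95% certain the relative risk
#' reduction is smaller than 20%).
#'
#' Effect scales:
#' * `"relative-risk-reduction"` (binary outcomes only): `1 - p_t / p_c`,
#'   the harmful-event convention, where the event probability is the arm
#'   parameter and lower is better.
#' * `"mean-difference"` (continuous): the treatment-minus-control mean
#'   difference oriented so that positive means clinical benefit
#'   (`direction` supplies the orientation).
#'
#' @param treat,control posterior states for the treatment and control arm.
#' @param margin non-negative effect margin on the chosen scale.
#' @param effect_scale `"relative-risk-reduction"` or `"mean-difference"`.
#' @param direction benefit direction, used for the mean-difference scale.
#' @param draws Monte-Carlo draw count.
#' @return probability in \[0, 1\].
#' @export
prob_effect_below_margin <- function(treat, control, margin,
                                     effect_scale = c("relative-risk-reduction", "mean-difference"),
                                     direction = c("higher-better", "lower-better"),
                                     draws = 10000L) {
  effect_scale <- match.arg(effect_scale)
  direction <- match.arg(direction)
  check_scalar_num(margin, "margin", lo = 0)
  check_scalar_num(draws, "draws", lo = 1)
  draws <- as.integer(draws)
  if (effect_scale == "relative-risk-reduction") {
    if (!inherits(treat, "binary_posterior") || !inherits(control, "binary_posterior"))
      stop_field("effect_scale",
                 "relative-risk-reduction requires binary outcomes")
    pt <- posterior_draws(treat, draws)
    pc <- posterior_draws(control, draws)
    eff <- 1 - pt / pc
  } else {
    dt <- posterior_draws(treat, draws)
    dc <- posterior_draws(control, draws)
    eff <- if (direction == "higher-better") dt - dc else dc - dt
  }
  mean(eff < margin)
}
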