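test_that("binary conjugate update is additive and validates counts", {
  cases <- list(list(prior = c(1, 1), r = 5, f = 5, out = c(6, 6)),
                list(prior = c(1, 1), r = 0, f = 0, out = c(1, 1)),
                list(prior = c(2, 3), r = 7, f = 11, out = c(9, 14)))
  for (cs in cases) {
    p <- update_binary(binary_posterior(cs$prior[1], cs$prior[2]), cs$r, cs$f)
    expect_equal(c(p$alpha, p$beta), cs$out)
  }
  expect_equal(post_mean(update_binary(binary_posterior(1, 1), 30, 70)), 31 / 102)
  expect_error(update_binary(binary_posterior(), -1, 0), "responses")
  expect_error(update_binary(binary_posterior(), 0, -2), "failures")
  expect_error(binary_posterior(0, 1), "alpha")
})

test_that("binary updates associate over data batches exactly", {
  set.seed(41)
  for (i in 1:20) {
    r <- sample(0:30, 2); f <- sample(0:30, 2)
    once <- update_binary(binary_posterior(), sum(r), sum(f))
    twice <- update_binary(update_binary(binary_posterior(), r[1], f[1]), r[2], f[2])
    expect_identical(once, twice)
  }
})

test_that("continuous update: identity, diffuse-prior limit, associativity", {
  p <- continuous_posterior(0, 1000, sigma0 = 2)
  expect_identical(update_continuous(p, numeric(0)), p)
  expect_identical(sigma_hat(p), 2) # planning SD until data can estimate it
  expect_identical(sigma_hat(update_continuous(p, 5)), 2)

  y <- c(9, 10, 11, 10.5, 9.5)
  up <- update_continuous(p, y)
  # diffuse prior: posterior mean -> sample mean as prior precision -> 0
  expect_equal(post_mean(up), mean(y), tolerance = 1e-6)
  expect_equal(sigma_hat(up), sd(y))

  u2 <- update_continuous(update_continuous(p, y[1:2]), y[3:5])
  expect_equal(post_mean(u2), post_mean(up), tolerance = 1e-12)
  expect_equal(post_scale(u2), post_scale(up), tolerance = 1e-12)

  expect_error(update_continuous(p, c(1, NA)), "observations")
})

test_that("continuous posterior scale shrinks monotonically with n", {
  p <- continuous_posterior(0, 10, sigma0 = 3)
  p$sigma_fixed <- 3 # fix the plug-in so only n varies
  scales <- vapply(c(0, 1, 5, 20, 100), function(n) {
    q <- p; q$n <- n; post_scale(q)
  }, 0)
  expect_true(all(diff(scales) < 0))
  expect_equal(scales[1], 10) # n = 0 equals the prior
})

test_that("continuous posterior concentrates on the truth (seeded sim)", {
  set.seed(7)
  y <- rnorm(100, 5, 2)
  up <- update_continuous(continuous_posterior(0, 1000, sigma0 = 2), y)
  expect_lt(abs(post_mean(up) - 5), 3 * post_scale(up))
})

test_that("prob_superior_each: symmetry, extremes, exact sum", {
  set.seed(11)
  sv <- prob_superior_each(list(binary_posterior(6, 6), binary_posterior(6, 6)),
                           "higher-better", 40000)
  expect_equal(unname(sv), c(0.5, 0.5), tolerance = 0.03)

  sv3 <- prob_superior_each(rep(list(binary_posterior(8, 4)), 3),
                            "higher-better", 60000)
  expect_equal(unname(sv3), rep(1 / 3, 3), tolerance = 0.03)

  strong <- prob_superior_each(list(binary_posterior(91, 11), binary_posterior(11, 91)),
                               "higher-better", 20000)
  expect_gt(strong[1], 0.999)
  # flipping the benefit direction flips the ordering
  strong_rev <- prob_superior_each(list(binary_posterior(91, 11), binary_posterior(11, 91)),
                                   "lower-better", 20000)
  expect_gt(strong_rev[2], 0.999)

  expect_error(prob_superior_each(list(binary_posterior()), "higher-better"),
               "at least 2")

  # entries sum to 1 exactly: each joint draw elects exactly one winner
  for (i in 1:10) {
    K <- sample(2:5, 1)
    posts <- lapply(seq_len(K), function(k)
      binary_posterior(runif(1, 0.5, 40), runif(1, 0.5, 40)))
    expect_equal(sum(prob_superior_each(posts, "higher-better", 500)), 1,
                 tolerance = 1e-12)
  }
})

test_that("superiority probability is monotone in the posterior mean (Gaussian grid)", {
  fixed <- continuous_posterior(1, 1000)
  fixed$n <- 100L; fixed$sx <- 100; fixed$sigma_fixed <- 10
  probs <- vapply(seq(-2, 4, by = 0.5), function(m) {
    mov <- fixed; mov$sx <- m * 100
    set.seed(99) # common random numbers make monotonicity exact
    prob_superior_each(list(mov, fixed), "higher-better", 5000)[1]
  }, 0)
  expect_true(all(diff(probs) >= 0))
})

test_that("closed-form pairwise oracle: Gaussian and beta", {
  a <- continuous_posterior(1, 1); b <- continuous_posterior(0, 1)
  expect_equal(prob_superior_pair_closed_form(a, b), pnorm(1 / sqrt(2)))
  expect_equal(prob_superior_pair_closed_form(b, b), 0.5)
  expect_equal(prob_superior_pair_closed_form(a, b, "lower-better"),
               1 - pnorm(1 / sqrt(2)))

  # P(Beta(2,1) > Beta(1,1)) = int 2x * x dx = 2/3 (exact)
  b21 <- binary_posterior(2, 1); b11 <- binary_posterior(1, 1)
  expect_equal(prob_superior_pair_closed_form(b21, b11), 2 / 3, tolerance = 1e-8)
  expect_equal(prob_superior_pair_closed_form(b11, b21), 1 / 3, tolerance = 1e-8)
  # independent Simpson oracle agrees
  expect_equal(prob_superior_pair_closed_form(binary_posterior(12, 8), binary_posterior(9, 11)),
               beta_pair_oracle(12, 8, 9, 11), tolerance = 1e-6)

  expect_error(prob_superior_pair_closed_form(b21, a), "outcome type")
})

test_that("prob_effect_below_margin behaves across scales and margins", {
  set.seed(21)
  # identical large-n posteriors, margin 0.20: true effect 0 < 0.20, so the
  # probability approaches 1 as the posteriors tighten
  big <- binary_posterior(401, 601)
  expect_gt(prob_effect_below_margin(big, big, 0.20, draws = 50000), 0.95)
  ctl <- binary_posterior(41, 61)

  # margin 0: P(effect < 0) > 0.5 when treatment is stochastically worse
  worse <- continuous_posterior(-1, 1); ref <- continuous_posterior(0, 1)
  expect_gt(prob_effect_below_margin(worse, ref, 0, "mean-difference",
                                     "higher-better", 50000), 0.5)

  # strong true RRR (~0.49): being below a 0.20 margin is very unlikely
  set.seed(22)
  p <- prob_effect_below_margin(binary_posterior(41, 61), binary_posterior(81, 21),
                                0.20, "relative-risk-reduction", draws = 1e6)
  expect_lt(p, 0.05)

  expect_error(prob_effect_below_margin(ref, worse, 0.2, "relative-risk-reduction"),
               "binary")
  expect_error(prob_effect_below_margin(ctl, ctl, -0.1), "margin")
})
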