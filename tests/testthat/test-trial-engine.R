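test_that("draw_outcome applies intent-to-treat adherence dilution", {
  rules <- design_rules("binary", max_n = 100L)
  ctl <- arm_spec("control", "control", 0.4)
  n <- 1e5
  emp <- function(arm) {
    set.seed(61)
    mean(draw_outcome(arm, ctl, rules, n))
  }
  se <- function(p) sqrt(p * (1 - p) / n)

  full <- arm_spec("t", "treatment", 0.2, adherence = 1)
  expect_lt(abs(emp(full) - 0.2), 3 * se(0.2))
  none <- arm_spec("t", "treatment", 0.2, adherence = 0)
  expect_lt(abs(emp(none) - 0.4), 3 * se(0.4)) # full crossover to control
  half <- arm_spec("t", "treatment", 0.2, adherence = 0.5)
  expect_lt(abs(emp(half) - 0.3), 3 * se(0.3)) # mixture mean
  # control draws its own distribution regardless of adherence
  expect_lt(abs(emp(arm_spec("control", "control", 0.4, adherence = 0)) - 0.4),
            3 * se(0.4))

  crules <- design_rules("continuous", max_n = 100L)
  carm <- arm_spec("t", "treatment", 2, true_sd = 1, adherence = 0.5)
  cctl <- arm_spec("control", "control", 0, true_sd = 1)
  set.seed(62)
  expect_lt(abs(mean(draw_outcome(carm, cctl, crules, n)) - 1), 3 * sqrt(2) / sqrt(n))
})

test_that("interim_decision applies the rules in the documented order", {
  rules <- design_rules("binary", max_n = 1000L, direction = "higher-better",
                        superiority_threshold = 0.99, futility_threshold = 0.01,
                        mcid_margin = NULL)
  ctl <- binary_posterior(500, 500)

  # overwhelming leader -> superiority stop, winner recorded
  set.seed(71)
  dec <- interim_decision(list(a = binary_posterior(900, 100),
                               b = binary_posterior(100, 900)),
                          rules, control = 2L)
  expect_identical(dec$stop, "superiority")
  expect_identical(dec$winner, 1L)
  expect_length(dec$drop, 0)

  # nothing extreme -> no action
  dec <- interim_decision(list(ctl, binary_posterior(510, 490),
                               binary_posterior(480, 520)),
                          rules, control = 1L)
  expect_identical(dec$stop, "none")
  expect_length(dec$drop, 0)
  expect_identical(dec$admit, 0L)

  # hopeless treatment arm -> dropped; queued arm admitted under platform
  prules <- design_rules("binary", max_n = 1000L, direction = "higher-better",
                         platform_enabled = TRUE, mcid_margin = NULL,
                         superiority_threshold = 0.999, futility_threshold = 0.01)
  dec <- interim_decision(list(ctl, binary_posterior(200, 800),
                               binary_posterior(520, 480)),
                          prules, control = 1L, queue_available = 1L)
  expect_identical(dec$stop, "none")
  expect_identical(dec$drop, 2L)
  expect_identical(dec$drop_reason, "futility")
  expect_identical(dec$admit, 1L)

  # two-arm trial whose only treatment is dropped -> futility-all stop.
  # (With two arms the probabilities are complementary, so the superiority
  # threshold must sit above 1 - futility_threshold for the futility rule to
  # fire first; at matched 0.99/0.01 thresholds superiority takes precedence.)
  arules <- design_rules("binary", max_n = 1000L, direction = "higher-better",
                         superiority_threshold = 0.999,
                         futility_threshold = 0.01, mcid_margin = NULL)
  dec <- interim_decision(list(ctl, binary_posterior(440, 560)),
                          arules, control = 1L)
  expect_identical(dec$stop, "futility-all")
  expect_identical(dec$drop, 2L)

  # margin rule drops an arm the probability-of-best rule keeps
  mrules <- design_rules("binary", max_n = 1000L,
                         superiority_threshold = 0.999, futility_threshold = 0,
                         mcid_margin = 0.20, mcid_certainty = 0.95)
  set.seed(72)
  dec <- interim_decision(list(ctl = binary_posterior(400, 600),
                               t = binary_posterior(395, 605)),
                          mrules, control = 1L)
  expect_identical(dec$stop, "futility-all")
  expect_identical(dec$drop_reason, "mcid")

  # vs-control mode reports NA for the control entry
  vrules <- design_rules("binary", max_n = 1000L, comparison_mode = "vs-control",
                         mcid_margin = NULL)
  dec <- interim_decision(list(ctl, binary_posterior(480, 520)), vrules, control = 1L)
  expect_true(is.na(dec$probs[1]))
  expect_false(is.na(dec$probs[2]))

  expect_error(interim_decision(list(ctl), rules), "at least 2")
})

test_that("simulate_trial honors hard contracts: no-rule world, determinism, conservation", {
  sc <- cheap_binary_scenario(0.4, 0.4, max_n = 300L, n_looks = 3L,
                              superiority_threshold = 1.0,
                              futility_threshold = 0, mcid_margin = NULL)
  tr <- simulate_trial(sc$arms, sc$rules, seed = 5)
  expect_identical(tr$stop_reason, "max-n")
  expect_identical(tr$total_n, 300L)
  expect_true(is.na(tr$winner))
  expect_identical(sum(tr$enrolled), 300L)
  expect_identical(tr$total_cost, 300)
  expect_identical(tr$duration, 300)
  expect_gt(nrow(tr$decision_log), 0)

  tr2 <- simulate_trial(sc$arms, sc$rules, seed = 5)
  expect_identical(serialize(tr, NULL), serialize(tr2, NULL))
})

test_that("a strong true effect stops early and picks the right winner", {
  arms <- list(arm_spec("control", "control", 0.40),
               arm_spec("treat", "treatment", 0.10))
  rules <- design_rules("binary", max_n = 2000L, n_looks = 10L,
                        superiority_threshold = 0.99, mcid_margin = NULL)
  trials <- lapply(1:200, function(i)
    simulate_trial(arms, rules, seed = child_seed(300, i)))
  n_tot <- vapply(trials, `[[`, 0L, "total_n")
  stopped <- vapply(trials, `[[`, "", "stop_reason") == "superiority"
  expect_lt(median(n_tot), 2000)
  expect_gt(mean(vapply(trials[stopped], `[[`, "", "winner") == "treat"), 0.95)
})

test_that("raising the superiority threshold never shortens a shared trajectory", {
  arms <- list(arm_spec("control", "control", 0.40),
               arm_spec("treat", "treatment", 0.25))
  for (i in 1:15) {
    n_by_thr <- vapply(c(0.90, 0.99), function(thr) {
      rules <- design_rules("binary", max_n = 600L, n_looks = 6L,
                            superiority_threshold = thr, futility_threshold = 0,
                            mcid_margin = NULL, decision_draws = 4000L)
      simulate_trial(arms, rules, seed = child_seed(400, i))$total_n
    }, 0L)
    expect_gte(n_by_thr[2], n_by_thr[1])
  }
})

test_that("the conventional comparator always runs to max_n", {
  sc <- cheap_binary_scenario(0.4, 0.3, max_n = 250L)
  n_tot <- vapply(1:20, function(i)
    simulate_conventional(sc$arms, sc$rules, seed = child_seed(500, i))$total_n, 0L)
  expect_true(all(n_tot == 250L))
  a <- simulate_conventional(sc$arms, sc$rules, seed = 9)
  b <- simulate_conventional(sc$arms, sc$rules, seed = 9)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_identical(a$stop_reason, "max-n")
})

test_that("secondary outcomes are monitored without touching decisions", {
  arms_plain <- list(arm_spec("control", "control", 0.40),
                     arm_spec("treat", "treatment", 0.30))
  arms_sec <- list(arm_spec("control", "control", 0.40, secondary_param = 0.25),
                   arm_spec("treat", "treatment", 0.30, secondary_param = 0.35))
  mk_rules <- function(sec) design_rules("binary", max_n = 400L, n_looks = 4L,
                                         mcid_margin = NULL,
                                         decision_draws = 2000L,
                                         secondary_outcome = sec)
  t_plain <- simulate_trial(arms_plain, mk_rules(NULL), seed = 13)
  t_sec <- simulate_trial(arms_sec, mk_rules("binary"), seed = 13)
  expect_identical(t_plain$decision_log, t_sec$decision_log)
  expect_identical(t_plain$total_n, t_sec$total_n)

  expect_false("secondary" %in% t_plain$final_estimates$outcome)
  sec_rows <- subset(t_sec$final_estimates, outcome == "secondary")
  expect_identical(nrow(sec_rows), 2L)

  # posterior concentrates on the secondary truth
  set.seed(14)
  est <- track_secondary(list(a = rbinom(1000, 1, 0.3)), "binary")
  expect_lt(abs(est$post_mean - 0.3), 3 * est$post_sd)
})

test_that("platform admission replaces a dropped arm and respects the cap", {
  cfg <- make_fixture("platform-3arm")
  tr <- simulate_trial(cfg$arms, cfg$rules, seed = 104)
  log <- tr$decision_log
  dropped <- grepl("^dropped", log$action) & log$arm == "treat1"
  expect_true(any(dropped))
  adm <- log$action == "admitted" & log$arm == "treat2"
  expect_true(any(adm))
  expect_identical(log$n[adm], log$n[dropped][1]) # admitted at the same look
  # the admitted arm actually enrolls afterwards
  expect_gt(tr$enrolled[["treat2"]], 0)
  # never more than max_active_arms concurrently evaluated
  per_look <- table(log$look[!is.na(log$prob_superior)])
  expect_true(all(per_look <= 2))
})

test_that("perpetual platform mode rolls the winner into a new comparison", {
  arms <- list(arm_spec("control", "control", 0.40),
               arm_spec("treat1", "treatment", 0.15),
               arm_spec("treat2", "treatment", 0.40, available_from = 1))
  rules <- design_rules("binary", max_n = 500L, n_looks = 5L,
                        superiority_threshold = 0.95, futility_threshold = 0,
                        mcid_margin = NULL, platform_enabled = TRUE,
                        perpetual = TRUE, perpetual_cap = 1500L,
                        decision_draws = 4000L)
  tr <- simulate_trial(arms, rules, seed = 210)
  log <- tr$decision_log
  expect_true(any(log$action == "stage-winner"))
  expect_true(any(log$action == "admitted" & log$arm == "treat2"))
  expect_identical(sum(tr$enrolled), tr$total_n)
  expect_lte(tr$total_n, 1500L)
  expect_true(tr$stop_reason %in% c("superiority", "futility-all", "perpetual-censored"))
})

test_that("response-adaptive randomization skews enrollment toward the better arm", {
  arms <- list(arm_spec("control", "control", 0.40),
               arm_spec("treat", "treatment", 0.15))
  rules <- design_rules("binary", max_n = 300L, n_looks = 1L,
                        direction = "lower-better",
                        superiority_threshold = 1.0, futility_threshold = 0,
                        mcid_margin = NULL, rar_enabled = TRUE, burn_in = 100L,
                        rar_draws = 300L)
  diff_enroll <- vapply(1:20, function(i) {
    tr <- simulate_trial(arms, rules, seed = child_seed(700, i))
    tr$enrolled[["treat"]] - tr$enrolled[["control"]]
  }, 0)
  expect_gt(mean(diff_enroll), 0)

  # burn-in contract: with max_n = burn_in the allocation stays equal, so the
  # split is binomial(max_n, 1/2) regardless of the posterior state
  rules_b <- design_rules("binary", max_n = 100L, n_looks = 1L,
                          superiority_threshold = 1.0, futility_threshold = 0,
                          mcid_margin = NULL, rar_enabled = TRUE, burn_in = 100L)
  splits <- vapply(1:30, function(i)
    simulate_trial(arms, rules_b, seed = child_seed(800, i))$enrolled[["treat"]], 0)
  expect_lt(abs(mean(splits) - 50), 3 * 5 / sqrt(30))
})

test_that("scenario validation reports field-level errors before simulating", {
  arms <- list(arm_spec("control", "control", 0.4),
               arm_spec("t", "treatment", 0.3))
  expect_error(design_rules("binary", max_n = 100L, superiority_threshold = 1.2),
               "superiority_threshold")
  expect_error(design_rules("binary", max_n = 100L, futility_threshold = 0.6),
               "futility_threshold")
  expect_error(design_rules("binary", max_n = 100L, burn_in = 200L), "burn_in")
  rules <- design_rules("binary", max_n = 100L)
  expect_error(validate_scenario(list(arms[[2]], arms[[2]]), rules), "control")
  expect_error(validate_scenario(list(arms[[1]], arm_spec("t", "treatment", 1.4)),
                                 rules), "true_param")
  carms <- list(arm_spec("control", "control", 0), arm_spec("t", "treatment", 1))
  expect_error(validate_scenario(carms, design_rules("continuous", max_n = 100L)),
               "true_sd")
})
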