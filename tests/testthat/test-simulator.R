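# Discrete-event foraging engine: validity, determinism, conservation,
# and the qualitative cost effect.

cohort4 <- function(seed = 1, ...) generate_cohort(4, seed = seed, ...)

test_that("identical condition, agents and seed give identical logs", {
  ag <- cohort4(3)
  l1 <- simulate_session(condition_low_cost(), ag, seed = 77)
  l2 <- simulate_session(condition_low_cost(), ag, seed = 77)
  expect_identical(l1, l2)
  l3 <- simulate_session(condition_low_cost(), ag, seed = 78)
  expect_false(identical(l1, l3))
})

test_that("event logs are valid streams", {
  for (s in 1:5) {
    ag <- cohort4(s)
    cond <- if (s %% 2) condition_low_cost() else condition_high_cost()
    log <- simulate_session(cond, ag, seed = 100 + s)
    expect_true(all(diff(log$time_s) >= 0))
    expect_true(all(log$time_s >= 0 & log$time_s <= cond$session_length))
    expect_true(all(log$units[log$event == "collect"] >= 1))
    expect_true(all(log$patch_id %in% seq_len(cond$n_patches)))

    # food conservation: collected <= F x successes; and per discovery
    n_succ <- sum(log$event == "search_success")
    expect_lte(sum(log$units[log$event == "collect"]), cond$food_per_patch * n_succ)

    # every join refers to a patch whose current discovery has uncollected
    # units and was found by someone else
    for (k in which(log$event == "join")) {
      prior <- log[seq_len(k - 1), ]
      prior <- prior[prior$patch_id == log$patch_id[k], ]
      succ <- which(prior$event == "search_success")
      expect_gt(length(succ), 0)
      last <- max(succ)
      expect_false(prior$agent_id[last] == log$agent_id[k])
      taken <- sum(prior$event[seq_len(nrow(prior)) > last] == "collect")
      expect_lt(taken, cond$food_per_patch)
    }
  }
})

test_that("zero success probability yields no discoveries, joins or collects", {
  log <- simulate_session(condition_low_cost(success_prob = 0), cohort4(2), seed = 5)
  expect_equal(sum(log$event %in% c("search_success", "join", "collect")), 0)
  expect_gt(sum(log$event == "search_fail"), 0)
})

test_that("search completions respect the time budget", {
  # t = 8 s in a 240 s session: at most 30 completed searches per agent
  ag <- cohort4(4, baseline_logit = 8, cost_sensitivity = 0)
  log <- simulate_session(condition_high_cost(), ag, seed = 11)
  done <- log[log$event %in% c("search_success", "search_fail"), ]
  per_agent <- table(done$agent_id)
  expect_true(all(per_agent <= floor(240 / 8)))
})

test_that("configuration errors are raised", {
  expect_error(
    simulate_session(condition_low_cost(), generate_cohort(5, seed = 1), seed = 1),
    class = "psforage_config_error"
  )
  expect_error(gft_condition("x", food_per_patch = 0), class = "psforage_validation_error")
  expect_error(gft_condition("x", success_prob = 1.2), class = "psforage_validation_error")
  expect_error(gft_condition("x", session_length = -5), class = "psforage_validation_error")
  expect_error(condition_low_cost(bogus = 1), class = "psforage_config_error")
})

test_that("higher production cost lowers producer responses (20 seeds)", {
  lo <- hi <- numeric(20)
  for (s in 1:20) {
    ag <- cohort4(s)
    lo[s] <- mean(summarize_foraging(
      simulate_session(condition_low_cost(), ag, seed = 1000 + s),
      participants = ag$agent_id, missing = "zero"
    )$producer_responses)
    hi[s] <- mean(summarize_foraging(
      simulate_session(condition_high_cost(), ag, seed = 2000 + s),
      participants = ag$agent_id, missing = "zero"
    )$producer_responses)
  }
  expect_lt(mean(hi), mean(lo))
  # and the ranking matches the clamped cost-discounted model prediction
  p_lo <- rmm_producer_proportion_cost(1, 5, 4, production_time = 0.01)$p
  p_hi <- rmm_producer_proportion_cost(1, 5, 4, production_time = 8)$p
  expect_lt(p_hi, p_lo)
})

test_that("pre-training preset stops after every agent holds five units", {
  cond <- condition_pretraining(success_prob = 1, collect_time = 0.5)
  ag <- cohort4(6, baseline_logit = 8, scrounge_opportunism = -20)
  log <- simulate_session(cond, ag, seed = 3)
  per_agent <- tapply(log$units[log$event == "collect"],
    log$agent_id[log$event == "collect"], sum,
    default = 0L
  )
  expect_true(all(per_agent >= 5))
  expect_lt(max(log$time_s), cond$session_length)
})

test_that("the realized finder's share is a proper fraction", {
  log <- simulate_session(condition_low_cost(), cohort4(8), seed = 21)
  fs <- estimate_finders_share(log)
  expect_true(fs$finders_share >= 0 && fs$finders_share <= 1)
  expect_true(fs$finders_units <= condition_low_cost()$food_per_patch)
})
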