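# Producer's index and event-log tallies.

test_that("producer's index evaluates, bounds, and flags the empty case", {
  expect_equal(producer_index(18, 1), 17 / 19)
  expect_equal(producer_index(3, 0), 1)
  expect_equal(producer_index(0, 5), -1)
  expect_true(is.na(producer_index(0, 0)))
  expect_error(producer_index(-1, 2), class = "psforage_validation_error")
  set.seed(42)
  p <- rpois(300, 6)
  s <- rpois(300, 3)
  idx <- producer_index(p, s)
  def <- !is.na(idx)
  expect_true(all(idx[def] >= -1 & idx[def] <= 1))
  # antisymmetry and scale invariance
  expect_equal(producer_index(s, p), -idx)
  for (k in c(2L, 7L)) {
    expect_equal(producer_index(k * p, k * s), idx)
  }
  # extremes only at pure strategies
  expect_true(all((idx[def] == 1) == (s[def] == 0 & p[def] > 0)))
  expect_true(all((idx[def] == -1) == (p[def] == 0 & s[def] > 0)))
})

test_that("tallies match a hand-worked two-agent log", {
  # a1 finds twice and collects both; a2 joins the first discovery and
  # collects, then finds once but never collects it
  log <- tibble::tibble(
    session_id = "s1", condition = "toy",
    time_s = c(1, 2, 3, 4, 5, 10, 11, 20, 21),
    agent_id = c("a1", "a1", "a2", "a2", "a1", "a1", "a1", "a2", "a2"),
    event = c(
      "search_start", "search_success", "join", "collect", "collect",
      "search_success", "collect", "search_start", "search_success"
    ),
    patch_id = c(1, 1, 1, 1, 1, 2, 2, 1, 1),
    units = c(NA, NA, NA, 1, 1, NA, 1, NA, NA)
  )
  tl <- tally_responses(log)
  expect_equal(tl$producer_responses[tl$participant_id == "a1"], 2L)
  expect_equal(tl$scrounger_responses[tl$participant_id == "a1"], 0L)
  expect_equal(tl$producer_responses[tl$participant_id == "a2"], 0L) # uncollected find
  expect_equal(tl$scrounger_responses[tl$participant_id == "a2"], 1L)
  expect_equal(tl$units_collected, c(2L, 1L))
  # with require_collection = FALSE the uncollected find counts
  tl2 <- tally_responses(log, require_collection = FALSE)
  expect_equal(tl2$producer_responses[tl2$participant_id == "a2"], 1L)
  expect_error(tally_responses(log, participant_id = "nobody"),
    class = "psforage_validation_error"
  )
})

test_that("tallies equal the brute-force event scan on random logs", {
  for (seed in 1:200) {
    log <- random_event_log(seed)
    got <- tally_responses(log)
    want <- oracle_tally(log)
    merged <- merge(got, want, by = c("session_id", "participant_id"))
    expect_equal(merged$producer_responses.x, merged$producer_responses.y)
    expect_equal(merged$scrounger_responses.x, merged$scrounger_responses.y)
    expect_equal(merged$units_collected.x, merged$units_collected.y)
  }
})

test_that("summaries cover every participant-condition cell", {
  logs <- dplyr::bind_rows(lapply(1:4, function(s) {
    l <- random_event_log(s)
    l$condition <- if (s %% 2) "c1" else "c2"
    l
  }))
  sm <- summarize_foraging(logs)
  expect_true(all(c(
    "participant_id", "condition", "producer_responses",
    "scrounger_responses", "producer_index", "units_collected"
  ) %in% names(sm)))
  expect_equal(
    sm$producer_index,
    producer_index(sm$producer_responses, sm$scrounger_responses)
  )
  # missing cells: warn + NA by default, zero-filled when the participant
  # is known to have been present
  expect_warning(
    sm2 <- summarize_foraging(logs, participants = c(unique(logs$agent_id), "ghost")),
    "missing"
  )
  expect_true(any(is.na(sm2$producer_responses[sm2$participant_id == "ghost"])))
  sm3 <- summarize_foraging(logs,
    participants = c(unique(logs$agent_id), "ghost"),
    missing = "zero"
  )
  expect_true(all(sm3$producer_responses[sm3$participant_id == "ghost"] == 0L))
  expect_true(all(is.na(sm3$producer_index[sm3$participant_id == "ghost"])))
})

test_that("an all-producer cohort has median index 1 in every condition", {
  ag <- generate_cohort(4,
    baseline_logit = 6, scrounge_opportunism = -20, seed = 5
  )
  log <- simulate_session(condition_low_cost(), ag, seed = 9)
  sm <- summarize_foraging(log)
  expect_equal(stats::median(sm$producer_index, na.rm = TRUE), 1)
})
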