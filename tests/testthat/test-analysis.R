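# Full pipeline report: structure, bookkeeping, determinism.

# small deterministic dataset built by hand: 12 participants, 2 conditions
build_hand_dataset <- function() {
  set.seed(77)
  ids <- sprintf("h%02d", 1:12)
  fg <- tidyr::expand_grid(participant_id = ids, condition = c("F5-0s", "F5-8s"))
  fg$producer_responses <- c(rbind(sample(10:25, 12, TRUE), sample(1:6, 12, TRUE)))
  fg$scrounger_responses <- c(rbind(sample(0:4, 12, TRUE), sample(0:2, 12, TRUE)))
  fg$producer_index <- producer_index(fg$producer_responses, fg$scrounger_responses)
  sc <- tibble::tibble(
    participant_id = ids,
    O = runif(12, 2, 5), C = runif(12, 2, 5), E = runif(12, 2, 5),
    A = runif(12, 2, 5), N = runif(12, 1, 4),
    CU = sample(0:3, 12, TRUE), IMP = sample(0:3, 12, TRUE), NAR = sample(0:4, 12, TRUE)
  )
  sc$apsd_total <- sc$CU + sc$IMP + sc$NAR # <= 10: everyone under cutoff
  sc$apsd_total[1:3] <- c(14, 13, 18) # force a 3-member above-cutoff group
  sc <- complete_scores(sc)
  list(foraging = fg, scores = sc)
}

test_that("the report has the published tables' shape", {
  d <- build_hand_dataset()
  rep <- run_full_analysis(d$foraging, d$scores, B = 50, seed = 1)
  expect_s3_class(rep, "ps_analysis")
  # (i) three variables compared between the two conditions
  expect_equal(nrow(rep$condition_comparison), 3)
  expect_setequal(
    rep$condition_comparison$variable,
    c("producer_index", "producer_responses", "scrounger_responses")
  )
  # (ii) cutoff comparison: 3 variables x 2 conditions, U in both orientations
  expect_equal(nrow(rep$cutoff_comparison), 6)
  mw <- rep$cutoff_comparison[grepl("mann-whitney", rep$cutoff_comparison$method), ]
  if (nrow(mw)) {
    expect_equal(mw$u_under + mw$u_above, mw$n_under * mw$n_above)
  }
  # (iii) 13 x 13 correlation matrix = 78 unique cells
  expect_equal(nrow(rep$correlations), 78)
  expect_equal(dim(attr(rep$correlations, "r_matrix")), c(13, 13))
  expect_equal(rep$meta$uncorrected_cells, 78)
  # (iv) bootstrap CIs for every index-trait pair
  expect_equal(nrow(rep$bootstrap), 22)
  expect_true(all(rep$bootstrap$lower <= rep$bootstrap$estimate + 1e-9))
  expect_true(all(rep$bootstrap$estimate <= rep$bootstrap$upper + 1e-9))
  # gate covers each variable in each condition
  expect_equal(nrow(rep$gate), 6)
  # broom-style accessors
  expect_equal(nrow(tidy(rep, "correlations")), 78)
  g <- glance(rep)
  expect_equal(g$n_analyzed, 12)
  expect_equal(g$n_above_cutoff, 3)
})

test_that("reports are deterministic under a fixed seed", {
  d <- build_hand_dataset()
  r1 <- run_full_analysis(d$foraging, d$scores, B = 80, seed = 5)
  r2 <- run_full_analysis(d$foraging, d$scores, B = 80, seed = 5)
  expect_identical(r1$condition_comparison, r2$condition_comparison)
  expect_identical(r1$correlations, r2$correlations)
  expect_identical(r1$bootstrap, r2$bootstrap)
  r3 <- run_full_analysis(d$foraging, d$scores, B = 80, seed = 6)
  expect_false(identical(r3$bootstrap, r1$bootstrap))
})

test_that("a thin above-cutoff group skips the comparison with a notice", {
  d <- build_hand_dataset()
  d$scores$apsd_total <- pmin(d$scores$apsd_total, 11)
  d$scores$cutoff_class <- NULL
  d$scores <- complete_scores(d$scores)
  rep <- run_full_analysis(d$foraging, d$scores, B = 0, seed = 1)
  expect_equal(nrow(rep$cutoff_comparison), 0)
  expect_match(rep$meta$notices, "skipped")
  expect_equal(nrow(rep$bootstrap), 0) # B = 0 skips bootstrap
})

test_that("exclusions are accounted for, never silent", {
  d <- build_hand_dataset()
  fg <- d$foraging[-1, ] # h01 lacks one condition cell
  sc <- d$scores[d$scores$participant_id != "h02", ] # h02 has no scores
  rep <- run_full_analysis(fg, sc, B = 0, seed = 1)
  expect_equal(rep$meta$n_analyzed, 10)
  ex <- rep$meta$exclusions
  expect_setequal(ex$participant_id, c("h01", "h02"))
  expect_equal(rep$meta$n_input - rep$meta$n_analyzed, nrow(ex) - sum(ex$reason == "no foraging data"))
})

test_that("degenerate inputs are rejected", {
  d <- build_hand_dataset()
  expect_error(
    run_full_analysis(d$foraging[d$foraging$condition == "F5-0s", ], d$scores),
    class = "psforage_validation_error"
  )
  expect_error(
    run_full_analysis(d$foraging[1:4, ], d$scores),
    class = "psforage_validation_error"
  )
})

test_that("plots build without evaluation errors", {
  d <- build_hand_dataset()
  rep <- run_full_analysis(d$foraging, d$scores, B = 20, seed = 2)
  for (tp in c("conditions", "correlations", "cutoff", "bootstrap")) {
    p <- ggplot2::autoplot(rep, type = tp)
    expect_s3_class(p, "ggplot")
    built <- ggplot2::ggplot_build(p)
    expect_true(length(built$data) >= 1)
  }
})
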