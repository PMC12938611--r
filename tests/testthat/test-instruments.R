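# Questionnaire scoring: keys, reversal, metatraits, cutoff.

test_that("shipped keys are complete and partitioned", {
  bfi <- scoring_key("bfi")
  apsd <- scoring_key("apsd")
  expect_setequal(bfi$item, 1:44)
  expect_setequal(apsd$item, 1:20)
  counts <- table(bfi$scale)
  expect_equal(sum(counts), 44)
  expect_setequal(names(counts), c("O", "C", "E", "A", "N"))
  fac <- table(apsd$scale)
  expect_lte(sum(fac[c("CU", "IMP", "NAR")]), 20)
  # a tampered key is rejected
  bad <- bfi
  bad$item[1] <- 2L
  tmp <- tempfile(fileext = ".csv")
  readr::write_csv(bad, tmp)
  expect_error(read_scoring_key(tmp, "bfi"), class = "psforage_validation_error")
})

test_that("uniform responses hit the reversal fixed point", {
  items <- items_from_scored(c("p1", "p2"), bfi_value = 3, apsd_value = 1)
  tr <- score_bfi(items)
  expect_true(all(abs(as.matrix(tr[c("O", "C", "E", "A", "N")]) - 3) < 1e-12))
  ap <- score_apsd(items)
  expect_equal(ap$apsd_total, c(20, 20))
  # a reverse-keyed item answered 1 contributes 5 to its trait mean
  key <- scoring_key("bfi")
  rev_item <- key$item[key$reverse][1]
  one <- items_from_scored("p3", bfi_value = 3)
  one[[paste0("bfi_", rev_item)]] <- 1
  tr1 <- score_bfi(one)
  sc <- key$scale[key$item == rev_item]
  k <- sum(key$scale == sc)
  expect_equal(tr1[[sc]], (3 * (k - 1) + 5) / k)
})

test_that("reversal is an involution", {
  items <- generate_questionnaires(generate_cohort(6, seed = 2), noise_sd = 0.7, seed = 3)
  flip <- items
  for (i in 1:44) flip[[paste0("bfi_", i)]] <- 6 - flip[[paste0("bfi_", i)]]
  for (i in 1:44) flip[[paste0("bfi_", i)]] <- 6 - flip[[paste0("bfi_", i)]]
  expect_equal(score_bfi(flip), score_bfi(items), ignore_attr = TRUE)
})

test_that("metatraits are exact composite means", {
  tr <- tibble::tibble(O = 3, C = 4, E = 2, A = 4, N = 2)
  mt <- compute_metatraits(tr)
  expect_equal(mt$stability, 4) # mean(4, 4, 6 - 2)
  expect_equal(mt$plasticity, 2.5) # mean(2, 3)
  # E = O = x gives plasticity x; all-3 is a fixed point
  mt2 <- compute_metatraits(tibble::tibble(O = 3.7, C = 3, E = 3.7, A = 3, N = 3))
  expect_equal(mt2$plasticity, 3.7)
  mt3 <- compute_metatraits(tibble::tibble(O = 3, C = 3, E = 3, A = 3, N = 3))
  expect_equal(mt3$stability, 3)
  expect_equal(mt3$plasticity, 3)
  # scores stay on the 1-5 scale
  set.seed(1)
  rnd <- tibble::as_tibble(matrix(runif(500, 1, 5), 100, 5,
    dimnames = list(NULL, c("O", "C", "E", "A", "N"))
  ))
  mt4 <- compute_metatraits(rnd)
  expect_true(all(mt4$stability >= 1 & mt4$stability <= 5))
  expect_true(all(mt4$plasticity >= 1 & mt4$plasticity <= 5))
})

test_that("cutoff classification is threshold-inclusive on the total", {
  zero <- items_from_scored("p0", apsd_value = 0)
  expect_equal(as.character(score_apsd(zero)$cutoff_class), "under")
  full <- items_from_scored("p2", apsd_value = 2)
  sc <- score_apsd(full)
  expect_equal(sc$apsd_total, 40)
  expect_equal(as.character(sc$cutoff_class), "above")
  # total exactly 12: above (tie rule)
  twelve <- items_from_scored("p12", apsd_value = c(rep(1, 12), rep(0, 8)))
  sc12 <- score_apsd(twelve)
  expect_equal(sc12$apsd_total, 12)
  expect_equal(as.character(sc12$cutoff_class), "above")
  expect_equal(as.character(score_apsd(twelve, threshold = 13)$cutoff_class), "under")
  # factor sums consistent with the key, totals bounded
  expect_true(all(sc$CU + sc$IMP + sc$NAR <= sc$apsd_total))
  m <- score_apsd(full, method = "mean")
  expect_true(all(c(m$CU, m$IMP, m$NAR) == 2))
})

test_that("incomplete or out-of-range participants are excluded, not patched", {
  items <- items_from_scored(c("ok", "bad7", "badNA"))
  items$bfi_5[2] <- 7
  items$bfi_9[3] <- NA
  expect_message(tr <- score_bfi(items), "excluded 2")
  expect_equal(tr$participant_id, "ok")
  ex <- attr(tr, "exclusions")
  expect_setequal(ex$participant_id, c("bad7", "badNA"))
  items2 <- items_from_scored(c("ok", "oops"))
  items2$apsd_3[2] <- 5
  expect_message(ap <- score_apsd(items2), "excluded 1")
  expect_equal(ap$participant_id, "ok")
})

test_that("noise-free questionnaires round-trip the latent traits", {
  ag <- dplyr::bind_rows(
    agent_profile("g1", O = 3, C = 4, E = 2, A = 5, N = 1, antisociality = 1),
    agent_profile("g2", O = 3.7, C = 3, E = 3, A = 3, N = 3, antisociality = 0)
  )
  qs <- generate_questionnaires(ag, noise_sd = 0, seed = 1)
  tr <- score_bfi(qs)
  # integer latents recover exactly; O = 3.7 sits on the 10-item 1/10 grid
  expect_equal(tr$O, c(3, 3.7))
  expect_equal(tr$C, c(4, 3))
  expect_equal(tr$E, c(2, 3))
  expect_equal(tr$A, c(5, 3))
  expect_equal(tr$N, c(1, 3))
  ap <- score_apsd(qs)
  expect_equal(ap$apsd_total, c(20, 0))
})

test_that("noisy questionnaires still track the latents closely", {
  ag <- generate_cohort(200, seed = 31)
  qs <- generate_questionnaires(ag, noise_sd = 0.5, seed = 32)
  tr <- score_bfi(qs)
  stopifnot(nrow(tr) == 200)
  for (v in c("O", "C", "E", "A", "N")) {
    expect_gt(stats::cor(ag[[v]], tr[[v]]), 0.9)
  }
  expect_identical(qs, generate_questionnaires(ag, noise_sd = 0.5, seed = 32))
})

test_that("scored trait correlations converge to the generating structure", {
  cfg <- trait_config_default()
  ag <- generate_cohort(600, seed = 44)
  sc <- score_bfi(generate_questionnaires(ag, noise_sd = 0.1, seed = 45))
  R <- stats::cor(as.matrix(sc[c("O", "C", "E", "A", "N")]))
  expect_lt(abs(R["O", "C"] - cfg$cor["O", "C"]), 0.12)
  expect_lt(abs(R["E", "A"] - cfg$cor["E", "A"]), 0.12)
  expect_lt(abs(R["N", "C"] - cfg$cor["N", "C"]), 0.12)
})
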