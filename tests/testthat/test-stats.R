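# Nonparametric test implementations against enumeration oracles and base R.

test_that("normality gate is affine-invariant and guards its domain", {
  set.seed(10)
  x <- rexp(40)
  g1 <- gate_normality(x)
  g2 <- gate_normality(3 * x - 7)
  expect_equal(g1$W, g2$W)
  expect_false(g1$normal) # heavy skew
  expect_true(gate_normality(rnorm(100, 5, 1))$normal)
  expect_error(gate_normality(c(1, 2)), class = "psforage_validation_error")
  expect_warning(gc <- gate_normality(rep(2, 10)), "constant")
  expect_false(gc$normal)
})

test_that("signed-rank test matches enumeration and base R, and is antisymmetric", {
  set.seed(21)
  for (n in c(4, 6, 8)) {
    for (rep in 1:8) {
      x <- sample(0:20, n, replace = TRUE)
      y <- sample(0:20, n, replace = TRUE)
      if (all(x == y)) x[1] <- x[1] + 1
      got <- ps_wilcoxon(x, y)
      expect_true(got$exact)
      expect_equal(got$p_value, oracle_signed_rank_p(x, y))
      # antisymmetry
      swp <- ps_wilcoxon(y, x)
      expect_equal(swp$z, -got$z)
      expect_equal(swp$p_value, got$p_value)
      expect_equal(swp$r_pb, -got$r_pb)
    }
  }
  # normal-approximation branch agrees with base R without continuity correction
  x <- rnorm(40)
  y <- rnorm(40, 0.3)
  got <- ps_wilcoxon(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE))
  expect_false(got$exact)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(got$w_plus, unname(ref$statistic))
  # identical samples: undefined
  expect_error(ps_wilcoxon(x, x), class = "psforage_validation_error")
  # rank-biserial from rank sums
  expect_equal(got$r_pb, (got$w_plus - got$w_minus) / (got$w_plus + got$w_minus))
})

test_that("Mann-Whitney U matches pair counting and enumeration on small instances", {
  got <- ps_mann_whitney(c(1, 2, 3), c(4, 5))
  expect_equal(got$u1, 0)
  expect_equal(got$u2, 6)
  set.seed(33)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      g1 <- sample(0:8, n1, replace = TRUE)
      g2 <- sample(0:8, n2, replace = TRUE)
      got <- ps_mann_whitney(g1, g2)
      expect_true(got$exact)
      expect_equal(got$u1, oracle_u(g1, g2))
      expect_equal(got$u2, oracle_u(g2, g1))
      expect_equal(got$u1 + got$u2, n1 * n2) # duality
      expect_equal(got$p_value, oracle_mw_exact_p(g1, g2))
    }
  }
  # identical multisets: U = n1 n2 / 2
  g <- c(1, 3, 3, 7)
  expect_equal(ps_mann_whitney(g, g)$u1, 8)
  expect_error(ps_mann_whitney(numeric(0), 1:3), class = "psforage_validation_error")
})

test_that("Mann-Whitney agrees with base R in both branches", {
  set.seed(34)
  # exact, tie-free: identical p to wilcox.test's exact branch
  g1 <- rnorm(8)
  g2 <- rnorm(9)
  got <- ps_mann_whitney(g1, g2)
  ref <- stats::wilcox.test(g1, g2, exact = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(got$u1, unname(ref$statistic))
  # large samples: normal approximation, tie-corrected, no continuity correction
  g1 <- sample(0:30, 40, replace = TRUE)
  g2 <- sample(0:30, 35, replace = TRUE) + 3
  got <- ps_mann_whitney(g1, g2)
  ref <- stats::wilcox.test(g1, g2, exact = FALSE, correct = FALSE)
  expect_false(got$exact)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("pearson matrix reproduces hand arithmetic and flags degeneracy", {
  # hand oracle: plain product-moment formula on a 4-point case
  x <- c(1, 2, 3, 4)
  y <- c(2, 4, 6, -8)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  d <- data.frame(x = x, y = y, z = c(5, 5, 5, 5), w = 4:1)
  pm <- pearson_matrix(d)
  expect_equal(pm$r[pm$var1 == "x" & pm$var2 == "y"], r_hand)
  expect_equal(pm$r[pm$var1 == "x" & pm$var2 == "w"], -1) # reversed sequence
  expect_true(is.na(pm$r[pm$var1 == "x" & pm$var2 == "z"])) # zero variance
  R <- attr(pm, "r_matrix")
  expect_equal(diag(R), rep(1, 4), ignore_attr = TRUE)
  expect_equal(R, t(R))
  expect_true(all(abs(R[!is.na(R)]) <= 1))
  # invariance under positive affine maps, sign flip under negative scaling
  d2 <- transform(d, x = 10 * x + 3)
  expect_equal(pearson_matrix(d2)$r[1], pm$r[1])
  d3 <- transform(d, x = -2 * x)
  expect_equal(pearson_matrix(d3)$r[1], -pm$r[1])
  # star tiers come from the t-transform p
  set.seed(9)
  n <- 50
  dd <- data.frame(a = rnorm(n))
  dd$b <- dd$a + rnorm(n, 0, 0.5)
  pm2 <- pearson_matrix(dd)
  ref <- stats::cor.test(dd$a, dd$b)
  expect_equal(pm2$p_value, ref$p.value)
  expect_equal(pm2$stars, "***")
})

test_that("bootstrap intervals are deterministic, degenerate-safe and shrink", {
  d <- data.frame(v = rep(4, 10))
  ci <- bootstrap_ci(d, function(df) mean(df$v), B = 100, seed = 1)
  expect_equal(ci$lower, 4)
  expect_equal(ci$upper, 4)
  set.seed(2)
  d2 <- data.frame(v = rnorm(40))
  a <- bootstrap_ci(d2, function(df) mean(df$v), B = 300, seed = 9)
  b <- bootstrap_ci(d2, function(df) mean(df$v), B = 300, seed = 9)
  expect_identical(a, b)
  expect_true(a$lower <= a$estimate && a$estimate <= a$upper)
  # width ~ n^(-1/2)
  set.seed(3)
  widths <- sapply(c(20, 80, 320), function(n) {
    dd <- data.frame(v = rnorm(n))
    ci <- bootstrap_ci(dd, function(df) mean(df$v), B = 400, seed = n)
    ci$upper - ci$lower
  })
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.5)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.5)
  # mostly-undefined statistic errors with a diagnostic
  d3 <- data.frame(v = c(0, 0, 0, 1))
  expect_error(
    bootstrap_ci(d3, function(df) if (stats::sd(df$v) == 0) NA_real_ else 1,
      B = 200, seed = 4
    ),
    class = "psforage_validation_error"
  )
  # BCa variant returns a sane interval containing the estimate for a mean
  bca <- bootstrap_ci(d2, function(df) mean(df$v), B = 400, method = "bca", seed = 5)
  expect_true(bca$lower <= bca$estimate && bca$estimate <= bca$upper)
})
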