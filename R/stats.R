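#' Shapiro-Wilk normality gate
#'
#' Thin wrapper around [stats::shapiro.test()] used to route between
#' parametric and nonparametric comparisons: a variable is flagged
#' non-normal when `p < alpha`. Constant samples (on which the test is
#' undefined) are routed to the nonparametric branch with a warning.
#'
#' @param x Numeric sample, `3 <= n <= 5000`.
#' @param alpha Routing threshold (default 0.05).
#' @return One-row tibble: `n`, `W`, `p_value`, `normal`.
#' @export
gate_normality <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) abort_validation("normality gate needs n >= 3, got %d", length(x))
  if (stats::sd(x) == 0) {
    rlang::warn("constant sample: normality undefined, routing to nonparametric branch")
    return(tibble::tibble(n = length(x), W = NA_real_, p_value = NA_real_, normal = FALSE))
  }
  sw <- stats::shapiro.test(x)
  tibble::tibble(
    n = length(x),
    W = unname(sw$statistic),
    p_value = sw$p.value,
    normal = sw$p.value >= alpha
  )
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Compares two paired measurements the way rank-based condition comparisons
#' are conventionally reported: zero differences are dropped before ranking;
#' the standardized statistic `z` uses the tie-corrected variance with no
#' continuity correction (so `z` may differ in the second decimal from
#' implementations that apply one); the effect size is the matched-pairs
#' rank-biserial correlation, `r_pb = (W+ - W-) / (W+ + W-)`, positive when
#' `x` tends to exceed `y`. For `n <= exact_limit` nonzero pairs the p-value
#' comes from full enumeration of the `2^n` sign patterns of the observed
#' ranks (valid under ties); otherwise from the normal approximation.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_limit Largest `n` for the exact enumeration branch.
#' @return One-row tibble: `n` (nonzero pairs), `n_zero` (dropped),
#'   `w_plus`, `w_minus`, `z`, `p_value`, `r_pb`, `exact`.
#' @export
#' @examples
#' ps_wilcoxon(c(5, 7, 3, 9), c(2, 6, 4, 1))
ps_wilcoxon <- function(x, y, exact_limit = 12L) {
  if (length(x) != length(y)) abort_validation("`x` and `y` must be paired (equal length)")
  keep <- !(is.na(x) | is.na(y))
  d <- x[keep] - y[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    abort_validation("all paired differences are zero: signed-rank statistic undefined")
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (w_plus - mu) / sqrt(sigma2) else NaN
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, w_plus)
    exact <- TRUE
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  tibble::tibble(
    n = n, n_zero = sum(keep) - n, w_plus = w_plus, w_minus = w_minus,
    z = z, p_value = min(p, 1), r_pb = (w_plus - w_minus) / (w_plus + w_minus),
    exact = exact
  )
}

# exact two-sided p by enumerating all 2^n sign assignments of the ranks
signed_rank_exact_p <- function(r, w_obs) {
  n <- length(r)
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

#' Mann-Whitney U test for two independent groups
#'
#' `u1` counts the pairs `(a in g1, b in g2)` with `a > b` plus half the
#' ties; `u2 = n1*n2 - u1` is the complementary orientation, and both are
#' reported since published tables mix the two conventions. The p-value is
#' exact — the full permutation distribution of the rank sum, computed by
#' dynamic programming over doubled midranks, so ties are handled — whenever
#' `n1 * n2 <= exact_limit`; otherwise the tie-corrected normal approximation
#' without continuity correction is used. The rank-biserial effect size is
#' `2 * u1 / (n1 * n2) - 1`.
#'
#' @param g1,g2 Numeric vectors (both nonempty).
#' @param exact_limit Largest `n1 * n2` for the exact branch.
#' @return One-row tibble: `n1`, `n2`, `u1`, `u2`, `z`, `p_value`, `r_rb`,
#'   `exact`.
#' @export
#' @examples
#' ps_mann_whitney(c(1, 2, 3), c(4, 5)) # u1 = 0, u2 = 6
ps_mann_whitney <- function(g1, g2, exact_limit = 400L) {
  g1 <- g1[!is.na(g1)]
  g2 <- g2[!is.na(g2)]
  n1 <- length(g1)
  n2 <- length(g2)
  if (n1 == 0L || n2 == 0L) abort_validation("both groups must be nonempty")
  r <- rank(c(g1, g2))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  nn <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  z <- if (sigma2 > 0) (u1 - n1 * n2 / 2) / sqrt(sigma2) else NaN
  if (n1 * n2 <= exact_limit) {
    p <- mann_whitney_exact_p(r, n1, u1)
    exact <- TRUE
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  tibble::tibble(
    n1 = n1, n2 = n2, u1 = u1, u2 = u2, z = z,
    p_value = min(p, 1), r_rb = 2 * u1 / (n1 * n2) - 1, exact = exact
  )
}

# Exact two-sided p for the Mann-Whitney U: permutation distribution of the
# group-1 rank sum over all choose(N, n1) subsets, via the shift algorithm on
# doubled midranks (integers even under ties). Subset counts stay below 2^53
# for the sizes this branch accepts, so double arithmetic is exact.
mann_whitney_exact_p <- function(r, n1, u_obs) {
  w <- as.integer(round(2 * r))
  N <- length(w)
  S <- sum(w)
  f <- matrix(0, nrow = n1 + 1L, ncol = S + 1L)
  f[1L, 1L] <- 1
  for (i in seq_len(N)) {
    kmax <- min(i, n1)
    for (k in kmax:1) {
      src <- seq_len(S + 1L - w[i])
      f[k + 1L, src + w[i]] <- f[k + 1L, src + w[i]] + f[k, src]
    }
  }
  counts <- f[n1 + 1L, ]
  s_vals <- (seq_len(S + 1L) - 1L) / 2 # rank sums
  u_vals <- s_vals - n1 * (n1 + 1) / 2
  center <- n1 * (N - n1) / 2
  sum(counts[abs(u_vals - center) >= abs(u_obs - center) - 1e-9]) / sum(counts)
}

#' Pairwise Pearson correlation matrix with significance tiers
#'
#' Product-moment correlations over all pairs of the selected numeric
#' columns, pairwise-complete, with two-sided p-values from the t transform
#' (via [stats::cor.test()]) and the conventional star tiers (`*` p < 0.05,
#' `**` p < 0.01, `***` p < 0.001). The squared correlation is exposed
#' alongside, as reports often print it next to p. Pairs with fewer than 3
#' complete observations or zero variance are flagged undefined (`NA`).
#'
#' @param data Data frame.
#' @param vars Character vector of columns to correlate (default: all
#'   numeric columns). Order is preserved in the matrix forms.
#' @return Tibble with one row per unordered pair (`var1`, `var2`, `r`,
#'   `r_squared`, `p_value`, `stars`, `n`), plus attributes `r_matrix`,
#'   `p_matrix`, `n_matrix` (symmetric, unit diagonal).
#' @export
pearson_matrix <- function(data, vars = NULL) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  miss <- setdiff(vars, names(data))
  if (length(miss)) abort_validation("unknown variables: %s", paste(miss, collapse = ", "))
  k <- length(vars)
  if (k < 2L) abort_validation("need at least two variables")
  R <- P <- Nm <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(R) <- 1
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      x <- data[[vars[i]]]
      y <- data[[vars[j]]]
      ok <- !(is.na(x) | is.na(y))
      n <- sum(ok)
      Nm[i, j] <- Nm[j, i] <- n
      if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        r <- p <- NA_real_
      } else {
        ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
        r <- unname(ct$estimate)
        p <- ct$p.value
      }
      R[i, j] <- R[j, i] <- r
      P[i, j] <- P[j, i] <- p
      rows[[length(rows) + 1L]] <- tibble::tibble(
        var1 = vars[i], var2 = vars[j], r = r, r_squared = r^2,
        p_value = p, stars = p_stars(p), n = n
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "r_matrix") <- R
  attr(out, "p_matrix") <- P
  attr(out, "n_matrix") <- Nm
  out
}

#' Case-resampling bootstrap confidence interval
#'
#' Draws `B` resamples of whole rows with replacement (paired values are
#' resampled jointly), evaluates `statistic` on each, and returns a
#' percentile interval — or a bias-corrected and accelerated (BCa) interval
#' with `method = "bca"`. Deterministic under `seed`. Resamples on which the
#' statistic is undefined (`NA`/`NaN`, e.g. a zero-variance correlation) are
#' tolerated up to 10% and dropped; beyond that the call errors with a
#' diagnostic, since the interval would no longer describe the intended
#' statistic.
#'
#' @param data Data frame of cases (a vector is treated as a one-column
#'   frame).
#' @param statistic Function mapping a data frame like `data` to one number.
#' @param B Number of resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param method `"percentile"` (default) or `"bca"`.
#' @param seed Integer seed.
#' @return One-row tibble: `estimate`, `lower`, `upper`, `B` (usable
#'   resamples), `level`, `method`, `n`, `n_undefined`, `seed`.
#' @export
#' @examples
#' d <- data.frame(x = rnorm(30), y = rnorm(30))
#' bootstrap_ci(d, function(df) cor(df$x, df$y), B = 200, seed = 1)
bootstrap_ci <- function(data, statistic, B = 1000L, level = 0.95,
                         method = c("percentile", "bca"), seed = 1L) {
  method <- match.arg(method)
  if (is.atomic(data) && is.null(dim(data))) data <- data.frame(value = data)
  n <- nrow(data)
  if (is.null(n) || n < 2L) abort_validation("bootstrap needs at least 2 cases")
  check_number(B, "B", lo = 1, integer = TRUE)
  check_number(level, "level", lo = 0.5, hi = 0.9999)
  est <- statistic(data)
  if (!is.numeric(est) || length(est) != 1L) {
    abort_validation("`statistic` must return a single number")
  }
  theta <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      as.numeric(statistic(data[idx, , drop = FALSE]))
    }, numeric(1))
  })
  bad <- !is.finite(theta)
  if (mean(bad) > 0.10) {
    abort_validation(
      "statistic undefined on %.0f%% of resamples (> 10%%); n = %d may be too small",
      100 * mean(bad), n
    )
  }
  theta <- theta[!bad]
  alpha <- (1 - level) / 2
  if (method == "percentile") {
    ci <- stats::quantile(theta, c(alpha, 1 - alpha), names = FALSE, type = 7)
  } else {
    z0 <- stats::qnorm(mean(theta < est) + 0.5 * mean(theta == est))
    jack <- vapply(seq_len(n), function(i) {
      as.numeric(statistic(data[-i, , drop = FALSE]))
    }, numeric(1))
    jm <- mean(jack, na.rm = TRUE)
    num <- sum((jm - jack)^3, na.rm = TRUE)
    den <- 6 * sum((jm - jack)^2, na.rm = TRUE)^1.5
    a <- if (den == 0) 0 else num / den
    zl <- stats::qnorm(alpha)
    zu <- stats::qnorm(1 - alpha)
    p1 <- stats::pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
    p2 <- stats::pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
    ci <- stats::quantile(theta, c(p1, p2), names = FALSE, type = 7)
  }
  tibble::tibble(
    estimate = est, lower = ci[1], upper = ci[2],
    B = length(theta), level = level, method = method,
    n = n, n_undefined = sum(bad), seed = as.integer(seed)
  )
}
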