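#' Rate-maximization prediction of the equilibrium producer proportion
#'
#' The rate-maximization model predicts the stable proportion of producers
#' `P` in a foraging group from the finder's share `a` (units the producer
#' consumes before scroungers join), patch richness `F` (units per
#' discovery) and group size `G`:
#'
#' \deqn{P = a/F + 1/G}
#'
#' `rmm_producer_proportion_cost()` discounts the finder's share by the time
#' `t` invested in producing, which captures why costlier searches depress
#' producing:
#'
#' \deqn{P = (a/t)/F + 1/G}
#'
#' The raw formulas can exceed 1; both the raw value and the value clamped to
#' `[0, 1]` are returned, with a flag marking where clamping bit. At `t = 1`
#' both equations coincide. The cost variant diverges as `t -> 0`, so `t`
#' must be strictly positive.
#'
#' @param finder_share Finder's share `a` (units, >= 0).
#' @param patch_food Food per patch `F` (> 0).
#' @param group_size Group size `G` (>= 1).
#' @param production_time Production time `t` in seconds (> 0; cost variant).
#' @return A tibble with the parameters plus `p_raw`, `p` (clamped to
#'   `[0, 1]`) and `clamped`. Inputs are recycled to a common length.
#' @export
#' @examples
#' rmm_producer_proportion(finder_share = 1, patch_food = 5, group_size = 4) # p = 0.45
#' rmm_producer_proportion_cost(1, 5, 4, production_time = 8) # p = 0.275
rmm_producer_proportion <- function(finder_share, patch_food, group_size) {
  v <- vctrs_recycle(finder_share = finder_share, patch_food = patch_food, group_size = group_size)
  validate_rmm(v)
  raw <- v$finder_share / v$patch_food + 1 / v$group_size
  tibble::tibble(
    finder_share = v$finder_share, patch_food = v$patch_food, group_size = v$group_size,
    p_raw = raw, p = clamp(raw, 0, 1), clamped = raw < 0 | raw > 1
  )
}

#' @rdname rmm_producer_proportion
#' @export
rmm_producer_proportion_cost <- function(finder_share, patch_food, group_size, production_time) {
  v <- vctrs_recycle(
    finder_share = finder_share, patch_food = patch_food,
    group_size = group_size, production_time = production_time
  )
  validate_rmm(v)
  if (any(v$production_time <= 0)) {
    abort_validation("`production_time` must be > 0 (the cost-discounted form diverges at t = 0)")
  }
  raw <- (v$finder_share / v$production_time) / v$patch_food + 1 / v$group_size
  tibble::tibble(
    finder_share = v$finder_share, patch_food = v$patch_food,
    group_size = v$group_size, production_time = v$production_time,
    p_raw = raw, p = clamp(raw, 0, 1), clamped = raw < 0 | raw > 1
  )
}

validate_rmm <- function(v) {
  if (any(!is.finite(unlist(v)))) abort_validation("RMM parameters must be finite")
  if (any(v$finder_share < 0)) abort_validation("`finder_share` must be >= 0")
  if (any(v$patch_food <= 0)) abort_validation("`patch_food` must be > 0")
  if (any(v$group_size < 1)) abort_validation("`group_size` must be >= 1")
  invisible(v)
}

vctrs_recycle <- function(...) {
  v <- list(...)
  n <- max(lengths(v))
  bad <- lengths(v) != n & lengths(v) != 1L
  if (any(bad)) abort_validation("arguments must have length 1 or %d", n)
  lapply(v, rep_len, n)
}

#' Sweep rate-maximization predictions over a parameter grid
#'
#' Evaluates both the plain and the cost-discounted prediction on the full
#' cross of the supplied parameter values. Invalid combinations (e.g.
#' nonpositive `production_time`) are kept in the output flagged
#' `valid = FALSE` rather than dropped.
#'
#' @param finder_share,patch_food,group_size,production_time Numeric vectors
#'   defining the grid.
#' @return A tibble, one row per combination: parameters, `p_raw`/`p` from
#'   the plain form, `p_raw_cost`/`p_cost` from the cost-discounted form,
#'   `clamped`, `clamped_cost`, `valid`, `note`.
#' @export
#' @examples
#' rmm_sweep(finder_share = 1, patch_food = 5, group_size = 4, production_time = c(1, 2, 4, 8))
rmm_sweep <- function(finder_share = 1, patch_food = 5, group_size = 4, production_time = 1) {
  grid <- tidyr::expand_grid(
    finder_share = finder_share, patch_food = patch_food,
    group_size = group_size, production_time = production_time
  )
  if (!nrow(grid)) abort_validation("empty parameter grid")
  note <- dplyr::case_when(
    !is.finite(grid$finder_share) | grid$finder_share < 0 ~ "finder_share < 0",
    !is.finite(grid$patch_food) | grid$patch_food <= 0 ~ "patch_food <= 0",
    !is.finite(grid$group_size) | grid$group_size < 1 ~ "group_size < 1",
    !is.finite(grid$production_time) | grid$production_time <= 0 ~ "production_time <= 0",
    TRUE ~ ""
  )
  valid <- note == ""
  raw <- ifelse(valid, grid$finder_share / grid$patch_food + 1 / grid$group_size, NA_real_)
  raw_c <- ifelse(valid,
    (grid$finder_share / grid$production_time) / grid$patch_food + 1 / grid$group_size,
    NA_real_
  )
  dplyr::mutate(grid,
    p_raw = raw, p = clamp(raw, 0, 1), clamped = raw < 0 | raw > 1,
    p_raw_cost = raw_c, p_cost = clamp(raw_c, 0, 1), clamped_cost = raw_c < 0 | raw_c > 1,
    valid = valid, note = note
  )
}
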