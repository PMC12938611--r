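# shared helpers; internal only

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

abort_config <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "psforage_config_error")
}

abort_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "psforage_validation_error")
}

check_number <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation("`%s` must be a single finite number", name)
  }
  if (x < lo || x > hi) {
    abort_validation("`%s` = %s is outside [%s, %s]", name, format(x), format(lo), format(hi))
  }
  if (integer && x != round(x)) {
    abort_validation("`%s` must be an integer, got %s", name, format(x))
  }
  invisible(x)
}

#' Derive a per-session random stream seed from a master seed
#'
#' One master seed drives a whole simulated experiment; each (group,
#' condition) session gets its own stream via a stable integer hash so that
#' adding or reordering sessions never perturbs the others. All arithmetic
#' stays below 2^53 so the hash is exact in double precision, and the result
#' is a valid 32-bit seed.
#'
#' @param master Master seed (single integer-valued number).
#' @param group Group index (>= 0).
#' @param condition Condition index (>= 0).
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
session_seed <- function(master, group = 0L, condition = 0L) {
  check_number(master, "master", integer = TRUE)
  check_number(group, "group", lo = 0, integer = TRUE)
  check_number(condition, "condition", lo = 0, integer = TRUE)
  m <- 2147483647
  h <- abs(master) %% m
  h <- (h * 69069 + 12345) %% m
  h <- (h + group * 1000003 + condition * 7919) %% m
  h <- (h * 69069 + 12345) %% m
  as.integer(h)
}

# stable star tiers used throughout the report tables
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}
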