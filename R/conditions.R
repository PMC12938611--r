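#' Define a foraging-session condition
#'
#' A condition fixes the ecology of one session of the group foraging task:
#' how rich a discovery is, how long a search takes, how likely it is to
#' succeed, and the timing constants of the abstracted arena. Conditions are
#' conventionally named `F<food>-<cost>s`, e.g. `F5-0s` (five food units per
#' discovery, near-zero search cost) and `F5-8s` (eight-second searches).
#'
#' Space is abstracted to zone-level states: agents are either inside one of
#' `n_patches` symmetric patch zones or traveling between zones at a fixed
#' `travel_time`. Food units are collected one at a time at `collect_time`
#' seconds per unit; a discovery stays joinable by other agents for
#' `scrounger_join_window` seconds. `decision_pause` is the time an idle agent
#' waits before reconsidering its options (human participants spend a lot of
#' session time wandering and watching).
#'
#' @param name Condition label.
#' @param food_per_patch Food units appearing after a successful search (F).
#' @param search_cost Seconds one search takes (t).
#' @param success_prob Probability a search produces food.
#' @param session_length Session duration, seconds.
#' @param group_size Number of players (G).
#' @param n_patches Number of patch zones.
#' @param travel_time Seconds to move between zones.
#' @param collect_time Seconds to collect one food unit.
#' @param scrounger_join_window Seconds a discovery remains joinable.
#' @param decision_pause Seconds an idle agent waits between decisions.
#' @param stop_after_units Optional early stop: end the session once every
#'   agent has collected this many units (used by the pre-training preset).
#' @return A `gft_condition` list.
#' @export
#' @examples
#' gft_condition("F5-8s", search_cost = 8)
gft_condition <- function(name,
                          food_per_patch = 5,
                          search_cost = 0.01,
                          success_prob = 0.5,
                          session_length = 240,
                          group_size = 4,
                          n_patches = 4,
                          travel_time = 3,
                          collect_time = 2,
                          scrounger_join_window = 5,
                          decision_pause = 4,
                          stop_after_units = Inf) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_validation("`name` must be a non-empty string")
  }
  check_number(food_per_patch, "food_per_patch", lo = 1, integer = TRUE)
  check_number(search_cost, "search_cost", lo = 0)
  check_number(success_prob, "success_prob", lo = 0, hi = 1)
  check_number(session_length, "session_length", lo = .Machine$double.eps)
  check_number(group_size, "group_size", lo = 2, integer = TRUE)
  check_number(n_patches, "n_patches", lo = 1, integer = TRUE)
  check_number(travel_time, "travel_time", lo = 0)
  check_number(collect_time, "collect_time", lo = 0)
  check_number(scrounger_join_window, "scrounger_join_window", lo = 0)
  check_number(decision_pause, "decision_pause", lo = .Machine$double.eps)
  if (!identical(stop_after_units, Inf)) {
    check_number(stop_after_units, "stop_after_units", lo = 1, integer = TRUE)
  }
  structure(
    list(
      name = name,
      food_per_patch = as.integer(food_per_patch),
      search_cost = search_cost,
      success_prob = success_prob,
      session_length = session_length,
      group_size = as.integer(group_size),
      n_patches = as.integer(n_patches),
      travel_time = travel_time,
      collect_time = collect_time,
      scrounger_join_window = scrounger_join_window,
      decision_pause = decision_pause,
      stop_after_units = stop_after_units
    ),
    class = "gft_condition"
  )
}

#' @export
print.gft_condition <- function(x, ...) {
  cat(sprintf(
    "<gft_condition %s>  F=%d  t=%gs  p=%g  %gs session, G=%d, %d patches\n",
    x$name, x$food_per_patch, x$search_cost, x$success_prob,
    x$session_length, x$group_size, x$n_patches
  ))
  invisible(x)
}

#' Standard condition presets
#'
#' `condition_low_cost()` is the F5-0s condition (searches take 0.01 s, kept
#' strictly positive so event ordering stays well defined); `condition_high_cost()`
#' is F5-8s (eight-second searches). Both use five food units per discovery, a
#' 50% search success probability, four-minute sessions, four players and four
#' patch zones. `condition_pretraining()` is the familiarization phase: a lone
#' forager, one patch, one unit per success, stopping after five collected
#' units; it is excluded from analysis datasets by default.
#'
#' @param ... Overrides passed on to [gft_condition()].
#' @return A `gft_condition`.
#' @export
condition_low_cost <- function(...) {
  override(gft_condition("F5-0s", search_cost = 0.01), ...)
}

#' @rdname condition_low_cost
#' @export
condition_high_cost <- function(...) {
  override(gft_condition("F5-8s", search_cost = 8), ...)
}

#' @rdname condition_low_cost
#' @param search_cost Search cost of the upcoming first condition, seconds.
#' @export
condition_pretraining <- function(search_cost = 0.01, ...) {
  override(
    gft_condition("pretraining",
      food_per_patch = 1, search_cost = search_cost,
      n_patches = 1, stop_after_units = 5
    ),
    ...
  )
}

override <- function(cond, ...) {
  dots <- list(...)
  if (!length(dots)) {
    return(cond)
  }
  bad <- setdiff(names(dots), setdiff(names(cond), "name"))
  if (length(bad) || is.null(names(dots)) || any(!nzchar(names(dots)))) {
    abort_config("unknown condition fields: %s", paste(bad, collapse = ", "))
  }
  args <- utils::modifyList(unclass(cond), dots)
  do.call(gft_condition, args)
}
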