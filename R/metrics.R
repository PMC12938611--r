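#' Producer's index
#'
#' The normalized balance of strategy use:
#' `(producers - scroungers) / (producers + scroungers)`, ranging from 1
#' (pure producer) to -1 (pure scrounger). Undefined when a participant made
#' no response at all (`p + s = 0`); those cases return `NA` and are excluded
#' from downstream statistics rather than imputed as 0, which would bias the
#' medians.
#'
#' @param producers,scroungers Nonnegative response counts (vectorized).
#' @return Numeric vector in `[-1, 1]`, `NA` where undefined.
#' @export
#' @examples
#' producer_index(18, 1) # 17/19
producer_index <- function(producers, scroungers) {
  if (length(producers) != length(scroungers)) {
    abort_validation("`producers` and `scroungers` must have equal length")
  }
  if (any(producers < 0, na.rm = TRUE) || any(scroungers < 0, na.rm = TRUE)) {
    abort_validation("response counts must be nonnegative")
  }
  tot <- producers + scroungers
  ifelse(tot > 0, (producers - scroungers) / tot, NA_real_)
}

#' Tally producer and scrounger responses from an event log
#'
#' A producer response is a successful search whose discoverer goes on to
#' collect at least one unit of its own discovery; a scrounger response is a
#' `join` of another agent's discovery followed by collecting at least one of
#' its units. Joins or successes with zero subsequent collection complete no
#' response and are not counted (configurable via `require_collection`).
#' The two counts come from disjoint event sets by construction.
#'
#' Discoveries are identified from the log alone: at most one discovery is
#' active per patch at a time, so each `join`/`collect` belongs to the most
#' recent `search_success` in its patch.
#'
#' @param log Event-log tibble (one or more sessions).
#' @param participant_id Optional single id to tally; default all agents in
#'   the log.
#' @param require_collection If `FALSE`, every `search_success` / `join`
#'   counts regardless of collection.
#' @return Tibble: `session_id`, `condition`, `participant_id`,
#'   `producer_responses`, `scrounger_responses`, `units_collected`.
#' @export
tally_responses <- function(log, participant_id = NULL, require_collection = TRUE) {
  validate_event_log(log)
  out <- log |>
    dplyr::group_by(.data$session_id, .data$condition) |>
    dplyr::group_modify(~ tally_one(.x, require_collection)) |>
    dplyr::ungroup()
  if (!is.null(participant_id)) {
    if (!participant_id %in% out$participant_id) {
      abort_validation("participant `%s` does not appear in the log", participant_id)
    }
    out <- dplyr::filter(out, .data$participant_id == !!participant_id)
  }
  out
}

tally_one <- function(log, require_collection) {
  agents <- sort(unique(log$agent_id))
  n <- nrow(log)
  prod_n <- scro_n <- units <- stats::setNames(numeric(length(agents)), agents)
  # per patch: index of the live discovery's finder, its collected-by table
  last_finder <- character(0)
  # walk once in time order, keyed by patch
  patches <- unique(log$patch_id[!is.na(log$patch_id)])
  finder <- stats::setNames(rep(NA_character_, length(patches)), patches)
  prod_credited <- stats::setNames(rep(FALSE, length(patches)), patches)
  joiners <- stats::setNames(vector("list", length(patches)), patches)

  for (k in seq_len(n)) {
    ev <- log$event[k]
    p <- as.character(log$patch_id[k])
    who <- log$agent_id[k]
    if (ev == "search_success") {
      finder[p] <- who
      prod_credited[p] <- FALSE
      joiners[[p]] <- character(0)
      if (!require_collection) {
        prod_n[who] <- prod_n[who] + 1
        prod_credited[p] <- TRUE
      }
    } else if (ev == "join") {
      if (!require_collection) {
        scro_n[who] <- scro_n[who] + 1
      } else {
        joiners[[p]] <- union(joiners[[p]], who)
      }
    } else if (ev == "collect") {
      units[who] <- units[who] + log$units[k]
      if (require_collection) {
        if (identical(finder[[p]], who) && !prod_credited[[p]]) {
          prod_n[who] <- prod_n[who] + 1
          prod_credited[p] <- TRUE
        } else if (who %in% joiners[[p]]) {
          scro_n[who] <- scro_n[who] + 1
          joiners[[p]] <- setdiff(joiners[[p]], who)
        }
      }
    }
  }
  tibble::tibble(
    participant_id = agents,
    producer_responses = as.integer(prod_n[agents]),
    scrounger_responses = as.integer(scro_n[agents]),
    units_collected = as.integer(units[agents])
  )
}

#' Summarize event logs into a per-participant foraging table
#'
#' One row per participant and condition with producer/scrounger response
#' counts, units collected, and the producer's index. Undefined indexes
#' (no responses at all) are `NA`, counted in the `n_undefined_index`
#' attribute, and excluded from downstream statistics. If `participants` is
#' given, participant-condition cells absent from the logs are emitted as
#' explicit all-`NA` rows with a warning rather than silently dropped.
#'
#' @param log Event-log tibble covering one or more sessions.
#' @param participants Optional character vector of expected participant ids.
#' @param require_collection Passed to [tally_responses()].
#' @param missing How to treat expected participant-condition cells absent
#'   from the logs: `"na"` (default) marks them missing with a warning —
#'   appropriate when sessions can be lost; `"zero"` records zero counts —
#'   appropriate when the participant is known to have been present but
#'   produced no codable event (simulated sessions).
#' @return Tibble: `participant_id`, `condition`, `producer_responses`,
#'   `scrounger_responses`, `producer_index`, `units_collected`.
#' @export
summarize_foraging <- function(log, participants = NULL, require_collection = TRUE,
                               missing = c("na", "zero")) {
  missing <- match.arg(missing)
  tallies <- tally_responses(log, require_collection = require_collection) |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::summarise(
      producer_responses = sum(.data$producer_responses),
      scrounger_responses = sum(.data$scrounger_responses),
      units_collected = sum(.data$units_collected),
      .groups = "drop"
    )
  if (!is.null(participants)) {
    grid <- tidyr::expand_grid(
      participant_id = as.character(participants),
      condition = unique(log$condition)
    )
    missing_cells <- dplyr::anti_join(grid, tallies, by = c("participant_id", "condition"))
    if (nrow(missing_cells) && missing == "na") {
      rlang::warn(sprintf(
        "summarize_foraging: %d participant-condition cell(s) missing from the logs",
        nrow(missing_cells)
      ))
    }
    tallies <- dplyr::left_join(grid, tallies, by = c("participant_id", "condition"))
    if (missing == "zero") {
      tallies <- tidyr::replace_na(tallies, list(
        producer_responses = 0L, scrounger_responses = 0L, units_collected = 0L
      ))
    }
  }
  out <- tallies |>
    dplyr::mutate(
      producer_index = producer_index(.data$producer_responses, .data$scrounger_responses)
    ) |>
    dplyr::relocate(
      "participant_id", "condition", "producer_responses",
      "scrounger_responses", "producer_index", "units_collected"
    ) |>
    dplyr::arrange(.data$participant_id, .data$condition)
  n_undef <- sum(!is.na(out$producer_responses) &
    out$producer_responses + out$scrounger_responses == 0)
  attr(out, "n_undefined_index") <- n_undef
  out
}
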