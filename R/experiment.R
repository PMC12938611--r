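#' Run a full simulated experiment
#'
#' Partitions a cohort into groups of `group_size`, simulates every group
#' under every condition (order randomized per group when
#' `randomize_order = TRUE`, mirroring a counterbalanced within-subject
#' design), tallies each session into per-participant response counts and
#' producer's indexes, and generates item-level questionnaire responses from
#' the same agents' latent traits. Session randomness is derived from the
#' master `seed` via [session_seed()], so a dataset is fully reproducible
#' from `(cohort, conditions, seed)`.
#'
#' @param cohort Agent tibble from [generate_cohort()]; its size must be an
#'   exact multiple of the conditions' `group_size`.
#' @param conditions List of [gft_condition()]s (all with the same
#'   `group_size`); defaults to the low-cost / high-cost pair.
#' @param randomize_order Randomize per-group condition order?
#' @param questionnaire_noise_sd Item-level noise, see
#'   [generate_questionnaires()].
#' @param keep_logs Keep the raw event logs in the result?
#' @param seed Master seed.
#' @return A `gft_dataset` list with elements `foraging_summary` (one row per
#'   participant and condition), `items` (wide questionnaire responses),
#'   `agents` (the cohort, including latent ground truth), `session_plan`
#'   (group, condition, order, session seed) and optionally `logs`.
#' @export
#' @examples
#' ds <- run_experiment(generate_cohort(8, seed = 1), seed = 1)
#' ds$foraging_summary
run_experiment <- function(cohort,
                           conditions = list(condition_low_cost(), condition_high_cost()),
                           randomize_order = TRUE,
                           questionnaire_noise_sd = 0.7,
                           keep_logs = FALSE,
                           seed = 1L) {
  cohort <- validate_agents(cohort)
  if (!length(conditions) || !all(vapply(conditions, inherits, logical(1), "gft_condition"))) {
    abort_validation("`conditions` must be a non-empty list of `gft_condition`s")
  }
  gs <- vapply(conditions, function(cn) cn$group_size, integer(1))
  if (length(unique(gs)) != 1L) abort_config("all conditions must share one group_size")
  G <- gs[[1]]
  n <- nrow(cohort)
  if (n %% G != 0L) {
    abort_config("cohort of %d cannot be split into full groups of %d", n, G)
  }
  check_number(seed, "seed", integer = TRUE)
  n_groups <- n %/% G
  cond_names <- vapply(conditions, function(cn) cn$name, character(1))
  if (anyDuplicated(cond_names)) abort_config("condition names must be unique")

  assignment <- withr::with_seed(
    session_seed(seed, 0L, 0L),
    sample.int(n)
  )
  plan <- vector("list", n_groups)
  logs <- list()
  summaries <- vector("list", n_groups)

  for (g in seq_len(n_groups)) {
    members <- cohort[assignment[((g - 1L) * G + 1L):(g * G)], , drop = FALSE]
    ord <- if (randomize_order) {
      withr::with_seed(session_seed(seed, g, 0L), sample.int(length(conditions)))
    } else {
      seq_along(conditions)
    }
    glogs <- vector("list", length(conditions))
    for (pos in seq_along(ord)) {
      ci <- ord[pos]
      cn <- conditions[[ci]]
      sseed <- session_seed(seed, g, ci)
      log <- simulate_session(cn, members, seed = sseed)
      log$session_id <- sprintf("g%02d_%s", g, cn$name)
      glogs[[pos]] <- log
    }
    glog <- dplyr::bind_rows(glogs)
    summaries[[g]] <- summarize_foraging(glog, participants = members$agent_id, missing = "zero")
    if (keep_logs) logs[[g]] <- glog
    plan[[g]] <- tibble::tibble(
      group = g,
      condition = cond_names[ord],
      order = seq_along(ord),
      session_seed = vapply(ord, function(ci) session_seed(seed, g, ci), integer(1))
    )
  }

  foraging <- dplyr::bind_rows(summaries) |>
    dplyr::rename(participant_id = "participant_id") |>
    dplyr::arrange(.data$participant_id, .data$condition)
  items <- generate_questionnaires(
    cohort,
    noise_sd = questionnaire_noise_sd,
    seed = session_seed(seed, n_groups + 1L, 0L)
  )

  structure(
    list(
      foraging_summary = foraging,
      items = items,
      agents = cohort,
      session_plan = dplyr::bind_rows(plan),
      conditions = conditions,
      seed = as.integer(seed),
      logs = if (keep_logs) dplyr::bind_rows(logs) else NULL
    ),
    class = "gft_dataset"
  )
}

#' @export
print.gft_dataset <- function(x, ...) {
  cat(sprintf(
    "<gft_dataset>  %d participants x %d conditions (%s), seed %d\n",
    nrow(x$agents), length(x$conditions),
    paste(vapply(x$conditions, function(cn) cn$name, character(1)), collapse = ", "),
    x$seed
  ))
  cat(sprintf(
    "  foraging_summary: %d rows; items: %d x %d\n",
    nrow(x$foraging_summary), nrow(x$items), ncol(x$items) - 1L
  ))
  invisible(x)
}
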