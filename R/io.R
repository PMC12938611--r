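# File interfaces. All delimited text, UTF-8, "." decimal; comma delimiter
# with a tab fallback for regional spreadsheet exports.

read_delim_auto <- function(path, delim = c("comma", "tab")) {
  delim <- match.arg(delim)
  if (!file.exists(path)) abort_config("file not found: %s", path)
  fn <- if (delim == "comma") readr::read_csv else readr::read_tsv
  fn(path, show_col_types = FALSE, progress = FALSE)
}

#' Read and write event logs
#'
#' Event logs are CSV with columns `session_id`, `condition`, `time_s`,
#' `agent_id`, `event`, `patch_id`, `units`.
#'
#' @param log Event-log tibble.
#' @param path File path.
#' @return `read_event_log()` returns a validated tibble;
#'   `write_event_log()` returns `path` invisibly.
#' @export
write_event_log <- function(log, path) {
  validate_event_log(log)
  readr::write_csv(log, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  log <- read_delim_auto(path)
  validate_event_log(log)
  tibble::as_tibble(log)
}

#' Write a simulated dataset to disk
#'
#' Two CSVs sharing `participant_id`: `foraging_summary.csv` and
#' `items.csv`, the same layout [read_dataset()] accepts back.
#'
#' @param dataset A `gft_dataset` from [run_experiment()], or a list with
#'   `foraging_summary` and `items` tibbles.
#' @param dir Output directory (created if missing).
#' @return The two file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!all(c("foraging_summary", "items") %in% names(dataset))) {
    abort_validation("`dataset` must contain `foraging_summary` and `items`")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- file.path(dir, "foraging_summary.csv")
  ip <- file.path(dir, "items.csv")
  readr::write_csv(dataset$foraging_summary, fp, progress = FALSE)
  readr::write_csv(dataset$items, ip, progress = FALSE)
  invisible(c(foraging = fp, items = ip))
}

#' Read a per-participant dataset, optionally through a column map
#'
#' Loads the foraging summary and either raw item responses or pre-scored
#' traits from delimited text files. External deposits rarely share our
#' column names, so `column_map` translates them: a named character vector
#' or list, `c(canonical = "their_name", ...)`. Canonical names are
#' `participant_id`, `condition`, `producer_responses`,
#' `scrounger_responses` (and optionally `producer_index`) for the foraging
#' table, `bfi_1` ... `bfi_44`, `apsd_1` ... `apsd_20` for items, or the
#' scored columns `O`, `C`, `E`, `A`, `N`, `CU`, `IMP`, `NAR`, `apsd_total`
#' for pre-scored input.
#'
#' Rows failing range checks (negative counts; items out of range) are
#' excluded with a logged reason in the `exclusions` attribute — nothing is
#' dropped silently. If `producer_index` is absent it is recomputed from the
#' counts.
#'
#' @param foraging_path CSV/TSV of per-participant, per-condition counts.
#' @param items_path CSV/TSV of raw item responses (or `NULL`).
#' @param scores_path CSV/TSV of pre-scored traits (or `NULL`); exactly one
#'   of `items_path`/`scores_path` must be given.
#' @param column_map Named character vector/list mapping canonical names to
#'   the file's names; unnamed canonical columns are looked up as-is.
#' @param delim `"comma"` (default) or `"tab"`.
#' @return A list (class `gft_dataset`) with `foraging_summary` and `items`
#'   and/or `scores`; exclusions in `attr(, "exclusions")`.
#' @export
read_dataset <- function(foraging_path, items_path = NULL, scores_path = NULL,
                         column_map = NULL, delim = c("comma", "tab")) {
  delim <- match.arg(delim)
  if (is.null(items_path) == is.null(scores_path)) {
    abort_config("give exactly one of `items_path` (raw items) or `scores_path` (pre-scored)")
  }
  cmap <- unlist(column_map)

  rename_canonical <- function(df, required, optional = character(0)) {
    for (canon in c(required, optional)) {
      src <- if (canon %in% names(cmap)) cmap[[canon]] else canon
      if (src %in% names(df)) {
        names(df)[names(df) == src] <- canon
      } else if (!canon %in% names(df) && canon %in% required) {
        # a map entry may only apply to one of the input files; the other
        # file may already use the canonical name
        abort_config("unmapped required column `%s` (looked for `%s`)", canon, src)
      }
    }
    df
  }

  fg <- read_delim_auto(foraging_path, delim) |>
    rename_canonical(
      required = c(
        "participant_id", "condition",
        "producer_responses", "scrounger_responses"
      ),
      optional = c("producer_index", "units_collected")
    )
  bad_fg <- is.na(fg$producer_responses) | is.na(fg$scrounger_responses) |
    fg$producer_responses < 0 | fg$scrounger_responses < 0
  exclusions <- tibble::tibble(
    participant_id = as.character(fg$participant_id[bad_fg]),
    reason = "negative or missing response count"
  )
  fg <- fg[!bad_fg, , drop = FALSE]
  fg$producer_responses <- as.integer(fg$producer_responses)
  fg$scrounger_responses <- as.integer(fg$scrounger_responses)
  if ("units_collected" %in% names(fg)) {
    fg$units_collected <- as.integer(fg$units_collected)
  }
  if (!"producer_index" %in% names(fg) || all(is.na(fg$producer_index))) {
    fg$producer_index <- producer_index(fg$producer_responses, fg$scrounger_responses)
  }
  fg <- dplyr::mutate(fg, participant_id = as.character(.data$participant_id))

  out <- list(foraging_summary = tibble::as_tibble(fg))
  if (!is.null(items_path)) {
    it <- read_delim_auto(items_path, delim) |>
      rename_canonical(
        required = c("participant_id", item_cols("bfi", 44), item_cols("apsd", 20))
      ) |>
      dplyr::mutate(participant_id = as.character(.data$participant_id))
    out$items <- tibble::as_tibble(it)
  } else {
    sc <- read_delim_auto(scores_path, delim) |>
      rename_canonical(
        required = c(
          "participant_id", "O", "C", "E", "A", "N",
          "CU", "IMP", "NAR", "apsd_total"
        ),
        optional = c("stability", "plasticity", "cutoff_class")
      ) |>
      dplyr::mutate(participant_id = as.character(.data$participant_id))
    bad_sc <- !stats::complete.cases(sc[c("O", "C", "E", "A", "N")]) |
      apply(sc[c("O", "C", "E", "A", "N")], 1, function(r) any(r < 1 | r > 5))
    exclusions <- dplyr::bind_rows(exclusions, tibble::tibble(
      participant_id = as.character(sc$participant_id[bad_sc]),
      reason = "trait score missing or outside 1-5"
    ))
    out$scores <- tibble::as_tibble(sc[!bad_sc, , drop = FALSE])
  }
  if (nrow(exclusions)) {
    rlang::inform(sprintf("read_dataset: excluded %d row(s), see attr(, 'exclusions')", nrow(exclusions)))
  }
  attr(out, "exclusions") <- exclusions
  class(out) <- "gft_dataset"
  out
}

#' Complete pre-scored traits for analysis
#'
#' Fills in the metatraits and the cutoff class when a pre-scored input did
#' not carry them, so [run_full_analysis()] can consume it.
#'
#' @param scores Pre-scored tibble with at least `O`-`N`, `CU`, `IMP`,
#'   `NAR`, `apsd_total`.
#' @param threshold Cutoff on `apsd_total` (default 12, threshold-inclusive).
#' @param neuroticism_direction `"neuroticism"` (default) if `N` is scored in
#'   the neurotic direction, `"stability"` if the deposit stores reversed
#'   (emotional-stability-direction) scores; the stability metatrait adapts.
#' @return The completed tibble.
#' @export
complete_scores <- function(scores, threshold = 12L,
                            neuroticism_direction = c("neuroticism", "stability")) {
  neuroticism_direction <- match.arg(neuroticism_direction)
  sc <- tibble::as_tibble(scores)
  n_eff <- if (neuroticism_direction == "stability") 6 - sc$N else sc$N
  if (!"stability" %in% names(sc)) {
    sc$stability <- (sc$C + sc$A + (6 - n_eff)) / 3
  }
  if (!"plasticity" %in% names(sc)) {
    sc$plasticity <- (sc$E + sc$O) / 2
  }
  if (!"cutoff_class" %in% names(sc)) {
    sc$cutoff_class <- factor(
      ifelse(sc$apsd_total >= threshold, "above", "under"),
      levels = c("under", "above")
    )
  } else {
    sc$cutoff_class <- factor(as.character(sc$cutoff_class), levels = c("under", "above"))
  }
  sc
}

#' Write an analysis report to disk
#'
#' Emits each table of a [run_full_analysis()] report as CSV plus a
#' plain-markdown rendering (`report.md`) mirroring the conventional
#' comparison/correlation table layout, and a machine-readable run log
#' (`run_log.yaml`) with seeds and exclusion counts.
#'
#' @param report A `ps_analysis`.
#' @param dir Output directory (created if missing).
#' @return Paths of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "ps_analysis")) abort_validation("`report` must be a `ps_analysis`")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tb in c("condition_comparison", "cutoff_comparison", "correlations", "bootstrap", "gate")) {
    if (nrow(report[[tb]])) {
      p <- file.path(dir, paste0(tb, ".csv"))
      readr::write_csv(report[[tb]], p, progress = FALSE)
      paths <- c(paths, p)
    }
  }
  md <- file.path(dir, "report.md")
  writeLines(render_report_md(report), md)
  lg <- file.path(dir, "run_log.yaml")
  yaml::write_yaml(
    list(
      seed = report$meta$seed,
      conditions = report$meta$conditions,
      n_input = report$meta$n_input,
      n_analyzed = report$meta$n_analyzed,
      n_excluded = nrow(report$meta$exclusions),
      n_above_cutoff = report$meta$n_above_cutoff,
      uncorrected_cells = report$meta$uncorrected_cells,
      notices = report$meta$notices,
      package_version = as.character(utils::packageVersion("psforage"))
    ),
    lg
  )
  invisible(c(paths, md, lg))
}

render_report_md <- function(x) {
  fmt <- function(v, d = 3) formatC(v, digits = d, format = "fg")
  cn <- x$meta$conditions
  out <- c(
    "# Foraging analysis report", "",
    sprintf(
      "n analyzed = %d (of %d; %d excluded). Conditions: %s vs %s.",
      x$meta$n_analyzed, x$meta$n_input, nrow(x$meta$exclusions), cn[1], cn[2]
    ), "",
    sprintf("## Condition comparison (%s vs %s)", cn[1], cn[2]), "",
    sprintf(
      "| Variable | M %s | SD | MDN | M %s | SD | MDN | stat | p | effect |",
      cn[1], cn[2]
    ),
    "|---|---|---|---|---|---|---|---|---|---|"
  )
  for (i in seq_len(nrow(x$condition_comparison))) {
    r <- x$condition_comparison[i, ]
    out <- c(out, sprintf(
      "| %s | %s | %s | %s | %s | %s | %s | %s | %s%s | %s |",
      r$variable, fmt(r$m1), fmt(r$sd1), fmt(r$mdn1), fmt(r$m2), fmt(r$sd2),
      fmt(r$mdn2), fmt(r$statistic), fmt(r$p_value), r$stars, fmt(r$effect)
    ))
  }
  out <- c(out, "", "## Cutoff-group comparison", "")
  if (nrow(x$cutoff_comparison)) {
    out <- c(
      out,
      "| Condition | Variable | MDN under | MDN above | U (under) | U (above) | p |",
      "|---|---|---|---|---|---|---|"
    )
    for (i in seq_len(nrow(x$cutoff_comparison))) {
      r <- x$cutoff_comparison[i, ]
      out <- c(out, sprintf(
        "| %s | %s | %s | %s | %s | %s | %s%s |",
        r$condition, r$variable, fmt(r$mdn_under), fmt(r$mdn_above),
        fmt(r$u_under), fmt(r$u_above), fmt(r$p_value), r$stars
      ))
    }
  } else {
    out <- c(out, "(skipped)", x$meta$notices)
  }
  out <- c(
    out, "", "## Correlations", "",
    "| Pair | r | r^2 | p | n |", "|---|---|---|---|---|"
  )
  for (i in seq_len(nrow(x$correlations))) {
    r <- x$correlations[i, ]
    out <- c(out, sprintf(
      "| %s ~ %s | %s%s | %s | %s | %d |",
      r$var1, r$var2, fmt(r$r), r$stars, fmt(r$r_squared), fmt(r$p_value), r$n
    ))
  }
  out <- c(out, "", sprintf(
    "%d uncorrected cells. * p < 0.05, ** p < 0.01, *** p < 0.001.",
    x$meta$uncorrected_cells
  ))
  if (nrow(x$bootstrap)) {
    out <- c(
      out, "", "## Bootstrap CIs (index-trait correlations)", "",
      "| Condition | Trait | r | lower | upper |", "|---|---|---|---|---|"
    )
    for (i in seq_len(nrow(x$bootstrap))) {
      r <- x$bootstrap[i, ]
      out <- c(out, sprintf(
        "| %s | %s | %s | %s | %s |",
        r$condition, r$trait, fmt(r$estimate), fmt(r$lower), fmt(r$upper)
      ))
    }
  }
  out
}
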