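#' Read a scenario configuration
#'
#' Scenarios are YAML files describing a simulated study: cohort size and
#' couplings, the condition list (fields mirroring [gft_condition()]
#' arguments), questionnaire noise and analysis options. The packaged
#' default scenario (`inst/extdata/default_scenario.yaml`) is the
#' two-condition, 40-participant setup.
#'
#' @param path YAML file; default the packaged scenario.
#' @return A validated scenario list with parsed `gft_condition`s.
#' @export
read_scenario <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_scenario.yaml", package = "psforage")
  }
  if (!file.exists(path)) abort_config("scenario file not found: %s", path)
  sc <- yaml::read_yaml(path)
  if (is.null(sc$cohort$n_participants)) abort_config("scenario must set cohort.n_participants")
  if (is.null(sc$conditions) || !length(sc$conditions)) {
    abort_config("scenario must list at least one condition")
  }
  if (!is.null(sc$cohort$coupling)) {
    # YAML 1.1 reads a bare N key as boolean FALSE; map it back
    names(sc$cohort$coupling)[names(sc$cohort$coupling) %in% c("FALSE", "no")] <- "N"
  }
  sc$conditions <- lapply(sc$conditions, function(cn) {
    if (is.null(cn$name)) abort_config("every condition needs a name")
    do.call(gft_condition, cn)
  })
  sc
}

#' Run the whole simulate-score-analyze chain
#'
#' End-to-end orchestration: generate a cohort from a scenario, simulate the
#' experiment, score the questionnaires, run the full statistical pipeline,
#' and (optionally) write every artifact — dataset CSVs, report tables,
#' markdown rendering and a run log — under `output_dir`. The chain is a
#' pure function of `(scenario, seed)`.
#'
#' @param scenario Scenario list from [read_scenario()] (default: the
#'   packaged scenario).
#' @param seed Master seed.
#' @param output_dir Directory for artifacts, or `NULL` to skip writing.
#' @param B Bootstrap resamples; overrides the scenario's analysis block.
#' @return A list with `dataset` (`gft_dataset`), `scores` and `report`
#'   (`ps_analysis`).
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(seed = 1, B = 100)
#' glance(res$report)
#' }
run_pipeline <- function(scenario = read_scenario(), seed = 1L,
                         output_dir = NULL, B = NULL) {
  coh_args <- scenario$cohort
  coh_args$coupling <- unlist(coh_args$coupling)
  coh_args$seed <- session_seed(seed, 0L, 1L)
  cohort <- do.call(generate_cohort, coh_args)

  dataset <- run_experiment(
    cohort,
    conditions = scenario$conditions,
    randomize_order = isTRUE(scenario$randomize_order),
    questionnaire_noise_sd = scenario$questionnaire_noise_sd %||% 0.7,
    seed = seed
  )
  scores <- score_instruments(
    dataset$items,
    threshold = scenario$analysis$cutoff_threshold %||% 12L
  )
  report <- run_full_analysis(
    dataset$foraging_summary, scores,
    B = B %||% scenario$analysis$bootstrap_B %||% 1000L,
    ci_level = scenario$analysis$ci_level %||% 0.95,
    seed = session_seed(seed, 0L, 2L)
  )
  if (!is.null(output_dir)) {
    write_dataset(dataset, output_dir)
    readr::write_csv(scores, file.path(output_dir, "scores.csv"), progress = FALSE)
    write_report(report, output_dir)
  }
  list(dataset = dataset, scores = scores, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
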