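#' Load a scoring key
#'
#' Item-to-scale keys for the 44-item Big Five Inventory (BFI-44) and the
#' 20-item Antisocial Process Screening Device (APSD). Keys are instrument
#' metadata, not study output, so they ship as editable CSV files
#' (`instrument,item,scale,reverse`) under `inst/extdata/`; the defaults
#' follow the standard published BFI-44 key and the three-factor APSD
#' structure (callous-unemotional CU, impulsivity IMP, narcissism NAR; two
#' APSD items load on no factor and count toward the total only, `scale =
#' "none"`). Point `read_scoring_key()` at your own file to use a divergent
#' translation's key.
#'
#' @param instrument `"bfi"` or `"apsd"`.
#' @param path CSV file with columns `instrument,item,scale,reverse`.
#' @return A tibble key, validated for completeness (every BFI item 1-44 /
#'   APSD item 1-20 present exactly once, each mapped to one scale).
#' @export
scoring_key <- function(instrument = c("bfi", "apsd")) {
  instrument <- match.arg(instrument)
  path <- system.file("extdata", paste0(instrument, "_key.csv"), package = "psforage")
  read_scoring_key(path, instrument)
}

#' @rdname scoring_key
#' @export
read_scoring_key <- function(path, instrument = c("bfi", "apsd")) {
  instrument <- match.arg(instrument)
  if (!file.exists(path)) abort_config("scoring key file not found: %s", path)
  key <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("instrument", "item", "scale", "reverse")
  if (!all(need %in% names(key))) {
    abort_validation("scoring key must have columns %s", paste(need, collapse = ", "))
  }
  n_items <- if (instrument == "bfi") 44L else 20L
  scales <- if (instrument == "bfi") c("O", "C", "E", "A", "N") else c("CU", "IMP", "NAR", "none")
  if (!setequal(key$item, seq_len(n_items)) || nrow(key) != n_items) {
    abort_validation("%s key must contain each item 1-%d exactly once", toupper(instrument), n_items)
  }
  if (!all(key$scale %in% scales)) {
    abort_validation(
      "%s key scales must be among %s", toupper(instrument),
      paste(scales, collapse = ", ")
    )
  }
  key$reverse <- as.logical(key$reverse)
  if (any(is.na(key$reverse))) abort_validation("`reverse` must be TRUE/FALSE")
  dplyr::arrange(tibble::as_tibble(key), .data$item)
}

item_cols <- function(instrument, n) sprintf("%s_%d", instrument, seq_len(n))

# Pull an item-response matrix out of a wide table, flagging participants
# with missing or out-of-range responses. Returns list(mat, excluded).
extract_items <- function(items, prefix, n_items, lo, hi) {
  cols <- item_cols(prefix, n_items)
  miss <- setdiff(cols, names(items))
  if (length(miss)) {
    abort_validation("item table is missing columns: %s", paste(miss, collapse = ", "))
  }
  if (!"participant_id" %in% names(items)) {
    abort_validation("item table needs a `participant_id` column")
  }
  mat <- as.matrix(items[cols])
  storage.mode(mat) <- "double"
  bad <- apply(mat, 1L, function(r) any(is.na(r) | r < lo | r > hi | r != round(r)))
  list(
    mat = mat[!bad, , drop = FALSE],
    ids = as.character(items$participant_id)[!bad],
    excluded = tibble::tibble(
      participant_id = as.character(items$participant_id)[bad],
      reason = sprintf("%s responses missing or outside %d-%d", toupper(prefix), lo, hi)
    )
  )
}

#' Score the Big Five Inventory
#'
#' Computes per-trait mean scores (not raw sums) from 44 item responses on a
#' 1-5 scale. Reverse-keyed items are inverted as `6 - x` before averaging.
#' Participants with missing or out-of-range responses are excluded and
#' reported in the `exclusions` attribute, mirroring the usual
#' incomplete-questionnaire exclusion rule.
#'
#' @param items Wide tibble with `participant_id` and `bfi_1` ... `bfi_44`.
#' @param key BFI scoring key, see [scoring_key()].
#' @return Tibble with `participant_id` and trait means `O`, `C`, `E`, `A`,
#'   `N` (all in `[1, 5]`); excluded participants in `attr(, "exclusions")`.
#' @export
#' @examples
#' ag <- generate_cohort(4, seed = 1)
#' qs <- generate_questionnaires(ag, noise_sd = 0, seed = 1)
#' score_bfi(qs)
score_bfi <- function(items, key = scoring_key("bfi")) {
  ex <- extract_items(items, "bfi", 44L, 1L, 5L)
  mat <- ex$mat
  rev <- key$reverse[match(seq_len(44L), key$item)]
  mat[, rev] <- 6 - mat[, rev]
  out <- tibble::tibble(participant_id = ex$ids)
  for (tr in c("O", "C", "E", "A", "N")) {
    sel <- key$item[key$scale == tr]
    out[[tr]] <- rowMeans(mat[, sel, drop = FALSE])
  }
  if (nrow(ex$excluded)) {
    rlang::inform(sprintf("score_bfi: excluded %d incomplete participant(s)", nrow(ex$excluded)))
  }
  attr(out, "exclusions") <- ex$excluded
  out
}

#' Add the stability and plasticity metatraits
#'
#' The two higher-order composites of the Big Five: stability is the mean of
#' conscientiousness, agreeableness and emotional stability (neuroticism
#' reversed as `6 - N` on the 1-5 mean scale, the only involution consistent
#' with "inverse neuroticism" for averaged scores); plasticity is the mean of
#' extraversion and openness.
#'
#' @param traits Tibble with columns `O`, `C`, `E`, `A`, `N`.
#' @return The input with `stability` and `plasticity` columns added.
#' @export
compute_metatraits <- function(traits) {
  need <- c("O", "C", "E", "A", "N")
  miss <- setdiff(need, names(traits))
  if (length(miss)) abort_validation("missing trait columns: %s", paste(miss, collapse = ", "))
  dplyr::mutate(
    tibble::as_tibble(traits),
    stability = (.data$C + .data$A + (6 - .data$N)) / 3,
    plasticity = (.data$E + .data$O) / 2
  )
}

#' Score the Antisocial Process Screening Device
#'
#' Sums the 20 APSD items (0-2 scale; reverse-keyed items inverted as
#' `2 - x`) into the callous-unemotional (CU), impulsivity (IMP) and
#' narcissism (NAR) factor scores and the overall total (0-40). Participants
#' are classified against the cutoff on the total score: `above` when
#' `total >= threshold` (the conventional 12-point screen is
#' threshold-inclusive), else `under`. Factor scores are sums by default so
#' the total is comparable with the cutoff; `method = "mean"` rescales the
#' factors (not the total) to per-item means for correlation analyses.
#'
#' @param items Wide tibble with `participant_id` and `apsd_1` ... `apsd_20`.
#' @param key APSD scoring key, see [scoring_key()].
#' @param threshold Cutoff on the total score (default 12).
#' @param method `"sum"` (default) or `"mean"` for the factor scores.
#' @return Tibble with `participant_id`, `CU`, `IMP`, `NAR`, `apsd_total`,
#'   `cutoff_class` (factor, levels `under` < `above`); exclusions in
#'   `attr(, "exclusions")`.
#' @export
score_apsd <- function(items, key = scoring_key("apsd"), threshold = 12L,
                       method = c("sum", "mean")) {
  method <- match.arg(method)
  check_number(threshold, "threshold", lo = 0, hi = 40, integer = TRUE)
  ex <- extract_items(items, "apsd", 20L, 0L, 2L)
  mat <- ex$mat
  rev <- key$reverse[match(seq_len(20L), key$item)]
  mat[, rev] <- 2 - mat[, rev]
  out <- tibble::tibble(participant_id = ex$ids)
  for (fac in c("CU", "IMP", "NAR")) {
    sel <- key$item[key$scale == fac]
    s <- rowSums(mat[, sel, drop = FALSE])
    out[[fac]] <- if (method == "mean") s / length(sel) else s
  }
  out$apsd_total <- rowSums(mat)
  out$cutoff_class <- factor(
    ifelse(out$apsd_total >= threshold, "above", "under"),
    levels = c("under", "above")
  )
  if (nrow(ex$excluded)) {
    rlang::inform(sprintf("score_apsd: excluded %d incomplete participant(s)", nrow(ex$excluded)))
  }
  attr(out, "exclusions") <- ex$excluded
  out
}

#' Score both instruments and join the results
#'
#' Convenience wrapper: BFI trait means, metatraits, APSD factors, total and
#' cutoff class in one tibble. Participants excluded from either instrument
#' are dropped from the joined table (listwise), with all exclusions kept in
#' the `exclusions` attribute.
#'
#' @inheritParams score_bfi
#' @param bfi_key,apsd_key Scoring keys.
#' @param threshold APSD cutoff, see [score_apsd()].
#' @return Tibble with `participant_id`, `O`-`N`, `stability`, `plasticity`,
#'   `CU`, `IMP`, `NAR`, `apsd_total`, `cutoff_class`.
#' @export
score_instruments <- function(items, bfi_key = scoring_key("bfi"),
                              apsd_key = scoring_key("apsd"), threshold = 12L) {
  bfi <- compute_metatraits(score_bfi(items, bfi_key))
  apsd <- score_apsd(items, apsd_key, threshold = threshold)
  out <- dplyr::inner_join(bfi, apsd, by = "participant_id")
  attr(out, "exclusions") <- dplyr::bind_rows(
    attr(bfi, "exclusions"), attr(apsd, "exclusions")
  )
  out
}
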