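#' Run the full foraging-personality analysis
#'
#' The complete statistical pipeline over a scored dataset:
#'
#' 1. **Normality gate** — Shapiro-Wilk on every behavioral variable within
#'    each condition; a variable is routed to the nonparametric branch when
#'    any of its condition samples departs from normality (`p < alpha`) or is
#'    constant.
#' 2. **Condition comparison** — producer's index, producer responses and
#'    scrounger responses between the two within-subject conditions:
#'    Wilcoxon signed-rank (`z`, tie-corrected, with the matched-pairs
#'    rank-biserial `r_pb`) on the nonparametric branch, paired t otherwise.
#' 3. **Cutoff comparison** — the same three variables between participants
#'    under vs above the antisociality-screen cutoff, per condition:
#'    Mann-Whitney U (both orientations reported, under-cutoff group first)
#'    or Welch t. Skipped with an explicit notice when a group has fewer
#'    than 2 members.
#' 4. **Correlation matrix** — Pearson r with star tiers over the 13
#'    analysis variables: the producer's index in each condition, the five
#'    traits, the two metatraits, the three screen factors and the screen
#'    total, pairwise-complete. No multiplicity correction is applied (the
#'    matrix reports its uncorrected cell count instead).
#' 5. **Bootstrap** — percentile (or BCa) confidence intervals from `B` case
#'    resamples for every index-trait correlation, per condition.
#'
#' Participants lacking either condition or a scores row are excluded
#' listwise for the comparisons and logged; correlations use pairwise
#' deletion. Undefined producer's indexes (no responses) stay `NA`.
#'
#' @param foraging_summary Tibble from [summarize_foraging()] /
#'   [run_experiment()]: `participant_id`, `condition`, `producer_responses`,
#'   `scrounger_responses`, `producer_index`.
#' @param scores Tibble from [score_instruments()].
#' @param B Bootstrap resamples (`B = 0` skips the bootstrap tables).
#' @param ci_level Bootstrap confidence level.
#' @param boot_method `"percentile"` or `"bca"`.
#' @param alpha Normality-gate and star threshold base level.
#' @param seed Seed driving all bootstrap resampling.
#' @return A `ps_analysis` object: list with `condition_comparison`,
#'   `cutoff_comparison`, `correlations`, `bootstrap`, `gate`, `data`
#'   (the merged wide analysis table) and `meta`. Has [tidy][generics::tidy],
#'   [glance][generics::glance], [ggplot2::autoplot()] and print methods.
#' @export
#' @examples
#' ds <- run_experiment(generate_cohort(8, seed = 1), seed = 1)
#' sc <- score_instruments(ds$items)
#' rep <- run_full_analysis(ds$foraging_summary, sc, B = 50, seed = 1)
#' glance(rep)
run_full_analysis <- function(foraging_summary, scores, B = 1000L, ci_level = 0.95,
                              boot_method = c("percentile", "bca"),
                              alpha = 0.05, seed = 1L) {
  boot_method <- match.arg(boot_method)
  need_f <- c(
    "participant_id", "condition", "producer_responses",
    "scrounger_responses", "producer_index"
  )
  miss <- setdiff(need_f, names(foraging_summary))
  if (length(miss)) {
    abort_validation("`foraging_summary` missing columns: %s", paste(miss, collapse = ", "))
  }
  trait_vars <- c(
    "O", "C", "E", "A", "N", "stability", "plasticity",
    "CU", "IMP", "NAR", "apsd_total"
  )
  miss <- setdiff(c("participant_id", trait_vars, "cutoff_class"), names(scores))
  if (length(miss)) abort_validation("`scores` missing columns: %s", paste(miss, collapse = ", "))

  conds <- unique(as.character(foraging_summary$condition))
  if (length(conds) != 2L) {
    abort_validation("the pipeline compares exactly 2 conditions, found %d", length(conds))
  }
  beh_vars <- c("producer_index", "producer_responses", "scrounger_responses")

  wide <- foraging_summary |>
    dplyr::mutate(participant_id = as.character(.data$participant_id)) |>
    dplyr::select(dplyr::all_of(need_f)) |>
    tidyr::pivot_wider(
      names_from = "condition",
      values_from = dplyr::all_of(beh_vars),
      names_sep = "."
    )
  complete_beh <- stats::complete.cases(
    wide[paste0("producer_responses.", conds)],
    wide[paste0("scrounger_responses.", conds)]
  )
  scores <- dplyr::mutate(scores, participant_id = as.character(.data$participant_id))
  merged <- dplyr::inner_join(wide[complete_beh, ], scores, by = "participant_id")

  exclusions <- dplyr::bind_rows(
    tibble::tibble(
      participant_id = wide$participant_id[!complete_beh],
      reason = "incomplete foraging data (missing condition cell)"
    ),
    tibble::tibble(
      participant_id = setdiff(wide$participant_id[complete_beh], merged$participant_id),
      reason = "no questionnaire scores"
    ),
    tibble::tibble(
      participant_id = setdiff(scores$participant_id, wide$participant_id),
      reason = "no foraging data"
    )
  )
  if (nrow(merged) < 3L) abort_validation("fewer than 3 complete participants")

  # 1. normality gate ----
  gate_grid <- tidyr::expand_grid(variable = beh_vars, condition = conds)
  gate <- dplyr::bind_cols(
    gate_grid,
    purrr::pmap_dfr(gate_grid, function(variable, condition) {
      gate_normality(merged[[paste(variable, condition, sep = ".")]], alpha = alpha)
    })
  )
  route <- gate |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(nonparametric = any(!.data$normal | is.na(.data$W)), .groups = "drop")

  # 2. condition comparison ----
  condition_comparison <- purrr::map_dfr(beh_vars, function(v) {
    x <- merged[[paste(v, conds[1], sep = ".")]]
    y <- merged[[paste(v, conds[2], sep = ".")]]
    ok <- !(is.na(x) | is.na(y))
    nonpar <- route$nonparametric[route$variable == v]
    desc <- tibble::tibble(
      variable = v,
      n = sum(ok),
      m1 = mean(x[ok]), sd1 = stats::sd(x[ok]), mdn1 = stats::median(x[ok]),
      m2 = mean(y[ok]), sd2 = stats::sd(y[ok]), mdn2 = stats::median(y[ok])
    )
    if (nonpar) {
      tst <- ps_wilcoxon(x[ok], y[ok])
      dplyr::mutate(desc,
        method = if (tst$exact) "wilcoxon signed-rank (exact)" else "wilcoxon signed-rank",
        statistic = tst$z, p_value = tst$p_value, effect = tst$r_pb
      )
    } else {
      tt <- stats::t.test(x[ok], y[ok], paired = TRUE)
      dplyr::mutate(desc,
        method = "paired t",
        statistic = unname(tt$statistic), p_value = tt$p.value,
        effect = unname(tt$statistic) / sqrt(sum(ok)) # Cohen's d (paired)
      )
    }
  }) |>
    dplyr::mutate(stars = p_stars(.data$p_value))

  # 3. cutoff comparison ----
  notices <- character(0)
  tab_cut <- table(merged$cutoff_class)
  if (any(tab_cut < 2L)) {
    cutoff_comparison <- tibble::tibble()
    notices <- c(notices, sprintf(
      "cutoff comparison skipped: group sizes under/above = %d/%d (need >= 2 each)",
      tab_cut[["under"]], tab_cut[["above"]]
    ))
  } else {
    cutoff_comparison <- purrr::map_dfr(conds, function(cn) {
      purrr::map_dfr(beh_vars, function(v) {
        val <- merged[[paste(v, cn, sep = ".")]]
        under <- val[merged$cutoff_class == "under" & !is.na(val)]
        above <- val[merged$cutoff_class == "above" & !is.na(val)]
        nonpar <- route$nonparametric[route$variable == v]
        desc <- tibble::tibble(
          condition = cn, variable = v,
          n_under = length(under), n_above = length(above),
          m_under = mean(under), sd_under = stats::sd(under), mdn_under = stats::median(under),
          m_above = mean(above), sd_above = stats::sd(above), mdn_above = stats::median(above)
        )
        if (nonpar) {
          tst <- ps_mann_whitney(under, above)
          dplyr::mutate(desc,
            method = if (tst$exact) "mann-whitney U (exact)" else "mann-whitney U",
            u_under = tst$u1, u_above = tst$u2, statistic = tst$u1,
            p_value = tst$p_value, effect = tst$r_rb
          )
        } else {
          tt <- stats::t.test(under, above)
          dplyr::mutate(desc,
            method = "welch t", u_under = NA_real_, u_above = NA_real_,
            statistic = unname(tt$statistic), p_value = tt$p.value,
            effect = NA_real_
          )
        }
      })
    }) |>
      dplyr::mutate(stars = p_stars(.data$p_value))
  }

  # 4. correlation matrix ----
  idx_vars <- paste0("producer_index.", conds)
  corr_vars <- c(idx_vars, trait_vars)
  correlations <- pearson_matrix(merged, vars = corr_vars)

  # 5. bootstrap CIs for index-trait correlations ----
  if (B > 0L) {
    cells <- tidyr::expand_grid(condition = conds, trait = trait_vars)
    bootstrap <- purrr::pmap_dfr(cells, function(condition, trait) {
      iv <- paste0("producer_index.", condition)
      d <- merged[c(iv, trait)]
      d <- d[stats::complete.cases(d), ]
      ci <- bootstrap_ci(
        d, function(df) stats::cor(df[[1]], df[[2]]),
        B = B, level = ci_level, method = boot_method,
        seed = session_seed(seed, match(condition, conds), match(trait, trait_vars))
      )
      dplyr::bind_cols(tibble::tibble(condition = condition, trait = trait), ci)
    })
  } else {
    bootstrap <- tibble::tibble()
  }

  structure(
    list(
      condition_comparison = condition_comparison,
      cutoff_comparison = cutoff_comparison,
      correlations = correlations,
      bootstrap = bootstrap,
      gate = gate,
      data = merged,
      meta = list(
        conditions = conds,
        n_input = nrow(wide),
        n_analyzed = nrow(merged),
        n_above_cutoff = sum(merged$cutoff_class == "above"),
        exclusions = exclusions,
        n_undefined_index = sum(is.na(merged[idx_vars])),
        uncorrected_cells = nrow(correlations),
        alpha = alpha,
        notices = notices,
        seed = as.integer(seed)
      )
    ),
    class = "ps_analysis"
  )
}

#' @export
print.ps_analysis <- function(x, digits = 3, ...) {
  cn <- x$meta$conditions
  cat(sprintf(
    "<ps_analysis>  n = %d analyzed (%d in, %d excluded), conditions %s vs %s\n\n",
    x$meta$n_analyzed, x$meta$n_input,
    nrow(x$meta$exclusions), cn[1], cn[2]
  ))
  cat(sprintf("Condition comparison (%s vs %s):\n", cn[1], cn[2]))
  print(as.data.frame(x$condition_comparison), digits = digits, row.names = FALSE)
  cat("\nCutoff-group comparison:\n")
  if (nrow(x$cutoff_comparison)) {
    print(
      as.data.frame(x$cutoff_comparison[c(
        "condition", "variable", "mdn_under", "mdn_above",
        "u_under", "u_above", "p_value", "stars"
      )]),
      digits = digits, row.names = FALSE
    )
  } else {
    cat("  (skipped)\n")
  }
  for (msg in x$meta$notices) cat("  note:", msg, "\n")
  cat(sprintf(
    "\nCorrelations: %d uncorrected cells, %d starred at p < %.2f\n",
    x$meta$uncorrected_cells,
    sum(x$correlations$stars != "", na.rm = TRUE), x$meta$alpha
  ))
  cat("  (* p < 0.05, ** p < 0.01, *** p < 0.001; no multiplicity correction)\n")
  if (nrow(x$bootstrap)) {
    cat(sprintf(
      "Bootstrap: %d index-trait CIs at %.0f%% (%s, B = %d)\n",
      nrow(x$bootstrap), 100 * x$bootstrap$level[1],
      x$bootstrap$method[1], max(x$bootstrap$B)
    ))
  }
  invisible(x)
}

#' Tidy a foraging analysis report
#'
#' @param x A `ps_analysis`.
#' @param table Which table to return: `"condition_comparison"`,
#'   `"cutoff_comparison"`, `"correlations"`, `"bootstrap"` or `"gate"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ps_analysis <- function(x, table = c(
                               "condition_comparison", "cutoff_comparison",
                               "correlations", "bootstrap", "gate"
                             ), ...) {
  table <- match.arg(table)
  tibble::as_tibble(x[[table]])
}

#' One-row summary of a foraging analysis report
#'
#' @param x A `ps_analysis`.
#' @param ... Unused.
#' @return One-row tibble with sample sizes, exclusion counts and the number
#'   of significant cells in each table.
#' @export
glance.ps_analysis <- function(x, ...) {
  tibble::tibble(
    n_analyzed = x$meta$n_analyzed,
    n_input = x$meta$n_input,
    n_excluded = nrow(x$meta$exclusions),
    n_above_cutoff = x$meta$n_above_cutoff,
    sig_condition = sum(x$condition_comparison$p_value < x$meta$alpha, na.rm = TRUE),
    sig_cutoff = if (nrow(x$cutoff_comparison)) {
      sum(x$cutoff_comparison$p_value < x$meta$alpha, na.rm = TRUE)
    } else {
      NA_integer_
    },
    sig_correlations = sum(x$correlations$stars != "", na.rm = TRUE),
    uncorrected_cells = x$meta$uncorrected_cells,
    seed = x$meta$seed
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
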