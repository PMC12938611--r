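#' Plot a foraging analysis report
#'
#' @param object A `ps_analysis`.
#' @param type `"conditions"` — behavioral variables by condition;
#'   `"correlations"` — the correlation matrix as a heatmap with star tiers;
#'   `"cutoff"` — producer's index and responses by cutoff group and
#'   condition; `"bootstrap"` — index-trait correlations with bootstrap CIs.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ps_analysis <- function(object, type = c("conditions", "correlations", "cutoff", "bootstrap"),
                                 ...) {
  type <- match.arg(type)
  switch(type,
    conditions = plot_condition_comparison(object),
    correlations = plot_correlation_matrix(object),
    cutoff = plot_cutoff_comparison(object),
    bootstrap = plot_bootstrap_ci(object)
  )
}

report_long_data <- function(x) {
  conds <- x$meta$conditions
  beh <- c("producer_index", "producer_responses", "scrounger_responses")
  cols <- as.vector(outer(beh, conds, paste, sep = "."))
  x$data |>
    dplyr::select(dplyr::all_of(c("participant_id", "cutoff_class", cols))) |>
    tidyr::pivot_longer(dplyr::all_of(cols),
      names_to = c("variable", "condition"), names_sep = "\\.", values_to = "value"
    )
}

#' @rdname autoplot.ps_analysis
#' @param x A `ps_analysis`.
#' @export
plot_condition_comparison <- function(x) {
  report_long_data(x) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~ .data$variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Behavioral variables by condition") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ps_analysis
#' @export
plot_cutoff_comparison <- function(x) {
  report_long_data(x) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$cutoff_class, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::facet_grid(.data$variable ~ .data$condition, scales = "free_y") +
    ggplot2::labs(
      x = "antisociality-screen cutoff group", y = NULL,
      title = "Behavioral variables by cutoff group"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ps_analysis
#' @export
plot_correlation_matrix <- function(x) {
  ord <- rownames(attr(x$correlations, "r_matrix"))
  x$correlations |>
    dplyr::mutate(
      var1 = factor(.data$var1, levels = ord),
      var2 = factor(.data$var2, levels = rev(ord))
    ) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$var1, y = .data$var2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f%s", .data$r, .data$stars)),
      size = 2.6
    ) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white", high = "#2166ac", limits = c(-1, 1)) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "r",
      title = "Correlation matrix",
      subtitle = "* p < 0.05, ** p < 0.01, *** p < 0.001 (uncorrected)"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.ps_analysis
#' @export
plot_bootstrap_ci <- function(x) {
  if (!nrow(x$bootstrap)) abort_validation("report has no bootstrap table (B = 0)")
  x$bootstrap |>
    ggplot2::ggplot(ggplot2::aes(x = .data$estimate, y = .data$trait)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower, xmax = .data$upper)) +
    ggplot2::facet_wrap(~ .data$condition) +
    ggplot2::labs(
      x = "Pearson r (producer's index vs trait)", y = NULL,
      title = sprintf(
        "Bootstrap %.0f%% CIs (%s)",
        100 * x$bootstrap$level[1], x$bootstrap$method[1]
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot rate-maximization predictions over production time
#'
#' @param sweep Tibble from [rmm_sweep()].
#' @return A ggplot object: clamped producer proportion (cost-discounted
#'   form) against production time, one line per finder's share.
#' @export
plot_rmm_sweep <- function(sweep) {
  sweep |>
    dplyr::filter(.data$valid) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$production_time, y = .data$p_cost,
      colour = factor(.data$finder_share),
      group = interaction(.data$finder_share, .data$patch_food, .data$group_size)
    )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::labs(
      x = "production time t (s)", y = "predicted producer proportion P",
      colour = "finder's share a",
      title = "Rate-maximization prediction, cost-discounted"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
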