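#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a positional kernel density
#'
#' @param object A `flex_density` tibble from [positional_density()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flex_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166AC") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "distance to gene start (bp)", y = "probability density") +
    ggplot2::theme_minimal()
}

#' Plot per-word binding preferences
#'
#' Bar chart of Spearman rho per word, the customary presentation for
#' word-level silencer binding preferences (TpA-step enrichment shows as the
#' tallest positive bar).
#'
#' @param object A [binding_preference()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.binding_preference <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$word <- stats::reorder(dat$word, -dat$rho)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$word, y = .data$rho,
                                    fill = .data$rho > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#B2182B", `FALSE` = "#2166AC")) +
    ggplot2::labs(x = NULL, y = "Spearman rho vs recruitment level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot recruitment-level relationships
#'
#' Per-bin mean +/- quartiles of AT% and motif count against mean enrichment
#' fold (requires a binned [recruitment_correlations()] result).
#'
#' @param object A `recruitment_cor` object computed with `bins`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recruitment_cor <- function(object, ...) {
  if (is.null(object$bin_summary)) {
    stop("autoplot needs a binned result; rerun recruitment_correlations() with `bins`",
         call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    object$bin_summary,
    cols = c("at_percent_median", "motif_count_median"),
    names_to = "variable", values_to = "median"
  )
  long$q1 <- ifelse(long$variable == "at_percent_median",
                    object$bin_summary$at_percent_q1[match(long$bin, object$bin_summary$bin)],
                    object$bin_summary$motif_count_q1[match(long$bin, object$bin_summary$bin)])
  long$q3 <- ifelse(long$variable == "at_percent_median",
                    object$bin_summary$at_percent_q3[match(long$bin, object$bin_summary$bin)],
                    object$bin_summary$motif_count_q3[match(long$bin, object$bin_summary$bin)])
  long$variable <- ifelse(long$variable == "at_percent_median",
                          "AT% of central region", "flexible-motif count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                             colour = "#2166AC") +
    ggplot2::facet_wrap(~.data$variable, scales = "free_y") +
    ggplot2::labs(x = "enrichment-fold bin", y = "median (IQR)") +
    ggplot2::theme_minimal()
}

#' Plot target enrichment/depletion by stratum
#'
#' Odds ratios (log scale) with significance from the per-stratum Fisher
#' exact tests.
#'
#' @param object An [enrichment_tests()] result.
#' @param alpha Significance threshold applied to the BH-adjusted p-values.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_tests <- function(object, alpha = 0.05, ...) {
  dat <- tibble::as_tibble(object)
  dat$significant <- dat$p_adj < alpha
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$stratum, y = .data$odds_ratio,
                                    colour = .data$significant,
                                    shape = .data$direction)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#B2182B", `FALSE` = "grey50")) +
    ggplot2::facet_wrap(~.data$stratify_by, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "odds ratio (target vs non-target)") +
    ggplot2::theme_minimal()
}

#' Plot spacer AT% comparisons
#'
#' Group means with standard errors per (sigma factor, context) stratum;
#' group sizes annotate the axis, as is customary for this figure.
#'
#' @param comparison Result of [spacer_at_comparison()].
#' @return A ggplot.
#' @export
plot_spacer_at <- function(comparison) {
  long <- tidyr::pivot_longer(
    comparison,
    cols = c("mean_target", "mean_non_target"),
    names_to = "group", values_to = "mean_at"
  )
  long$se <- ifelse(long$group == "mean_target", long$se_target, long$se_non_target)
  long$n <- ifelse(long$group == "mean_target", long$n_target, long$n_non_target)
  long$group <- ifelse(long$group == "mean_target", "target", "non-target")
  long$label <- paste0(long$group, " (", long$n, ")")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$context, y = .data$mean_at,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_at - .data$se,
                                        ymax = .data$mean_at + .data$se),
                           position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::facet_wrap(~.data$sigma) +
    ggplot2::scale_fill_manual(values = c(target = "#B2182B",
                                          `non-target` = "grey60")) +
    ggplot2::labs(x = NULL, y = "spacer AT%", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot expression by subset and target status
#'
#' Mean log2 expression per conservation subset, split by target status and
#' faceted by condition.
#'
#' @param x An [expression_by_group()] result.
#' @return A ggplot.
#' @export
plot_expression_by_group <- function(x) {
  dat <- x$summary
  dat$group <- ifelse(dat$is_target, "target", "non-target")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$subset, y = .data$mean_log2,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::facet_wrap(~.data$condition) +
    ggplot2::scale_fill_manual(values = c(target = "#B2182B",
                                          `non-target` = "grey60")) +
    ggplot2::labs(x = "conservation subset", y = "mean log2(expression + 1)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
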