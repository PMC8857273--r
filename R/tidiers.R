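#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a preference-vs-genome-deviation fit
#'
#' @param x A `pref_genome_fit` object.
#' @param ... Unused.
#' @return Coefficient-level tibble (`term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`).
#' @export
tidy.pref_genome_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname tidy.pref_genome_fit
#' @return For `glance()`: a one-row tibble with `r.squared`,
#'   `adj.r.squared`, `sigma`, `nobs`.
#' @export
glance.pref_genome_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    nobs = nrow(x$data)
  )
}

#' Tidy recruitment-correlation results
#'
#' @param x A `recruitment_cor` object.
#' @param ... Unused.
#' @return The correlation tibble (`variable`, `scale`, `rho`, `p_value`, `n`).
#' @export
tidy.recruitment_cor <- function(x, ...) x$correlations

#' @rdname tidy.recruitment_cor
#' @export
glance.recruitment_cor <- function(x, ...) {
  raw <- x$correlations[x$correlations$scale == "raw", ]
  tibble::tibble(
    n_peaks = x$n_peaks,
    rho_at = raw$rho[raw$variable == "at_percent"],
    rho_motif = raw$rho[raw$variable == "motif_count"],
    n_bins = if (is.null(x$bin_summary)) NA_integer_ else nrow(x$bin_summary)
  )
}

#' Tidy a per-word binding-preference table
#'
#' @param x A `binding_preference` object.
#' @param ... Unused.
#' @return The table as a plain tibble, strongest positive rho first.
#' @export
tidy.binding_preference <- function(x, ...) {
  out <- tibble::as_tibble(x)
  dplyr::arrange(out, dplyr::desc(.data$rho))
}

#' @rdname tidy.binding_preference
#' @export
glance.binding_preference <- function(x, ...) {
  ord <- order(-x$rho)
  tibble::tibble(
    k = attr(x, "k"),
    n_words = nrow(x),
    top_word = x$word[ord[1]],
    top_rho = x$rho[ord[1]],
    rank_TA = if ("TA" %in% x$word) match("TA", x$word[ord]) else NA_integer_
  )
}

#' Tidy grouped-expression results
#'
#' @param x An `expr_by_group` object.
#' @param ... Unused.
#' @return The target-vs-non-target test tibble.
#' @export
tidy.expr_by_group <- function(x, ...) x$target_tests

#' @rdname tidy.expr_by_group
#' @export
glance.expr_by_group <- function(x, ...) {
  tibble::tibble(
    n_strata = nrow(x$target_tests),
    n_positive_delta = sum(x$target_tests$delta > 0, na.rm = TRUE),
    mutant_delta = if (is.null(x$mutant_contrast)) NA_real_ else x$mutant_contrast$delta,
    mutant_p = if (is.null(x$mutant_contrast)) NA_real_ else x$mutant_contrast$p_value
  )
}
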