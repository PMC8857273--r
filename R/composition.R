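#' AT percentage of DNA sequences
#'
#' `100 * (A + T) / (A + C + G + T)`, computed over unambiguous bases only:
#' `N` counts toward neither numerator nor denominator, so assembly gaps do
#' not bias composition.
#'
#' @param seq Character vector of DNA strings (ACGTN).
#' @return Numeric vector in `[0, 100]`.
#' @export
at_percent <- function(seq) {
  seq <- toupper(seq)
  n_at <- nchar(gsub("[^AT]", "", seq))
  n_acgt <- nchar(gsub("[^ACGT]", "", seq))
  if (any(n_acgt == 0)) {
    stop("sequence(s) contain no unambiguous bases; AT% undefined", call. = FALSE)
  }
  100 * n_at / n_acgt
}

# Overlapping k-mer counts of one sequence over the ACGT alphabet,
# non-circular. Windows containing N are not counted.
count_words <- function(seq, k) {
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                 width = k)
  counts[order(names(counts))]
}

#' Zero-order-Markov oligonucleotide usage deviation
#'
#' For each word `W` of length `k`, the deviation is the observed count of
#' `W` (overlapping, non-circular windows) divided by its expected count
#' under a zero-order Markov model: `(L - k + 1) * prod(f(W_i))`, with `f`
#' the mononucleotide frequencies of the sequence itself (N-free). Dividing
#' by this expectation removes biases in mononucleotide composition, so
#' deviations isolate word-level (e.g. dinucleotide-step) preferences. A word
#' whose expectation is zero (an absent base) is reported `NA`.
#'
#' @param seq A single DNA string.
#' @param k Word length; one of 2, 3, 4.
#' @param region_id Optional label carried into the output.
#' @return A tibble `region_id`, `word`, `observed`, `expected`, `deviation`
#'   with `4^k` rows in alphabetical word order.
#' @export
oligo_deviation <- function(seq, k, region_id = "region") {
  if (!k %in% 2:4) stop("k must be 2, 3 or 4", call. = FALSE)
  seq <- toupper(seq)
  if (nchar(seq) < k) stop("sequence shorter than k", call. = FALSE)
  observed <- count_words(seq, k)
  words <- names(observed)
  mono <- count_words(seq, 1)
  f <- mono / sum(mono)
  windows <- nchar(seq) - k + 1
  word_mat <- do.call(rbind, strsplit(words, "", fixed = TRUE))
  expected <- windows * apply(matrix(f[word_mat], nrow = length(words)), 1, prod)
  tibble::tibble(
    region_id = region_id,
    word = words,
    observed = as.numeric(observed),
    expected = as.numeric(expected),
    deviation = ifelse(expected > 0, observed / expected, NA_real_)
  )
}

#' Genome-wide oligonucleotide usage deviation
#'
#' Pools observed word counts across replicons (windows never span replicon
#' boundaries) and computes expectations from genome-wide mononucleotide
#' frequencies.
#'
#' @param genome Genome (see [read_genome()]).
#' @inheritParams oligo_deviation
#' @return A tibble as in [oligo_deviation()], `region_id = "genome"`.
#' @export
oligo_deviation_genome <- function(genome, k) {
  if (!k %in% 2:4) stop("k must be 2, 3 or 4", call. = FALSE)
  seqs <- as_genome_chr(genome)
  obs_list <- lapply(seqs, count_words, k = k)
  observed <- Reduce(`+`, obs_list)
  words <- names(observed)
  mono <- Reduce(`+`, lapply(seqs, count_words, k = 1))
  f <- mono / sum(mono)
  windows <- sum(pmax(nchar(seqs) - k + 1, 0))
  word_mat <- do.call(rbind, strsplit(words, "", fixed = TRUE))
  expected <- windows * apply(matrix(f[word_mat], nrow = length(words)), 1, prod)
  tibble::tibble(
    region_id = "genome",
    word = words,
    observed = as.numeric(observed),
    expected = as.numeric(expected),
    deviation = ifelse(expected > 0, observed / expected, NA_real_)
  )
}

#' Per-word binding preference from peak composition
#'
#' For every word of length `k`, the Spearman rank correlation (average-rank
#' ties) across peaks between the word's usage deviation in the peak's
#' central region and the peak's enrichment fold — a proxy for protein
#' occupancy. A positive rho marks words over-used in strongly bound regions;
#' for AT-rich-binding silencers the TpA step typically ranks highest.
#'
#' @param peak_regions Tibble with columns `peak_id` (or `region_id`), `seq`
#'   and `enrichment_fold`.
#' @param k Word length (2, 3 or 4).
#' @param adjust Apply Benjamini-Hochberg correction across the `4^k` words
#'   (default `FALSE`; the raw values are always reported).
#' @return A tibble `word`, `rho`, `p_value`, `n` (pairs used), plus `p_adj`
#'   when `adjust = TRUE`; class `binding_preference`.
#' @export
binding_preference <- function(peak_regions, k = 2, adjust = FALSE) {
  id_col <- if ("peak_id" %in% names(peak_regions)) "peak_id" else "region_id"
  assert_cols(peak_regions, c(id_col, "seq", "enrichment_fold"), "peak regions")
  if (nrow(peak_regions) < 3) stop("need at least 3 peaks", call. = FALSE)
  fold <- peak_regions$enrichment_fold
  if (stats::sd(fold) == 0) {
    stop("enrichment fold is constant across peaks; rho undefined", call. = FALSE)
  }
  dev_tbl <- purrr::map2_dfr(
    peak_regions$seq, peak_regions[[id_col]],
    function(s, id) oligo_deviation(s, k, region_id = id)
  )
  dev_wide <- tidyr::pivot_wider(
    dplyr::select(dev_tbl, "region_id", "word", "deviation"),
    names_from = "word", values_from = "deviation"
  )
  dev_wide <- dev_wide[match(peak_regions[[id_col]], dev_wide$region_id), ]
  words <- sort(setdiff(names(dev_wide), "region_id"))
  res <- purrr::map_dfr(words, function(w) {
    x <- dev_wide[[w]]
    ok <- !is.na(x)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0) {
      return(tibble::tibble(word = w, rho = NA_real_, p_value = NA_real_,
                            n = sum(ok)))
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], fold[ok], method = "spearman"))
    tibble::tibble(word = w, rho = unname(ct$estimate),
                   p_value = ct$p.value, n = sum(ok))
  })
  if (adjust) res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  class(res) <- c("binding_preference", class(res))
  attr(res, "k") <- k
  res
}

#' Regress binding preference on genome-wide usage deviation
#'
#' Ordinary least squares of per-word Spearman rho (from
#' [binding_preference()]) on the genome-wide usage deviation of the same
#' words. A strong linear relation indicates that the protein's word
#' preferences mirror what the genome itself under- or over-uses.
#'
#' @param preferences A [binding_preference()] result.
#' @param genome_deviation An [oligo_deviation_genome()] table of the same `k`.
#' @return An object of class `pref_genome_fit` with [generics::tidy()] and
#'   [generics::glance()] methods; `glance()` reports `r.squared`.
#' @export
preference_vs_genome_deviation <- function(preferences, genome_deviation) {
  joined <- dplyr::inner_join(
    dplyr::select(preferences, "word", "rho"),
    dplyr::select(genome_deviation, "word", "deviation"),
    by = "word"
  )
  joined <- joined[stats::complete.cases(joined), ]
  if (nrow(joined) < 3) stop("fewer than 3 words with data", call. = FALSE)
  fit <- stats::lm(rho ~ deviation, data = joined)
  structure(
    list(model = fit, data = joined,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared),
    class = "pref_genome_fit"
  )
}

#' @export
print.pref_genome_fit <- function(x, ...) {
  cat("<pref_genome_fit> rho ~ genome deviation over", nrow(x$data), "words\n")
  cat(sprintf("  slope = %.4f  intercept = %.4f  R^2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Recruitment level versus AT content and motif count
#'
#' Pearson correlation (with p-value) of peak enrichment fold against AT% of
#' the central region and against flexible-motif count. When `bins` (fold bin
#' edges) are provided the correlations are additionally computed on bin
#' means, matching the binned box-plot presentation common for this analysis;
#' per-bin medians and quartiles are emitted for plotting.
#'
#' @param peaks Tibble with `at_percent`, `motif_count`, `enrichment_fold`.
#' @param bins Optional increasing numeric vector of fold bin edges (a final
#'   `Inf` is appended if absent); `NULL` for raw-peak correlations only.
#' @return An object of class `recruitment_cor` with `tidy()`/`glance()`
#'   methods; components `correlations` (tibble: `variable`, `scale`, `rho`,
#'   `p_value`, `n`) and `bin_summary`.
#' @export
recruitment_correlations <- function(peaks, bins = NULL) {
  assert_cols(peaks, c("at_percent", "motif_count", "enrichment_fold"), "peaks")
  if (nrow(peaks) < 3) stop("need at least 3 peaks", call. = FALSE)
  raw_cor <- function(v) {
    ct <- stats::cor.test(peaks[[v]], peaks$enrichment_fold, method = "pearson")
    tibble::tibble(variable = v, scale = "raw", rho = unname(ct$estimate),
                   p_value = ct$p.value, n = nrow(peaks))
  }
  correlations <- dplyr::bind_rows(raw_cor("at_percent"), raw_cor("motif_count"))
  bin_summary <- NULL
  if (!is.null(bins)) {
    if (is.unsorted(bins, strictly = TRUE)) stop("bins must be strictly increasing", call. = FALSE)
    if (is.finite(bins[length(bins)])) bins <- c(bins, Inf)
    peaks$.bin <- cut(peaks$enrichment_fold, breaks = bins, right = FALSE)
    empty <- setdiff(levels(peaks$.bin), unique(as.character(peaks$.bin)))
    if (length(empty)) warning("empty fold bin(s) dropped: ", paste(empty, collapse = ", "))
    bin_summary <- peaks |>
      dplyr::filter(!is.na(.data$.bin)) |>
      dplyr::group_by(bin = .data$.bin) |>
      dplyr::summarise(
        n = dplyr::n(),
        fold_mean = mean(.data$enrichment_fold),
        dplyr::across(c("at_percent", "motif_count"),
                      list(mean = mean, median = stats::median,
                           q1 = ~stats::quantile(.x, .25),
                           q3 = ~stats::quantile(.x, .75))),
        .groups = "drop"
      )
    if (nrow(bin_summary) >= 3) {
      bin_cor <- function(v) {
        ct <- stats::cor.test(bin_summary[[paste0(v, "_mean")]],
                              bin_summary$fold_mean, method = "pearson")
        tibble::tibble(variable = v, scale = "binned", rho = unname(ct$estimate),
                       p_value = ct$p.value, n = nrow(bin_summary))
      }
      correlations <- dplyr::bind_rows(correlations, bin_cor("at_percent"),
                                       bin_cor("motif_count"))
    }
  }
  structure(list(correlations = correlations, bin_summary = bin_summary,
                 n_peaks = nrow(peaks)),
            class = "recruitment_cor")
}

#' @export
print.recruitment_cor <- function(x, ...) {
  cat("<recruitment_cor>", x$n_peaks, "peaks\n")
  print(x$correlations)
  invisible(x)
}
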