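#' Read an ortholog-cluster membership table
#'
#' Expected TSV columns: `gene_id`, `cluster_id`, `strains` (comma-separated
#' strain ids present in the cluster). Clustering itself (e.g. CD-HIT at 70%
#' identity) is upstream of this package; its output is consumed here.
#'
#' @param path Path to the TSV.
#' @return A tibble with a list-column `strains`.
#' @export
read_clusters <- function(path) {
  if (!file.exists(path)) stop("cluster table not found: ", path, call. = FALSE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(tbl, c("gene_id", "cluster_id", "strains"), "cluster table")
  tbl$strains <- strsplit(as.character(tbl$strains), ",", fixed = TRUE)
  if (anyDuplicated(tbl$gene_id)) {
    stop("each focal-genome gene may appear at most once in the cluster table",
         call. = FALSE)
  }
  tbl
}

#' Assign genes to hierarchical pangenome conservation subsets
#'
#' Subsets are defined top-down on the strain sets spanned by each gene's
#' ortholog cluster: subset I (genus core) iff the cluster spans every genus
#' strain; else II (species core) iff it spans every species strain; else III
#' iff it spans every closely-related strain; else IV (strain-specific).
#' Genes absent from the cluster table are assigned IV with a warning —
#' strain-specific by absence of orthologs.
#'
#' @param clusters Cluster tibble (see [read_clusters()]), or any tibble with
#'   `gene_id` and list-column `strains`.
#' @param strain_groups A list with elements `genus`, `species`, `close`
#'   (character vectors of strain ids) and `focal` (single id), satisfying
#'   `focal %in% close`, `close <= species <= genus` (set inclusion).
#' @param gene_ids Optional full focal gene universe; defaults to the genes
#'   in `clusters`.
#' @return A tibble `gene_id`, `subset` (factor I/II/III/IV).
#' @export
assign_subsets <- function(clusters, strain_groups, gene_ids = NULL) {
  for (nm in c("genus", "species", "close", "focal")) {
    if (is.null(strain_groups[[nm]])) {
      stop("strain_groups must contain `", nm, "`", call. = FALSE)
    }
  }
  g <- strain_groups
  if (!(g$focal %in% g$close) || !all(g$close %in% g$species) ||
      !all(g$species %in% g$genus)) {
    stop("require focal %in% close, close <= species <= genus", call. = FALSE)
  }
  gene_ids <- gene_ids %||% clusters$gene_id
  idx <- match(gene_ids, clusters$gene_id)
  missing <- is.na(idx)
  if (any(missing)) {
    warning(sum(missing), " gene(s) absent from the cluster table assigned ",
            "subset IV (no detectable orthologs)")
  }
  subset <- vapply(idx, function(i) {
    if (is.na(i)) return("IV")
    strains <- clusters$strains[[i]]
    if (all(g$genus %in% strains)) "I"
    else if (all(g$species %in% strains)) "II"
    else if (all(g$close %in% strains)) "III"
    else "IV"
  }, character(1))
  tibble::tibble(gene_id = gene_ids,
                 subset = factor(subset, levels = c("I", "II", "III", "IV")))
}

#' Target enrichment/depletion by replicon or conservation subset
#'
#' For every stratum (each replicon, or each subset), a two-sided Fisher
#' exact test on the 2x2 table (in stratum vs out) x (target vs non-target).
#' Benjamini-Hochberg-adjusted p-values are reported alongside the raw ones,
#' within each stratification family.
#'
#' @param targets Character vector of target gene ids (subset of `genes`).
#' @param genes Gene-model tibble; needs `replicon_id` and/or `subset`.
#' @param stratify_by `"replicon"`, `"subset"`, or both (default both where
#'   available).
#' @return A tibble: `stratify_by`, `stratum`, `n_stratum`,
#'   `n_target_in_stratum`, `odds_ratio`, `p_value`, `p_adj`, `direction`.
#' @export
enrichment_tests <- function(targets, genes,
                             stratify_by = c("replicon", "subset")) {
  stratify_by <- match.arg(stratify_by, several.ok = TRUE)
  if (!all(targets %in% genes$gene_id)) {
    stop("targets must be a subset of the gene universe", call. = FALSE)
  }
  is_target <- genes$gene_id %in% targets
  one_family <- function(fam) {
    col <- if (fam == "replicon") "replicon_id" else "subset"
    assert_cols(genes, col, "gene table")
    strata <- unique(as.character(genes[[col]]))
    res <- purrr::map_dfr(strata, function(st) {
      in_st <- as.character(genes[[col]]) == st
      if (!any(in_st)) return(NULL)
      tab <- matrix(c(sum(in_st & is_target), sum(in_st & !is_target),
                      sum(!in_st & is_target), sum(!in_st & !is_target)),
                    nrow = 2)
      ft <- stats::fisher.test(tab, alternative = "two.sided")
      tibble::tibble(
        stratify_by = fam, stratum = st,
        n_stratum = sum(in_st), n_target_in_stratum = sum(in_st & is_target),
        odds_ratio = unname(ft$estimate), p_value = ft$p.value,
        direction = ifelse(unname(ft$estimate) > 1, "enriched", "depleted")
      )
    })
    res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
    res
  }
  out <- dplyr::bind_rows(lapply(stratify_by, one_family))
  class(out) <- c("enrichment_tests", class(out))
  out
}

#' Per-gene AT percentage over the annotated coding span
#'
#' AT% of the coding span is strand-symmetric, so the forward-strand sequence
#' is used.
#'
#' @param genes Gene-model tibble.
#' @param genome Genome (see [read_genome()]).
#' @return `genes` with an `at_percent` column.
#' @export
gene_at_percent <- function(genes, genome) {
  assert_cols(genes, c("gene_id", "replicon_id", "start", "end"), "gene table")
  seqs <- extract_interval(genome, genes$replicon_id, genes$start, genes$end, "+")
  dplyr::mutate(genes, at_percent = at_percent(seqs))
}

#' Gene AT% by replicon/subset and target status
#'
#' Group means and standard errors of per-gene AT%, per stratum (each
#' replicon and each subset) split by target status, with two Welch t-tests
#' per stratum: targets versus all genes of the stratum (the "stratum
#' average" comparison customary in these figures) and targets versus
#' non-targets.
#'
#' @param genes Gene-model tibble (with `subset` where available).
#' @param genome Genome.
#' @param targets Character vector of target gene ids.
#' @param stratify_by `"replicon"`, `"subset"`, or both.
#' @return A tibble per stratum with group summaries and test results.
#' @export
at_by_group <- function(genes, genome, targets,
                        stratify_by = c("replicon", "subset")) {
  stratify_by <- match.arg(stratify_by, several.ok = TRUE)
  per_gene <- gene_at_percent(genes, genome)
  per_gene$is_target <- per_gene$gene_id %in% targets
  one_family <- function(fam) {
    col <- if (fam == "replicon") "replicon_id" else "subset"
    assert_cols(per_gene, col, "gene table")
    per_gene |>
      dplyr::group_by(stratum = as.character(.data[[col]])) |>
      dplyr::summarise(
        stratify_by = fam,
        n_genes = dplyr::n(),
        n_target = sum(.data$is_target),
        mean_all = mean(.data$at_percent),
        se_all = stats::sd(.data$at_percent) / sqrt(dplyr::n()),
        mean_target = mean(.data$at_percent[.data$is_target]),
        mean_non_target = mean(.data$at_percent[!.data$is_target]),
        t_vs_all = welch_or_na(.data$at_percent[.data$is_target],
                               .data$at_percent, "statistic"),
        p_vs_all = welch_or_na(.data$at_percent[.data$is_target],
                               .data$at_percent, "p.value"),
        t_vs_non_target = welch_or_na(.data$at_percent[.data$is_target],
                                      .data$at_percent[!.data$is_target],
                                      "statistic"),
        p_vs_non_target = welch_or_na(.data$at_percent[.data$is_target],
                                      .data$at_percent[!.data$is_target],
                                      "p.value"),
        .groups = "drop"
      ) |>
      dplyr::relocate("stratify_by")
  }
  dplyr::bind_rows(lapply(stratify_by, one_family))
}

welch_or_na <- function(x, y, what) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  tt <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
  if (is.null(tt)) return(NA_real_)
  if (what == "statistic") unname(tt$statistic) else tt$p.value
}

#' Expression by subset, target status and condition
#'
#' Descriptive integration of an expression table with target status and
#' conservation subsets: per (subset, target status, condition) mean and
#' median expression; a Welch t-test of target versus non-target within each
#' (subset, condition); and, when a wild-type/mutant condition pair is named,
#' the paired contrast of target-gene expression between the two strains.
#' No differential-expression calling is performed.
#'
#' @param expr Long expression tibble (`gene_id`, `condition`, `expression`).
#' @param genes Gene tibble with `subset` (see [assign_subsets()]).
#' @param targets Character vector of target gene ids.
#' @param mutant_vs_wt Optional named character vector
#'   `c(wt = "<label>", mutant = "<label>")` naming two condition labels.
#' @param log_scale Test on `log2(x + 1)` (default `TRUE`; expression spans
#'   decades).
#' @return A list of class `expr_by_group`: `summary`, `target_tests`, and
#'   `mutant_contrast` (`NULL` unless requested).
#' @export
expression_by_group <- function(expr, genes, targets, mutant_vs_wt = NULL,
                                log_scale = TRUE) {
  assert_cols(expr, c("gene_id", "condition", "expression"), "expression table")
  assert_cols(genes, c("gene_id", "subset"), "gene table")
  dat <- dplyr::inner_join(expr, dplyr::select(genes, "gene_id", "subset"),
                           by = "gene_id")
  dat$is_target <- dat$gene_id %in% targets
  dat$y <- if (log_scale) log2(dat$expression + 1) else dat$expression
  if (!is.null(mutant_vs_wt)) {
    bad <- setdiff(unname(mutant_vs_wt), unique(dat$condition))
    if (length(bad)) {
      stop("unknown condition label(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  summary <- dat |>
    dplyr::group_by(.data$subset, .data$is_target, .data$condition) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_expression = mean(.data$expression),
                     median_expression = stats::median(.data$expression),
                     mean_log2 = mean(log2(.data$expression + 1)),
                     .groups = "drop")
  target_tests <- dat |>
    dplyr::group_by(.data$subset, .data$condition) |>
    dplyr::summarise(
      n_target = sum(.data$is_target),
      n_non_target = sum(!.data$is_target),
      delta = mean(.data$y[.data$is_target]) - mean(.data$y[!.data$is_target]),
      t_statistic = welch_or_na(.data$y[.data$is_target],
                                .data$y[!.data$is_target], "statistic"),
      p_value = welch_or_na(.data$y[.data$is_target],
                            .data$y[!.data$is_target], "p.value"),
      .groups = "drop"
    )
  mutant_contrast <- NULL
  if (!is.null(mutant_vs_wt)) {
    tg <- dat[dat$is_target & dat$condition %in% unname(mutant_vs_wt), ]
    wide <- tidyr::pivot_wider(
      dplyr::select(tg, "gene_id", "subset", "condition", "y"),
      names_from = "condition", values_from = "y"
    )
    wt <- wide[[mutant_vs_wt[["wt"]]]]
    mu <- wide[[mutant_vs_wt[["mutant"]]]]
    ok <- stats::complete.cases(wt, mu)
    tt <- stats::t.test(mu[ok], wt[ok], paired = TRUE)
    mutant_contrast <- tibble::tibble(
      n_genes = sum(ok),
      mean_wt = mean(wt[ok]), mean_mutant = mean(mu[ok]),
      delta = mean(mu[ok] - wt[ok]),
      t_statistic = unname(tt$statistic), p_value = tt$p.value,
      scale = if (log_scale) "log2(x+1)" else "linear"
    )
  }
  structure(list(summary = summary, target_tests = target_tests,
                 mutant_contrast = mutant_contrast),
            class = "expr_by_group")
}

#' @export
print.expr_by_group <- function(x, ...) {
  cat("<expr_by_group>\n")
  print(x$target_tests)
  if (!is.null(x$mutant_contrast)) {
    cat("mutant vs wild-type contrast (target genes):\n")
    print(x$mutant_contrast)
  }
  invisible(x)
}

#' Conservation-subset composition of targets by recruitment level
#'
#' Bins merged peaks by enrichment fold and, within each bin, reports the
#' fraction of associated target genes in each conservation subset, plus a
#' Spearman trend of the genus-core (subset I) fraction against the bin
#' midpoint. A negative trend indicates that strongly bound targets skew
#' towards less conserved genes.
#'
#' @param peaks Merged-peak tibble.
#' @param assignments Target-assignment tibble ([assign_targets()]).
#' @param genes Gene tibble with `subset`.
#' @param bins Fold bin edges (default `c(1, 2, 5, 10, Inf)`).
#' @return A list of class `recruitment_conservation`: `bin_composition`
#'   (tibble bin x subset fractions) and `trend` (subset-I rho and p).
#' @export
recruitment_by_conservation <- function(peaks, assignments, genes,
                                        bins = c(1, 2, 5, 10, Inf)) {
  assert_cols(peaks, c("peak_id", "enrichment_fold"), "merged peaks")
  assert_cols(assignments, c("gene_id", "peak_id"), "assignments")
  dat <- assignments |>
    dplyr::inner_join(dplyr::select(peaks, "peak_id", "enrichment_fold"),
                      by = "peak_id") |>
    dplyr::inner_join(dplyr::select(genes, "gene_id", "subset"), by = "gene_id")
  if (is.finite(bins[length(bins)])) bins <- c(bins, Inf)
  dat$bin <- cut(dat$enrichment_fold, breaks = bins, right = FALSE)
  dat <- dat[!is.na(dat$bin), ]
  mids <- (utils::head(bins, -1) + pmin(utils::tail(bins, -1),
                                        max(dat$enrichment_fold))) / 2
  names(mids) <- levels(dat$bin)
  comp <- dat |>
    dplyr::count(.data$bin, .data$subset, .drop = FALSE) |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(n_bin = sum(.data$n),
                  fraction = ifelse(.data$n_bin > 0, .data$n / .data$n_bin, NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_bin > 0) |>
    dplyr::mutate(bin_midpoint = mids[as.character(.data$bin)])
  s1 <- comp[comp$subset == "I", ]
  trend <- if (nrow(s1) >= 3 && stats::sd(s1$fraction) > 0) {
    ct <- suppressWarnings(stats::cor.test(s1$bin_midpoint, s1$fraction,
                                           method = "spearman"))
    tibble::tibble(subset = "I", rho = unname(ct$estimate), p_value = ct$p.value,
                   n_bins = nrow(s1))
  } else {
    tibble::tibble(subset = "I", rho = NA_real_, p_value = NA_real_,
                   n_bins = nrow(s1))
  }
  structure(list(bin_composition = comp, trend = trend),
            class = "recruitment_conservation")
}

#' @export
print.recruitment_conservation <- function(x, ...) {
  cat("<recruitment_conservation>\n")
  print(x$trend)
  invisible(x)
}
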