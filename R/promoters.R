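#' Build a position-specific scoring matrix from aligned sites
#'
#' Column probabilities are `(count + pseudocount) / (n + 4 * pseudocount)`;
#' scores are `log2(probability / background)`. Deterministic.
#'
#' @param aligned_sites Character vector of equal-length ACGT strings (>= 2).
#' @param pseudocount Added to every cell (default 0.5).
#' @param background Named mononucleotide background frequencies summing to 1
#'   (default uniform).
#' @return A `4 x w` log-odds matrix (rows A, C, G, T) with the probability
#'   matrix in `attr(, "probs")` and the training sites in
#'   `attr(, "training_sites")`.
#' @export
build_pssm <- function(aligned_sites, pseudocount = 0.5,
                       background = c(A = .25, C = .25, G = .25, T = .25)) {
  if (length(aligned_sites) < 2) stop("need at least 2 training sites", call. = FALSE)
  aligned_sites <- toupper(aligned_sites)
  w <- unique(nchar(aligned_sites))
  if (length(w) != 1) stop("training sites must have equal length", call. = FALSE)
  if (any(grepl("[^ACGT]", aligned_sites))) {
    stop("training sites must be over ACGT", call. = FALSE)
  }
  background <- background[DNA_BASES]
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1", call. = FALSE)
  mat <- do.call(rbind, strsplit(aligned_sites, "", fixed = TRUE))
  counts <- vapply(seq_len(w), function(j) {
    tab <- table(factor(mat[, j], levels = DNA_BASES))
    as.numeric(tab)
  }, numeric(4))
  rownames(counts) <- DNA_BASES
  probs <- (counts + pseudocount) / (length(aligned_sites) + 4 * pseudocount)
  scores <- log2(probs / background)
  attr(scores, "probs") <- probs
  attr(scores, "training_sites") <- aligned_sites
  scores
}

# Score every window of width w on a base-index vector; returns numeric
# vector of length n - w + 1 (or empty).
score_windows <- function(code, pssm) {
  w <- ncol(pssm)
  n <- length(code)
  if (n < w) return(numeric(0))
  m <- n - w + 1L
  sc <- numeric(m)
  for (j in seq_len(w)) {
    col <- pssm[, j]
    idx <- code[seq_len(m) + j - 1L]
    add <- col[idx]
    add[is.na(add)] <- -Inf  # N never matches a PSSM column
    sc <- sc + unname(add)
  }
  sc
}

score_sites <- function(sites, pssm) {
  vapply(sites, function(s) {
    code <- match(seq_chars(s), DNA_BASES)
    score_windows(code, pssm)[1]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Paired -35/-10 promoter model
#'
#' Bundles the two element PSSMs of a sigma factor with its spacer-length
#' constraint and per-element score thresholds. By default each threshold is
#' the given percentile of the training sites' own scores under their PSSM —
#' a self-contained, reproducible cutoff rule.
#'
#' @param pssm_35,pssm_10 Log-odds matrices from [build_pssm()].
#' @param spacer_range Length-2 integer `[min, max]` spacer length in bp.
#' @param sigma_label One of `"RpoD"`, `"RpoH1"`, `"RpoH2"`, `"RpoE2"`,
#'   `"RpoN"`, `"custom"`.
#' @param threshold_percentile Percentile of training-site scores used as the
#'   per-element cutoff (default 0.10, i.e. the 10th percentile, retaining
#'   90% of training sites).
#' @param score_threshold_35,score_threshold_10 Explicit thresholds; override
#'   the percentile rule when given.
#' @return An object of class `promoter_model`.
#' @export
promoter_model <- function(pssm_35, pssm_10, spacer_range = c(15L, 19L),
                           sigma_label = "custom",
                           threshold_percentile = 0.10,
                           score_threshold_35 = NULL,
                           score_threshold_10 = NULL) {
  if (length(spacer_range) != 2 || spacer_range[1] > spacer_range[2]) {
    stop("spacer_range must be c(min, max) with min <= max", call. = FALSE)
  }
  thr <- function(pssm, given) {
    if (!is.null(given)) return(given)
    tr <- attr(pssm, "training_sites")
    if (is.null(tr)) stop("PSSM lacks training sites; supply score_threshold_*",
                          call. = FALSE)
    unname(stats::quantile(score_sites(tr, pssm), threshold_percentile))
  }
  structure(
    list(sigma_label = sigma_label, pssm_35 = pssm_35, pssm_10 = pssm_10,
         spacer_range = as.integer(spacer_range),
         score_threshold_35 = thr(pssm_35, score_threshold_35),
         score_threshold_10 = thr(pssm_10, score_threshold_10)),
    class = "promoter_model"
  )
}

#' @export
print.promoter_model <- function(x, ...) {
  cat("<promoter_model>", x$sigma_label,
      sprintf("| -35 width %d (thr %.2f) | spacer %d-%d | -10 width %d (thr %.2f)\n",
              ncol(x$pssm_35), x$score_threshold_35,
              x$spacer_range[1], x$spacer_range[2],
              ncol(x$pssm_10), x$score_threshold_10))
  invisible(x)
}

#' Scan a genome for paired promoter elements
#'
#' Slides both strands; every (-35 hit, downstream -10 hit on the same
#' strand) pair whose spacer length lies in the model's `spacer_range` is
#' reported — overlapping pairs are all kept, since downstream spacer
#' statistics are per hit. Coordinates are reported on the forward axis;
#' `spacer_seq` is strand-oriented (the sequence strictly between the two
#' elements, read on the hit strand).
#'
#' @param genome Genome (see [read_genome()]).
#' @param model A [promoter_model()].
#' @return A tibble: `replicon_id`, `strand`, `start_35`, `end_35`,
#'   `start_10`, `end_10`, `score_35`, `score_10`, `spacer_len`,
#'   `spacer_seq`, `spacer_at`, `sigma`.
#' @export
scan_paired <- function(genome, model) {
  if (!inherits(model, "promoter_model")) stop("`model` must be a promoter_model", call. = FALSE)
  seqs <- as_genome_chr(genome)
  w35 <- ncol(model$pssm_35)
  w10 <- ncol(model$pssm_10)

  scan_one_strand <- function(s) {
    code <- match(seq_chars(s), DNA_BASES)
    sc35 <- score_windows(code, model$pssm_35)
    sc10 <- score_windows(code, model$pssm_10)
    p35 <- which(sc35 >= model$score_threshold_35)
    p10 <- which(sc10 >= model$score_threshold_10)
    if (!length(p35) || !length(p10)) {
      return(tibble::tibble(s35 = integer(0), s10 = integer(0),
                            score_35 = numeric(0), score_10 = numeric(0)))
    }
    # pair: -10 start = -35 end + spacer + 1
    pairs <- purrr::map_dfr(model$spacer_range[1]:model$spacer_range[2],
                            function(sp) {
      cand10 <- p35 + w35 + sp
      ok <- cand10 %in% p10
      tibble::tibble(s35 = p35[ok], s10 = cand10[ok])
    })
    if (!nrow(pairs)) {
      return(tibble::tibble(s35 = integer(0), s10 = integer(0),
                            score_35 = numeric(0), score_10 = numeric(0)))
    }
    pairs$score_35 <- sc35[pairs$s35]
    pairs$score_10 <- sc10[pairs$s10]
    pairs
  }

  one <- function(id) {
    s <- seqs[[id]]
    n <- nchar(s)
    fwd <- scan_one_strand(s)
    rev <- scan_one_strand(revcomp(s))
    res <- dplyr::bind_rows(
      if (nrow(fwd)) tibble::tibble(
        replicon_id = id, strand = "+",
        start_35 = fwd$s35, end_35 = fwd$s35 + w35 - 1L,
        start_10 = fwd$s10, end_10 = fwd$s10 + w10 - 1L,
        score_35 = fwd$score_35, score_10 = fwd$score_10
      ),
      if (nrow(rev)) tibble::tibble(
        replicon_id = id, strand = "-",
        # map scan coordinates back onto the forward axis
        start_35 = n - (rev$s35 + w35 - 1L) + 1L, end_35 = n - rev$s35 + 1L,
        start_10 = n - (rev$s10 + w10 - 1L) + 1L, end_10 = n - rev$s10 + 1L,
        score_35 = rev$score_35, score_10 = rev$score_10
      )
    )
    res
  }
  hits <- dplyr::bind_rows(lapply(names(seqs), one))
  if (!nrow(hits)) {
    return(tibble::tibble(
      replicon_id = character(0), strand = character(0),
      start_35 = integer(0), end_35 = integer(0), start_10 = integer(0),
      end_10 = integer(0), score_35 = numeric(0), score_10 = numeric(0),
      spacer_len = integer(0), spacer_seq = character(0),
      spacer_at = numeric(0), sigma = character(0)
    ))
  }
  sp_start <- ifelse(hits$strand == "+", hits$end_35 + 1L, hits$end_10 + 1L)
  sp_end <- ifelse(hits$strand == "+", hits$start_10 - 1L, hits$start_35 - 1L)
  hits$spacer_len <- as.integer(sp_end - sp_start + 1L)
  hits$spacer_seq <- extract_interval(seqs, hits$replicon_id, sp_start, sp_end,
                                      hits$strand)
  hits$spacer_at <- at_percent(hits$spacer_seq)
  hits$sigma <- model$sigma_label
  dplyr::arrange(hits, .data$replicon_id, .data$start_35, .data$strand)
}

#' Classify promoter hits as intergenic or intragenic and associate genes
#'
#' A hit is `intragenic` iff the 3' end of its -10 element lies within any
#' gene body, on either strand; otherwise `intergenic`. The associated gene
#' is the nearest downstream (in promoter orientation) gene start on the hit
#' strand within `max_distance` bp, or `NA`.
#'
#' @param hits Hit tibble from [scan_paired()].
#' @param genes Gene-model tibble.
#' @param max_distance Association window in bp (default 500, mirroring the
#'   target-window upstream bound).
#' @return `hits` with `context` and `associated_gene` columns.
#' @export
classify_context <- function(hits, genes, max_distance = 500) {
  assert_cols(genes, c("gene_id", "replicon_id", "start", "end", "strand"),
              "gene table")
  if (!nrow(hits)) {
    hits$context <- character(0)
    hits$associated_gene <- character(0)
    return(hits)
  }
  # 3' end of the -10 element on the forward axis
  end3 <- ifelse(hits$strand == "+", hits$end_10, hits$start_10)
  hits$context <- vapply(seq_len(nrow(hits)), function(i) {
    g <- genes[genes$replicon_id == hits$replicon_id[i], ]
    if (any(g$start <= end3[i] & g$end >= end3[i])) "intragenic" else "intergenic"
  }, character(1))
  hits$associated_gene <- vapply(seq_len(nrow(hits)), function(i) {
    g <- genes[genes$replicon_id == hits$replicon_id[i] &
                 genes$strand == hits$strand[i], ]
    if (!nrow(g)) return(NA_character_)
    if (hits$strand[i] == "+") {
      d <- g$start - end3[i]
    } else {
      d <- end3[i] - g$end  # start codon of a "-" gene sits at its end
    }
    ok <- d >= 0 & d <= max_distance
    if (!any(ok)) return(NA_character_)
    g$gene_id[ok][which.min(d[ok])]
  }, character(1))
  hits
}

#' Compare spacer AT% between target- and non-target-associated promoters
#'
#' Within each (sigma factor, context) stratum, a Welch two-sample t-test of
#' spacer AT% for hits associated with target genes versus non-target genes.
#' Hits without an associated gene are excluded. Strata with fewer than 2
#' hits in either group are skipped with a warning. Group sizes are reported
#' so results can be presented with bracketed n's, as is customary.
#'
#' @param hits Classified hit tibble (see [classify_context()]).
#' @param target_gene_ids Character vector of target gene ids.
#' @return A tibble per stratum: `sigma`, `context`, `n_target`,
#'   `n_non_target`, `mean_target`, `mean_non_target`, `se_target`,
#'   `se_non_target`, `delta_at`, `t_statistic`, `p_value`.
#' @export
spacer_at_comparison <- function(hits, target_gene_ids) {
  assert_cols(hits, c("sigma", "context", "spacer_at", "associated_gene"),
              "promoter hits")
  hits <- dplyr::filter(hits, !is.na(.data$associated_gene))
  hits$is_target <- hits$associated_gene %in% target_gene_ids
  strata <- dplyr::distinct(hits, .data$sigma, .data$context)
  out <- purrr::pmap_dfr(strata, function(sigma, context) {
    h <- hits[hits$sigma == sigma & hits$context == context, ]
    x <- h$spacer_at[h$is_target]
    y <- h$spacer_at[!h$is_target]
    if (length(x) < 2 || length(y) < 2) {
      warning("stratum (", sigma, ", ", context,
              ") skipped: fewer than 2 hits in a group")
      return(NULL)
    }
    tt <- stats::t.test(x, y)
    tibble::tibble(
      sigma = sigma, context = context,
      n_target = length(x), n_non_target = length(y),
      mean_target = mean(x), mean_non_target = mean(y),
      se_target = stats::sd(x) / sqrt(length(x)),
      se_non_target = stats::sd(y) / sqrt(length(y)),
      delta_at = mean(x) - mean(y),
      t_statistic = unname(tt$statistic), p_value = tt$p.value
    )
  })
  out
}
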