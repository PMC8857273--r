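#' Specify a flexible DNA pattern with indel-tolerant gaps
#'
#' The class-A flexible pattern is a degenerate motif of short fixed literal
#' blocks separated by non-conserved regions of nominal length, each of which
#' may expand or contract by up to its tolerance (insertions/deletions). The
#' default reproduces the periodic-T pattern `TTxxxGxxxTxxxxxxxxxxTT`:
#' literals `TT`, `G`, `T`, `TT` with nominal gaps 3, 3, 10 and per-region
#' tolerances 1, 1, 2.
#'
#' @param literals Ordered fixed strings (ACGT only).
#' @param gaps Nominal non-conserved region lengths, one per internal gap.
#' @param tolerances Maximum absolute indel per region (same length as `gaps`).
#' @param shared_budget If `TRUE`, regions 1 and 2 share a single pooled indel
#'   budget equal to `max(tolerances[1:2])` instead of each having its own.
#' @return An object of class `flex_pattern`.
#' @export
flex_pattern <- function(literals = c("TT", "G", "T", "TT"),
                         gaps = c(3L, 3L, 10L),
                         tolerances = c(1L, 1L, 2L),
                         shared_budget = FALSE) {
  if (length(gaps) != length(literals) - 1L ||
      length(tolerances) != length(gaps)) {
    stop("need length(gaps) = length(tolerances) = length(literals) - 1",
         call. = FALSE)
  }
  if (any(grepl("[^ACGT]", literals))) {
    stop("pattern literals must be over ACGT", call. = FALSE)
  }
  if (any(tolerances < 0) || any(gaps < tolerances)) {
    stop("require tolerances >= 0 and gaps >= tolerances", call. = FALSE)
  }
  structure(
    list(literals = toupper(literals), gaps = as.integer(gaps),
         tolerances = as.integer(tolerances),
         shared_budget = isTRUE(shared_budget)),
    class = "flex_pattern"
  )
}

#' @export
print.flex_pattern <- function(x, ...) {
  gap_str <- paste0("[", x$gaps - x$tolerances, "-", x$gaps + x$tolerances, "]")
  cat("<flex_pattern> ",
      paste(rbind(x$literals, c(gap_str, "")), collapse = " "),
      if (x$shared_budget) " (shared indel budget, regions 1-2)", "\n", sep = "")
  invisible(x)
}

# All admissible gap-length combinations, in lexicographic order.
flex_gap_grid <- function(spec) {
  ranges <- Map(function(g, t) (g - t):(g + t), spec$gaps, spec$tolerances)
  grid <- rev(expand.grid(rev(ranges), KEEP.OUT.ATTRS = FALSE))
  names(grid) <- paste0("g", seq_along(ranges))
  if (spec$shared_budget && length(ranges) >= 2) {
    budget <- max(spec$tolerances[1:2])
    keep <- abs(grid[[1]] - spec$gaps[1]) + abs(grid[[2]] - spec$gaps[2]) <= budget
    grid <- grid[keep, , drop = FALSE]
  }
  grid <- grid[do.call(order, grid), , drop = FALSE]
  as.matrix(grid)
}

# Logical vector: does literal `lit` start at each position of base vector x?
literal_at <- function(x, lit) {
  ch <- seq_chars(lit)
  n <- length(x)
  ok <- x == ch[1]
  if (length(ch) > 1) {
    for (j in 2:length(ch)) {
      shifted <- c(x[-seq_len(j - 1)], rep(NA, j - 1))
      ok <- ok & !is.na(shifted) & shifted == ch[j]
    }
  }
  ok & !is.na(ok)
}

# Forward-strand scan of one plain sequence; returns start, end, g1..gk.
scan_flexible_fwd <- function(seq, spec) {
  x <- seq_chars(seq)
  n <- length(x)
  lits <- spec$literals
  widths <- nchar(lits)
  lit_ok <- lapply(lits, literal_at, x = x)
  grid <- flex_gap_grid(spec)
  k <- ncol(grid)

  best <- vector("list", nrow(grid))
  found_start <- integer(0)
  found_row <- integer(0)
  for (r in seq_len(nrow(grid))) {
    gaps <- grid[r, ]
    offs <- cumsum(c(0L, widths[-length(widths)] + gaps))
    span <- offs[length(offs)] + widths[length(widths)]
    if (span > n) next
    m <- n - span + 1L
    ok <- lit_ok[[1]][seq_len(m)]
    for (b in 2:length(lits)) {
      ok <- ok & lit_ok[[b]][seq_len(m) + offs[b]]
    }
    starts <- which(ok)
    if (length(starts)) {
      new <- !(starts %in% found_start)
      found_start <- c(found_start, starts[new])
      found_row <- c(found_row, rep.int(r, sum(new)))
    }
  }
  if (!length(found_start)) {
    return(tibble::tibble(start = integer(0), end = integer(0), gaps = list()))
  }
  o <- order(found_start)
  found_start <- found_start[o]
  found_row <- found_row[o]
  spans <- rowSums(grid[found_row, , drop = FALSE]) + sum(widths)
  tibble::tibble(
    start = found_start,
    end = found_start + as.integer(spans) - 1L,
    gaps = lapply(found_row, function(r) unname(grid[r, ]))
  )
}

#' Scan sequences for a flexible pattern
#'
#' Reports every start position (per strand) at which at least one assignment
#' of gap lengths within tolerance spells the literal blocks in order.
#' Overlapping matches are all reported, but each (start, strand) is reported
#' once, with the lexicographically smallest feasible gap realisation.
#' Minus-strand matches are found by scanning the reverse complement and are
#' reported in forward-axis coordinates.
#'
#' @param seqs A named character vector / `DNAStringSet` of sequences, or a
#'   single unnamed string (reported under replicon id `"seq"`).
#' @param spec A [flex_pattern()].
#' @param strand_mode `"both"` (default) or `"forward"`.
#' @return A tibble: `replicon_id`, `start`, `end`, `strand`, `midpoint`
#'   (`(start+end)/2`, possibly half-integer), and list-column `gaps`
#'   (realised gap lengths, in scan orientation).
#' @export
scan_flexible <- function(seqs, spec = flex_pattern(),
                          strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  if (!inherits(spec, "flex_pattern")) stop("`spec` must be a flex_pattern", call. = FALSE)
  if (is.character(seqs) && is.null(names(seqs)) && length(seqs) == 1L) {
    names(seqs) <- "seq"
  }
  seqs <- as_genome_chr(seqs)

  one <- function(id) {
    s <- seqs[[id]]
    fwd <- scan_flexible_fwd(s, spec)
    fwd$strand <- rep("+", nrow(fwd))
    res <- fwd
    if (strand_mode == "both") {
      n <- nchar(s)
      rev <- scan_flexible_fwd(revcomp(s), spec)
      if (nrow(rev)) {
        res <- dplyr::bind_rows(fwd, tibble::tibble(
          start = n - rev$end + 1L,
          end = n - rev$start + 1L,
          gaps = rev$gaps,
          strand = "-"
        ))
      }
    }
    res$replicon_id <- rep(id, nrow(res))
    res
  }
  out <- dplyr::bind_rows(lapply(names(seqs), one))
  if (!nrow(out)) {
    return(tibble::tibble(replicon_id = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          midpoint = numeric(0), gaps = list()))
  }
  out$midpoint <- (out$start + out$end) / 2
  out <- dplyr::arrange(out, .data$replicon_id, .data$start, .data$strand)
  dplyr::select(out, "replicon_id", "start", "end", "strand", "midpoint", "gaps")
}

#' Count matches per region by midpoint membership
#'
#' A match is counted in a region iff its midpoint (a real value; half-integer
#' for even-span matches, never rounded) lies inside `[start, end]`.
#'
#' @param matches Match tibble from [scan_flexible()].
#' @param regions Tibble with `region_id` (or `peak_id`), `replicon_id`,
#'   `start`, `end`.
#' @return `regions` with an integer `n_matches` column.
#' @export
count_in_regions <- function(matches, regions) {
  id_col <- if ("region_id" %in% names(regions)) "region_id" else "peak_id"
  assert_cols(regions, c(id_col, "replicon_id", "start", "end"), "region table")
  counts <- vapply(seq_len(nrow(regions)), function(i) {
    sum(matches$replicon_id == regions$replicon_id[i] &
          matches$midpoint >= regions$start[i] &
          matches$midpoint <= regions$end[i])
  }, integer(1))
  dplyr::mutate(regions, n_matches = counts)
}

#' Strand-oriented motif-to-gene-start distances
#'
#' For each gene, the signed distance of each motif midpoint to the first
#' nucleotide of the gene (positive = into the coding region). Only motifs on
#' the gene's coding strand are considered by default: promoter analyses are
#' inherently oriented. Distances are kept when they fall in
#' `[-upstream_bound, +coding_bound]`; for genes shorter than `coding_bound`,
#' positive distances past the stop codon are dropped so downstream
#' intergenic sequence never masquerades as intragenic signal.
#'
#' @param matches Match tibble from [scan_flexible()].
#' @param genes Gene-model tibble.
#' @param upstream_bound,coding_bound Retention bounds in bp (defaults 500 and
#'   2000).
#' @param coding_strand_only Restrict to matches on the gene's strand
#'   (default `TRUE`).
#' @return A tibble `gene_id`, `distance`.
#' @export
motif_gene_distances <- function(matches, genes, upstream_bound = 500,
                                 coding_bound = 2000,
                                 coding_strand_only = TRUE) {
  assert_cols(genes, c("gene_id", "replicon_id", "start", "end", "strand"),
              "gene table")
  pairs <- dplyr::inner_join(
    dplyr::select(matches, "replicon_id", "midpoint",
                  match_strand = "strand"),
    dplyr::select(genes, "gene_id", "replicon_id", "start", "end", "strand"),
    by = "replicon_id", relationship = "many-to-many"
  )
  if (coding_strand_only) {
    pairs <- dplyr::filter(pairs, .data$match_strand == .data$strand)
  }
  d <- ifelse(pairs$strand == "+",
              pairs$midpoint - pairs$start,
              pairs$end - pairs$midpoint)
  glen <- pairs$end - pairs$start + 1
  keep <- d >= -upstream_bound & d <= coding_bound & d <= glen - 1
  tibble::tibble(gene_id = pairs$gene_id[keep], distance = d[keep]) |>
    dplyr::arrange(.data$gene_id, .data$distance)
}

#' Positional kernel density of motif (or summit) distances
#'
#' Gaussian-kernel density estimate of signed distances on a fixed grid
#' spanning `[from, to]`, renormalised so the trapezoid integral over the
#' grid is exactly 1. Bandwidth defaults to Silverman's rule.
#'
#' @param distances Numeric vector of signed distances (>= 2 values).
#' @param bandwidth Kernel bandwidth in bp; `NULL` for Silverman's rule.
#' @param from,to Grid limits (defaults −500 and +2000).
#' @param n Grid size (default 512).
#' @return A tibble `position`, `density` with class `flex_density`.
#' @export
positional_density <- function(distances, bandwidth = NULL,
                               from = -500, to = 2000, n = 512) {
  if (length(distances) < 2) {
    stop("need at least 2 distances for a density estimate", call. = FALSE)
  }
  d <- stats::density(distances, bw = bandwidth %||% "nrd0",
                      kernel = "gaussian", from = from, to = to, n = n)
  dx <- diff(d$x)
  integral <- sum((d$y[-1] + d$y[-length(d$y)]) / 2 * dx)
  out <- tibble::tibble(position = d$x, density = d$y / integral)
  class(out) <- c("flex_density", class(out))
  attr(out, "bandwidth") <- d$bw
  attr(out, "n_obs") <- length(distances)
  out
}
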