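# Independent oracles and shared fixtures for the test suite.
# Oracles are deliberately naive (substring comparisons, O(n^2) loops,
# explicit enumeration) and never share code paths with the implementation.

rand_dna <- function(n, gc = 0.5, alphabet = c("A", "C", "G", "T")) {
  if (length(alphabet) == 4) {
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  } else {
    probs <- rep(1 / length(alphabet), length(alphabet))
  }
  paste(sample(alphabet, n, replace = TRUE, prob = probs), collapse = "")
}

# Brute-force flexible-pattern scanner: at every start position, try every
# gap-length combination by direct substring comparison.
oracle_scan_fwd <- function(seq, spec) {
  n <- nchar(seq)
  lits <- spec$literals
  widths <- nchar(lits)
  combos <- expand.grid(lapply(seq_along(spec$gaps), function(i) {
    (spec$gaps[i] - spec$tolerances[i]):(spec$gaps[i] + spec$tolerances[i])
  }))
  if (isTRUE(spec$shared_budget) && length(spec$gaps) >= 2) {
    budget <- max(spec$tolerances[1:2])
    combos <- combos[abs(combos[[1]] - spec$gaps[1]) +
                       abs(combos[[2]] - spec$gaps[2]) <= budget, , drop = FALSE]
  }
  combos <- combos[do.call(order, combos), , drop = FALSE]  # lexicographic
  hits <- list()
  for (start in seq_len(n)) {
    for (r in seq_len(nrow(combos))) {
      pos <- start
      ok <- TRUE
      for (b in seq_along(lits)) {
        if (substr(seq, pos, pos + widths[b] - 1) != lits[b]) { ok <- FALSE; break }
        pos <- pos + widths[b]
        if (b < length(lits)) pos <- pos + combos[r, b]
      }
      if (ok && pos - 1 <= n) {
        hits[[length(hits) + 1]] <- c(start = start, end = pos - 1)
        break  # one match per start position
      }
    }
  }
  if (!length(hits)) return(data.frame(start = integer(0), end = integer(0)))
  as.data.frame(do.call(rbind, hits))
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# O(n^2) single-linkage 1-D clustering by repeated merging of cluster pairs.
oracle_merge_1d <- function(pos, threshold) {
  labels <- seq_along(pos)
  repeat {
    changed <- FALSE
    for (i in seq_along(pos)) {
      for (j in seq_along(pos)) {
        if (labels[i] != labels[j] && abs(pos[i] - pos[j]) < threshold) {
          labels[labels == labels[j]] <- labels[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(labels, unique(labels))
}

# Naive Spearman rho via explicit ranks (average ties).
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Two-sided Fisher exact p from hypergeometric point probabilities.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small, fast synthetic dataset shared across test files (built once).
test_config <- function(seed = 42, ...) {
  synth_config(
    seed = seed,
    replicons = tibble::tibble(
      id = c("chromosome", "chromid", "pSym"),
      length = c(150000L, 80000L, 50000L),
      gc = c(62, 61, 58),
      role = c("chromosome", "chromid", "symbiosis_plasmid")
    ),
    n_genes = c(110L, 60L, 30L),
    n_peaks = 150L,
    ...
  )
}

synth_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synth_generate(test_config())
    cache
  }
})

# Vectorised substring-comparison oracle (same enumeration semantics as
# oracle_scan_fwd, fast enough for kb-scale sequences). Still independent of
# the scanner: it compares extracted substrings per gap combination.
oracle_scan_fwd_vec <- function(seq, spec) {
  n <- nchar(seq)
  lits <- spec$literals
  widths <- nchar(lits)
  combos <- expand.grid(lapply(seq_along(spec$gaps), function(i) {
    (spec$gaps[i] - spec$tolerances[i]):(spec$gaps[i] + spec$tolerances[i])
  }))
  if (isTRUE(spec$shared_budget) && length(spec$gaps) >= 2) {
    budget <- max(spec$tolerances[1:2])
    combos <- combos[abs(combos[[1]] - spec$gaps[1]) +
                       abs(combos[[2]] - spec$gaps[2]) <= budget, , drop = FALSE]
  }
  combos <- combos[do.call(order, combos), , drop = FALSE]
  best_end <- rep(NA_integer_, n)
  for (r in seq_len(nrow(combos))) {
    gaps <- as.integer(combos[r, ])
    offs <- cumsum(c(0L, widths[-length(widths)] + gaps))
    span <- offs[length(offs)] + widths[length(widths)]
    m <- n - span + 1L
    if (m < 1L) next
    idx <- seq_len(m)
    ok <- rep(TRUE, m)
    for (b in seq_along(lits)) {
      st <- idx + offs[b]
      ok <- ok & substring(seq, st, st + widths[b] - 1L) == lits[b]
    }
    newly <- idx[ok & is.na(best_end[idx])]
    best_end[newly] <- newly + span - 1L
  }
  starts <- which(!is.na(best_end))
  data.frame(start = starts, end = best_end[starts])
}
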