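#' Read a called-peak table
#'
#' Consumes a TSV of called ChIP-seq peaks (one row per peak per sample) with
#' columns `replicon_id`, `summit`, `enrichment_fold`, `q_value`, `condition`
#' and `replicate`. MACS2 summit BED files (0-based half-open) can be read via
#' `format = "summits_bed"`, in which case summits are converted to 1-based
#' coordinates and `condition`/`replicate` must be supplied.
#'
#' @param path Path to the peak table.
#' @param format `"tsv"` (default) or `"summits_bed"`.
#' @param condition,replicate Labels applied to every row when reading BED.
#' @param genome Optional genome for summit bounds validation.
#' @return A tibble of peak records.
#' @export
read_peaks <- function(path, format = c("tsv", "summits_bed"),
                       condition = NULL, replicate = NULL, genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("peak table not found: ", path, call. = FALSE)
  if (format == "tsv") {
    peaks <- readr::read_tsv(path, show_col_types = FALSE)
    assert_cols(peaks, c("replicon_id", "summit", "enrichment_fold",
                         "q_value", "condition", "replicate"), "peak table")
  } else {
    if (is.null(condition)) stop("`condition` is required for BED input", call. = FALSE)
    bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
    peaks <- tibble::tibble(
      replicon_id = as.character(bed[[1]]),
      summit = as.integer(bed[[2]]) + 1L,  # 0-based half-open -> 1-based
      enrichment_fold = if (ncol(bed) >= 5) as.numeric(bed[[5]]) else NA_real_,
      q_value = NA_real_,
      condition = condition,
      replicate = replicate %||% "combined"
    )
  }
  validate_peaks(peaks, genome)
  peaks
}

validate_peaks <- function(peaks, genome = NULL) {
  if (any(peaks$enrichment_fold <= 0, na.rm = TRUE)) {
    stop("enrichment_fold must be positive", call. = FALSE)
  }
  if (any(peaks$summit < 1L)) stop("summits must be >= 1", call. = FALSE)
  if (!is.null(genome)) {
    seqs <- as_genome_chr(genome)
    unknown <- setdiff(unique(peaks$replicon_id), names(seqs))
    if (length(unknown)) {
      stop("peaks on unknown replicon(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    over <- peaks$summit > nchar(seqs)[peaks$replicon_id]
    if (any(over)) stop("peak summit(s) beyond replicon end", call. = FALSE)
  }
  invisible(peaks)
}

#' Consolidate peaks across samples by summit distance
#'
#' Re-allocates peaks from different samples/conditions to a common peak id
#' when their summits fall within `max_summit_distance` of each other.
#' Clustering is single-linkage per replicon on summit position with a strict
#' `< max_summit_distance` link rule, which on sorted 1-D summits reduces to
#' chaining consecutive gaps. Input order never matters: records are sorted by
#' (replicon, summit, condition, replicate) first.
#'
#' The consensus summit of a merged peak is the median member summit (lower
#' median for even-sized chains, so ties resolve to the smaller coordinate).
#' Per-condition enrichment is the maximum member fold of that condition; a
#' condition absent from the chain is reported `NA`. `shared_flag` is
#' `"shared"` when both conditions contributed, else `"<cond>_only"`.
#'
#' @param peaks Peak-record tibble (see [read_peaks()]); multiple tables may
#'   be passed as a list and are row-bound.
#' @param max_summit_distance Linking threshold in bp (default 200; two
#'   summits are linked iff their distance is strictly below it).
#' @param genome Optional genome for validation.
#' @return A tibble of merged peaks: `peak_id`, `replicon_id`,
#'   `consensus_summit`, `n_members`, `fold_FC`, `fold_BC` (one column per
#'   condition present, prefixed `fold_`), `enrichment_fold` (max across
#'   conditions), `shared_flag`, and a list-column `members`.
#' @export
merge_peaks <- function(peaks, max_summit_distance = 200, genome = NULL) {
  if (is.list(peaks) && !is.data.frame(peaks)) peaks <- dplyr::bind_rows(peaks)
  assert_cols(peaks, c("replicon_id", "summit", "enrichment_fold",
                       "condition", "replicate"), "peak table")
  if (max_summit_distance < 0) stop("max_summit_distance must be >= 0", call. = FALSE)
  validate_peaks(peaks, genome)

  peaks <- dplyr::arrange(peaks, .data$replicon_id, .data$summit,
                          .data$condition, .data$replicate)
  peaks <- dplyr::group_by(peaks, .data$replicon_id)
  peaks <- dplyr::mutate(
    peaks,
    .new_chain = c(TRUE, diff(.data$summit) >= max_summit_distance),
    .chain = cumsum(.data$.new_chain)
  )
  peaks <- dplyr::ungroup(peaks)

  conds <- sort(unique(peaks$condition))
  merged <- peaks |>
    dplyr::group_by(.data$replicon_id, .data$.chain) |>
    dplyr::summarise(
      consensus_summit = sort(.data$summit)[floor((dplyr::n() + 1) / 2)],
      n_members = dplyr::n(),
      members = list(dplyr::pick(dplyr::everything())),
      .fold_by_cond = list(tapply(.data$enrichment_fold, .data$condition, max)),
      .groups = "drop"
    )
  for (cc in conds) {
    merged[[paste0("fold_", cc)]] <- vapply(
      merged$.fold_by_cond,
      function(x) if (cc %in% names(x)) unname(x[[cc]]) else NA_real_,
      numeric(1)
    )
  }
  fold_cols <- paste0("fold_", conds)
  fold_mat <- as.matrix(merged[fold_cols])
  merged$enrichment_fold <- apply(fold_mat, 1, max, na.rm = TRUE)
  present <- !is.na(fold_mat)
  merged$shared_flag <- ifelse(
    rowSums(present) == length(conds) & length(conds) > 1, "shared",
    paste0(conds[apply(present, 1, which.max)], "_only")
  )
  merged$.fold_by_cond <- NULL
  merged <- dplyr::arrange(merged, .data$replicon_id, .data$consensus_summit)
  merged$peak_id <- sprintf("peak_%04d", seq_len(nrow(merged)))
  merged$.chain <- NULL
  dplyr::relocate(merged, "peak_id")
}

#' Central region of a merged peak
#'
#' Returns the forward-strand window of `width` bp centred on the consensus
#' summit: positions `[summit - width/2 + 1, summit + width/2]`. Windows that
#' would extend past a replicon end are truncated there and flagged.
#'
#' @param peaks Merged-peak tibble (or anything with `peak_id`, `replicon_id`
#'   and `consensus_summit` columns).
#' @param genome Genome (see [read_genome()]).
#' @param width Window width in bp; must be even and >= 2 (default 200).
#' @return A tibble `peak_id`, `replicon_id`, `start`, `end`, `seq`,
#'   `truncated`.
#' @export
central_region <- function(peaks, genome, width = 200) {
  if (width < 2 || width %% 2 != 0) stop("width must be even and >= 2", call. = FALSE)
  assert_cols(peaks, c("peak_id", "replicon_id", "consensus_summit"),
              "merged peak table")
  seqs <- as_genome_chr(genome)
  unknown <- setdiff(unique(peaks$replicon_id), names(seqs))
  if (length(unknown)) {
    stop("peaks on unknown replicon(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  lens <- nchar(seqs)[peaks$replicon_id]
  if (any(peaks$consensus_summit < 1L | peaks$consensus_summit > lens)) {
    stop("summit out of replicon bounds", call. = FALSE)
  }
  start <- peaks$consensus_summit - width / 2 + 1
  end <- peaks$consensus_summit + width / 2
  truncated <- unname(start < 1L | end > lens)
  start <- pmax(start, 1L)
  end <- pmin(end, lens)
  tibble::tibble(
    peak_id = peaks$peak_id,
    replicon_id = peaks$replicon_id,
    start = as.integer(start),
    end = as.integer(end),
    seq = extract_interval(seqs, peaks$replicon_id, start, end, "+"),
    truncated = truncated
  )
}

#' Assign merged peaks to target genes through promoter windows
#'
#' A gene is a target of a peak when the consensus summit lies in the gene's
#' regulation window around the start codon: `[start - upstream,
#' start + downstream]` for a `"+"` gene and the mirror-image window anchored
#' at `end` for a `"-"` gene. Both boundaries are inclusive. A peak may target
#' several genes (divergent promoters) and a gene may carry several peaks.
#'
#' @param peaks Merged-peak tibble (see [merge_peaks()]).
#' @param genes Gene-model tibble (see [read_annotation()]).
#' @param upstream,downstream Window extents in bp (defaults 500 and 100).
#' @param circular Wrap windows across position 1 of each replicon (default
#'   `FALSE`: windows are truncated at replicon ends).
#' @param genome Genome, required only when `circular = TRUE`.
#' @return A tibble `gene_id`, `peak_id`, `summit_offset` (signed bp relative
#'   to the start codon; negative = upstream).
#' @export
assign_targets <- function(peaks, genes, upstream = 500, downstream = 100,
                           circular = FALSE, genome = NULL) {
  if (upstream < 0 || downstream < 0) {
    stop("upstream/downstream must be non-negative", call. = FALSE)
  }
  assert_cols(peaks, c("peak_id", "replicon_id", "consensus_summit"),
              "merged peak table")
  assert_cols(genes, c("gene_id", "replicon_id", "start", "end", "strand"),
              "gene table")
  lens <- NULL
  if (circular) {
    if (is.null(genome)) stop("`genome` is required when circular = TRUE", call. = FALSE)
    lens <- nchar(as_genome_chr(genome))
  }

  pairs <- dplyr::inner_join(
    dplyr::select(peaks, "peak_id", "replicon_id", "consensus_summit"),
    dplyr::select(genes, "gene_id", "replicon_id", "start", "end", "strand"),
    by = "replicon_id", relationship = "many-to-many"
  )
  offset <- ifelse(pairs$strand == "+",
                   pairs$consensus_summit - pairs$start,
                   pairs$end - pairs$consensus_summit)
  hit <- offset >= -upstream & offset <= downstream
  if (circular) {
    # a window crossing position 1 (or the replicon end) wraps around
    L <- lens[pairs$replicon_id]
    wrapped <- ifelse(pairs$strand == "+",
                      pairs$consensus_summit - pairs$start - L,
                      pairs$end - pairs$consensus_summit - L)
    wrapped2 <- ifelse(pairs$strand == "+",
                       pairs$consensus_summit - pairs$start + L,
                       pairs$end - pairs$consensus_summit + L)
    hit2 <- (wrapped >= -upstream & wrapped <= downstream) |
      (wrapped2 >= -upstream & wrapped2 <= downstream)
    offset <- ifelse(!hit & hit2 & (wrapped >= -upstream & wrapped <= downstream),
                     wrapped,
                     ifelse(!hit & hit2, wrapped2, offset))
    hit <- hit | hit2
  }
  out <- tibble::tibble(
    gene_id = pairs$gene_id[hit],
    peak_id = pairs$peak_id[hit],
    summit_offset = as.integer(offset[hit])
  )
  dplyr::arrange(out, .data$gene_id, .data$peak_id)
}

#' Summarise shared versus condition-specific peaks
#'
#' Counts merged peaks by `shared_flag` and reports, among condition-specific
#' peaks, how many have enrichment fold below `low_fold_threshold` — the
#' signature reported for condition-specific silencer peaks (low occupancy).
#'
#' @param peaks Merged-peak tibble with a `shared_flag` column.
#' @param low_fold_threshold Fold cut for "low" condition-specific peaks
#'   (default 5).
#' @return A one-row tibble: `n_peaks`, `n_shared`, `n_condition_specific`,
#'   `n_condition_specific_low_fold`, `low_fold_threshold`.
#' @export
classify_condition_specific <- function(peaks, low_fold_threshold = 5.0) {
  assert_cols(peaks, c("shared_flag", "enrichment_fold"), "merged peak table")
  spec <- peaks$shared_flag != "shared"
  tibble::tibble(
    n_peaks = nrow(peaks),
    n_shared = sum(!spec),
    n_condition_specific = sum(spec),
    n_condition_specific_low_fold = sum(spec & peaks$enrichment_fold < low_fold_threshold),
    low_fold_threshold = low_fold_threshold
  )
}
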