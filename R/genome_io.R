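#' Read a multi-replicon genome from FASTA
#'
#' Reads a (possibly multi-record) FASTA file into a [Biostrings::DNAStringSet],
#' one entry per replicon. Sequences are uppercased; `N` is allowed, any other
#' ambiguity code is rejected. Record names are truncated at the first
#' whitespace, as is conventional for replicon ids.
#'
#' Multipartite bacterial genomes (chromosome + chromid + plasmids) are common
#' in the rhizobia this package was designed around; all downstream functions
#' accept the returned object wherever a `genome` argument appears.
#'
#' @param fasta_path Path to a FASTA file.
#' @param roles Optional named character vector mapping replicon id to a role
#'   label (`"chromosome"`, `"chromid"`, `"plasmid"`, `"symbiosis_plasmid"`,
#'   `"unspecified"`). Roles are biological knowledge, not inferred from
#'   sequence; unknown ids default to `"unspecified"`.
#' @return A named `DNAStringSet` with a `role` column in its `mcols()`.
#' @export
read_genome <- function(fasta_path, roles = NULL) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path, call. = FALSE)
  }
  first <- readLines(fasta_path, n = 1L)
  if (length(first) == 0L) stop("empty FASTA file: ", fasta_path, call. = FALSE)
  if (!startsWith(first, ">")) {
    stop("malformed FASTA (line 1 does not start with '>'): ", fasta_path,
         call. = FALSE)
  }
  dss <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) stop("FASTA parse error in ", fasta_path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  names(dss) <- sub("\\s.*$", "", names(dss))
  seqs <- as_genome_chr(dss)
  out <- Biostrings::DNAStringSet(seqs)
  S4Vectors::mcols(out)$role <- replicon_roles(names(out), roles)
  out
}

#' @rdname read_genome
#' @param genome Genome to write (a `DNAStringSet` or named character vector).
#' @param path Output FASTA path.
#' @export
write_genome <- function(genome, path) {
  seqs <- as_genome_chr(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

replicon_roles <- function(ids, roles = NULL) {
  allowed <- c("chromosome", "chromid", "plasmid", "symbiosis_plasmid",
               "unspecified")
  out <- rep("unspecified", length(ids))
  names(out) <- ids
  if (!is.null(roles)) {
    bad <- setdiff(roles, allowed)
    if (length(bad)) {
      stop("unknown replicon role(s): ", paste(bad, collapse = ", "),
           "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
    }
    hit <- intersect(names(roles), ids)
    out[hit] <- roles[hit]
  }
  out
}

#' Read gene models from GFF3
#'
#' Imports gene/CDS features from a GFF3 file, validates them against the
#' genome, and returns a tibble of gene models. Coordinates follow the GFF3
#' convention (1-based, inclusive) throughout the package.
#'
#' @param gff_path Path to a GFF3 file with `gene` (or `CDS`) features that
#'   carry an `ID` attribute.
#' @param genome Genome the annotation refers to (see [read_genome()]).
#' @param feature_types Feature types to keep (default `"gene"`, falling back
#'   to `"CDS"` if no `gene` features are present).
#' @return A tibble with columns `gene_id`, `replicon_id`, `start`, `end`,
#'   `strand`, `subset` (initialised `"unassigned"`), `product`.
#' @export
read_annotation <- function(gff_path, genome, feature_types = "gene") {
  if (!file.exists(gff_path)) stop("GFF3 file not found: ", gff_path, call. = FALSE)
  seqs <- as_genome_chr(genome)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  keep <- as.character(gr$type) %in% feature_types
  if (!any(keep) && identical(feature_types, "gene")) {
    keep <- as.character(gr$type) %in% "CDS"
  }
  gr <- gr[keep]
  if (length(gr) == 0L) stop("no gene/CDS features found in ", gff_path, call. = FALSE)
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    stop("GFF3 features must carry an ID attribute", call. = FALSE)
  }
  genes <- tibble::tibble(
    gene_id = as.character(ids),
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    subset = "unassigned",
    product = if (!is.null(gr$product)) as.character(gr$product) else NA_character_
  )
  validate_genes(genes, seqs)
  genes
}

validate_genes <- function(genes, seqs) {
  unknown <- setdiff(unique(genes$replicon_id), names(seqs))
  if (length(unknown)) {
    stop("annotation references replicon(s) absent from the genome: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id(s): ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(genes$start < 1L) || any(genes$start > genes$end)) {
    stop("gene coordinates must satisfy 1 <= start <= end", call. = FALSE)
  }
  over <- genes$end > nchar(seqs)[genes$replicon_id]
  if (any(over)) {
    stop("gene(s) extend past the end of their replicon: ",
         paste(genes$gene_id[over], collapse = ", "), call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  invisible(genes)
}

#' @rdname read_annotation
#' @param genes Gene-model tibble to write.
#' @param path Output GFF3 path.
#' @export
write_annotation <- function(genes, path) {
  assert_cols(genes, c("gene_id", "replicon_id", "start", "end", "strand"),
              "gene table")
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon_id,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$Name <- genes$gene_id
  if ("product" %in% names(genes)) gr$product <- genes[["product"]]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an expression matrix as a long tibble
#'
#' The expected layout is a TSV with a `gene_id` first column and one column
#' per condition label, holding non-negative normalised expression values.
#'
#' @param path Path to the TSV.
#' @param genes Optional gene-model tibble; gene ids absent from it are
#'   flagged with a warning (column `known_gene`).
#' @return A tibble with columns `gene_id`, `condition`, `expression` (and
#'   `known_gene` when `genes` is supplied).
#' @export
read_expression <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("expression table not found: ", path, call. = FALSE)
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  names(wide)[1] <- "gene_id"
  long <- tidyr::pivot_longer(wide, -"gene_id",
                              names_to = "condition", values_to = "expression")
  if (any(long$expression < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  if (!is.null(genes)) {
    long$known_gene <- long$gene_id %in% genes$gene_id
    n_bad <- sum(!long$known_gene[!duplicated(long$gene_id)])
    if (n_bad > 0) {
      warning(n_bad, " gene id(s) in the expression table are absent from the annotation")
    }
  }
  long
}

#' Extract an interval from a genome, strand-aware
#'
#' Returns the forward-strand substring for `strand = "+"` and its reverse
#' complement for `strand = "-"`. Coordinates are 1-based inclusive and must
#' lie within the replicon: this layer never clamps silently.
#'
#' All arguments after `genome` are vectorised and recycled to a common
#' length, so a tibble of intervals can be fed column-wise.
#'
#' @param genome Genome (see [read_genome()]).
#' @param replicon_id Replicon id(s).
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @return Character vector of sequences, `length = end - start + 1` each.
#' @export
extract_interval <- function(genome, replicon_id, start, end, strand = "+") {
  seqs <- as_genome_chr(genome)
  n <- max(length(replicon_id), length(start), length(end), length(strand))
  replicon_id <- rep_len(replicon_id, n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  strand <- rep_len(strand, n)
  unknown <- setdiff(unique(replicon_id), names(seqs))
  if (length(unknown)) {
    stop("unknown replicon id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  lens <- nchar(seqs)[replicon_id]
  if (any(start < 1L) || any(end < start) || any(end > lens)) {
    stop("interval out of bounds: require 1 <= start <= end <= replicon length",
         call. = FALSE)
  }
  out <- substring(seqs[replicon_id], start, end)
  rev_idx <- strand == "-"
  if (any(rev_idx)) out[rev_idx] <- revcomp(out[rev_idx])
  unname(out)
}
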