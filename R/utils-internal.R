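# Internal helpers shared across modules. Not exported.

DNA_BASES <- c("A", "C", "G", "T")

# Reverse complement of a plain character vector of DNA strings (ACGTN).
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Coerce genome input (DNAStringSet, named character vector, or list) to a
# named uppercase character vector restricted to ACGTN.
as_genome_chr <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (is.character(genome)) {
    out <- genome
  } else if (is.list(genome)) {
    out <- unlist(genome)
  } else {
    stop("`genome` must be a DNAStringSet or a named character vector of sequences",
         call. = FALSE)
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop("every replicon sequence must be named by its replicon id", call. = FALSE)
  }
  if (anyDuplicated(names(out))) {
    stop("replicon ids must be unique", call. = FALSE)
  }
  out <- toupper(out)
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    stop("replicon(s) ", paste(names(out)[bad], collapse = ", "),
         " contain characters outside the ACGTN alphabet", call. = FALSE)
  }
  if (any(!nzchar(out))) stop("replicon sequences must be non-empty", call. = FALSE)
  out
}

# Split a DNA string into a character vector of single bases.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Deterministic sub-seed for a generator component, kept below 2^31.
sub_seed <- function(seed, offset) {
  (as.integer(seed) %% 20000000L) * 97L + as.integer(offset)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}
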