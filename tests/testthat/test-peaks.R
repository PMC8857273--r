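mk_peaks <- function(summit, condition = "FC", replicon = "chr",
                     fold = 5, replicate = "rep1") {
  tibble::tibble(replicon_id = replicon, summit = as.integer(summit),
                 enrichment_fold = fold, q_value = 0.001,
                 condition = condition, replicate = replicate)
}

test_that("summits within the link distance share a peak id, others do not", {
  two <- dplyr::bind_rows(mk_peaks(100, "FC"), mk_peaks(250, "BC"))
  m <- merge_peaks(two, max_summit_distance = 200)
  expect_equal(nrow(m), 1L)
  expect_equal(m$shared_flag, "shared")
  expect_equal(m$n_members, 2L)

  apart <- dplyr::bind_rows(mk_peaks(100, "FC"), mk_peaks(350, "BC"))
  m2 <- merge_peaks(apart, max_summit_distance = 200)
  expect_equal(nrow(m2), 2L)
  expect_setequal(m2$shared_flag, c("FC_only", "BC_only"))
})

test_that("merging is order-invariant and respects structural invariants", {
  set.seed(7)
  pk <- tibble::tibble(
    replicon_id = sample(c("chr", "p1"), 300, TRUE),
    summit = sample(50000, 300),
    enrichment_fold = stats::runif(300, 1.1, 30),
    q_value = stats::runif(300, 0, 0.01),
    condition = sample(c("FC", "BC"), 300, TRUE),
    replicate = sample(paste0("rep", 1:3), 300, TRUE)
  )
  m1 <- merge_peaks(pk)
  m2 <- merge_peaks(pk[sample(nrow(pk)), ])
  expect_equal(m1, m2)
  expect_lte(nrow(m1), nrow(pk))
  # per-condition enrichment is the max over members of that condition
  for (i in sample(nrow(m1), 10)) {
    mem <- m1$members[[i]]
    for (cc in unique(mem$condition)) {
      expect_equal(m1[[paste0("fold_", cc)]][i],
                   max(mem$enrichment_fold[mem$condition == cc]))
    }
  }
})

test_that("merge with threshold zero is the identity partition", {
  set.seed(8)
  pk <- mk_peaks(sample(10000, 100))
  expect_equal(nrow(merge_peaks(pk, max_summit_distance = 0)), 100L)
  expect_error(merge_peaks(pk, max_summit_distance = -5), ">= 0")
})

test_that("single-linkage merge matches a naive O(n^2) clustering oracle", {
  set.seed(9)
  pos <- sort(sample(200000, 400))
  pk <- mk_peaks(pos)
  m <- merge_peaks(pk, max_summit_distance = 200)
  oracle <- oracle_merge_1d(pos, 200)
  expect_equal(nrow(m), length(unique(oracle)))
  # membership identical: summits grouped together iff oracle groups them
  got <- lapply(m$members, function(d) sort(d$summit))
  want <- unname(lapply(split(pos, oracle), sort))
  expect_setequal(got, want)
})

test_that("consensus summit is the lower median of member summits", {
  m <- merge_peaks(mk_peaks(c(100, 150, 260)))
  expect_equal(m$consensus_summit, 150L)
  m2 <- merge_peaks(mk_peaks(c(100, 150, 260, 300)))
  expect_equal(m2$consensus_summit, 150L)  # even chain: smaller middle
})

test_that("central regions are summit-centred, truncated at replicon ends", {
  g <- c(chr = paste(rep("ACGT", 2500), collapse = ""))
  pk <- tibble::tibble(peak_id = c("p1", "p2"), replicon_id = "chr",
                       consensus_summit = c(500L, 50L))
  cr <- central_region(pk, g, width = 200)
  expect_equal(cr$start, c(401L, 1L))
  expect_equal(cr$end, c(600L, 150L))
  expect_equal(cr$truncated, c(FALSE, TRUE))
  expect_equal(cr$seq[1], substr(g[["chr"]], 401, 600))
  expect_error(central_region(pk, g, width = 3), "even")

  set.seed(10)
  for (i in 1:500) {
    s <- sample(10000, 1)
    cr1 <- central_region(tibble::tibble(peak_id = "p", replicon_id = "chr",
                                         consensus_summit = s), g, 200)
    expect_identical(cr1$seq, substr(g[["chr"]], max(1, s - 99), min(10000, s + 100)))
  }
})

test_that("target windows honour strand and inclusive boundaries", {
  genes <- tibble::tibble(
    gene_id = c("plus", "minus"), replicon_id = "chr",
    start = c(1000L, 5000L), end = c(2000L, 6000L), strand = c("+", "-")
  )
  pk <- function(s) tibble::tibble(peak_id = paste0("p", s), replicon_id = "chr",
                                   consensus_summit = as.integer(s))
  hit <- assign_targets(pk(600), genes)
  expect_equal(hit$gene_id, "plus")
  expect_equal(hit$summit_offset, -400L)
  expect_equal(nrow(assign_targets(pk(1100), genes)), 1L)   # +100 inclusive
  expect_equal(nrow(assign_targets(pk(1101), genes)), 0L)   # just outside
  expect_equal(nrow(assign_targets(pk(500), genes)), 1L)    # -500 inclusive
  expect_equal(nrow(assign_targets(pk(499), genes)), 0L)
  # "-" gene: start codon at end; window extends upstream to larger coords
  hm <- assign_targets(pk(6300), genes)
  expect_equal(hm$gene_id, "minus")
  expect_equal(hm$summit_offset, -300L)
  expect_equal(nrow(assign_targets(pk(5899), genes)), 0L)
  expect_equal(assign_targets(pk(5900), genes)$summit_offset, 100L)
  expect_equal(nrow(assign_targets(pk(6500), genes)), 1L)   # -500 inclusive
  expect_equal(nrow(assign_targets(pk(6501), genes)), 0L)
  expect_error(assign_targets(pk(600), genes, upstream = -1), "non-negative")
})

test_that("summit offsets re-derive from gene coordinates and stay in range", {
  x <- synth_fixture()
  merged <- merge_peaks(x$peak_records)
  tg <- assign_targets(merged, x$genes)
  expect_true(all(tg$summit_offset >= -500 & tg$summit_offset <= 100))
  joined <- tg |>
    dplyr::inner_join(merged, by = "peak_id") |>
    dplyr::inner_join(x$genes, by = c("gene_id", "replicon_id"))
  rederived <- ifelse(joined$strand == "+",
                      joined$consensus_summit - joined$start,
                      joined$end - joined$consensus_summit)
  expect_equal(joined$summit_offset, as.integer(rederived))
})

test_that("condition-specific classification counts shared and low-fold peaks", {
  all_shared <- merge_peaks(dplyr::bind_rows(mk_peaks(c(100, 900), "FC"),
                                             mk_peaks(c(120, 910), "BC")))
  s <- classify_condition_specific(all_shared)
  expect_equal(s$n_condition_specific, 0L)
  expect_equal(s$n_shared, 2L)

  x <- synth_fixture()
  m <- merge_peaks(x$peak_records)
  cls <- classify_condition_specific(m)
  p_hat <- cls$n_shared / cls$n_peaks
  p_true <- x$config$shared_fraction
  ci_half <- 3 * sqrt(p_true * (1 - p_true) / cls$n_peaks)
  expect_lt(abs(p_hat - p_true), ci_half)
})

test_that("MACS2 summit BED input converts to 1-based coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr\t99\t100\tpk1\t12.5", "chr\t499\t500\tpk2\t3.1"), bed)
  pk <- read_peaks(bed, format = "summits_bed", condition = "FC",
                   replicate = "rep1")
  expect_equal(pk$summit, c(100L, 500L))
  expect_equal(pk$enrichment_fold, c(12.5, 3.1))
  expect_equal(unique(pk$condition), "FC")
  expect_error(read_peaks(bed, format = "summits_bed"), "condition")
})
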