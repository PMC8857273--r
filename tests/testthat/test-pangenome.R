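strain_groups <- function() {
  list(genus = sprintf("S%02d", 1:12), species = sprintf("S%02d", 1:5),
       close = sprintf("S%02d", 1:3), focal = "S01")
}

test_that("hierarchical subset rules resolve top-down", {
  cl <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    cluster_id = paste0("c", 1:4),
    strains = list(sprintf("S%02d", 1:12),        # genus core -> I
                   sprintf("S%02d", 1:5),         # species core -> II
                   sprintf("S%02d", 1:3),         # close strains only -> III
                   "S01")                         # focal only -> IV
  )
  a <- assign_subsets(cl, strain_groups())
  expect_equal(as.character(a$subset), c("I", "II", "III", "IV"))
  expect_warning(
    a2 <- assign_subsets(cl, strain_groups(), gene_ids = c(cl$gene_id, "gX")),
    "absent"
  )
  expect_equal(as.character(a2$subset[a2$gene_id == "gX"]), "IV")
  bad <- strain_groups(); bad$focal <- "S99"
  expect_error(assign_subsets(cl, bad), "focal")
})

test_that("subset assignment recovers the generator's planted labels exactly", {
  x <- synth_fixture()
  a <- assign_subsets(x$clusters, x$config$strains, gene_ids = x$genes$gene_id)
  expect_equal(as.character(a$subset[match(x$genes$gene_id, a$gene_id)]),
               as.character(x$genes$subset))
  # partition: subset sizes sum to the gene universe
  expect_equal(sum(table(a$subset)), nrow(x$genes))
})

test_that("Fisher enrichment matches a hypergeometric-tail oracle", {
  set.seed(61)
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:200),
    replicon_id = sample(c("chr", "p1", "p2"), 200, TRUE,
                         prob = c(0.6, 0.25, 0.15)),
    subset = factor(sample(c("I", "II", "III", "IV"), 200, TRUE),
                    levels = c("I", "II", "III", "IV"))
  )
  targets <- sample(genes$gene_id, 60)
  res <- enrichment_tests(targets, genes)
  for (i in seq_len(nrow(res))) {
    col <- if (res$stratify_by[i] == "replicon") "replicon_id" else "subset"
    in_st <- as.character(genes[[col]]) == res$stratum[i]
    is_t <- genes$gene_id %in% targets
    tab <- matrix(c(sum(in_st & is_t), sum(!in_st & is_t),
                    sum(in_st & !is_t), sum(!in_st & !is_t)), nrow = 2,
                  byrow = TRUE)
    expect_equal(res$p_value[i], oracle_fisher_p(tab), tolerance = 1e-7)
  }
})

test_that("extreme placement yields enrichment on one replicon, depletion elsewhere", {
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:120),
    replicon_id = rep(c("chr", "p1"), each = 60)
  )
  targets <- genes$gene_id[genes$replicon_id == "p1"][1:40]
  res <- enrichment_tests(targets, genes, stratify_by = "replicon")
  expect_equal(res$direction[res$stratum == "p1"], "enriched")
  expect_equal(res$direction[res$stratum == "chr"], "depleted")
  expect_lt(res$p_value[res$stratum == "p1"], 1e-6)
  # row/label swap invariance: p unchanged, odds ratio inverted
  anti <- setdiff(genes$gene_id, targets)
  res2 <- enrichment_tests(anti, genes, stratify_by = "replicon")
  expect_equal(res$p_value, res2$p_value, tolerance = 1e-9)
})

test_that("uniformly random targets trigger ~5% of strata at alpha 0.05", {
  set.seed(62)
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:400),
    replicon_id = sample(c("chr", "p1", "p2"), 400, TRUE),
    subset = factor(sample(c("I", "II", "III", "IV"), 400, TRUE),
                    levels = c("I", "II", "III", "IV"))
  )
  hits <- 0L; total <- 0L
  for (rep in 1:30) {
    targets <- sample(genes$gene_id, 100)
    res <- enrichment_tests(targets, genes)
    hits <- hits + sum(res$p_value < 0.05)
    total <- total + nrow(res)
  }
  fp <- hits / total
  expect_lt(fp, 0.09)  # Fisher is conservative on discrete tables
})

test_that("gene AT% groups recover the planted subset ordering", {
  x <- synth_fixture()
  targets <- unique(x$ledger$true_targets$gene_id)
  res <- at_by_group(x$genes, x$genome, targets, stratify_by = "subset")
  means <- res$mean_all[match(c("I", "II", "III", "IV"), res$stratum)]
  expect_true(all(diff(means) > 0))  # AT increases I -> IV
  # group mean equals the naive per-gene average
  per_gene <- gene_at_percent(x$genes, x$genome)
  for (s in c("I", "IV")) {
    naive <- mean(per_gene$at_percent[as.character(per_gene$subset) == s])
    expect_equal(res$mean_all[res$stratum == s], naive, tolerance = 1e-12)
  }
})

test_that("identical gene sequences give equal group means and null t", {
  g <- c(chr = strrep("ACGT", 1000))
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:20), replicon_id = "chr",
    start = seq(1, 3801, by = 200), end = seq(100, 3900, by = 200),
    strand = "+",
    subset = factor(rep(c("I", "IV"), 10), levels = c("I", "II", "III", "IV"))
  )
  res <- at_by_group(genes, g, targets = genes$gene_id[1:10],
                     stratify_by = "replicon")
  expect_equal(res$mean_target, res$mean_non_target)
  expect_true(is.na(res$t_vs_all) || abs(res$t_vs_all) < 1e-9)
})

test_that("expression contrasts recover planted boosts with correct signs", {
  x <- synth_fixture()
  targets <- unique(x$ledger$true_targets$gene_id)
  res <- expression_by_group(
    x$expression, x$genes, targets,
    mutant_vs_wt = c(wt = "free_living_WT", mutant = "free_living_mucR1")
  )
  # targets transcribed higher than non-targets overall (planted boost)
  expect_gt(mean(res$target_tests$delta, na.rm = TRUE), 0)
  # mutant up-shift of targets recovered with correct sign and rough size
  expect_gt(res$mutant_contrast$delta, 0)
  expect_lt(res$mutant_contrast$p_value, 0.01)
  expect_equal(res$mutant_contrast$delta, log2(x$config$mutant_shift),
               tolerance = 0.35)
  # subset means decrease with decreasing conservation (I > IV)
  sm <- res$summary[res$summary$condition == "free_living_WT" &
                      !res$summary$is_target, ]
  ord <- sm$mean_log2[match(c("I", "II", "III", "IV"), as.character(sm$subset))]
  expect_true(all(diff(ord) < 0))
  expect_error(
    expression_by_group(x$expression, x$genes, targets,
                        mutant_vs_wt = c(wt = "nope", mutant = "free_living_mucR1")),
    "unknown condition"
  )
})

test_that("constant expression yields null contrasts", {
  genes <- tibble::tibble(gene_id = paste0("g", 1:40),
                          subset = factor(rep(c("I", "IV"), 20),
                                          levels = c("I", "II", "III", "IV")))
  expr <- tidyr::expand_grid(gene_id = genes$gene_id,
                             condition = c("c1", "c2"))
  expr$expression <- 10
  res <- expression_by_group(expr, genes, targets = paste0("g", 1:10))
  expect_true(all(res$target_tests$delta == 0))
})

test_that("subset composition fractions sum to one within fold bins", {
  x <- synth_fixture()
  merged <- merge_peaks(x$peak_records)
  tg <- assign_targets(merged, x$genes)
  rc <- recruitment_by_conservation(merged, tg, x$genes)
  sums <- rc$bin_composition |>
    dplyr::group_by(bin) |>
    dplyr::summarise(s = sum(fraction))
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-12)
})

test_that("subset-independent folds give a near-null conservation trend", {
  set.seed(63)
  peaks <- tibble::tibble(peak_id = paste0("p", 1:400),
                          enrichment_fold = stats::runif(400, 1, 30))
  tg <- tibble::tibble(gene_id = paste0("g", 1:400), peak_id = peaks$peak_id)
  genes <- tibble::tibble(gene_id = paste0("g", 1:400),
                          subset = factor(sample(c("I", "II", "III", "IV"), 400,
                                                 TRUE, prob = c(.4, .2, .2, .2)),
                                          levels = c("I", "II", "III", "IV")))
  rc <- recruitment_by_conservation(peaks, tg, genes)
  expect_lt(abs(rc$trend$rho), 0.9)  # no systematic monotone trend
})
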