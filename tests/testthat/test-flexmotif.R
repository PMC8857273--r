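test_that("pattern specification validates its geometry", {
  expect_s3_class(flex_pattern(), "flex_pattern")
  expect_error(flex_pattern(gaps = c(3, 3)), "length")
  expect_error(flex_pattern(literals = c("TT", "G", "T", "NN")), "ACGT")
  expect_error(flex_pattern(tolerances = c(5, 1, 2)), "gaps >= tolerances")
})

test_that("the canonical periodic-T instance yields exactly one forward match", {
  canon <- "TTAAAGAAATAAAAAAAAAATT"
  m <- scan_flexible(canon, strand_mode = "forward")
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 1L)
  expect_equal(m$end, 22L)
  expect_equal(m$gaps[[1]], c(3L, 3L, 10L))
  expect_equal(m$midpoint, 11.5)
})

test_that("sequences lacking the literals yield no matches", {
  expect_equal(nrow(scan_flexible(strrep("A", 200))), 0L)
  expect_equal(nrow(scan_flexible(strrep("CG", 100))), 0L)
})

test_that("scanner equals the exhaustive gap-enumeration oracle on random DNA", {
  set.seed(21)
  spec <- flex_pattern()
  for (i in 1:30) {
    s <- rand_dna(1000, gc = sample(c(0.3, 0.45, 0.6), 1))
    got <- scan_flexible(s, spec, strand_mode = "forward")
    want <- oracle_scan_fwd(s, spec)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("scanner equals the oracle on short AT-rich edge-case fixtures", {
  set.seed(22)
  spec <- flex_pattern()
  for (i in 1:150) {
    s <- rand_dna(sample(18:60, 1), alphabet = c("A", "T", "G"))
    got <- scan_flexible(s, spec, strand_mode = "forward")
    want <- oracle_scan_fwd(s, spec)
    expect_equal(got$start, want$start, info = s)
    expect_equal(got$end, want$end, info = s)
  }
})

test_that("match sets grow monotonically with gap tolerance", {
  set.seed(23)
  tight <- flex_pattern(tolerances = c(0L, 0L, 0L))
  mid <- flex_pattern(tolerances = c(1L, 1L, 1L))
  wide <- flex_pattern(tolerances = c(1L, 1L, 2L))
  for (i in 1:20) {
    s <- rand_dna(2000, gc = 0.35)
    k0 <- scan_flexible(s, tight)
    k1 <- scan_flexible(s, mid)
    k2 <- scan_flexible(s, wide)
    # the invariant site is the scan-orientation start: forward `start` on
    # "+", forward `end` on "-" (the realised span varies with tolerance)
    key <- function(m) paste(ifelse(m$strand == "+", m$start, m$end), m$strand)
    expect_true(all(key(k0) %in% key(k1)))
    expect_true(all(key(k1) %in% key(k2)))
  }
})

test_that("minus-strand matches mirror forward matches of the reverse complement", {
  set.seed(24)
  for (i in 1:10) {
    s <- rand_dna(1500, gc = 0.35)
    n <- nchar(s)
    both <- scan_flexible(s)
    rc_fwd <- scan_flexible(oracle_revcomp(s), strand_mode = "forward")
    minus <- both[both$strand == "-", ]
    expect_setequal(n - rc_fwd$end + 1, minus$start)
    expect_setequal(n - rc_fwd$start + 1, minus$end)
  }
})

test_that("every exact planted motif is recovered (sensitivity 1.0)", {
  x <- synth_fixture()
  plants <- x$ledger$motif_plants
  m <- scan_flexible(x$genome)
  key_m <- paste(m$replicon_id, m$start, m$strand)
  expect_true(all(paste(plants$replicon_id, plants$start, plants$strand) %in% key_m))
})

test_that("region counts use real-valued midpoints with inclusive bounds", {
  matches <- tibble::tibble(replicon_id = "chr", start = c(140L, 89L),
                            end = c(160L, 110L), strand = "+",
                            midpoint = c(150, 99.5), gaps = list(NULL, NULL))
  regions <- tibble::tibble(region_id = "r1", replicon_id = "chr",
                            start = 100L, end = 200L)
  expect_equal(count_in_regions(matches, regions)$n_matches, 1L)
  # counts on planted-motif synthetic regions equal the generator ledger
  x <- synth_fixture()
  plants <- x$ledger$motif_plants
  regions <- tibble::tibble(
    region_id = x$ledger$peak_sites$site_id,
    replicon_id = x$ledger$peak_sites$replicon_id,
    start = x$ledger$peak_sites$summit - 99L,
    end = x$ledger$peak_sites$summit + 100L
  )
  got <- count_in_regions(plants, regions)
  expect_equal(got$n_matches, x$ledger$peak_sites$motif_count)
})

test_that("gene-relative distances drop downstream intergenic positions", {
  genes <- tibble::tibble(gene_id = c("gA", "gB"), replicon_id = "chr",
                          start = c(1000L, 5000L), end = c(3500L, 5899L),
                          strand = "+")
  mk <- function(mid) tibble::tibble(replicon_id = "chr", start = mid - 10L,
                                     end = mid + 10L, strand = "+",
                                     midpoint = mid, gaps = list(NULL))
  d <- motif_gene_distances(mk(800), genes)
  expect_equal(d$distance, -200)
  # gene gB is 900 bp long: +1500 lands past its stop codon and is dropped
  expect_equal(nrow(motif_gene_distances(mk(6500), genes)), 0L)
  # but the same offset within the long gene gA is retained
  expect_equal(motif_gene_distances(mk(2500), genes)$distance, 1500)
  # beyond the coding bound: dropped even inside a long gene
  expect_equal(nrow(motif_gene_distances(mk(3100), genes,
                                         coding_bound = 2000)), 0L)
})

test_that("distances agree with a naive per-gene filter oracle", {
  x <- synth_fixture()
  m <- scan_flexible(x$genome)
  got <- motif_gene_distances(m, x$genes)
  got <- dplyr::arrange(got, gene_id, distance)
  naive <- list()
  for (i in seq_len(nrow(x$genes))) {
    g <- x$genes[i, ]
    mm <- m[m$replicon_id == g$replicon_id & m$strand == g$strand, ]
    d <- if (g$strand == "+") mm$midpoint - g$start else g$end - mm$midpoint
    d <- d[d >= -500 & d <= 2000 & d <= (g$end - g$start)]
    if (length(d)) naive[[g$gene_id]] <- sort(d)
  }
  naive_tbl <- tibble::tibble(
    gene_id = rep(names(naive), lengths(naive)),
    distance = unlist(naive, use.names = FALSE)
  ) |> dplyr::arrange(gene_id, distance)
  expect_equal(got, naive_tbl)
})

test_that("positional densities are normalised and shaped as expected", {
  expect_error(positional_density(0), "at least 2")
  peaked <- positional_density(rep(0, 50), bandwidth = 5)
  expect_equal(peaked$position[which.max(peaked$density)], 0, tolerance = 5)
  trap <- function(d) {
    dx <- diff(d$position)
    sum((d$density[-1] + d$density[-nrow(d)]) / 2 * dx)
  }
  expect_equal(trap(peaked), 1, tolerance = 1e-3)

  set.seed(25)
  unif <- positional_density(stats::runif(10000, -500, 2000), bandwidth = 50)
  expect_equal(trap(unif), 1, tolerance = 1e-3)
  inner <- unif[unif$position > -300 & unif$position < 1800, ]
  expect_lt(max(inner$density) / min(inner$density), 1.5)

  skewed <- positional_density(stats::rnorm(500, -150, 60))
  expect_equal(trap(skewed), 1, tolerance = 1e-3)
})
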