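#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions emulated by [synth_generate()]: a
#' multipartite genome of differing per-replicon GC%, AT-rich islands,
#' genes in four conservation subsets with subset-dependent GC and
#' expression, planted flexible motifs, ChIP peaks whose enrichment fold
#' increases with AT% and motif count under Gaussian noise, and planted
#' promoters with controlled spacer AT%.
#'
#' The enrichment model is
#' `fold = max(1.01, beta0 + beta_at * AT% + beta_motif * motifs +
#' beta_ta * deviation(TA) + Normal(0, sigma))`,
#' evaluated on the true 200-bp central region of each peak; the floor just
#' above 1 mirrors real peak tables, where folds exceed 1.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param replicons Tibble with `id`, `length`, `gc`, `role`.
#' @param n_genes Integer vector, genes per replicon.
#' @param subset_proportions Four probabilities (I-IV) summing to 1.
#' @param subset_gc_offsets Four GC-point offsets added to the replicon GC
#'   inside gene bodies; AT increases from subset I to IV.
#' @param island_gc GC% of AT-rich islands (intergenic positions only).
#' @param island_per_bp One island per this many bp of replicon.
#' @param n_peaks Number of true binding sites.
#' @param target_fraction Fraction of sites aimed at gene regulation windows.
#' @param shared_fraction Fraction of sites present under both conditions.
#' @param specific_damp Multiplicative damping of the above-baseline fold of
#'   condition-specific sites (`fold = 1 + damp * (fold - 1)`); emulates the
#'   weak occupancy characteristic of condition-specific silencer peaks.
#' @param beta0,beta_at,beta_motif,beta_ta,sigma Enrichment-model
#'   coefficients and noise s.d.
#' @param motif_lambda_island,motif_lambda_background Poisson means for
#'   motifs planted in a peak's central region (island vs background peaks).
#' @param motif_rate_island,motif_rate_background Planted motifs per kb of
#'   island / background intergenic sequence (outside peaks).
#' @param subset_meanlog Lognormal meanlog of expression per subset (I-IV,
#'   decreasing).
#' @param expr_sdlog Lognormal sdlog of expression.
#' @param target_boost Multiplicative expression boost of target genes.
#' @param mutant_shift Multiplicative up-shift of target genes in the mutant.
#' @param conditions Condition labels; those containing `mutant_tag` are
#'   mutant conditions.
#' @param mutant_tag Substring marking mutant conditions.
#' @param promoter_n_per_group Planted promoters per group (target-associated
#'   and non-target-associated).
#' @param promoter_n_out_of_range Additional plants with an out-of-range
#'   spacer (should be rejected by the scan).
#' @param spacer_len In-range planted spacer length (bp).
#' @param spacer_len_out_of_range Spacer length of out-of-range plants.
#' @param spacer_range Admissible spacer range for the scan.
#' @param spacer_at_target,spacer_at_non_target Mean planted spacer AT% per
#'   group (the default +8-point shift for targets mirrors the biology this
#'   generator emulates).
#' @param spacer_at_sd S.d. of planted spacer AT%.
#' @param consensus_35,consensus_10 Element consensus sequences.
#' @param n_training_sites Training sites generated per element.
#' @param training_mut_rate Per-position mutation rate of training sites.
#' @param strains Strain universe: list with `genus`, `species`, `close`,
#'   `focal`.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(
    seed = 1L,
    replicons = tibble::tibble(
      id = c("chromosome", "chromid", "pSym"),
      length = c(300000L, 150000L, 80000L),
      gc = c(62, 61, 58),
      role = c("chromosome", "chromid", "symbiosis_plasmid")
    ),
    n_genes = c(110L, 60L, 30L),
    subset_proportions = c(I = 0.45, II = 0.15, III = 0.15, IV = 0.25),
    subset_gc_offsets = c(I = 2, II = 0.5, III = -1, IV = -3),
    island_gc = 42,
    island_per_bp = 40000,
    n_peaks = 300L,
    target_fraction = 0.4,
    shared_fraction = 0.65,
    specific_damp = 0.25,
    beta0 = -10, beta_at = 0.45, beta_motif = 1.5, beta_ta = 0, sigma = 2,
    motif_lambda_island = 2.0, motif_lambda_background = 0.7,
    motif_rate_island = 1.0, motif_rate_background = 0.05,
    subset_meanlog = log(c(I = 100, II = 60, III = 35, IV = 20)),
    expr_sdlog = 0.8,
    target_boost = 1.8,
    mutant_shift = 1.6,
    conditions = c("free_living_WT", "free_living_mucR1",
                   "bacteroid_WT", "bacteroid_mucR1"),
    mutant_tag = "mucR1",
    promoter_n_per_group = 50L,
    promoter_n_out_of_range = 0L,
    spacer_len = 17L,
    spacer_len_out_of_range = 25L,
    spacer_range = c(15L, 19L),
    spacer_at_target = 60,
    spacer_at_non_target = 52,
    spacer_at_sd = 4,
    consensus_35 = "TTGACA",
    consensus_10 = "TATAAT",
    n_training_sites = 40L,
    training_mut_rate = 0.12,
    strains = list(genus = sprintf("S%02d", 1:12),
                   species = sprintf("S%02d", 1:5),
                   close = sprintf("S%02d", 1:3),
                   focal = "S01")) {
  stopifnot(length(n_genes) == nrow(replicons))
  if (abs(sum(subset_proportions) - 1) > 1e-9) {
    stop("subset_proportions must sum to 1", call. = FALSE)
  }
  if (any(replicons$length < 10000)) stop("replicon lengths must be >= 10 kb", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

# ---- internal generator stages ------------------------------------------

synth_layout <- function(cfg) {
  genes <- purrr::map_dfr(seq_len(nrow(cfg$replicons)), function(r) {
    L <- cfg$replicons$length[r]
    n <- cfg$n_genes[r]
    lens <- sample(600:1200, n, replace = TRUE)
    free <- L - sum(lens) - 400L
    if (free < 80L * (n + 1L)) {
      stop("infeasible packing: too many genes for replicon ",
           cfg$replicons$id[r], call. = FALSE)
    }
    raw <- stats::runif(n)
    gaps <- 80L + floor(raw / sum(raw) * (free - 80L * n))
    starts <- cumsum(gaps) + cumsum(c(0L, lens[-n])) + 1L
    tibble::tibble(
      replicon_id = cfg$replicons$id[r],
      start = as.integer(starts),
      end = as.integer(starts + lens - 1L),
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
  })
  genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
  genes$subset <- factor(
    sample(names(cfg$subset_proportions), nrow(genes), replace = TRUE,
           prob = cfg$subset_proportions),
    levels = c("I", "II", "III", "IV")
  )
  genes$product <- paste("hypothetical protein", genes$gene_id)
  genes <- dplyr::relocate(genes, "gene_id")

  islands <- purrr::map_dfr(seq_len(nrow(cfg$replicons)), function(r) {
    L <- cfg$replicons$length[r]
    n_isl <- max(1L, round(L / cfg$island_per_bp))
    len <- sample(1500:3000, n_isl, replace = TRUE)
    start <- sort(sample(seq_len(L - 3200L), n_isl))
    tibble::tibble(replicon_id = cfg$replicons$id[r],
                   start = as.integer(start),
                   end = as.integer(start + len - 1L))
  })
  islands$island_id <- sprintf("isl%03d", seq_len(nrow(islands)))
  list(genes = genes, islands = dplyr::relocate(islands, "island_id"))
}

synth_sequence <- function(cfg, layout) {
  out <- lapply(seq_len(nrow(cfg$replicons)), function(r) {
    id <- cfg$replicons$id[r]
    L <- cfg$replicons$length[r]
    gc <- rep(cfg$replicons$gc[r], L)
    isl <- layout$islands[layout$islands$replicon_id == id, ]
    for (i in seq_len(nrow(isl))) {
      gc[isl$start[i]:isl$end[i]] <- cfg$island_gc
    }
    gn <- layout$genes[layout$genes$replicon_id == id, ]
    for (i in seq_len(nrow(gn))) {
      gc[gn$start[i]:gn$end[i]] <-
        cfg$replicons$gc[r] + cfg$subset_gc_offsets[[as.character(gn$subset[i])]]
    }
    is_gc <- stats::runif(L) < gc / 100
    pick <- stats::runif(L) < 0.5
    # index into G/C/A/T: GC draw decides the pair, pick decides the member
    idx <- 1L + (!is_gc) * 2L + pick
    paste(c("G", "C", "A", "T")[idx], collapse = "")
  })
  names(out) <- cfg$replicons$id
  unlist(out)
}

# naive strand-aware regulation-window membership, used for ledger truth
naive_targets <- function(summits, genes, upstream = 500, downstream = 100) {
  purrr::map_dfr(seq_len(nrow(summits)), function(i) {
    g <- genes[genes$replicon_id == summits$replicon_id[i], ]
    off <- ifelse(g$strand == "+", summits$summit[i] - g$start,
                  g$end - summits$summit[i])
    hit <- off >= -upstream & off <= downstream
    if (!any(hit)) return(NULL)
    tibble::tibble(site_id = summits$site_id[i], gene_id = g$gene_id[hit],
                   summit_offset = off[hit])
  })
}

synth_peak_sites <- function(cfg, layout) {
  genes <- layout$genes
  n_target <- round(cfg$n_peaks * cfg$target_fraction)
  pool <- sample(genes$gene_id)
  accepted <- tibble::tibble(replicon_id = character(0), summit = integer(0),
                             aimed_gene = character(0))
  lens <- stats::setNames(cfg$replicons$length, cfg$replicons$id)
  ok_dist <- function(repl, pos) {
    same <- accepted$summit[accepted$replicon_id == repl]
    !length(same) || min(abs(same - pos)) >= 500
  }
  for (gid in pool) {
    if (nrow(accepted) >= n_target) break
    g <- genes[genes$gene_id == gid, ]
    off <- sample(20:450, 1)
    pos <- if (g$strand == "+") g$start - off else g$end + off
    if (pos < 101 || pos > lens[[g$replicon_id]] - 100) next
    if (!ok_dist(g$replicon_id, pos)) next
    accepted <- dplyr::add_row(accepted, replicon_id = g$replicon_id,
                               summit = as.integer(pos), aimed_gene = gid)
  }
  n_nt <- cfg$n_peaks - nrow(accepted)
  in_any_window <- function(repl, pos) {
    g <- genes[genes$replicon_id == repl, ]
    off <- ifelse(g$strand == "+", pos - g$start, g$end - pos)
    any(off >= -500 & off <= 100)
  }
  tries <- 0L
  while (n_nt > 0 && tries < 200L * cfg$n_peaks) {
    tries <- tries + 1L
    r <- sample(seq_len(nrow(cfg$replicons)), 1, prob = cfg$replicons$length)
    repl <- cfg$replicons$id[r]
    pos <- sample(300:(lens[[repl]] - 300L), 1)
    if (!ok_dist(repl, pos) || in_any_window(repl, pos)) next
    accepted <- dplyr::add_row(accepted, replicon_id = repl,
                               summit = as.integer(pos), aimed_gene = NA_character_)
    n_nt <- n_nt - 1L
  }
  if (n_nt > 0) stop("could not place all peak sites; reduce n_peaks", call. = FALSE)
  accepted <- dplyr::arrange(accepted, .data$replicon_id, .data$summit)
  accepted$site_id <- sprintf("site_%04d", seq_len(nrow(accepted)))
  isl <- layout$islands
  accepted$in_island <- vapply(seq_len(nrow(accepted)), function(i) {
    ii <- isl[isl$replicon_id == accepted$replicon_id[i], ]
    any(ii$start <= accepted$summit[i] & ii$end >= accepted$summit[i])
  }, logical(1))
  dplyr::relocate(accepted, "site_id")
}

random_filler <- function(n, at_prob = 0.7) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c(at_prob / 2, (1 - at_prob) / 2,
                        (1 - at_prob) / 2, at_prob / 2)),
        collapse = "")
}

canonical_motif <- function() {
  paste0("TT", random_filler(3), "G", random_filler(3), "T",
         random_filler(10), "TT")
}

# occupied intervals bookkeeping: list of integer matrices per replicon
overlaps_occupied <- function(occ, repl, start, end, margin = 5L) {
  m <- occ[[repl]]
  if (is.null(m) || nrow(m) == 0) return(FALSE)
  any(start <= m[, 2] + margin & end >= m[, 1] - margin)
}

# Apply collected plants (substring replacements) in one pass per replicon.
apply_plants <- function(seqs, plants) {
  if (!nrow(plants)) return(seqs)
  for (repl in unique(plants$replicon_id)) {
    ch <- seq_chars(seqs[[repl]])
    p <- plants[plants$replicon_id == repl, ]
    for (i in seq_len(nrow(p))) {
      ch[p$start[i]:p$end[i]] <- seq_chars(p$seq[i])
    }
    seqs[[repl]] <- paste(ch, collapse = "")
  }
  seqs
}

synth_promoter_plants <- function(cfg, layout, seqs, target_genes) {
  genes <- layout$genes
  w35 <- nchar(cfg$consensus_35)
  w10 <- nchar(cfg$consensus_10)
  groups <- c(rep("target", cfg$promoter_n_per_group),
              rep("non_target", cfg$promoter_n_per_group),
              rep("out_of_range", cfg$promoter_n_out_of_range))
  t_pool <- intersect(genes$gene_id, target_genes)
  nt_pool <- setdiff(genes$gene_id, target_genes)
  if (length(t_pool) < cfg$promoter_n_per_group ||
      length(nt_pool) < cfg$promoter_n_per_group + cfg$promoter_n_out_of_range) {
    stop("not enough genes to host the requested promoter plants", call. = FALSE)
  }
  host <- c(sample(t_pool, cfg$promoter_n_per_group),
            sample(nt_pool, cfg$promoter_n_per_group + cfg$promoter_n_out_of_range))
  occupied <- stats::setNames(vector("list", nrow(cfg$replicons)), cfg$replicons$id)
  plants <- purrr::map_dfr(seq_along(host), function(i) {
    g <- genes[genes$gene_id == host[i], ]
    grp <- groups[i]
    sp_len <- if (grp == "out_of_range") cfg$spacer_len_out_of_range else cfg$spacer_len
    at_mean <- switch(grp, target = cfg$spacer_at_target,
                      non_target = cfg$spacer_at_non_target,
                      out_of_range = cfg$spacer_at_non_target)
    at_draw <- max(25, min(90, stats::rnorm(1, at_mean, cfg$spacer_at_sd)))
    spacer <- random_filler(sp_len, at_prob = at_draw / 100)
    plant <- paste0(cfg$consensus_35, spacer, cfg$consensus_10)
    plen <- nchar(plant)
    if (g$strand == "+") {
      p_end <- g$start - 15L          # -10 3' end 15 bp upstream of start codon
      p_start <- p_end - plen + 1L
      fwd_seq <- plant
    } else {
      p_start <- g$end + 15L
      p_end <- p_start + plen - 1L
      fwd_seq <- revcomp(plant)
    }
    if (p_start < 1 || p_end > nchar(seqs[[g$replicon_id]])) return(NULL)
    if (overlaps_occupied(occupied, g$replicon_id, p_start, p_end)) return(NULL)
    occupied[[g$replicon_id]] <<- rbind(occupied[[g$replicon_id]],
                                        c(p_start, p_end))
    tibble::tibble(
      gene_id = g$gene_id, replicon_id = g$replicon_id, strand = g$strand,
      start = p_start, end = p_end, seq = fwd_seq, group = grp,
      spacer_len = sp_len, spacer_seq = spacer,
      spacer_at = at_percent(spacer)
    )
  })
  list(seqs = apply_plants(seqs, plants), plants = plants, occupied = occupied)
}

synth_motif_plants <- function(cfg, layout, sites, seqs, occupied) {
  place <- function(repl, lo, hi) {
    # budget of 20 draws for a free slot
    for (t in 1:20) {
      st <- sample(lo:hi, 1)
      en <- st + 21L
      if (!overlaps_occupied(occupied, repl, st, en, margin = 8L)) {
        occupied[[repl]] <<- rbind(occupied[[repl]], c(st, en))
        return(tibble::tibble(replicon_id = repl, start = st, end = en,
                              strand = "+", seq = canonical_motif()))
      }
    }
    NULL
  }
  plants <- list()
  # inside peak central regions: the count drives the enrichment model
  for (i in seq_len(nrow(sites))) {
    lam <- if (sites$in_island[i]) cfg$motif_lambda_island else cfg$motif_lambda_background
    n_i <- stats::rpois(1, lam)
    lo <- sites$summit[i] - 99L
    hi <- sites$summit[i] + 79L
    for (j in seq_len(n_i)) {
      p <- place(sites$replicon_id[i], lo, hi)
      if (!is.null(p)) plants[[length(plants) + 1L]] <- dplyr::mutate(p, context = "peak")
    }
  }
  # islands and background, away from peaks
  for (r in seq_len(nrow(cfg$replicons))) {
    repl <- cfg$replicons$id[r]
    isl <- layout$islands[layout$islands$replicon_id == repl, ]
    isl_len <- sum(isl$end - isl$start + 1)
    n_isl <- stats::rpois(1, isl_len / 1000 * cfg$motif_rate_island)
    for (j in seq_len(n_isl)) {
      k <- sample(seq_len(nrow(isl)), 1, prob = isl$end - isl$start + 1)
      p <- place(repl, isl$start[k], isl$end[k] - 22L)
      if (!is.null(p)) plants[[length(plants) + 1L]] <- dplyr::mutate(p, context = "island")
    }
    n_bg <- stats::rpois(1, cfg$replicons$length[r] / 1000 * cfg$motif_rate_background)
    for (j in seq_len(n_bg)) {
      p <- place(repl, 100L, cfg$replicons$length[r] - 130L)
      if (!is.null(p)) plants[[length(plants) + 1L]] <- dplyr::mutate(p, context = "background")
    }
  }
  plants <- dplyr::bind_rows(plants)
  if (nrow(plants)) plants$midpoint <- (plants$start + plants$end) / 2
  list(seqs = apply_plants(seqs, plants), plants = plants, occupied = occupied)
}

synth_peak_records <- function(cfg, sites, motif_plants, seqs) {
  region_start <- pmax(sites$summit - 99L, 1L)
  region_end <- pmin(sites$summit + 100L,
                     nchar(seqs)[sites$replicon_id])
  region_seq <- substring(seqs[sites$replicon_id], region_start, region_end)
  sites$at_percent <- at_percent(region_seq)
  sites$motif_count <- vapply(seq_len(nrow(sites)), function(i) {
    if (!nrow(motif_plants)) return(0L)
    sum(motif_plants$replicon_id == sites$replicon_id[i] &
          motif_plants$midpoint >= region_start[i] &
          motif_plants$midpoint <= region_end[i])
  }, integer(1))
  sites$ta_deviation <- if (cfg$beta_ta != 0) {
    vapply(region_seq, function(s) {
      d <- oligo_deviation(s, 2)
      d$deviation[d$word == "TA"]
    }, numeric(1), USE.NAMES = FALSE)
  } else rep(0, nrow(sites))
  sites$noise <- stats::rnorm(nrow(sites), 0, cfg$sigma)
  sites$fold_true <- pmax(
    1.01,
    cfg$beta0 + cfg$beta_at * sites$at_percent +
      cfg$beta_motif * sites$motif_count +
      cfg$beta_ta * sites$ta_deviation + sites$noise
  )
  sites$shared <- stats::runif(nrow(sites)) < cfg$shared_fraction
  # condition-specific binding is weak: damp its above-baseline fold
  sites$fold_true <- ifelse(sites$shared, sites$fold_true,
                            1 + cfg$specific_damp * (sites$fold_true - 1))
  sites$condition_if_specific <- ifelse(sites$shared, NA_character_,
                                        sample(c("FC", "BC"), nrow(sites),
                                               replace = TRUE))
  n_sites <- nrow(sites)
  site_idx <- rep(seq_len(n_sites), ifelse(sites$shared, 2L, 1L))
  condition <- unlist(lapply(seq_len(n_sites), function(i) {
    if (sites$shared[i]) c("FC", "BC") else sites$condition_if_specific[i]
  }))
  k <- length(site_idx)
  fold_cond <- pmax(1.01, sites$fold_true[site_idx] *
                      exp(stats::rnorm(k, 0, 0.03)))
  records <- tibble::tibble(
    replicon_id = rep(sites$replicon_id[site_idx], each = 3),
    summit = rep(sites$summit[site_idx], each = 3) +
      sample(-60:60, 3L * k, replace = TRUE),
    enrichment_fold = pmax(1.01, rep(fold_cond, each = 3) *
                             exp(stats::rnorm(3L * k, 0, 0.03))),
    q_value = stats::runif(3L * k, 0, 0.009),
    condition = rep(condition, each = 3),
    replicate = rep(paste0("rep", 1:3), times = k),
    site_id = rep(sites$site_id[site_idx], each = 3)
  )
  list(sites = sites, records = records)
}

synth_expression <- function(cfg, genes, target_genes) {
  is_mut <- grepl(cfg$mutant_tag, cfg$conditions, fixed = TRUE)
  purrr::map_dfr(seq_along(cfg$conditions), function(ci) {
    ml <- cfg$subset_meanlog[as.character(genes$subset)] +
      log(cfg$target_boost) * (genes$gene_id %in% target_genes) +
      log(cfg$mutant_shift) * (genes$gene_id %in% target_genes) * is_mut[ci]
    tibble::tibble(
      gene_id = genes$gene_id,
      condition = cfg$conditions[ci],
      expression = stats::rlnorm(nrow(genes), meanlog = ml,
                                 sdlog = cfg$expr_sdlog),
      true_meanlog = unname(ml)
    )
  })
}

synth_clusters <- function(cfg, genes) {
  st <- cfg$strains
  rest_genus <- setdiff(st$genus, st$species)
  rest_species <- setdiff(st$species, st$close)
  rest_close <- setdiff(st$close, st$focal)
  strains_for <- function(subset) {
    switch(as.character(subset),
      I = st$genus,
      II = c(st$species, sample(rest_genus, sample(0:(length(rest_genus) - 1L), 1))),
      III = c(st$close, sample(rest_species, sample(0:(length(rest_species) - 1L), 1))),
      IV = c(st$focal, sample(rest_close, sample(0:(length(rest_close) - 1L), 1)))
    )
  }
  tibble::tibble(
    gene_id = genes$gene_id,
    cluster_id = sprintf("clu_%04d", seq_len(nrow(genes))),
    strains = lapply(genes$subset, function(s) sort(strains_for(s)))
  )
}

mutate_site <- function(consensus, rate) {
  ch <- seq_chars(consensus)
  hit <- stats::runif(length(ch)) < rate
  ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(DNA_BASES, b), 1),
                    character(1))
  paste(ch, collapse = "")
}

synth_training_sites <- function(cfg) {
  list(
    minus35 = vapply(seq_len(cfg$n_training_sites),
                     function(i) mutate_site(cfg$consensus_35, cfg$training_mut_rate),
                     character(1)),
    minus10 = vapply(seq_len(cfg$n_training_sites),
                     function(i) mutate_site(cfg$consensus_10, cfg$training_mut_rate),
                     character(1))
  )
}

#' Generate a synthetic study dataset with a ground-truth ledger
#'
#' Produces a genome, annotation, raw peak records, expression table,
#' ortholog-cluster table, promoter training sets and planted promoters, all
#' deterministic given `config$seed`, together with a ledger recording every
#' planted feature (motif coordinates, per-site true AT%/motif count/noise,
#' per-gene subset and expression means, per-promoter group and spacer AT%).
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_data` with components `config`, `genome`
#'   (`DNAStringSet`), `genes`, `islands`, `peak_records`, `expression`
#'   (long tibble, including the true meanlog), `clusters`,
#'   `promoter_training`, `ledger` (list: `peak_sites`, `motif_plants`,
#'   `true_targets`, `promoter_plants`, `subset_proportions`).
#' @export
synth_generate <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) stop("`config` must be a synth_config", call. = FALSE)
  cfg <- config

  set.seed(sub_seed(cfg$seed, 1L))
  layout <- synth_layout(cfg)
  set.seed(sub_seed(cfg$seed, 2L))
  seqs <- synth_sequence(cfg, layout)
  set.seed(sub_seed(cfg$seed, 3L))
  sites <- synth_peak_sites(cfg, layout)
  truth <- naive_targets(sites, layout$genes)
  target_genes <- unique(truth$gene_id)
  set.seed(sub_seed(cfg$seed, 4L))
  prom <- synth_promoter_plants(cfg, layout, seqs, target_genes)
  set.seed(sub_seed(cfg$seed, 5L))
  mot <- synth_motif_plants(cfg, layout, sites, prom$seqs, prom$occupied)
  set.seed(sub_seed(cfg$seed, 6L))
  pk <- synth_peak_records(cfg, sites, mot$plants, mot$seqs)
  set.seed(sub_seed(cfg$seed, 7L))
  expr <- synth_expression(cfg, layout$genes, target_genes)
  set.seed(sub_seed(cfg$seed, 8L))
  clusters <- synth_clusters(cfg, layout$genes)
  set.seed(sub_seed(cfg$seed, 9L))
  training <- synth_training_sites(cfg)

  genome <- Biostrings::DNAStringSet(mot$seqs)
  S4Vectors::mcols(genome)$role <- cfg$replicons$role

  props <- prop.table(table(layout$genes$subset))
  structure(list(
    config = cfg,
    genome = genome,
    genes = layout$genes,
    islands = layout$islands,
    peak_records = pk$records,
    expression = expr,
    clusters = clusters,
    promoter_training = training,
    ledger = list(
      peak_sites = pk$sites,
      motif_plants = mot$plants,
      true_targets = truth,
      promoter_plants = prom$plants,
      subset_proportions = tibble::tibble(
        subset = names(props), proportion = as.numeric(props)
      )
    )
  ), class = "synth_data")
}

#' @export
print.synth_data <- function(x, ...) {
  cat("<synth_data> seed", x$config$seed, "|",
      nrow(x$config$replicons), "replicons (",
      sum(x$config$replicons$length), "bp ) |",
      nrow(x$genes), "genes |",
      nrow(x$ledger$peak_sites), "peak sites |",
      nrow(x$ledger$motif_plants), "planted motifs |",
      nrow(x$ledger$promoter_plants), "planted promoters\n")
  invisible(x)
}

#' Write a synthetic dataset to standard files
#'
#' Emits FASTA, GFF3, a raw-peak TSV, a wide expression TSV, a cluster TSV,
#' promoter-training FASTAs and the ledger tables, all plain text.
#'
#' @param x A `synth_data` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
synth_write <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome(x$genome, file.path(dir, "genome.fasta"))
  write_annotation(x$genes, file.path(dir, "annotation.gff3"))
  readr::write_tsv(dplyr::select(x$peak_records, -"site_id"),
                   file.path(dir, "peaks.tsv"))
  wide <- tidyr::pivot_wider(
    dplyr::select(x$expression, "gene_id", "condition", "expression"),
    names_from = "condition", values_from = "expression"
  )
  readr::write_tsv(wide, file.path(dir, "expression.tsv"))
  cl <- dplyr::mutate(x$clusters,
                      strains = vapply(.data$strains, paste, character(1),
                                       collapse = ","))
  readr::write_tsv(cl, file.path(dir, "clusters.tsv"))
  writeLines(paste0(">m35_", seq_along(x$promoter_training$minus35), "\n",
                    x$promoter_training$minus35),
             file.path(dir, "training_minus35.fasta"))
  writeLines(paste0(">m10_", seq_along(x$promoter_training$minus10), "\n",
                    x$promoter_training$minus10),
             file.path(dir, "training_minus10.fasta"))
  ledger_dir <- file.path(dir, "ledger")
  dir.create(ledger_dir, showWarnings = FALSE)
  for (nm in names(x$ledger)) {
    tbl <- x$ledger[[nm]]
    if (is.data.frame(tbl)) {
      tbl <- dplyr::mutate(tbl, dplyr::across(
        dplyr::where(is.list), ~vapply(.x, paste, character(1), collapse = ",")))
      readr::write_tsv(tbl, file.path(ledger_dir, paste0(nm, ".tsv")))
    }
  }
  invisible(dir)
}

#' Expected summary statistics implied by a ledger
#'
#' Closed-form / bookkeeping expectations for the main pipeline outputs, for
#' parameter-recovery tests: configured subset proportions, the enrichment
#' slope on AT% (`beta_at`, exact when `beta_motif = 0`), expected gene AT%
#' per subset (100 − replicon GC − subset offset, length-weighted across
#' replicons), the expected shared-peak fraction, and the planted expression
#' contrasts.
#'
#' @param x A `synth_data` object.
#' @return A list of tibbles/scalars.
#' @export
ledger_expectations <- function(x) {
  cfg <- x$config
  w <- cfg$n_genes / sum(cfg$n_genes)
  at_by_subset <- tibble::tibble(
    subset = names(cfg$subset_gc_offsets),
    expected_at = 100 - (sum(w * cfg$replicons$gc) + unname(cfg$subset_gc_offsets))
  )
  list(
    subset_proportions = tibble::tibble(
      subset = names(cfg$subset_proportions),
      proportion = unname(cfg$subset_proportions)
    ),
    slope_fold_on_at = cfg$beta_at,
    slope_fold_on_motifs = cfg$beta_motif,
    at_by_subset = at_by_subset,
    shared_fraction = cfg$shared_fraction,
    target_boost_log2 = log2(cfg$target_boost),
    mutant_shift_log2 = log2(cfg$mutant_shift),
    spacer_at_shift = cfg$spacer_at_target - cfg$spacer_at_non_target
  )
}
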