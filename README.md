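# silencerscope

Genome-wide characterisation of xenogeneic silencer targetomes from called
ChIP-seq peaks.

## The problem

Xenogeneic silencers — nucleoid-associated proteins such as H-NS, Lsr2,
MvaT, Rok and the zinc-finger MucR family of α-proteobacteria — bind and
transcriptionally repress horizontally acquired AT-rich DNA. Characterising
such a protein's **targetome** means answering, from ChIP-seq peak tables
plus a genome, annotation, expression data and an ortholog-cluster table:

* which peaks are reproducible across conditions, and which genes they
  regulate;
* what sequence signature the protein binds — AT%, a degenerate flexible
  motif with periodic T repeats (`TTxxxGxxxTxxxxxxxxxxTT`, with per-region
  indel tolerance), and word-level usage-deviation preferences (TpA steps);
* whether target promoters carry AT-rich spacers between their −35 and −10
  elements, predisposing them to high transcription;
* how targets distribute across replicons and hierarchical pangenome
  conservation classes (genus core → strain-specific), and how recruitment
  relates to conservation and expression.

`silencerscope` is a tidyverse-native R package implementing this pipeline,
with a fully seeded synthetic-data generator (ground-truth ledger included)
so every stage is testable end-to-end.

## Core methods

* **Peak consolidation** — single-linkage clustering of summit positions per
  replicon with a strict `< d` link rule (default *d* = 200 bp); consensus
  summit = lower median; per-condition fold = max over members; shared vs
  condition-specific classification.
* **Target assignment** — a gene is a target when a consensus summit lies in
  its regulation window `[start − 500, start + 100]` around the start codon
  (strand-aware, inclusive).
* **Flexible motif scan** — exact enumeration of all admissible gap
  realisations (gaps 3±1, 3±1, 10±2 around literals `TT`,`G`,`T`,`TT`), one
  match per (start, strand), validated against a brute-force oracle.
* **Zero-order-Markov usage deviation** —
  `dev(W) = obs(W) / [(L−k+1)·∏ f(Wᵢ)]`, per-region mononucleotide
  normalisation; per-word binding preference = Spearman ρ of `dev(W)` vs
  enrichment fold across peaks.
* **Promoter models** — per-element log-odds PSSMs
  (`log2[(count+0.5)/(n+2)/background]`), paired −35/−10 scan under
  spacer-length constraints, intergenic/intragenic classification, Welch
  tests of spacer AT% for target vs non-target promoters.
* **Pangenome integration** — hierarchical subset assignment (I genus core,
  II species core, III near-strain shared, IV strain-specific), Fisher
  exact enrichment by replicon/subset, AT% and expression group contrasts.

## Worked example

```r
library(silencerscope)

x <- synth_generate(synth_config(seed = 42))   # genome + peaks + truth ledger
merged <- merge_peaks(x$peak_records)
classify_condition_specific(merged)
#>   n_peaks n_shared n_condition_specific n_condition_specific_low_fold
#> 1     300      184                  116                            98

targets <- unique(assign_targets(merged, x$genes)$gene_id)
length(targets)
#> [1] 130

cr <- central_region(merged, x$genome)          # 200-bp central regions
m  <- scan_flexible(setNames(cr$seq, cr$peak_id))
pk <- tibble::tibble(
  peak_id = cr$peak_id, seq = cr$seq,
  at_percent = at_percent(cr$seq),
  motif_count = as.integer(table(factor(m$replicon_id, cr$peak_id))[cr$peak_id]),
  enrichment_fold = merged$enrichment_fold
)
tidy(recruitment_correlations(pk, bins = c(1, 2, 5, 10)))
#>   variable    scale    rho  p_value     n
#> 1 at_percent  raw    0.436 2.54e-15   300
#> 2 motif_count raw    0.380 1.03e-11   300
#> 3 at_percent  binned 0.885 1.15e- 1     4
#> 4 motif_count binned 0.956 4.42e- 2     4
```

Reading the output: 300 true binding sites were reconstructed from 1,470
raw per-sample peak records; 184 are shared between the free-living and
bacteroid conditions, and 98 of the 116 condition-specific peaks sit below
enrichment fold 5 — the weak-occupancy signature of condition-specific
silencer binding. 130 genes carry a summit in their regulation window.
Enrichment fold rises with both AT% and flexible-motif count of the central
region (raw Pearson ρ 0.44 and 0.38), the planted compositional preference
of the synthetic silencer.

Real data enter through `read_genome()`, `read_annotation()`,
`read_peaks()`, `read_expression()` and `read_clusters()`; every analysis
function takes plain tibbles, returns tibbles (or objects with
`tidy()`/`glance()` methods), and has an `autoplot()`/`plot_*()`
companion.

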