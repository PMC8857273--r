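---
title: "Characterising a xenogeneic silencer's targetome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising a xenogeneic silencer's targetome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silencerscope)
```

## The biological problem

Bacteria with open pangenomes continually acquire foreign DNA by horizontal
transfer. Newly acquired regions are AT-rich relative to the host genome, and
their promoters — in particular the spacer between the −35 and −10 elements —
are predisposed to high transcription. Xenogeneic silencers (H-NS, Lsr2,
MvaT, Rok, and the zinc-finger MucR family of α-proteobacteria) are
nucleoid-associated proteins that recognise this AT-rich signature and
repress it, buying the cell time to integrate useful foreign genes into its
regulatory network.

`silencerscope` implements the computational characterisation of such a
silencer's **targetome** from called ChIP-seq peaks: peak consolidation and
target-gene assignment, compositional signatures of binding (AT%, a flexible
periodic-T motif, oligonucleotide usage deviations), promoter-spacer
analysis, and integration with hierarchical pangenome conservation classes.
Everything runs end-to-end on synthetic genomes with planted structure, so
each stage can be validated against known ground truth.

## Peak consolidation and target assignment

Peaks called per sample (condition × replicate) are re-allocated to a common
peak id when their summits lie within a linking distance *d* (default 200 bp,
strictly `<`). On 1-D summit positions, single-linkage clustering reduces to
chaining sorted summits whose consecutive gaps are below *d*; records are
canonically sorted first, so the merge is invariant to input order. The
consensus summit is the lower median of member summits; a merged peak's
per-condition enrichment is the maximum member fold of that condition, a
conservative recovery of the strongest signal. We pool all samples in a
single clustering rather than merging within condition first: the pairwise
re-allocation rule has a unique minimal deterministic closure (transitive
chaining), and pooling avoids an arbitrary ordering of conditions.

A gene is a **target** of a peak when the consensus summit falls in the
gene's regulation window around the start codon, `[start − 500, start + 100]`
(strand-aware, both bounds inclusive — inclusivity is the common annotation
convention, and both extents are arguments). A peak may target two divergent
genes and a gene may carry several peaks. Operon membership is deliberately
not expanded: only the peak-proximal gene is called a target, which makes
target counts conservative. Windows crossing a replicon end are truncated
by default; `circular = TRUE` enables wrap-around for closed replicons.

Sequence features of a peak are computed on its **200-bp central region**
(summit-centred, `[summit − 99, summit + 100]`), truncated and flagged at
replicon ends.

## The flexible periodic-T motif

The class-A flexible pattern consists of the literal blocks `TT`, `G`, `T`,
`TT` separated by three non-conserved regions of nominal lengths 3, 3 and
10 nt. Each of the first two regions tolerates up to one insertion or
deletion and the third up to two, read as **per-region** tolerances — the
phrasing is parallel across regions, and a pooled budget for regions 1–2 is
available via `shared_budget = TRUE` for the alternative reading. The
default span is therefore 18–26 bp.

`scan_flexible()` reports every start position (per strand) where at least
one admissible gap assignment spells the literals in order. One match is
reported per (start, strand) even when several gap realisations fit — the
lexicographically smallest realisation is recorded — so counts mean "number
of match start sites" and are not inflated combinatorially. Overlapping
matches at different starts are all kept. Minus-strand matches are found by
scanning the reverse complement and reported on the forward axis. The
scanner is validated against an exhaustive gap-enumeration oracle.

For positional summaries, a match is located at its midpoint
`(start + end)/2`, a half-integer for even spans, used as a real value so no
systematic half-bp bias is introduced. Motif-to-gene distances are
strand-oriented (positive = into the coding region); matches are kept in
`[−500, +2000]`, and for genes shorter than 2 kb positive distances past the
stop codon are dropped so downstream intergenic sequence cannot masquerade
as intragenic signal. Distance analysis uses the coding strand only by
default — promoter analyses are oriented, and the pattern is not
palindromic — while genome-wide scans use both strands; both choices are
arguments. Densities are Gaussian-kernel estimates (bandwidth by Silverman's
rule unless overridden), renormalised so the trapezoid integral over the
plotted grid is exactly 1.

## Compositional signatures

`at_percent()` is `100·(A+T)/(A+C+G+T)`; `N` is excluded from both numerator
and denominator so assembly gaps do not bias composition, and an all-N
sequence is an error rather than a silent 0.

Oligonucleotide usage deviation (zero-order Markov): for a word *W* of
length *k* ∈ {2, 3, 4},

  deviation(W) = observed(W) / [(L − k + 1) · ∏ᵢ f(Wᵢ)]

with observed counts over overlapping, non-circular windows and *f* the
mononucleotide frequencies **of the analysed sequence itself**. Per-region
normalisation is used for peak regions (removing each region's own
mononucleotide bias, which is what isolates word-level structure such as
TpA steps); genome-wide deviations use genome-wide frequencies. A word whose
expectation is zero (an absent base) is reported `NA`, and a deviation is 0
exactly when the word is unobserved.

Per-word **binding preference** is the Spearman rank correlation, across
peaks, between the word's deviation in the 200-bp central region and the
peak's enrichment fold. For AT-binding silencers the TpA step — the most
flexible dinucleotide step, widening the minor groove the protein occupies —
is expected to rank highest. Benjamini–Hochberg correction across the 4^k
words is available (`adjust = TRUE`) but off by default, since raw rho/p per
word is the customary report. Regressing per-word rho on genome-wide
deviation (`preference_vs_genome_deviation()`) quantifies how far the
protein's preferences mirror genome-scale word usage (R² from OLS).

Recruitment-level relationships (`recruitment_correlations()`) report
Pearson correlations of enrichment fold with AT% and with motif count, both
on raw peaks and, when fold bins are supplied, on bin means. Default bin
edges `[1, 2), [2, 5), [5, 10), [10, ∞)` reuse the fold-5 cut that separates
low condition-specific peaks elsewhere in the analysis; the exact edges are
an argument because no canonical set exists.

## Promoter models and spacer AT%

For each sigma factor, −35 and −10 elements of a promoter training set are
turned into separate position-specific scoring matrices with pseudocount
0.5: column probability `(count + 0.5)/(n + 2)`, score
`log2(probability/background)`. The per-element score threshold is a
percentile of the training sites' own scores under the model (default: the
10th percentile, retaining 90% of training sites) — the original search
used an external tool with unstated cutoffs, so a self-contained,
reproducible rule is used instead and exposed in the model object.

`scan_paired()` slides both strands and reports every (−35, downstream −10)
pair whose spacer length falls in the sigma factor's admissible range;
overlapping pairs are all reported, because the downstream statistics are
per hit. Spacer-length defaults (RpoD 15–19 bp, others configurable) are
explicit placeholders for the user's organism-specific values. A hit is
**intragenic** when the 3′ end of its −10 element lies inside any gene body
on either strand (the −10 end is the transcription-proximal landmark);
the associated gene is the nearest downstream gene start on the hit strand
within 500 bp, mirroring the target-window upstream bound. Spacer AT% of
target-associated versus non-target-associated promoters is compared per
(sigma, context) stratum with Welch's t-test, with group sizes reported.

## Pangenome conservation classes

Genes are assigned to hierarchical subsets from an ortholog-cluster table
(clustering itself, e.g. CD-HIT at 70% identity, is upstream): subset I
(genus core) if the cluster spans all genus strains, else II (species core),
else III (shared by the closely related strains), else IV
(strain-specific). Genes absent from the cluster table are assigned IV with
a warning — strain-specific by absence of detectable orthologs, the natural
reading, flagged because it is an assumption. Target
enrichment/depletion per replicon and per subset uses two-sided Fisher exact
tests; BH-adjusted p-values are reported alongside raw ones within each
stratification family, since per-stratum stars and family-level control are
both wanted in practice. Gene AT% is computed over the annotated coding span
(strand-symmetric). Expression integration is descriptive only — group
means/medians, Welch tests of target vs non-target within subset, and a
paired wild-type vs mutant contrast for target genes on `log2(x + 1)`;
differential-expression calling is out of scope and consumed, if at all, as
an external table.

## The synthetic-data generator

`synth_generate()` produces a complete study dataset from a single integer
seed: a three-replicon genome (chromosome 300 kb at GC 62%, chromid 150 kb
at 61%, symbiosis plasmid 80 kb at 58% — the multipartite architecture and
GC ordering typical of rhizobia), 200 non-overlapping genes, AT-rich islands
(GC 42%, ~1 per 40 kb, applied to intergenic positions), conservation
subsets drawn with proportions 0.45/0.15/0.15/0.25 and gene-body GC offsets
+2/+0.5/−1/−3 (AT rising from genus core to strain-specific), planted
canonical motif instances, 300 binding sites with three replicate peak
records per condition, a lognormal expression table with subset-decreasing
means, an ortholog-cluster table realising the subset hierarchy, and
planted promoters with controlled spacer AT% (+8 points for
target-associated plants).

The enrichment model is

  fold = max(1.01, β₀ + β_AT·AT% + β_motif·motifs + β_TA·dev(TA) + ε),
  ε ~ N(0, σ)

evaluated on the true central region, with defaults β₀ = −10, β_AT = 0.45
per AT point, β_motif = 1.5 per match, β_TA = 0 (enabled only when the
TpA-coupling analysis is exercised) and σ = 2. The floor just above 1
mirrors real peak tables (folds exceed 1); β₀ is set so the floor binds for
under ~5% of sites — if the floor dominated, the linear model the generator
claims to instantiate would be unobservable and most folds would pin at the
boundary. Condition-specific sites (1 − shared fraction; shared fraction
0.65, matching the roughly two-thirds sharing seen in real silencer ChIP
data) have their above-baseline fold damped by a factor 0.25, emulating the
weak occupancy of condition-specific peaks. Every planted feature is
recorded in a ground-truth ledger sufficient to recompute expected
summaries without re-running the generator (`ledger_expectations()`).

Randomness comes from one seed; each component draws under a deterministic
sub-seed (`seed·97 + component offset`, kept below 2³¹), so outputs are
bitwise identical across runs and components are locally stable under
config changes elsewhere.

What the generator does **not** emulate: codon structure and ORFs, repeats
and low-complexity sequence, read-level noise (no FASTQ or coverage
tracks), operon structure, replication-strand skew, and real island
mosaicism. Passing tests therefore demonstrate the correctness of the
statistical machinery under the stated generative model — not robustness to
every artefact of real sequencing data.

## Numerical and edge-case conventions

* All public coordinates are 1-based inclusive (GFF3 convention); BED-style
  input (MACS2 summits) is converted on read.
* Out-of-bounds interval extraction is an error; only summit-centred
  windows and regulation windows truncate at replicon ends, and truncation
  is flagged.
* `N` never matches a motif literal or a PSSM column (score −∞) and is
  excluded from AT% entirely.
* Even-length merged chains take the lower median summit (ties resolve to
  the smaller coordinate); merge is strict (`<` threshold), so threshold 0
  is the identity partition.
* Spearman p-values under ties use the t approximation (the exact
  distribution is unavailable with ties); constant enrichment vectors are
  an error, not a silent `NA`.
* Density curves are renormalised to trapezoid integral 1 on the plotted
  grid (tolerance 1e−3 asserted in tests).

## Validation scale

The test suite validates desk-scale problems chosen to finish quickly while
leaving no behaviour untested: scanner-vs-oracle equivalence on one hundred
5-kb sequences plus short adversarial fixtures; merge-vs-oracle on 1,000
random peaks; parameter recovery over 20 seeded datasets of 500 peaks;
promoter recovery with 100 plants per group; Fisher size under a uniform
null over 40 replicates. The acceptance script
(`scripts/acceptance.R`) re-runs the full pipeline on a fresh synthetic
dataset and writes its headline quantities as JSON.

## Known limitations

* The published peak-table counts of the motivating study require its
  supplementary table, which cannot be redistributed here; the
  consolidation pipeline accepts such a table directly
  (`read_peaks()` + `merge_peaks()` + `classify_condition_specific()`).
* Promoter spacer-length thresholds and element widths are placeholders to
  be replaced with organism-specific values.
* The flexible-pattern scanner is exact but enumerative; for patterns with
  many more gap regions a lazier matching strategy would be needed.
* No genomic-island prediction: island coordinates, if wanted for
  stratified counts, are an input.
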