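---
title: "termscape: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{termscape: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model behind each stage, the thresholds and their defaults, what the
synthetic data emulate, and the numerical decisions taken where the
procedure was genuinely open.

## The biological problem

In bacteria, where a transcript ends is as much a regulatory decision as
where it starts. Rho-independent (intrinsic) terminators — a GC-rich RNA
hairpin followed by a run of uridines — release RNA polymerase
efficiently; Rho-dependent sites and post-transcriptional processing
leave 3′ ends with weaker or no structural signature. In high-GC
actinobacteria such as *Streptomyces*, background RNA structure is so
stable that terminator detection by folding energy alone needs a
genome-calibrated threshold rather than literature defaults. Term-seq
sequences the exact 3′ terminus of each transcript, producing per-strand
count tracks whose sharp peaks mark candidate transcript 3′-end positions
(TEPs), surrounded by lower "shadow" counts from imprecise ends.

## TEP calling

Calling works per replicate and per strand on the raw count track:

1. nonzero positions closer than `cluster_gap` (100 bp) are single-linkage
   clustered;
2. each cluster is greedily split left to right into subclusters whose
   positional *population* standard deviation stays below `subcluster_sd`
   (25); the maximum-count member of each subcluster represents it (a tie
   goes to the 5′-most position in transcript orientation);
3. representatives with fewer than `min_peak_count` (4) raw counts, or
   with no signal within `replicate_tol` (±2 nt) in every other
   replicate, are discarded;
4. each survivor gets a Z-score against its ±50-nt flank,
   `z = (x − μ)/max(σ, 1)`; the σ floor of 1 keeps sparse flanks from
   producing unbounded scores. The flank statistic is deliberately local:
   it asks how a peak compares with its own shadows;
5. survivors with `z > zscore_min` (6) *and* read-through fraction below
   0.5 become KNN training positives. The low-read-through screen is a
   deterministic replacement for what was historically a manual curation
   step (peaks with visibly decreased downstream RNA); it is the one
   place the calling chain consults RNA-seq. Negatives are the 20
   flanking offsets (−10..+10, excluding 0) of each positive;
6. a K-nearest-neighbour classifier (`knn_k = 5`, Euclidean distance on
   `log1p` count profiles of length 21) labels every candidate. Mean
   held-out accuracy over `cv_reps` (1000) random 50/50 splits is
   reported. The final call set is the union of positive calls over
   replicates, collapsing positions within ±2 nt (higher count wins).

KNN hyperparameters are conventional defaults — the profiles are nearly
separable by construction, so the classifier is insensitive to `k` in the
range 3–9; all values are configurable. The `log1p` transform stops a
single huge peak count from dominating the Euclidean metric.

Calls are categorized with the precedence Internal → P/S → Pre → A → N:
inside a same-strand CDS; within `downstream_assoc_window` (500 bp) past
a same-strand stop codon (highest count per gene = primary P, others
secondary S, nearest stop wins when windows overlap); between
`premature_offset` (70 bp) downstream of a primary TSS and its gene's
start codon (premature); inside an opposite-strand CDS (antisense);
otherwise intergenic. The precedence follows the order in which the
categories are defined; it matters only for the rare positions satisfying
two rules.

## TEP classification

The `fold_window` (40 nt) of upstream transcript sequence — offsets
−40..−1, the TEP base excluded — is folded at `fold_temperature` (30 °C,
the organism's growth temperature) by delegating to ViennaRNA's `RNAfold`
with default energy parameters; the engine and temperature are recorded
with the results. Ends with ΔG strictly below `hs_threshold`
(−23 kcal/mol) are highly structured; a tie is LS, since HS is defined by
"lower than" the split value. HS ends split on `utract_min_u` (3)
uridines within `utract_window` (8 nt) downstream of the stem.

"The stem" when several helices exist is the 3′-most hairpin — the helix
closest to the transcript end, where termination mechanics act — walked
outward while interior bulges stay ≤ 1 nt. When no pair exists at all the
U-tract window falls back to the 8 nt ending at the TEP, which keeps the
classification total. `bimodal_split()` is a diagnostic: it fits a
two-component Gaussian mixture to a ΔG sample and reports where the
weighted component densities intersect (components closer than
1 kcal/mol are a degenerate fit and flagged); the pipeline itself always
uses the fixed configured threshold.

Nucleotide enrichment divides per-offset base frequencies among TEPs by a
background computed as the position-averaged base frequency over
`random_n` (10 000) seeded uniform genomic positions; sampling is uniform
per strand because the reference procedure specifies only "random
genomic positions".

## Read-through and coverage statistics

The read-through fraction is the downstream-flank sum over the
upstream-flank sum of (RPM-normalized) coverage, offsets +1..+300 over
−300..−1 in transcript orientation, averaged over growth phases. The TEP
base belongs to neither flank: that is the only assignment under which
flat coverage gives exactly 1 and a clean 100→10 step gives exactly 0.1,
and it avoids counting one base twice. Zero upstream signal makes the
fraction undefined; such records are flagged and excluded from
distribution summaries rather than imputed. Summaries discard the top 5 %
of values (`trimmed_distribution_summary`) before reporting medians, as
read-through ratios are unbounded above. Which library normalization
underlies "normalized counts" is not observable from the outputs; RPM per
library is used, and the fraction is invariant to it anyway since both
flanks share the factor.

## TU and TUC assembly

Every same-strand TSS × TEP combination with positive span up to
`max_span` (20 kb, a tractability bound on the all-pairs search) is
evaluated over the region from `tss_offset` (100 bp) past the TSS to
`tep_offset` (100 bp) before the TEP — pairs spanning under
`short_pair_cutoff` (200 bp) use the untrimmed region. Windows of
`tu_window` (200 bp) slide by 1 nt across the whole evaluation region;
a phase passes when every window's normalized mean exceeds `tu_frac`
(5 %) of the region mean and no window's raw mean falls below
`tu_min_raw` (5). The raw-count rule is read as excluding the *candidate*
in that phase (a raw-coverage gap breaks transcript continuity); the
lenient reading that merely skips the window is available as
`tu_window_rule = "skip-window"`. One passing phase suffices.

Accepted TUs are categorized by the genes whose CDS is *fully* contained
in the span on the same strand (Mono = 1, Poly ≥ 2; gene-free TUs are Pre
when ending at a premature TEP, else Inter). TUCs are the connected
components of the ≥ 1-bp interval-overlap graph, computed by a sorted
sweep; members whose TEP equals the cluster's 3′-most TEP are terminal,
ties included.

## Downstream analyses

Convergent TEPs (plus-strand end `f`, minus-strand end `r`) overlap by
`f − r + 1` nt; pairs with overlap in [1, 60) are bidirectional TEPs,
matched greedily from the smallest overlap so each end joins at most one
pair. COG enrichment of a gene set is the modal category's share of the
category-assigned genes (L, L, C, unassigned → 2/3). 3′-UTR lengths run
from the first base after the stop codon to the primary TEP inclusive.
The small-protein screen recomputes the median CDS RPF RPKM and median
log2 RPF/RNA ratio from the supplied annotation, falling back to the
published genome-wide values (18.75 and 0.74) only when no CDS set is
given; candidate ORFs may start at ATG, GTG or TTG, the common start
codons of high-GC actinobacteria. Poisson protein distances use pairwise
gap deletion and `d = −ln(1 − p)` with no variance estimation.

## The synthetic data: what it emulates, and what it does not

`simulate_dataset()` is the package's study-conditions generator. Its
defaults — 20 genes on a single contig at GC 0.72, intergenic spacers of
700–900 nt, two term-seq replicates with Poisson main peaks of mean 50,
six shadow draws per end at positional sd 3 nt (truncated to ±10),
background 0.02 counts/nt, four RNA-seq phases at depth 100 with
step-down ratios 0.05 / 0.4 / 0.9 for HS-U-rich / HS-U-lack / LS, and a
class mix of 0.4 / 0.3 / 0.3 — were chosen once as a realistic desk-scale
miniature of a term-seq experiment in a GC-rich actinobacterium: peak
heights and noise give clean but nontrivial separation, and spacer and
cassette geometry guarantee that flanks, read-through regions and
neighbouring transcription units never collide by construction.

Planted HS cassettes (GC stem of 10–12 bp, all-A loop of 4–6 nt, then an
8-nt U-tract or a U-free 8-mer) are *verified against the folding engine
at planting time* with a 2 kcal/mol margin beyond the class threshold, so
truth labels remain correct even when a call jitters by a couple of
nucleotides; LS flanks are resampled from the background composition
until they fold weaker than the threshold, with an unpairable A/G
fallback after 20 attempts. All generators are bit-reproducible from
their seed.

What passing tests on these data show: the calling chain resolves
shadows, the replicate/intensity/Z-score/KNN screens keep true ends and
reject background, classification recovers planted structure classes,
and TU assembly reconstructs planted TSS–TEP spans. What they cannot
show: behaviour under real library-size imbalance, 3′-end heterogeneity
beyond symmetric Gaussian shadows, RNA structure contexts not planted
(pseudoknots, tandem terminators), Rho-dependent termination biology, or
genome-scale multiplicity — the reference study's counts (1,427 TEPs,
1,648 TUs, 610 TUCs) arise from deep real libraries and are not
reproducible from a toy genome, which is why the acceptance checks are
property-based at this scale.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open everywhere internally and in
  BED/TSV outputs; GFF3 is converted on read/write by one tested pair of
  functions. Upstream/downstream always mean transcript orientation;
  minus-strand windows are reverse-complemented, never re-indexed.
* Population (n-denominator) standard deviations are used for the
  subclustering bound, the Z-score flanks and the premature-TU log-ratio
  spread.
* All-zero term-seq tracks yield empty call sets, not errors; all-zero
  coverage makes RPM normalization fail loudly.
* Ties: subcluster representatives break toward the 5′-most transcript
  position; ΔG exactly at the threshold is LS; TUs sharing the 3′-most
  TEP of a TUC are all terminal.
* Windows clipped at contig edges are computed on the available
  positions and flagged; upstream folding windows clipped below 10 nt
  are skipped with a warning.
* Every stochastic step (generators, CV splits, random backgrounds)
  takes an explicit seed and restores the caller's RNG state.

## Problem sizes

The test-suite and the acceptance script run the complete pipeline on the
default 20-gene (~30 kb) simulation — about 5 s end to end including
folding and the 1000-split cross-validation — plus brute-force oracle
comparisons on regions up to 2 kb, position sets up to 500, and
structures up to 16 nt. These sizes were chosen so every oracle can be
exhaustive or near-exhaustive while the simulated signal still exercises
clustering, shadows, replicate logic and multi-phase coverage.

## Known limitations

* The folding engine's default dangling-end treatment is accepted as-is;
  energies from engines with other defaults may shift near-threshold
  classifications.
* The SVM comparison classifier of the original workflow is out of
  scope; only KNN is implemented.
* Motif discovery, covariance-model scans of noncoding TUs, and
  alignment computation are consumed, not produced: `poisson_distance`
  expects pre-aligned sequences.
* `categorize_teps` assigns one gene per TEP; genuinely ambiguous ends
  between convergent genes keep only the nearest association.
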