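# termscape

Genome-wide mapping and interpretation of bacterial transcript 3′ ends
from term-seq data, built for high-GC actinobacterial genomes where
intrinsic terminators carry unusually stable GC hairpins.

## What it does

Term-seq captures exact transcript 3′ termini; each sequenced 3′ end
increments a per-strand count track. `termscape` turns replicate tracks of
those counts, plus a genome, gene annotation, transcription start sites
(TSSs) and RNA-seq coverage, into an annotated transcription landscape:

1. **TEP calling.** Transcript 3′-end positions (TEPs) are called by
   single-linkage clustering of nonzero peaks (gaps < 100 bp), greedy
   subclustering at positional standard deviation < 25, selection of the
   maximum-intensity representative per subcluster, discarding peaks with
   fewer than 4 raw counts or absent from a biological replicate, and a
   K-nearest-neighbour classifier over the 21-count profile at offsets
   −10..+10. Training positives are peaks with flank Z-score
   z = (x − μ)/max(σ, 1) > 6 and a decreased downstream RNA profile; the
   final call set is the union of positively labelled candidates over
   replicates.
2. **TEP classification.** The 40-nt upstream RNA of every call is folded
   at 30 °C (ViennaRNA). Ends with ΔG < −23 kcal/mol are highly
   structured (HS); HS ends with ≥ 3 uridines in the 8 nt downstream of
   the stem are HS-U-rich (canonical intrinsic terminators), the rest
   HS-U-lack; everything else is LS. Stem length, loop length, stem-end
   offset, nucleotide enrichment and base-pair interaction frequencies
   are computed alongside.
3. **TU/TUC assembly.** Every same-strand TSS × TEP combination is a
   transcription-unit (TU) candidate; it is accepted when every 200-bp
   window (slid by 1 bp between TSS+100 and TEP−100) exceeds 5 % of the
   region's mean normalized coverage, with raw window means ≥ 5, in at
   least one growth phase. Overlapping TUs form TU clusters (TUCs);
   members ending at the cluster's 3′-most TEP are terminal.
4. **Downstream statistics.** Read-through fraction (downstream/upstream
   300-bp flank ratio around each TEP, averaged over phases),
   bidirectional TEP pairs (convergent 3′ ends overlapping < 60 bp), COG
   functional enrichment (modal-category share of assigned genes),
   3′-UTR lengths from primary TEPs, small-protein screening of
   noncoding TUs (RPF and RPF/RNA medians + ORF rule), and
   Poisson-corrected protein distances d = −ln(1 − p).

A synthetic-data module generates a GC-rich toy genome with planted
terminator cassettes and matched term-seq/RNA-seq/RPF tracks, so the whole
pipeline runs and is tested without any external data.

## Worked example

```r
library(termscape)

sim <- simulate_dataset(seed = 1)            # 20 genes, GC 0.72
run <- run_pipeline(sim$genome, sim$genes, sim$tss,
                    sim$termseq, sim$rnaseq)
recovery_metrics(run, sim$truth)
run$report$readthrough_by_class
```

On the default simulation this prints precision, recall, class agreement
and TU recall of `1.0` over the 20 planted ends, KNN cross-validation
accuracies of `98.6 %` and `99.0 %` for the two replicates, and trimmed
median read-through fractions of `0.050` (HS-U-rich), `0.399` (HS-U-lack)
and `0.903` (LS) — recovering the planted step-down ratios 0.05/0.4/0.9
and their ordering: structured, U-tract-bearing ends terminate most
efficiently.

The same analysis, written out step by step with on-disk intermediates
(FASTA/GFF3/BedGraph/TSV under `results/`), lives in the numbered scripts
in `analysis/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_teps.R
Rscript analysis/03_classify_teps.R
Rscript analysis/04_assemble_tus.R
Rscript analysis/05_downstream.R
```

## Vignette

`vignettes/termscape-methods.Rmd` documents the model assumptions, every
tunable threshold with its default and unit, what the synthetic generator
does and does not emulate, and the numerical conventions (coordinate
system, tie-breaks, degenerate inputs).
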