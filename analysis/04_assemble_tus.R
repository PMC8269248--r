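#!/usr/bin/env Rscript
# Step 4 - assemble transcription units and TU clusters.
#
# Tests every same-strand TSS x TEP combination with the sliding-window
# continuity criterion (200-bp windows moved by 1 bp between TSS+100 and
# TEP-100; every window above 5% of the region mean and raw mean >= 5 in
# at least one phase), categorizes the accepted TUs by gene content,
# clusters overlapping TUs into TUCs, and labels terminal/nonterminal
# members. BED/TSV outputs land under results/features.

suppressPackageStartupMessages(library(termscape))

d <- "results/simulated_data"
genome <- read_genome(file.path(d, "genome.fa"))
genes <- read_genes(file.path(d, "genes.gff3"))
tss <- read_tss(file.path(d, "tss.tsv"))
teps <- read.table("results/teps_classified.tsv", header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
rnaseq <- lapply(1:4, function(ph)
  read_bedgraph_track(file.path(d, sprintf("rnaseq_phase%d_plus.bg", ph)),
                      file.path(d, sprintf("rnaseq_phase%d_minus.bg", ph)),
                      genome$lengths))

config <- pipeline_config()
tus <- assemble_tus(tss, teps, rnaseq, genes, config)
tc <- build_tucs(tus)
tus <- assign_terminality(tc$tus)

message("TUs by category:")
print(table(tus$category))
message("TUCs: ", nrow(tc$tucs), " (",
        sum(tc$tucs$n_tus == 1), " single-TU, ",
        sum(tc$tucs$n_tus > 1), " multi-TU)")
message("terminality: ",
        sum(tus$terminality == "terminal"), " terminal, ",
        sum(tus$terminality == "nonterminal"), " nonterminal")

write_features(teps, tus, tc$tucs, "results/features")
message("wrote results/features/{teps,tus,tucs}.{bed,tsv}")
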