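#!/usr/bin/env Rscript
# Step 5 - downstream statistics over the assembled landscape.
#
# Detects bidirectional (convergent) TEP pairs, computes per-TUC COG
# functional enrichment, the 3'-UTR length histogram from primary TEPs,
# the small-protein screen over gene-free TUs (RPF / RPF-to-RNA medians +
# ORF rule), recovery against the planted truth, and the final summary
# report.

suppressPackageStartupMessages(library(termscape))

d <- "results/simulated_data"
genome <- read_genome(file.path(d, "genome.fa"))
genes <- read_genes(file.path(d, "genes.gff3"))
truth <- read.table(file.path(d, "truth.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
feats <- read_features("results/features")
teps <- feats$teps; tus <- feats$tus; tucs <- feats$tucs
rna <- read_bedgraph_track(file.path(d, "rnaseq_phase1_plus.bg"),
                           file.path(d, "rnaseq_phase1_minus.bg"),
                           genome$lengths)
rpf <- read_bedgraph_track(file.path(d, "rpf_plus.bg"),
                           file.path(d, "rpf_minus.bg"), genome$lengths)

config <- pipeline_config()
biteps <- detect_biteps(teps[teps$category != "Internal", ],
                        config$bitep_max_overlap)
message("Bi-TEP pairs: ", nrow(biteps), " (",
        2 * nrow(biteps), " member TEPs)")

tuc_scores <- vapply(seq_len(nrow(tucs)), function(k) {
  members <- tus[tus$tuc_id == tucs$tuc_id[k], ]
  ids <- unlist(strsplit(members$gene_ids[!is.na(members$gene_ids) &
                                          nzchar(members$gene_ids)], ","))
  cog_enrichment(genes$cog[match(unique(ids), genes$gene_id)])
}, 0)
message("mean per-TUC COG enrichment: ",
        sprintf("%.3f", mean(tuc_scores, na.rm = TRUE)))

utr <- utr3_lengths(genes, teps)
message("3'-UTR lengths (primary TEPs): median ",
        stats::median(utr$lengths$length), " nt; modal bin ",
        names(which.max(utr$histogram)))
write.table(utr$lengths, "results/utr3_lengths.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

noncoding <- tus[tus$n_genes == 0, , drop = FALSE]
if (nrow(noncoding)) {
  sp <- screen_small_proteins(noncoding, rna, rpf, genes, genome, config)
  message("small-protein candidates among ", nrow(noncoding),
          " gene-free TUs: ", sum(sp$candidate))
  write.table(sp, "results/small_protein_screen.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
} else {
  message("no gene-free TUs to screen (every planted TU is coding)")
}

# recovery against the planted truth
tol <- 2
matched <- vapply(seq_len(nrow(truth)), function(i)
  any(teps$contig == truth$contig[i] & teps$strand == truth$strand[i] &
      abs(teps$position - truth$position[i]) <= tol), TRUE)
message(sprintf("planted-TEP recall at +/-%d nt: %.2f", tol,
                mean(matched)))

rep_ <- report_summary(teps, tus, tucs, biteps)
message("TEP categories: ", paste(names(rep_$tep_category),
                                  rep_$tep_category, collapse = ", "))
message("total TEPs ", rep_$total_teps, "; TUs ", rep_$total_tus,
        "; TUCs ", rep_$total_tucs)
sink("results/report.txt")
print(rep_[c("tep_category", "tep_class", "tu_category", "tuc_sizes")])
cat("bi-TEP pairs:", rep_$n_biteps_pairs, "\n")
sink()
message("wrote results/report.txt")
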