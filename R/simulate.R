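#' Generate a toy GC-rich genome with annotated genes and TSSs
#'
#' Builds a single-contig genome emulating a high-GC actinobacterial
#' chromosome (default GC 0.72): non-overlapping genes on both strands,
#' each with an ATG start codon, an in-frame stop codon, a primary TSS
#' 20-150 nt upstream of the start codon, and intergenic spacers of at
#' least 700 nt so 3'-flank cassettes, read-through regions and flank
#' statistics never collide.
#'
#' @param n_genes number of genes (>= 1).
#' @param gc target GC fraction in (0, 1).
#' @param seed RNG seed; the construction is bit-reproducible.
#' @return list with `genome` (a `termscape_genome`), `genes` (data.frame),
#'   `tss` (data.frame).
#' @export
generate_genome <- function(n_genes = 20, gc = 0.72, seed = 1) {
  stopifnot(n_genes >= 1, gc > 0, gc < 1)
  local_seeded(seed, {
    spacer <- sample(700:900, n_genes + 1, replace = TRUE)
    cds_len <- 3 * sample(150:300, n_genes, replace = TRUE)  # 450-900 nt
    tss_off <- sample(20:150, n_genes, replace = TRUE)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    total <- sum(spacer) + sum(cds_len)
    base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                    T = (1 - gc) / 2)
    seq_chars <- sample(names(base_probs), total, replace = TRUE,
                        prob = base_probs)
    cds_start <- integer(n_genes)
    cursor <- 0L
    for (i in seq_len(n_genes)) {
      cursor <- cursor + spacer[i]
      cds_start[i] <- cursor
      cursor <- cursor + cds_len[i]
    }
    cds_end <- cds_start + cds_len
    stops <- c("TGA", "TAA", "TAG")
    for (i in seq_len(n_genes)) {
      stop_codon <- sample(stops, 1)
      if (strand[i] == "+") {
        seq_chars[(cds_start[i] + 1):(cds_start[i] + 3)] <-
          c("A", "T", "G")
        seq_chars[(cds_end[i] - 2):cds_end[i]] <-
          strsplit(stop_codon, "")[[1]]
      } else {
        seq_chars[(cds_end[i] - 2):cds_end[i]] <- c("C", "A", "T")
        seq_chars[(cds_start[i] + 1):(cds_start[i] + 3)] <-
          rev(strsplit(chartr("ACGT", "TGCA", stop_codon), "")[[1]])
      }
    }
    cogs <- sample(c("J", "K", "L", "C", "E", "G", "M", "T"), n_genes,
                   replace = TRUE)
    genes <- data.frame(
      gene_id = sprintf("g%03d", seq_len(n_genes)),
      contig = "chr",
      strand = strand,
      cds_start = cds_start,
      cds_end = cds_end,
      cog = cogs,
      smbgc = NA_character_,
      stringsAsFactors = FALSE
    )
    tss_pos <- ifelse(strand == "+", cds_start - tss_off,
                      cds_end - 1L + tss_off)
    tss <- data.frame(
      contig = "chr",
      position = as.integer(tss_pos),
      strand = strand,
      category = "primary",
      gene_id = genes$gene_id,
      stringsAsFactors = FALSE
    )
    genome <- new_genome(c(chr = paste(seq_chars, collapse = "")))
    list(genome = genome, genes = genes, tss = tss)
  })
}

#' Plant terminator cassettes and record ground truth
#'
#' Writes into each gene's 3' flank one of three cassettes and records the
#' intended TEP:
#' \itemize{
#'   \item HS-U-rich: a GC inverted repeat (stem 10-12 bp, all-A loop of
#'     4-6 nt) followed by an 8-nt oligo-U tract (T on the coding strand);
#'     the TEP sits at the last tract base.
#'   \item HS-U-lack: the same hairpin followed by a T-free 8-mer.
#'   \item LS: no inverted repeat; the 40-nt window upstream of the TEP is
#'     resampled from the background composition until it folds weaker
#'     than the HS threshold (bounded retries, with an unpairable A/G
#'     fallback).
#' }
#' Cassettes are verified against the folding engine at planting time with
#' a 2 kcal/mol safety margin so that calls jittered by a couple of
#' nucleotides still classify correctly. Minus-strand cassettes are
#' reverse-complemented into the genome.
#'
#' @param sim output of [generate_genome()].
#' @param class_mix named proportions for HS-U-rich / HS-U-lack / LS
#'   (summing to 1).
#' @param seed RNG seed.
#' @param config a [pipeline_config()] (folding window/temperature and
#'   class thresholds).
#' @return list with modified `genome`, `genes`, `tss`, and `truth`, a
#'   data.frame of planted TEPs (contig, position, strand, class,
#'   category, gene_id, tss).
#' @export
plant_terminators <- function(sim,
                              class_mix = c("HS-U-rich" = 0.4,
                                            "HS-U-lack" = 0.3,
                                            "LS" = 0.3),
                              seed = 1,
                              config = pipeline_config()) {
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix proportions must sum to 1")
  genome <- sim$genome
  genes <- sim$genes
  local_seeded(seed, {
    n <- nrow(genes)
    classes <- sample(names(class_mix), n, replace = TRUE,
                      prob = class_mix)
    chars <- strsplit(genome$contigs[["chr"]], "")[[1]]
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      d <- sample(80:140, 1)
      if (genes$strand[i] == "+") {
        tep <- genes$cds_end[i] - 1L + d
      } else {
        tep <- genes$cds_start[i] - d
      }
      cassette <- build_cassette(classes[i], chars, tep, genes$strand[i],
                                 config)
      chars <- cassette$chars
      truth[[i]] <- data.frame(
        contig = "chr", position = tep, strand = genes$strand[i],
        class = classes[i], category = "P", gene_id = genes$gene_id[i],
        tss = sim$tss$position[i], stringsAsFactors = FALSE
      )
    }
    genome2 <- new_genome(c(chr = paste(chars, collapse = "")))
    list(genome = genome2, genes = genes, tss = sim$tss,
         truth = do.call(rbind, truth))
  })
}

# stamp one cassette ending at the TEP; returns modified char vector
build_cassette <- function(class, chars, tep, strand, config) {
  margin <- 2
  for (attempt in 1:30) {
    if (class %in% c("HS-U-rich", "HS-U-lack")) {
      stem_len <- sample(10:12, 1)
      loop_len <- sample(4:6, 1)
      stem <- sample(c("G", "C"), stem_len, replace = TRUE)
      loop <- rep("A", loop_len)
      rc_stem <- rev(chartr("GC", "CG", stem))
      tract <- if (class == "HS-U-rich") rep("T", 8)
               else sample(c("G", "C", "A"), 8, replace = TRUE)
      cassette <- c(stem, loop, rc_stem, tract)
    } else {
      # LS: composition-matched resample of the folded window plus the
      # TEP base; no planted repeat
      cassette <- sample(c("A", "C", "G", "T"), config$fold_window + 1,
                        replace = TRUE,
                        prob = c(0.14, 0.36, 0.36, 0.14))
      if (attempt > 20) cassette <- sample(c("A", "G"),
                                           config$fold_window + 1,
                                           replace = TRUE)
    }
    chars2 <- stamp_cassette(chars, cassette, tep, strand)
    tmp_genome <- list(contigs = list(chr = paste(chars2, collapse = "")),
                       lengths = c(chr = length(chars2)))
    class(tmp_genome) <- "termscape_genome"
    win <- window_seq(tmp_genome, "chr", tep, strand,
                      -config$fold_window, -1, rna = TRUE)
    dg <- fold_mfe_batch(win, config$fold_temperature)$delta_g
    ok <- if (class == "LS") dg > config$hs_threshold + margin
          else dg < config$hs_threshold - margin
    if (ok) return(list(chars = chars2, delta_g = dg))
  }
  stop("placement error: could not realize a ", class,
       " cassette near position ", tep)
}

stamp_cassette <- function(chars, cassette, tep, strand) {
  C <- length(cassette)
  if (strand == "+") {
    g0 <- tep - C + 1L  # 0-based
    if (g0 < 0) stop("placement error: flank too short for cassette")
    chars[(g0 + 1):(tep + 1)] <- cassette
  } else {
    g1 <- tep + C - 1L
    if (g1 >= length(chars))
      stop("placement error: flank too short for cassette")
    rc <- rev(chartr("ACGT", "TGCA", cassette))
    chars[(tep + 1):(g1 + 1)] <- rc
  }
  chars
}

#' Simulate replicate term-seq 3'-end count tracks
#'
#' For every planted TEP and replicate: a main-peak count drawn
#' Poisson(`peak_height`) at the true position, `n_shadows` shadow counts
#' at offsets drawn rounded-Normal(0, `shadow_sd`) truncated to +/-10 nt
#' with per-shadow mean `peak_height / 10`, plus uniform Poisson background
#' at `noise_rate` counts/nt. All replicates share the truth; the noise
#' differs.
#'
#' @param truth planted-TEP table from [plant_terminators()].
#' @param lengths named contig lengths.
#' @param replicates number of replicate tracks (>= 2).
#' @param peak_height mean main-peak count.
#' @param shadow_sd positional sd of shadows, nt.
#' @param n_shadows shadow draws per TEP.
#' @param noise_rate background counts per nt.
#' @param seed RNG seed.
#' @return list of `termscape_track`, one per replicate.
#' @export
simulate_termseq <- function(truth, lengths, replicates = 2,
                             peak_height = 50, shadow_sd = 3,
                             n_shadows = 6, noise_rate = 0.02, seed = 1) {
  stopifnot(replicates >= 2)
  local_seeded(seed, {
    lapply(seq_len(replicates), function(r) {
      tr <- new_track(lengths)
      for (contig in names(lengths)) {
        L <- lengths[[contig]]
        for (strand in c("+", "-")) {
          bg <- if (noise_rate > 0) stats::rpois(L, noise_rate)
                else integer(L)
          key <- if (strand == "+") "plus" else "minus"
          tr[[contig]][[key]] <- as.numeric(bg)
        }
      }
      for (i in seq_len(nrow(truth))) {
        p <- truth$position[i]
        ct <- truth$contig[i]
        st <- truth$strand[i]
        tr <- track_add(tr, ct, st, p, stats::rpois(1, peak_height))
        if (n_shadows > 0) {
          offs <- pmax(-10, pmin(10, round(stats::rnorm(n_shadows, 0,
                                                        shadow_sd))))
          cnts <- stats::rpois(n_shadows, peak_height / 10)
          for (k in seq_len(n_shadows)) {
            sp <- p + offs[k]
            if (sp >= 0 && sp < lengths[[ct]] && cnts[k] > 0)
              tr <- track_add(tr, ct, st, sp, cnts[k])
          }
        }
      }
      tr
    })
  })
}

#' Simulate per-phase RNA-seq coverage with step-downs at planted TEPs
#'
#' Coverage mean is `depth` over each planted TU span (TSS..TEP),
#' `depth * ratio(class)` over the `readthrough_len` nt downstream of the
#' TEP, and `background_frac * depth` elsewhere. Each growth phase draws
#' independent Poisson noise around the same means (`noise = FALSE` returns
#' the exact means, useful for analytic checks).
#'
#' @param truth planted-TEP table (with `tss` column).
#' @param lengths named contig lengths.
#' @param phases number of growth phases.
#' @param depth mean within-TU coverage.
#' @param readthrough_by_class named down-step ratios per class.
#' @param readthrough_len nt of down-stepped coverage past the TEP.
#' @param background_frac intergenic background as a fraction of depth.
#' @param noise draw Poisson noise (TRUE) or return exact means (FALSE).
#' @param seed RNG seed.
#' @return list of `termscape_track`, one per phase.
#' @export
simulate_rnaseq <- function(truth, lengths, phases = 4, depth = 100,
                            readthrough_by_class = c("HS-U-rich" = 0.05,
                                                     "HS-U-lack" = 0.4,
                                                     "LS" = 0.9),
                            readthrough_len = 350,
                            background_frac = 0.01,
                            noise = TRUE, seed = 1) {
  mean_tr <- new_track(lengths)
  for (contig in names(lengths)) {
    L <- lengths[[contig]]
    mean_tr[[contig]]$plus <- rep(background_frac * depth, L)
    mean_tr[[contig]]$minus <- rep(background_frac * depth, L)
  }
  for (i in seq_len(nrow(truth))) {
    ct <- truth$contig[i]; st <- truth$strand[i]
    tss <- truth$tss[i]; tep <- truth$position[i]
    span <- if (st == "+") tss:tep else tep:tss
    mean_tr <- track_set(mean_tr, ct, st, span, depth)
    ratio <- readthrough_by_class[[truth$class[i]]]
    rt <- tx_positions(tep, st, seq_len(readthrough_len))
    rt <- rt[rt >= 0 & rt < lengths[[ct]]]
    mean_tr <- track_set(mean_tr, ct, st, rt, depth * ratio)
  }
  if (!noise) return(rep(list(mean_tr), phases))
  local_seeded(seed, {
    lapply(seq_len(phases), function(ph) {
      tr <- mean_tr
      for (contig in names(lengths)) {
        tr[[contig]]$plus <- as.numeric(
          stats::rpois(length(tr[[contig]]$plus), mean_tr[[contig]]$plus))
        tr[[contig]]$minus <- as.numeric(
          stats::rpois(length(tr[[contig]]$minus), mean_tr[[contig]]$minus))
      }
      tr
    })
  })
}

#' Simulate ribosome-profiling coverage
#'
#' RPF mean is `coding_boost` times the RNA mean inside CDSs and inside any
#' designated small-protein spans, and background elsewhere; Poisson noise
#' on top.
#'
#' @param rnaseq_track one RNA-seq `termscape_track` (means or a phase).
#' @param genes gene table (CDS spans).
#' @param lengths named contig lengths.
#' @param coding_boost multiplicative RPF enrichment in coding regions
#'   (> 1).
#' @param small_protein_spans optional data.frame (contig, start, end,
#'   strand; 0-based half-open) of intergenic regions that translate.
#' @param background mean RPF level outside coding regions.
#' @param noise draw Poisson noise or return exact means.
#' @param seed RNG seed.
#' @return a `termscape_track`.
#' @export
simulate_rpf <- function(rnaseq_track, genes, lengths, coding_boost = 3,
                         small_protein_spans = NULL, background = 0.5,
                         noise = TRUE, seed = 1) {
  stopifnot(coding_boost > 1)
  tr <- new_track(lengths)
  for (contig in names(lengths)) {
    tr[[contig]]$plus <- rep(background, lengths[[contig]])
    tr[[contig]]$minus <- rep(background, lengths[[contig]])
  }
  spans <- data.frame(contig = genes$contig, start = genes$cds_start,
                      end = genes$cds_end, strand = genes$strand,
                      stringsAsFactors = FALSE)
  if (!is.null(small_protein_spans))
    spans <- rbind(spans, small_protein_spans[, c("contig", "start",
                                                  "end", "strand")])
  for (i in seq_len(nrow(spans))) {
    pos <- spans$start[i]:(spans$end[i] - 1)
    rna <- track_values(rnaseq_track, spans$contig[i], spans$strand[i], pos)
    tr <- track_set(tr, spans$contig[i], spans$strand[i], pos,
                    coding_boost * rna)
  }
  if (!noise) return(tr)
  local_seeded(seed, {
    for (contig in names(lengths)) {
      tr[[contig]]$plus <- as.numeric(stats::rpois(lengths[[contig]],
                                                   tr[[contig]]$plus))
      tr[[contig]]$minus <- as.numeric(stats::rpois(lengths[[contig]],
                                                    tr[[contig]]$minus))
    }
    tr
  })
}

#' Simulate a complete data set under the default study conditions
#'
#' Convenience wrapper chaining [generate_genome()], [plant_terminators()],
#' [simulate_termseq()], [simulate_rnaseq()] and [simulate_rpf()] with the
#' default conditions used throughout the test-suite: 20 genes at GC 0.72,
#' two term-seq replicates at mean peak height 50 with background 0.02
#' counts/nt, and four RNA-seq phases at depth 100 with class step-down
#' ratios 0.05 / 0.4 / 0.9.
#'
#' @param seed master seed; sub-stages derive fixed offsets from it.
#' @param n_genes,gc,class_mix,peak_height,noise_rate,replicates,phases,depth
#'   generator conditions (see the stage functions).
#' @param out_dir if non-NULL, writes FASTA, GFF3, TSS TSV, BedGraphs and
#'   the truth TSV there.
#' @param config a [pipeline_config()].
#' @return list with `genome`, `genes`, `tss`, `truth`, `termseq` (list of
#'   replicate tracks), `rnaseq` (list of phase tracks), `rpf`.
#' @export
simulate_dataset <- function(seed = 1, n_genes = 20, gc = 0.72,
                             class_mix = c("HS-U-rich" = 0.4,
                                           "HS-U-lack" = 0.3,
                                           "LS" = 0.3),
                             peak_height = 50, noise_rate = 0.02,
                             replicates = 2, phases = 4, depth = 100,
                             out_dir = NULL,
                             config = pipeline_config()) {
  sim <- generate_genome(n_genes = n_genes, gc = gc, seed = seed)
  planted <- plant_terminators(sim, class_mix = class_mix,
                               seed = seed + 11L, config = config)
  lengths <- planted$genome$lengths
  termseq <- simulate_termseq(planted$truth, lengths,
                              replicates = replicates,
                              peak_height = peak_height,
                              noise_rate = noise_rate, seed = seed + 23L)
  rnaseq <- simulate_rnaseq(planted$truth, lengths, phases = phases,
                            depth = depth, seed = seed + 37L)
  rpf <- simulate_rpf(rnaseq[[1]], planted$genes, lengths,
                      seed = seed + 41L)
  out <- list(genome = planted$genome, genes = planted$genes,
              tss = planted$tss, truth = planted$truth,
              termseq = termseq, rnaseq = rnaseq, rpf = rpf)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genome(out$genome, file.path(out_dir, "genome.fa"))
    write_genes(out$genes, out$genome, file.path(out_dir, "genes.gff3"))
    write_tss(out$tss, file.path(out_dir, "tss.tsv"))
    utils::write.table(out$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (r in seq_along(termseq)) {
      write_bedgraph_track(termseq[[r]], "+",
                           file.path(out_dir,
                                     sprintf("termseq_rep%d_plus.bg", r)))
      write_bedgraph_track(termseq[[r]], "-",
                           file.path(out_dir,
                                     sprintf("termseq_rep%d_minus.bg", r)))
    }
    for (ph in seq_along(rnaseq)) {
      write_bedgraph_track(rnaseq[[ph]], "+",
                           file.path(out_dir,
                                     sprintf("rnaseq_phase%d_plus.bg", ph)))
      write_bedgraph_track(rnaseq[[ph]], "-",
                           file.path(out_dir,
                                     sprintf("rnaseq_phase%d_minus.bg", ph)))
    }
    write_bedgraph_track(rpf, "+", file.path(out_dir, "rpf_plus.bg"))
    write_bedgraph_track(rpf, "-", file.path(out_dir, "rpf_minus.bg"))
  }
  out
}
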