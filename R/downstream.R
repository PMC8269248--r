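#' Detect bidirectional (convergent) TEP pairs
#'
#' A plus-strand TEP at `f` and a minus-strand TEP at `r` on the same
#' contig converge with overlap `f - r + 1` nt; a pair is reported when
#' `1 <= overlap < bitep_max_overlap`. Each TEP joins at most one pair:
#' valid pairs are matched greedily from the smallest overlap (nearest
#' partner) up, which prevents double counting in dense regions.
#'
#' @param teps TEP data.frame (contig, position, strand).
#' @param bitep_max_overlap bp bound, exclusive (default 60).
#' @return data.frame with forward_idx, reverse_idx (row indices into
#'   `teps`), forward_pos, reverse_pos, overlap.
#' @export
detect_biteps <- function(teps, bitep_max_overlap = 60) {
  empty <- data.frame(forward_idx = integer(0), reverse_idx = integer(0),
                      forward_pos = integer(0), reverse_pos = integer(0),
                      overlap = integer(0))
  fwd <- which(teps$strand == "+")
  rev_ <- which(teps$strand == "-")
  if (!length(fwd) || !length(rev_)) return(empty)
  cand <- list()
  for (i in fwd) for (j in rev_) {
    if (teps$contig[i] != teps$contig[j]) next
    ov <- teps$position[i] - teps$position[j] + 1
    if (ov >= 1 && ov < bitep_max_overlap)
      cand[[length(cand) + 1]] <- c(i, j, ov)
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  used <- integer(0)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (cand[k, 1] %in% used || cand[k, 2] %in% used) next
    keep[k] <- TRUE
    used <- c(used, cand[k, 1], cand[k, 2])
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(forward_idx = cand[, 1], reverse_idx = cand[, 2],
             forward_pos = teps$position[cand[, 1]],
             reverse_pos = teps$position[cand[, 2]],
             overlap = cand[, 3])
}

#' COG functional enrichment of a gene set
#'
#' The fraction of category-assigned genes that fall in the modal
#' category; genes without an assigned category are not counted. A set of
#' categories L, L, C with one unassigned gene scores 2/3.
#'
#' @param cogs character vector of single-letter categories, `NA` for
#'   unassigned.
#' @return score in (0, 1], or `NA` (flagged) when no gene is assigned.
#' @export
cog_enrichment <- function(cogs) {
  cogs <- cogs[!is.na(cogs) & nzchar(cogs)]
  if (!length(cogs)) return(NA_real_)
  max(table(cogs)) / length(cogs)
}

#' 3'-UTR lengths from primary TEPs
#'
#' For every gene with a primary (P) TEP, the distance from the first base
#' after the stop codon to the TEP base inclusive, in transcript
#' orientation, with a histogram in `bin_width`-nt bins. Secondary TEPs
#' are not used.
#'
#' @param genes gene table.
#' @param teps categorized TEP table.
#' @param bin_width histogram bin width, nt (default 10).
#' @return list with `lengths` (data.frame gene_id, length, bin) and
#'   `histogram` (table by bin label).
#' @export
utr3_lengths <- function(genes, teps, bin_width = 10) {
  p <- teps[teps$category == "P", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(p))) {
    g <- genes[genes$gene_id == p$gene_id[i], , drop = FALSE]
    if (!nrow(g)) next
    len <- if (g$strand[1] == "+") p$position[i] - g$cds_end[1] + 1
           else g$cds_start[1] - p$position[i]
    if (len < 1) next
    rows[[length(rows) + 1]] <- data.frame(gene_id = g$gene_id[1],
                                           length = len,
                                           stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(list(lengths = data.frame(gene_id = character(0),
                                     length = integer(0),
                                     bin = character(0)),
                histogram = table(character(0))))
  df <- do.call(rbind, rows)
  lo <- (df$length %/% bin_width) * bin_width
  df$bin <- sprintf("%d-%d", lo, lo + bin_width - 1)
  list(lengths = df, histogram = table(df$bin))
}

# first ORF (configurable starts, in-frame stop) fully inside a
# transcript-orientation sequence; returns TRUE/FALSE
has_orf <- function(seq, starts = c("ATG", "GTG", "TTG"),
                    stops = c("TGA", "TAA", "TAG"), min_codons = 2) {
  n <- nchar(seq)
  if (n < (min_codons + 1) * 3) return(FALSE)
  for (i in seq_len(n - 5)) {
    if (!substr(seq, i, i + 2) %in% starts) next
    j <- i + 3
    while (j + 2 <= n) {
      if (substr(seq, j, j + 2) %in% stops) {
        if ((j - i) / 3 >= min_codons) return(TRUE)
        break
      }
      j <- j + 3
    }
  }
  FALSE
}

#' Screen intergenic TUs for potential small proteins
#'
#' A noncoding TU is a small-protein candidate when (i) its mean RPF RPKM
#' exceeds the median RPF RPKM of the CDS set, (ii) its log2 RPF/RNA RPKM
#' ratio exceeds the CDS median of the same ratio, and (iii) an ORF with a
#' start codon (ATG/GTG/TTG) and an in-frame stop lies fully within the TU
#' on its strand. The medians are recomputed from the supplied CDS set;
#' the published genome-wide values (18.75 and 0.74) are used only when no
#' CDS set is given.
#'
#' @param tus data.frame of candidate TUs (contig, start, end, strand).
#' @param rna_track,rpf_track raw coverage tracks.
#' @param genes CDS set for the medians, or `NULL` for the defaults.
#' @param genome a `termscape_genome` for ORF scanning.
#' @param config a [pipeline_config()].
#' @return `tus` with columns `rpf_rpkm`, `log2_rpf_rna`, `has_orf`,
#'   `candidate`.
#' @export
screen_small_proteins <- function(tus, rna_track, rpf_track, genes,
                                  genome, config = pipeline_config()) {
  rna_tot <- track_total(rna_track)
  rpf_tot <- track_total(rpf_track)
  feature_stats <- function(df) {
    rpf <- vapply(seq_len(nrow(df)), function(i)
      rpkm(rpf_track, df$contig[i], df$start[i], df$end[i], df$strand[i],
           rpf_tot), 0)
    rna <- vapply(seq_len(nrow(df)), function(i)
      rpkm(rna_track, df$contig[i], df$start[i], df$end[i], df$strand[i],
           rna_tot), 0)
    list(rpf = rpf, ratio = log2(ifelse(rna > 0 & rpf > 0, rpf / rna, NA)))
  }
  if (!is.null(genes) && nrow(genes)) {
    cds <- data.frame(contig = genes$contig, start = genes$cds_start,
                      end = genes$cds_end, strand = genes$strand,
                      stringsAsFactors = FALSE)
    cs <- feature_stats(cds)
    med_rpf <- stats::median(cs$rpf, na.rm = TRUE)
    med_ratio <- stats::median(cs$ratio, na.rm = TRUE)
  } else {
    med_rpf <- config$rpf_median_default
    med_ratio <- config$rpf_rna_log_ratio_default
  }
  st <- feature_stats(tus)
  tus$rpf_rpkm <- st$rpf
  tus$log2_rpf_rna <- st$ratio
  tus$has_orf <- vapply(seq_len(nrow(tus)), function(i) {
    s <- window_seq(genome, tus$contig[i],
                    if (tus$strand[i] == "+") tus$start[i]
                    else tus$end[i] - 1,
                    tus$strand[i], 0, tus$end[i] - tus$start[i] - 1,
                    rna = FALSE)
    has_orf(s)
  }, TRUE)
  tus$candidate <- tus$rpf_rpkm > med_rpf &
    !is.na(tus$log2_rpf_rna) & tus$log2_rpf_rna > med_ratio &
    tus$has_orf
  attr(tus, "medians") <- c(rpf = med_rpf, log2_ratio = med_ratio)
  tus
}

#' Poisson-corrected distance between two aligned protein sequences
#'
#' Sites where either sequence carries a gap are skipped (pairwise
#' deletion); `p` is the fraction of compared sites that differ and the
#' distance is `d = -ln(1 - p)`, the Poisson model with no variance
#' estimation.
#'
#' @param a,b aligned sequences of equal length ('-' for gaps).
#' @return list with `p`, `d` (Inf flagged when p = 1) and
#'   `compared_sites`; both NA when no sites compare.
#' @export
poisson_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("aligned lengths differ")
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  use <- ca != "-" & cb != "-"
  n <- sum(use)
  if (n == 0)
    return(list(p = NA_real_, d = NA_real_, compared_sites = 0L))
  p <- sum(ca[use] != cb[use]) / n
  list(p = p, d = -log(1 - p), compared_sites = n)
}

#' Summary report over a completed run
#'
#' Tallies TEP categories and classes, TU categories, TUC sizes and
#' Bi-TEPs, summarizes read-through by class (top outliers trimmed) and
#' compares the class distributions with two-sided rank-sum tests.
#'
#' @param teps classified, categorized TEP table (with `readthrough`).
#' @param tus TU table with `tuc_id`.
#' @param tucs TUC table.
#' @param biteps Bi-TEP pair table.
#' @param trim outlier fraction for the read-through summaries.
#' @return list of tables: `tep_category`, `tep_class`, `tu_category`,
#'   `tuc_sizes`, totals, `readthrough_by_class`
#'   (trimmed summaries), `rank_sum_p` (pairwise class comparisons),
#'   `n_biteps_pairs`, `n_biteps_members`.
#' @export
report_summary <- function(teps, tus, tucs, biteps = NULL, trim = 0.05) {
  noninternal <- teps[teps$category != "Internal", , drop = FALSE]
  tep_category <- tally(teps$category,
                        c("P", "S", "Pre", "A", "N", "Internal"))
  tep_class <- tally(noninternal$class,
                     c("HS-U-rich", "HS-U-lack", "LS"))
  tu_category <- tally(tus$category, c("Mono", "Poly", "Pre", "Inter"))
  tuc_sizes <- if (!is.null(tucs) && nrow(tucs))
    table(factor(ifelse(tucs$n_tus == 1, "single", "multi"),
                 levels = c("single", "multi")))
  else table(factor(character(0), levels = c("single", "multi")))
  rt <- list(); pvals <- list()
  if (!is.null(noninternal$readthrough) && !is.null(noninternal$class)) {
    for (cl in c("HS-U-rich", "HS-U-lack", "LS")) {
      v <- noninternal$readthrough[noninternal$class == cl]
      v <- v[!is.na(v)]
      if (length(v)) rt[[cl]] <- trimmed_distribution_summary(v, trim)
    }
    combos <- utils::combn(c("HS-U-rich", "HS-U-lack", "LS"), 2)
    for (k in seq_len(ncol(combos))) {
      a <- noninternal$readthrough[noninternal$class == combos[1, k]]
      b <- noninternal$readthrough[noninternal$class == combos[2, k]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) && length(b))
        pvals[[paste(combos[, k], collapse = " vs ")]] <-
          stats::wilcox.test(a, b, exact = FALSE)$p.value
    }
  }
  list(tep_category = tep_category,
       tep_class = tep_class,
       tu_category = tu_category,
       tuc_sizes = tuc_sizes,
       total_teps = sum(tep_category),
       total_noninternal_teps = nrow(noninternal),
       total_tus = sum(tu_category),
       total_tucs = if (!is.null(tucs)) nrow(tucs) else 0L,
       readthrough_by_class = rt,
       rank_sum_p = pvals,
       n_biteps_pairs = if (!is.null(biteps)) nrow(biteps) else 0L,
       n_biteps_members = if (!is.null(biteps)) 2L * nrow(biteps) else 0L)
}

tally <- function(x, levels) {
  if (is.null(x)) x <- character(0)
  table(factor(x, levels = levels))
}
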