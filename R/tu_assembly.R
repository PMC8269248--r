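#' Candidate TSS-TEP pairs
#'
#' All same-contig, same-strand combinations with the TEP downstream of
#' the TSS in transcript orientation and a span of at most `max_span` bp
#' (an explicit tractability bound on the otherwise unbounded all-pairs
#' search).
#'
#' @param tss TSS table.
#' @param teps TEP table.
#' @param max_span bp (default 20000).
#' @return data.frame with tss_idx, tep_idx, contig, strand, tss, tep and
#'   `span` (nt, TSS base through TEP base inclusive).
#' @export
candidate_pairs <- function(tss, teps, max_span = 20000) {
  out <- list()
  for (i in seq_len(nrow(tss))) {
    same <- which(teps$contig == tss$contig[i] &
                  teps$strand == tss$strand[i])
    if (!length(same)) next
    if (tss$strand[i] == "+") {
      span <- teps$position[same] - tss$position[i] + 1
    } else {
      span <- tss$position[i] - teps$position[same] + 1
    }
    ok <- span > 1 & span <= max_span
    if (!any(ok)) next
    out[[length(out) + 1]] <- data.frame(
      tss_idx = i, tep_idx = same[ok], contig = tss$contig[i],
      strand = tss$strand[i], tss = tss$position[i],
      tep = teps$position[same[ok]], span = span[ok],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(tss_idx = integer(0), tep_idx = integer(0),
                      contig = character(0), strand = character(0),
                      tss = integer(0), tep = integer(0),
                      span = integer(0)))
  do.call(rbind, out)
}

#' Evaluate one TSS-TEP pair by sliding-window coverage continuity
#'
#' The evaluation region runs from `tss_offset` bp downstream of the TSS
#' to `tep_offset` bp upstream of the TEP (transcript orientation); pairs
#' spanning fewer than `short_pair_cutoff` bp are evaluated over the full
#' TSS..TEP region without end trimming. Per phase, windows of `tu_window`
#' bp slide by 1 nt across the region (a region shorter than the window is
#' a single window); the phase passes when every window's normalized mean
#' exceeds `tu_frac` of the region's normalized mean and every window's
#' raw mean is at least `tu_min_raw` (under the default
#' "exclude-candidate" rule; "skip-window" only ignores low-raw windows).
#' The pair is a TU when at least one phase passes.
#'
#' @param pair one row of [candidate_pairs()].
#' @param cov_norm list of per-phase RPM-normalized tracks.
#' @param cov_raw list of per-phase raw tracks.
#' @param config a [pipeline_config()].
#' @return list with `is_tu` and `passing_phases` (integer indices).
#' @export
evaluate_pair <- function(pair, cov_norm, cov_raw,
                          config = pipeline_config()) {
  reg <- evaluation_region(pair$tss, pair$tep, pair$strand,
                           config$tss_offset, config$tep_offset,
                           config$short_pair_cutoff)
  passing <- integer(0)
  for (ph in seq_along(cov_norm)) {
    vn <- track_values(cov_norm[[ph]], pair$contig, pair$strand, reg)
    vr <- track_values(cov_raw[[ph]], pair$contig, pair$strand, reg)
    if (phase_passes(vn, vr, config)) passing <- c(passing, ph)
  }
  list(is_tu = length(passing) > 0, passing_phases = passing)
}

# genomic 0-based positions of the evaluation region, 5'->3'
evaluation_region <- function(tss, tep, strand, tss_offset, tep_offset,
                              short_cutoff) {
  span <- if (strand == "+") tep - tss + 1 else tss - tep + 1
  if (span < short_cutoff || span <= tss_offset + tep_offset) {
    offs <- 0:(span - 1)
  } else {
    offs <- tss_offset:(span - 1 - tep_offset)
  }
  tx_positions(tss, strand, offs)
}

phase_passes <- function(vn, vr, config) {
  w <- min(config$tu_window, length(vn))
  region_mean <- mean(vn)
  win_norm <- window_means(vn, w)
  win_raw <- window_means(vr, w)
  low_raw <- win_raw < config$tu_min_raw
  if (config$tu_window_rule == "exclude-candidate") {
    if (any(low_raw)) return(FALSE)
    all(win_norm > config$tu_frac * region_mean)
  } else {
    use <- !low_raw
    if (!any(use)) return(FALSE)
    all(win_norm[use] > config$tu_frac * region_mean)
  }
}

# means of all length-w windows sliding by 1 over v
window_means <- function(v, w) {
  n <- length(v)
  if (w >= n) return(mean(v))
  cs <- cumsum(c(0, v))
  (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
}

#' Categorize a TU by its gene content
#'
#' Counts genes whose CDS is fully contained in the TU span on the same
#' strand: 1 gene is monocistronic, 2+ polycistronic; gene-free TUs ending
#' in a premature TEP are premature, the rest intergenic.
#'
#' @param tu row with contig, strand and genomic `start`/`end` (0-based
#'   half-open).
#' @param genes gene table.
#' @param tep_category category of the TU's TEP.
#' @return list with `category` ("Mono"/"Poly"/"Pre"/"Inter") and
#'   `gene_ids`.
#' @export
categorize_tu <- function(tu, genes, tep_category) {
  inside <- genes$contig == tu$contig & genes$strand == tu$strand &
    genes$cds_start >= tu$start & genes$cds_end <= tu$end
  ids <- genes$gene_id[inside]
  category <- if (length(ids) >= 2) "Poly"
  else if (length(ids) == 1) "Mono"
  else if (identical(tep_category, "Pre")) "Pre"
  else "Inter"
  list(category = category, gene_ids = ids)
}

#' Assemble TUs from called TEPs, TSSs and coverage
#'
#' Runs [candidate_pairs()] and [evaluate_pair()] over all combinations
#' and categorizes the accepted TUs.
#'
#' @param tss TSS table.
#' @param teps categorized TEP table.
#' @param cov_raw list of per-phase raw coverage tracks.
#' @param genes gene table.
#' @param config a [pipeline_config()].
#' @return data.frame of TUs: tu_id, contig, strand, tss, tep, start, end
#'   (genomic half-open span), span, category, n_genes, gene_ids
#'   (comma-separated), tep_category, passing_phases (comma-separated).
#' @export
assemble_tus <- function(tss, teps, cov_raw, genes,
                         config = pipeline_config()) {
  cov_norm <- lapply(cov_raw, normalize_rpm)
  pairs <- candidate_pairs(tss, teps, config$max_span)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    pr <- pairs[i, ]
    ev <- evaluate_pair(pr, cov_norm, cov_raw, config)
    if (!ev$is_tu) next
    start <- min(pr$tss, pr$tep)
    end <- max(pr$tss, pr$tep) + 1
    cat_res <- categorize_tu(list(contig = pr$contig, strand = pr$strand,
                                  start = start, end = end),
                             genes, teps$category[pr$tep_idx])
    rows[[length(rows) + 1]] <- data.frame(
      contig = pr$contig, strand = pr$strand, tss = pr$tss, tep = pr$tep,
      start = start, end = end, span = pr$span,
      category = cat_res$category,
      n_genes = length(cat_res$gene_ids),
      gene_ids = paste(cat_res$gene_ids, collapse = ","),
      tep_category = teps$category[pr$tep_idx],
      tep_idx = pr$tep_idx,
      passing_phases = paste(ev$passing_phases, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(tu_id = character(0), contig = character(0),
                      strand = character(0), tss = integer(0),
                      tep = integer(0), start = integer(0),
                      end = integer(0), span = integer(0),
                      category = character(0), n_genes = integer(0),
                      gene_ids = character(0), tep_category = character(0),
                      tep_idx = integer(0), passing_phases = character(0)))
  tus <- do.call(rbind, rows)
  tus <- tus[order(tus$contig, tus$start, tus$end), , drop = FALSE]
  tus$tu_id <- sprintf("TU%04d", seq_len(nrow(tus)))
  rownames(tus) <- NULL
  tus[, c("tu_id", setdiff(names(tus), "tu_id"))]
}

#' Cluster TUs into TUCs by interval overlap
#'
#' Connected components of the >= 1 bp overlap graph over TU spans, per
#' contig and strand (half-open spans sharing only a boundary do not
#' overlap).
#'
#' @param tus TU data.frame from [assemble_tus()].
#' @return list with `tus` (input plus `tuc_id`) and `tucs` (data.frame:
#'   tuc_id, contig, strand, start, end, n_tus, member ids).
#' @export
build_tucs <- function(tus) {
  tus$tuc_id <- NA_character_
  tuc_rows <- list()
  k <- 0L
  for (ct in unique(tus$contig)) for (st in c("+", "-")) {
    idx <- which(tus$contig == ct & tus$strand == st)
    if (!length(idx)) next
    idx <- idx[order(tus$start[idx])]
    comp_end <- -Inf
    comp <- integer(0)
    flush <- function(members) {
      k <<- k + 1L
      id <- sprintf("TUC%03d", k)
      tus$tuc_id[members] <<- id
      tuc_rows[[k]] <<- data.frame(
        tuc_id = id, contig = ct, strand = st,
        start = min(tus$start[members]), end = max(tus$end[members]),
        n_tus = length(members),
        members = paste(tus$tu_id[members], collapse = ","),
        stringsAsFactors = FALSE)
    }
    for (i in idx) {
      if (length(comp) && tus$start[i] >= comp_end) {
        flush(comp)
        comp <- integer(0); comp_end <- -Inf
      }
      comp <- c(comp, i)
      comp_end <- max(comp_end, tus$end[i])
    }
    if (length(comp)) flush(comp)
  }
  list(tus = tus, tucs = do.call(rbind, tuc_rows))
}

#' Terminal vs nonterminal labelling within TUCs
#'
#' TUs whose TEP coincides with the 3'-most TEP of their TUC are terminal;
#' the rest are nonterminal. The labels propagate to the TEPs.
#'
#' @param tus TU data.frame carrying `tuc_id` (from [build_tucs()]).
#' @return `tus` with a `terminality` column ("terminal"/"nonterminal").
#' @export
assign_terminality <- function(tus) {
  tus$terminality <- NA_character_
  for (id in unique(tus$tuc_id)) {
    idx <- which(tus$tuc_id == id)
    st <- tus$strand[idx[1]]
    term_tep <- if (st == "+") max(tus$tep[idx]) else min(tus$tep[idx])
    tus$terminality[idx] <- ifelse(tus$tep[idx] == term_tep,
                                   "terminal", "nonterminal")
  }
  tus
}
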