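#' Reads-per-million normalization of a track
#'
#' Scales every position by `1e6 / total` where the total is the sum over
#' both strands of all contigs.
#'
#' @param track a `termscape_track`.
#' @return the normalized track (total becomes 1e6).
#' @export
normalize_rpm <- function(track) {
  tot <- track_total(track)
  if (tot <= 0) stop("normalization error: empty track")
  f <- 1e6 / tot
  for (contig in names(track)) {
    track[[contig]]$plus <- track[[contig]]$plus * f
    track[[contig]]$minus <- track[[contig]]$minus * f
  }
  track
}

#' Read-through fraction at a transcript 3' end
#'
#' Per phase, the sum of coverage over the downstream flank (transcript
#' offsets `+1..+flank`) divided by the sum over the upstream flank
#' (`-flank..-1`); the TEP base itself belongs to neither flank, so flat
#' coverage gives exactly 1. The reported value is the arithmetic mean over
#' phases. A zero upstream sum makes the phase (and, if all phases are
#' zero, the record) undefined and flagged.
#'
#' @param cov_list list of per-phase `termscape_track`s (typically
#'   RPM-normalized).
#' @param contig,position,strand TEP coordinates.
#' @param flank flank length, bp (default 300).
#' @return list with `fraction` (mean over defined phases, NA if none),
#'   `per_phase` and `flagged`.
#' @export
readthrough_fraction <- function(cov_list, contig, position, strand,
                                 flank = 300) {
  per_phase <- vapply(cov_list, function(tr) {
    up <- sum(track_values(tr, contig, strand,
                           tx_positions(position, strand, -(flank:1))))
    down <- sum(track_values(tr, contig, strand,
                             tx_positions(position, strand, 1:flank)))
    if (up == 0) NA_real_ else down / up
  }, 0)
  ok <- !is.na(per_phase)
  list(fraction = if (any(ok)) mean(per_phase[ok]) else NA_real_,
       per_phase = per_phase,
       flagged = !all(ok))
}

#' Mean normalized read-density profile around TEPs
#'
#' Per TEP and phase the coverage window at offsets `-flank..+flank` is
#' scaled so its maximum is 1; scaled windows are summed across TEPs per
#' offset and divided by the grand sum, and the per-phase profiles are
#' averaged. Windows with no coverage are skipped.
#'
#' @param teps TEP data.frame.
#' @param cov_list list of per-phase tracks.
#' @param flank offset half-width (default 300).
#' @return list with `profile` (numeric, sums to 1 over offsets),
#'   `offsets`, `skipped` (count of all-zero windows).
#' @export
density_profile <- function(teps, cov_list, flank = 300) {
  if (!nrow(teps)) stop("density_profile: empty TEP set")
  offs <- -flank:flank
  skipped <- 0L
  phase_profiles <- lapply(cov_list, function(tr) {
    acc <- numeric(length(offs))
    for (i in seq_len(nrow(teps))) {
      v <- track_values(tr, teps$contig[i], teps$strand[i],
                        tx_positions(teps$position[i], teps$strand[i],
                                     offs))
      m <- max(v)
      if (m <= 0) { skipped <<- skipped + 1L; next }
      acc <- acc + v / m
    }
    if (sum(acc) > 0) acc / sum(acc) else acc
  })
  profile <- Reduce(`+`, phase_profiles) / length(phase_profiles)
  list(profile = profile, offsets = offs, skipped = skipped)
}

#' RPKM of a feature
#'
#' `count_sum / ((length / 1e3) * (library_total / 1e6))`.
#'
#' @param track a raw-count `termscape_track`.
#' @param contig,start,end feature span, 0-based half-open.
#' @param strand feature strand.
#' @param library_total total mapped reads/counts of the library (defaults
#'   to the track total).
#' @return reads per kilobase per million.
#' @export
rpkm <- function(track, contig, start, end, strand,
                 library_total = track_total(track)) {
  if (end <= start) stop("feature length must be positive")
  if (library_total <= 0) stop("zero library total")
  cnt <- sum(track_values(track, contig, strand, start:(end - 1)))
  cnt / (((end - start) / 1e3) * (library_total / 1e6))
}

#' Expression ratio of a CDS to its premature TU
#'
#' Per phase, `RPKM(CDS) / RPKM(premature TU)`; reports the minimum ratio
#' over phases and the population standard deviation of the log2 ratios.
#' Phases where the premature TU has zero RPKM are skipped and flagged.
#'
#' @param tu list/row with contig, start, end, strand of the premature TU.
#' @param cds same fields for the downstream CDS.
#' @param tracks list of per-phase raw tracks.
#' @return list with `ratios` (per usable phase), `min_ratio`,
#'   `log2_sd`, `flagged`.
#' @export
premature_ratio <- function(tu, cds, tracks) {
  ratios <- vapply(tracks, function(tr) {
    tu_rpkm <- rpkm(tr, tu$contig, tu$start, tu$end, tu$strand)
    if (tu_rpkm == 0) return(NA_real_)
    rpkm(tr, cds$contig, cds$start, cds$end, cds$strand) / tu_rpkm
  }, 0)
  ok <- !is.na(ratios)
  lg <- log2(ratios[ok])
  list(ratios = ratios[ok],
       min_ratio = if (any(ok)) min(ratios[ok]) else NA_real_,
       log2_sd = if (any(ok)) pop_sd(lg) else NA_real_,
       flagged = !all(ok))
}

#' Distribution summary after discarding top outliers
#'
#' Drops the largest `trim` fraction of the values (outlier read-through
#' fractions, typically) before computing the summary.
#'
#' @param values numeric vector.
#' @param trim fraction to discard from the top (default 0.05).
#' @return list with `median`, `q1`, `q3`, `n_used`, `n_dropped`.
#' @export
trimmed_distribution_summary <- function(values, trim = 0.05) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to summarize")
  n_drop <- floor(trim * length(values))
  kept <- sort(values)[seq_len(length(values) - n_drop)]
  q <- stats::quantile(kept, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3],
       n_used = length(kept), n_dropped = n_drop)
}
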