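#' Dense per-strand coverage/count tracks
#'
#' A track stores one numeric value per genomic position per strand, densely.
#' Index `i` of the vector holds the value at 0-based position `i - 1`.
#' Term-seq 3'-end counts, RNA-seq depth and ribosome-profiling depth all
#' use this container.
#'
#' @param lengths named integer vector of contig lengths.
#' @return a `termscape_track`: per contig a list with numeric vectors
#'   `plus` and `minus`.
#' @export
new_track <- function(lengths) {
  tr <- lapply(lengths, function(L) list(plus = numeric(L),
                                         minus = numeric(L)))
  names(tr) <- names(lengths)
  structure(tr, class = "termscape_track")
}

#' @export
print.termscape_track <- function(x, ...) {
  tot <- sum(vapply(x, function(ct) sum(ct$plus) + sum(ct$minus), 0))
  cat("termscape track:", length(x), "contig(s), total signal",
      format(tot), "\n")
  invisible(x)
}

track_total <- function(track) {
  sum(vapply(track, function(ct) sum(ct$plus) + sum(ct$minus), 0))
}

# Value at 0-based positions `pos` (vectorized) on one contig/strand;
# out-of-bounds positions return 0.
track_values <- function(track, contig, strand, pos) {
  v <- if (strand == "+") track[[contig]]$plus else track[[contig]]$minus
  out <- numeric(length(pos))
  ok <- pos >= 0 & pos < length(v)
  out[ok] <- v[pos[ok] + 1]
  out
}

track_set <- function(track, contig, strand, pos, values) {
  key <- if (strand == "+") "plus" else "minus"
  track[[contig]][[key]][pos + 1] <- values
  track
}

track_add <- function(track, contig, strand, pos, values) {
  key <- if (strand == "+") "plus" else "minus"
  track[[contig]][[key]][pos + 1] <- track[[contig]][[key]][pos + 1] + values
  track
}

#' Read a stranded track from a pair of BedGraph files
#'
#' BedGraph intervals are 0-based half-open; positions not covered by any
#' interval are 0. Track definition lines are ignored and float values
#' accepted.
#'
#' @param plus_path,minus_path BedGraph files for the two strands
#'   (`minus_path` may be `NULL` for an unstranded track stored on plus).
#' @param lengths named integer contig lengths.
#' @return a `termscape_track`.
#' @export
read_bedgraph_track <- function(plus_path, minus_path, lengths) {
  track <- new_track(lengths)
  track <- fill_from_bedgraph(track, plus_path, "+", lengths)
  if (!is.null(minus_path))
    track <- fill_from_bedgraph(track, minus_path, "-", lengths)
  track
}

fill_from_bedgraph <- function(track, path, strand, lengths) {
  if (!file.exists(path)) stop("BedGraph not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!length(gr)) return(track)
  contigs <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr) - 1L  # back to 0-based half-open
  ends <- GenomicRanges::end(gr)
  bad <- !(contigs %in% names(lengths)) | starts < 0 |
    ends > lengths[contigs]
  if (any(bad)) {
    i <- which(bad)[1]
    stop("format error in ", path, ": interval ", contigs[i], ":",
         starts[i], "-", ends[i], " outside contig bounds")
  }
  score <- as.numeric(gr$score)
  for (i in seq_along(gr)) {
    if (score[i] == 0) next
    idx <- (starts[i] + 1):ends[i]
    key <- if (strand == "+") "plus" else "minus"
    track[[contigs[i]]][[key]][idx] <- track[[contigs[i]]][[key]][idx] +
      score[i]
  }
  track
}

#' Write one strand of a track as BedGraph
#'
#' Runs of equal nonzero value are emitted as single intervals, so a track
#' round-trips exactly through [read_bedgraph_track()].
#'
#' @param track a `termscape_track`.
#' @param strand "+" or "-".
#' @param path output file.
#' @export
write_bedgraph_track <- function(track, strand, path) {
  con <- file(path, "w")
  on.exit(close(con))
  key <- if (strand == "+") "plus" else "minus"
  for (contig in names(track)) {
    v <- track[[contig]][[key]]
    if (!length(v) || all(v == 0)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based half-open starts
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", contig,
                       starts[keep], ends[keep],
                       formatC(r$values[keep], format = "g",
                               digits = 15)),
               con)
  }
  invisible(path)
}
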