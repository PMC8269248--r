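#' Cluster nonzero term-seq positions
#'
#' Single-linkage clustering of nonzero positions on one strand:
#' consecutive nonzero positions closer than `cluster_gap` bp share a
#' cluster.
#'
#' @param positions sorted 0-based positions with nonzero counts (or a
#'   numeric track vector, from which nonzero positions are taken).
#' @param cluster_gap bp; gaps >= this split clusters (default 100).
#' @return list of integer vectors (clusters, left to right); empty list
#'   for an all-zero track.
#' @examples
#' cluster_peaks(c(100, 150, 260))  # {100,150} and {260}
#' @export
cluster_peaks <- function(positions, cluster_gap = 100) {
  if (!length(positions)) return(list())
  positions <- sort(as.integer(positions))
  grp <- cumsum(c(0L, diff(positions) >= cluster_gap))
  unname(split(positions, grp))
}

#' Subcluster a peak cluster by positional spread
#'
#' Greedy left-to-right grouping: the current subcluster is extended while
#' the population standard deviation of its member positions stays below
#' `subcluster_sd`; within each subcluster the maximum-count position is
#' the representative, ties broken toward the 5'-most position in
#' transcript orientation.
#'
#' @param positions sorted 0-based member positions of one cluster.
#' @param counts counts at those positions.
#' @param subcluster_sd positional sd bound (default 25).
#' @param strand "+" or "-" (tie-break orientation).
#' @return data.frame with columns `position`, `count`, `subcluster`,
#'   `representative` (logical).
#' @export
subcluster_peaks <- function(positions, counts, subcluster_sd = 25,
                             strand = "+") {
  stopifnot(length(positions) == length(counts), length(positions) > 0)
  ord <- order(positions)
  positions <- positions[ord]; counts <- counts[ord]
  sub <- integer(length(positions))
  cur <- 1L
  start <- 1L
  for (i in seq_along(positions)) {
    member <- positions[start:i]
    if (pop_sd(member) >= subcluster_sd) {
      cur <- cur + 1L
      start <- i
    }
    sub[i] <- cur
  }
  rep_flag <- logical(length(positions))
  for (s in unique(sub)) {
    idx <- which(sub == s)
    mx <- idx[counts[idx] == max(counts[idx])]
    pick <- if (strand == "+") mx[which.min(positions[mx])]
            else mx[which.max(positions[mx])]
    rep_flag[pick] <- TRUE
  }
  data.frame(position = positions, count = counts, subcluster = sub,
             representative = rep_flag)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Filter representative peaks by intensity and replicate presence
#'
#' Keeps representatives with at least `min_peak_count` counts in the
#' calling replicate that also carry signal (count >= 1 within
#' `replicate_tol` nt) in every other replicate.
#'
#' @param reps data.frame with contig, position, strand, count
#'   (representatives from the calling replicate).
#' @param tracks list of all replicate `termscape_track`s.
#' @param calling_rep index of the calling replicate within `tracks`.
#' @param min_peak_count minimum raw count (default 4).
#' @param replicate_tol positional tolerance, nt (default 2).
#' @return the surviving subset of `reps`.
#' @export
filter_candidates <- function(reps, tracks, calling_rep,
                              min_peak_count = 4, replicate_tol = 2) {
  stopifnot(length(tracks) >= 2)
  keep <- reps$count >= min_peak_count
  others <- setdiff(seq_along(tracks), calling_rep)
  for (r in others) {
    present <- vapply(seq_len(nrow(reps)), function(i) {
      pos <- (reps$position[i] - replicate_tol):(reps$position[i] +
                                                 replicate_tol)
      sum(track_values(tracks[[r]], reps$contig[i], reps$strand[i],
                       pos)) >= 1
    }, TRUE)
    keep <- keep & present
  }
  reps[keep, , drop = FALSE]
}

#' Peak Z-score against its flanks
#'
#' `z = (x - mu) / max(sigma, 1)` where `x` is the peak count and `mu`,
#' `sigma` are the mean and population sd of counts at offsets
#' `-flank..-1` and `+1..+flank` on the same strand. The sd floor of 1
#' keeps sparse flanks from inflating the score. Windows clipped at a
#' contig edge use the available positions.
#'
#' @param track a `termscape_track`.
#' @param contig,position,strand peak coordinates.
#' @param flank flank half-width, nt (default 50).
#' @return the dimensionless Z-score.
#' @export
peak_zscore <- function(track, contig, position, strand, flank = 50) {
  L <- length(track[[contig]]$plus)
  offs <- c(-(flank:1), 1:flank)
  pos <- position + offs
  pos <- pos[pos >= 0 & pos < L]
  fl <- track_values(track, contig, strand, pos)
  x <- track_values(track, contig, strand, position)
  (x - mean(fl)) / max(pop_sd(fl), 1)
}

# count-profile feature vector: counts at transcript offsets -w..+w
peak_features <- function(track, contig, position, strand, halfwidth = 10) {
  pos <- tx_positions(position, strand, -halfwidth:halfwidth)
  track_values(track, contig, strand, pos)
}

#' Build KNN training sets from screened candidates
#'
#' Positives are candidates exceeding the Z-score cutoff whose RNA-seq
#' read-through fraction falls below `readthrough_cutoff` (a deterministic
#' automation of the original manual screen for decreased RNA profiles
#' around true ends). Negatives are the 20 offset positions at -10..+10
#' (excluding 0) of each positive, dropping any offset that coincides with
#' another positive. Features are the 21-count profiles around each
#' position.
#'
#' @param candidates data.frame with contig, position, strand, zscore and
#'   readthrough columns.
#' @param track the calling replicate's term-seq track (feature source).
#' @param config a [pipeline_config()].
#' @return list with `features` (matrix, rows = examples), `labels`
#'   (factor positive/negative) and `positives` (the positive subset of
#'   `candidates`).
#' @export
build_training_sets <- function(candidates, track,
                                config = pipeline_config()) {
  w <- config$knn_window_halfwidth
  pos_idx <- which(candidates$zscore > config$zscore_min &
                   !is.na(candidates$readthrough) &
                   candidates$readthrough < config$readthrough_cutoff)
  if (length(pos_idx) < 10)
    stop("training error: only ", length(pos_idx),
         " positive examples; enlarge the simulation or relax screens")
  positives <- candidates[pos_idx, , drop = FALSE]
  pos_key <- paste(positives$contig, positives$strand, positives$position)
  feats <- list(); labels <- character(0)
  for (i in seq_len(nrow(positives))) {
    feats[[length(feats) + 1]] <-
      peak_features(track, positives$contig[i], positives$position[i],
                    positives$strand[i], w)
    labels <- c(labels, "positive")
    for (off in c(-(w:1), 1:w)) {
      npos <- positives$position[i] + off
      if (paste(positives$contig[i], positives$strand[i], npos) %in%
          pos_key) next
      feats[[length(feats) + 1]] <-
        peak_features(track, positives$contig[i], npos,
                      positives$strand[i], w)
      labels <- c(labels, "negative")
    }
  }
  list(features = do.call(rbind, feats),
       labels = factor(labels, levels = c("negative", "positive")),
       positives = positives)
}

#' Train the KNN peak classifier and label candidates
#'
#' K-nearest-neighbour classification (Euclidean distance on
#' log1p-transformed count profiles) of every candidate, with mean
#' held-out accuracy over `cv_reps` random 50/50 splits of the training
#' set reported alongside.
#'
#' @param training output of [build_training_sets()].
#' @param candidates candidate data.frame.
#' @param track track supplying candidate feature vectors.
#' @param config a [pipeline_config()]; `knn_k` and `cv_reps` are used.
#' @param seed RNG seed for the CV splits and tie-breaking.
#' @return list with `labels` (factor per candidate) and `cv_accuracy`
#'   (NA when `cv_reps` is 0).
#' @export
train_and_call <- function(training, candidates, track,
                           config = pipeline_config(), seed = 1) {
  if (nlevels(droplevels(training$labels)) < 2)
    stop("training error: both classes required")
  w <- config$knn_window_halfwidth
  train_x <- log1p(training$features)
  cand_x <- log1p(t(vapply(seq_len(nrow(candidates)), function(i)
    peak_features(track, candidates$contig[i], candidates$position[i],
                  candidates$strand[i], w), numeric(2 * w + 1))))
  local_seeded(seed, {
    cv_acc <- NA_real_
    if (config$cv_reps > 0) {
      n <- nrow(train_x)
      accs <- vapply(seq_len(config$cv_reps), function(rep) {
        half <- sample.int(n, floor(n / 2))
        if (nlevels(droplevels(training$labels[half])) < 2)
          return(NA_real_)
        pred <- class::knn(train_x[half, , drop = FALSE],
                           train_x[-half, , drop = FALSE],
                           training$labels[half], k = config$knn_k)
        mean(pred == training$labels[-half])
      }, 0)
      cv_acc <- mean(accs, na.rm = TRUE)
    }
    labels <- class::knn(train_x, cand_x, training$labels,
                         k = config$knn_k)
    list(labels = labels, cv_accuracy = cv_acc)
  })
}

#' Call TEPs from replicate term-seq tracks
#'
#' Full calling pipeline, run once per replicate: cluster nonzero peaks
#' (< 100 bp gaps), subcluster at positional sd < 25, take maximum-count
#' representatives, discard those under 4 raw counts or absent from any
#' other replicate, compute flank Z-scores and read-through fractions,
#' train the KNN on the Z > 6 / low-read-through positives against their
#' offset negatives, and label every candidate. The final set is the union
#' of positively labelled candidates over replicates, collapsing calls
#' within the replicate tolerance (higher count wins).
#'
#' @param termseq list of replicate `termscape_track`s (>= 2).
#' @param rnaseq list of per-phase coverage tracks (for the training
#'   screen).
#' @param config a [pipeline_config()].
#' @param seed RNG seed.
#' @return list with `teps` (data.frame: contig, position, strand, count,
#'   zscore), `cv_accuracy` (per replicate), `candidates` (per-replicate
#'   candidate tables with labels).
#' @export
call_teps <- function(termseq, rnaseq, config = pipeline_config(),
                      seed = 1) {
  stopifnot(length(termseq) >= 2)
  norm_cov <- lapply(rnaseq, normalize_rpm)
  per_rep <- vector("list", length(termseq))
  cv <- numeric(length(termseq))
  for (r in seq_along(termseq)) {
    cand <- candidate_table(termseq[[r]], config)
    if (!nrow(cand)) {
      per_rep[[r]] <- cand
      cv[r] <- NA_real_
      next
    }
    cand <- filter_candidates(cand, termseq, r, config$min_peak_count,
                              config$replicate_tol)
    if (!nrow(cand)) {
      per_rep[[r]] <- cand
      cv[r] <- NA_real_
      next
    }
    cand$zscore <- vapply(seq_len(nrow(cand)), function(i)
      peak_zscore(termseq[[r]], cand$contig[i], cand$position[i],
                  cand$strand[i], config$zscore_flank), 0)
    cand$readthrough <- vapply(seq_len(nrow(cand)), function(i)
      readthrough_fraction(norm_cov, cand$contig[i], cand$position[i],
                           cand$strand[i],
                           config$readthrough_flank)$fraction, 0)
    training <- build_training_sets(cand, termseq[[r]], config)
    fit <- train_and_call(training, cand, termseq[[r]], config,
                          seed = seed + r)
    cand$called <- fit$labels == "positive"
    per_rep[[r]] <- cand
    cv[r] <- fit$cv_accuracy
  }
  called <- do.call(rbind, lapply(per_rep, function(d)
    d[isTRUE_vec(d$called), c("contig", "position", "strand", "count",
                              "zscore"), drop = FALSE]))
  teps <- dedupe_calls(called, config$replicate_tol)
  list(teps = teps, cv_accuracy = cv, candidates = per_rep)
}

isTRUE_vec <- function(x) if (is.null(x)) logical(0) else x %in% TRUE

# cluster + subcluster one replicate into a representative table
candidate_table <- function(track, config) {
  out <- list()
  for (contig in names(track)) {
    for (strand in c("+", "-")) {
      v <- if (strand == "+") track[[contig]]$plus else
        track[[contig]]$minus
      nz <- which(v > 0) - 1L
      for (cl in cluster_peaks(nz, config$cluster_gap)) {
        sc <- subcluster_peaks(cl, v[cl + 1L], config$subcluster_sd,
                               strand)
        rep_rows <- sc[sc$representative, , drop = FALSE]
        if (nrow(rep_rows))
          out[[length(out) + 1]] <- data.frame(
            contig = contig, position = rep_rows$position,
            strand = strand, count = rep_rows$count,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0), position = integer(0),
                      strand = character(0), count = numeric(0)))
  do.call(rbind, out)
}

# collapse union calls within +/- tol nt on one strand, keeping the
# higher-count position
dedupe_calls <- function(called, tol = 2) {
  if (is.null(called) || !nrow(called))
    return(data.frame(contig = character(0), position = integer(0),
                      strand = character(0), count = numeric(0),
                      zscore = numeric(0)))
  called <- called[order(called$contig, called$strand, called$position,
                         -called$count), , drop = FALSE]
  keep <- logical(nrow(called))
  taken <- list()
  ord <- order(-called$count)
  for (i in ord) {
    key <- paste(called$contig[i], called$strand[i])
    near <- taken[[key]]
    if (!is.null(near) &&
        any(abs(near - called$position[i]) <= tol)) next
    keep[i] <- TRUE
    taken[[key]] <- c(near, called$position[i])
  }
  out <- called[keep, , drop = FALSE]
  out[order(out$contig, out$strand, out$position), , drop = FALSE]
}

#' Categorize TEPs relative to the annotation
#'
#' Precedence: Internal (inside a same-strand CDS), then primary/secondary
#' (within the 500-bp region downstream of a same-strand gene's stop
#' codon; the highest-count TEP per gene is primary, the rest secondary),
#' then premature (same strand, between 70 bp downstream of a primary TSS
#' and the start codon of that TSS's gene), then antisense (inside an
#' opposite-strand CDS), then intergenic.
#'
#' @param teps TEP data.frame (contig, position, strand, count).
#' @param genes gene table.
#' @param tss TSS table (primary rows used).
#' @param config a [pipeline_config()].
#' @return `teps` with `category` and `gene_id` columns added.
#' @export
categorize_teps <- function(teps, genes, tss, config = pipeline_config()) {
  n <- nrow(teps)
  teps$category <- rep("N", n)
  teps$gene_id <- rep(NA_character_, n)
  if (!n) return(teps)
  W <- config$downstream_assoc_window
  prim <- tss[tss$category == "primary", , drop = FALSE]
  for (i in seq_len(n)) {
    p <- teps$position[i]; st <- teps$strand[i]; ct <- teps$contig[i]
    g_same <- genes[genes$contig == ct & genes$strand == st, ,
                    drop = FALSE]
    g_opp <- genes[genes$contig == ct & genes$strand != st, ,
                   drop = FALSE]
    if (any(p >= g_same$cds_start & p < g_same$cds_end)) {
      teps$category[i] <- "Internal"
      gi <- which(p >= g_same$cds_start & p < g_same$cds_end)[1]
      teps$gene_id[i] <- g_same$gene_id[gi]
      next
    }
    # downstream window past the stop codon, transcript orientation
    if (st == "+") {
      hit <- which(p >= g_same$cds_end & p < g_same$cds_end + W)
      dist <- p - g_same$cds_end[hit]
    } else {
      hit <- which(p < g_same$cds_start & p >= g_same$cds_start - W)
      dist <- g_same$cds_start[hit] - 1 - p
    }
    if (length(hit)) {
      gi <- hit[which.min(dist)]
      teps$category[i] <- "S"  # resolved to P per gene below
      teps$gene_id[i] <- g_same$gene_id[gi]
      next
    }
    pr <- prim[prim$contig == ct & prim$strand == st, , drop = FALSE]
    pre_hit <- FALSE
    for (k in seq_len(nrow(pr))) {
      g <- genes[genes$gene_id == pr$gene_id[k], , drop = FALSE]
      if (!nrow(g)) next
      if (st == "+") {
        lo <- pr$position[k] + config$premature_offset
        hi <- g$cds_start[1]  # first base of the start codon, exclusive
        inside <- p >= lo && p < hi
      } else {
        lo <- pr$position[k] - config$premature_offset
        hi <- g$cds_end[1] - 1
        inside <- p <= lo && p > hi
      }
      if (inside) {
        teps$category[i] <- "Pre"
        teps$gene_id[i] <- pr$gene_id[k]
        pre_hit <- TRUE
        break
      }
    }
    if (pre_hit) next
    if (any(p >= g_opp$cds_start & p < g_opp$cds_end)) {
      teps$category[i] <- "A"
      gi <- which(p >= g_opp$cds_start & p < g_opp$cds_end)[1]
      teps$gene_id[i] <- g_opp$gene_id[gi]
      next
    }
  }
  # resolve P vs S: highest count per associated gene
  ds <- which(teps$category == "S")
  for (g in unique(teps$gene_id[ds])) {
    idx <- ds[teps$gene_id[ds] == g]
    best <- idx[which.max(teps$count[idx])]
    teps$category[best] <- "P"
  }
  teps
}
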