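# Independent brute-force references used to cross-check the
# implementation. Written deliberately in the most literal style possible;
# none of these share code with the package internals they check.

# single-linkage clustering by O(n^2) union-find: i and j connected iff
# |pi - pj| < gap
bf_cluster <- function(positions, gap) {
  n <- length(positions)
  if (!n) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(positions[i] - positions[j]) < gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  unname(lapply(split(positions, roots), sort))
}

# literal window scan for the TU continuity criterion
bf_phase_passes <- function(vn, vr, w, frac, min_raw,
                            rule = "exclude-candidate") {
  n <- length(vn)
  if (w >= n) {
    wins_n <- mean(vn); wins_r <- mean(vr)
  } else {
    wins_n <- wins_r <- numeric(n - w + 1)
    for (s in seq_len(n - w + 1)) {
      wins_n[s] <- mean(vn[s:(s + w - 1)])
      wins_r[s] <- mean(vr[s:(s + w - 1)])
    }
  }
  if (rule == "exclude-candidate") {
    if (any(wins_r < min_raw)) return(FALSE)
    all(wins_n > frac * mean(vn))
  } else {
    use <- wins_r >= min_raw
    if (!any(use)) return(FALSE)
    all(wins_n[use] > frac * mean(vn))
  }
}

# all convergent opposite-strand pairs by explicit double loop, then the
# same nearest-partner greedy matching, implemented on a matrix
bf_biteps <- function(teps, max_overlap) {
  pairs <- NULL
  for (i in seq_len(nrow(teps))) for (j in seq_len(nrow(teps))) {
    if (teps$strand[i] != "+" || teps$strand[j] != "-") next
    if (teps$contig[i] != teps$contig[j]) next
    ov <- teps$position[i] - teps$position[j] + 1
    if (ov >= 1 && ov < max_overlap) pairs <- rbind(pairs, c(i, j, ov))
  }
  if (is.null(pairs)) return(pairs)
  pairs <- pairs[order(pairs[, 3]), , drop = FALSE]
  used <- c()
  out <- NULL
  for (k in seq_len(nrow(pairs))) {
    if (pairs[k, 1] %in% used || pairs[k, 2] %in% used) next
    out <- rbind(out, pairs[k, ])
    used <- c(used, pairs[k, 1:2])
  }
  out
}

# independent dot-bracket pairing (array scan, no stack reuse from the
# package) plus exhaustive helix enumeration
bf_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  open <- c()
  pairs <- NULL
  for (i in seq_along(ch)) {
    if (ch[i] == "(") open <- c(open, i)
    if (ch[i] == ")") {
      pairs <- rbind(pairs, c(open[length(open)], i))
      open <- open[-length(open)]
    }
  }
  pairs
}

# stem metrics of the 3'-most hairpin by exhaustive enumeration: find all
# hairpin pairs, pick the one with the largest closing j, then collect
# every enclosing pair chained with gaps <= 1 on both sides
bf_stem <- function(db) {
  pairs <- bf_pairs(db)
  if (is.null(pairs)) return(NULL)
  L <- nchar(db)
  paired <- rep(FALSE, L)
  paired[c(pairs[, 1], pairs[, 2])] <- TRUE
  is_hairpin <- apply(pairs, 1, function(pr) {
    if (pr[2] - pr[1] < 2) return(FALSE)
    inner <- (pr[1] + 1):(pr[2] - 1)
    !any(paired[inner])
  })
  hp <- pairs[is_hairpin, , drop = FALSE]
  if (!nrow(hp)) return(NULL)
  hp <- hp[which.max(hp[, 2]), ]
  helix <- matrix(hp, ncol = 2)
  repeat {
    cur <- helix[nrow(helix), ]
    cand <- NULL
    for (r in seq_len(nrow(pairs))) {
      pr <- pairs[r, ]
      if (pr[1] < cur[1] && pr[2] > cur[2] &&
          (cur[1] - pr[1] - 1) <= 1 && (pr[2] - cur[2] - 1) <= 1) {
        # must be the immediately enclosing pair
        if (is.null(cand) || pr[1] > cand[1]) cand <- pr
      }
    }
    # reject if anything paired sits between cur and cand (branching)
    if (!is.null(cand)) {
      left <- if (cand[1] + 1 <= cur[1] - 1) (cand[1] + 1):(cur[1] - 1)
              else integer(0)
      right <- if (cur[2] + 1 <= cand[2] - 1) (cur[2] + 1):(cand[2] - 1)
               else integer(0)
      if (any(paired[c(left, right)])) cand <- NULL
    }
    if (is.null(cand)) break
    helix <- rbind(helix, cand)
  }
  list(stem_len = nrow(helix),
       loop_len = hp[2] - hp[1] - 1,
       stem_end_offset = max(helix[, 2]) - L - 1)
}

# a tiny flat genome for coordinate tests
toy_genome <- function(seq = NULL, len = 2000) {
  if (is.null(seq))
    seq <- paste(rep("ACGT", ceiling(len / 4)), collapse = "")
  termscape::new_genome(c(c1 = substr(seq, 1, len)))
}

# build a track with given values on one strand of a 1-contig genome
toy_track <- function(len, strand = "+", pos = integer(0),
                      values = numeric(0), fill = 0) {
  tr <- termscape::new_track(c(c1 = len))
  key <- if (strand == "+") "plus" else "minus"
  tr[["c1"]][[key]][] <- fill
  if (length(pos)) tr[["c1"]][[key]][pos + 1] <- values
  tr
}
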