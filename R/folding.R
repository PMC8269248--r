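#' Minimum-free-energy RNA folding
#'
#' Folds RNA sequences with a standard nearest-neighbour thermodynamic
#' model by delegating to the ViennaRNA `RNAfold` executable, the same
#' engine commonly used for intrinsic-terminator analysis. The call site
#' fixes the parameters: MFE structure only, at the given temperature.
#'
#' @param rna character vector of RNA sequences (A/C/G/U).
#' @param temperature folding temperature in degrees C (default 30, the
#'   organism's growth temperature).
#' @return for a single sequence, a list with `delta_g` (kcal/mol, <= 0)
#'   and `dot_bracket`; for several, a data.frame with columns `delta_g`
#'   and `dot_bracket`.
#' @examples
#' \dontrun{
#' fold_mfe("GGGGGAAAACCCCC")$delta_g
#' }
#' @export
fold_mfe <- function(rna, temperature = 30) {
  res <- fold_mfe_batch(rna, temperature)
  if (length(rna) == 1)
    list(delta_g = res$delta_g[1], dot_bracket = res$dot_bracket[1])
  else res
}

fold_mfe_batch <- function(rna, temperature = 30) {
  if (!length(rna))
    return(data.frame(delta_g = numeric(0), dot_bracket = character(0)))
  rna <- toupper(rna)
  rna <- chartr("T", "U", rna)
  if (any(grepl("[^ACGU]", rna)))
    stop("input error: RNA alphabet must be A/C/G/U")
  if (any(nchar(rna) < 1)) stop("input error: empty RNA sequence")
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe))
    stop("RNAfold executable not found on PATH; ViennaRNA is required")
  fasta <- as.vector(rbind(paste0(">s", seq_along(rna)), rna))
  out <- suppressWarnings(system2(exe,
                                  args = c("--noPS",
                                           paste0("--temp=", temperature)),
                                  input = fasta, stdout = TRUE,
                                  stderr = FALSE))
  # output per record: header, sequence, "structure ( dG)"
  struct_lines <- out[seq(3, length(out), by = 3)]
  m <- regmatches(struct_lines,
                  regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s*$",
                          struct_lines))
  if (any(vapply(m, length, 1L) != 3))
    stop("could not parse RNAfold output")
  data.frame(
    delta_g = vapply(m, function(x) as.numeric(x[3]), 0),
    dot_bracket = vapply(m, function(x) x[2], ""),
    stringsAsFactors = FALSE
  )
}

#' Upstream RNA sequence of a transcript 3' end
#'
#' Returns the transcript-orientation sequence at offsets
#' `-window .. -1` from the TEP base (the TEP base itself excluded),
#' with T transcribed to U. Windows clipped at a contig edge to fewer
#' than 10 nt return `NA` with a warning.
#'
#' @param genome a `termscape_genome`.
#' @param contig,position,strand TEP coordinates (0-based).
#' @param window window size in nt (default 40).
#' @return RNA string, or `NA_character_` if over-clipped.
#' @export
upstream_rna <- function(genome, contig, position, strand, window = 40) {
  s <- window_seq(genome, contig, position, strand, -window, -1, rna = TRUE)
  if (nchar(s) < 10) {
    warning("upstream window at ", contig, ":", position, strand,
            " clipped to <10 nt; skipped")
    return(NA_character_)
  }
  s
}

# Pair table of a dot-bracket string: integer vector, pt[i] = partner of i
# (1-based string index) or 0. Errors on unbalanced strings.
pair_table <- function(db) {
  ch <- strsplit(db, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("structure error: unbalanced dot-bracket")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    } else if (ch[i] != ".") stop("structure error: bad character '", ch[i], "'")
  }
  if (length(stack)) stop("structure error: unbalanced dot-bracket")
  pt
}

#' Parse the 3'-most stem-loop of an MFE structure
#'
#' Locates the hairpin whose closing pair lies closest to the 3' end of the
#' folded window (the transcript end, where termination mechanics act) and
#' walks its helix outward, tolerating interior bulges of at most 1 nt on
#' either side. Multi-branch junctions terminate the helix.
#'
#' @param dot_bracket balanced dot-bracket string for a window covering
#'   offsets `-L..-1` relative to the TEP.
#' @return `NULL` if no base pair exists, else a list with `stem_len`
#'   (base pairs), `loop_len` (nt), `stem_end_offset` (offset of the
#'   helix's 3'-most paired base relative to the TEP, e.g. -1 for the last
#'   window base) and `dot_bracket`.
#' @export
parse_stem_loop <- function(dot_bracket) {
  pt <- pair_table(dot_bracket)
  L <- length(pt)
  if (!any(pt > 0)) return(NULL)
  # hairpin closing pairs: (i,j) paired with everything strictly inside
  # unpaired
  closers <- which(pt > seq_len(L))  # i with partner j > i
  hairpin_i <- closers[vapply(closers, function(i) {
    j <- pt[i]
    j > i + 1 && all(pt[(i + 1):(j - 1)] == 0)
  }, TRUE)]
  if (!length(hairpin_i)) return(NULL)
  # 3'-most hairpin: the one whose closing pair's 3' base is largest
  i <- hairpin_i[which.max(pt[hairpin_i])]
  j <- pt[i]
  loop_len <- j - i - 1
  # walk outward along the helix
  stem <- 1L
  cur_i <- i; cur_j <- j
  repeat {
    # next outer paired base 5' of cur_i
    a <- cur_i - 1L
    while (a >= 1 && pt[a] == 0) a <- a - 1L
    if (a < 1) break
    b <- pt[a]
    if (b <= cur_j) break                      # branching, not enclosing
    if ((cur_i - a - 1) > 1 || (b - cur_j - 1) > 1) break  # bulge > 1 nt
    stem <- stem + 1L
    cur_i <- a; cur_j <- b
  }
  list(stem_len = stem,
       loop_len = loop_len,
       stem_end_offset = cur_j - L - 1L,
       dot_bracket = dot_bracket)
}

#' Count uridines downstream of the stem
#'
#' Counts U in the 8-nt (configurable) transcript window immediately 3' of
#' the stem end. When no stem exists the window is the 8 nt ending at the
#' TEP base, which keeps classification total.
#'
#' @param genome a `termscape_genome`.
#' @param contig,position,strand TEP coordinates.
#' @param stem result of [parse_stem_loop()] or `NULL`.
#' @param window window size (default 8).
#' @return integer count of uridines, 0..window.
#' @export
count_u_tract <- function(genome, contig, position, strand, stem,
                          window = 8) {
  if (is.null(stem)) {
    from <- -(window - 1); to <- 0
  } else {
    from <- stem$stem_end_offset + 1
    to <- stem$stem_end_offset + window
  }
  s <- window_seq(genome, contig, position, strand, from, to, rna = TRUE)
  sum(strsplit(s, "")[[1]] == "U")
}

#' Classify a TEP from folding energy and U-tract
#'
#' Highly structured (HS) ends have upstream MFE strictly below the
#' threshold (a tie is less structured, since HS is defined as "lower
#' than" the split value); HS ends split into U-rich (>= `utract_min_u`
#' uridines downstream of the stem) and U-lack.
#'
#' @param delta_g upstream-window MFE, kcal/mol.
#' @param u_count downstream uridine count.
#' @param hs_threshold split value, kcal/mol (default -23).
#' @param utract_min_u minimum uridines for U-rich (default 3).
#' @return one of "HS-U-rich", "HS-U-lack", "LS".
#' @export
classify_tep <- function(delta_g, u_count, hs_threshold = -23,
                         utract_min_u = 3) {
  ifelse(delta_g < hs_threshold,
         ifelse(u_count >= utract_min_u, "HS-U-rich", "HS-U-lack"),
         "LS")
}

#' Data-driven threshold between the two folding-energy modes
#'
#' Fits a two-component Gaussian mixture to a bimodal MFE distribution and
#' returns the point between the component means where the weighted
#' densities intersect. Diagnostic only: the pipeline uses the fixed
#' configured threshold.
#'
#' @param values numeric MFE values (>= 50 of them).
#' @return list with `threshold` (numeric or NA), `ok` (logical) and the
#'   fitted `means`, `sds`, `weights`.
#' @export
bimodal_split <- function(values) {
  if (length(values) < 50) stop("need >= 50 values for a mixture fit")
  # mclust dispatches several helpers unqualified; give the call an
  # environment that can see the whole namespace
  env <- new.env(parent = asNamespace("mclust"))
  env$values <- values
  fit <- eval(quote(Mclust(values, G = 2, modelNames = c("E", "V"),
                           verbose = FALSE)), env)
  mu <- as.numeric(fit$parameters$mean)
  ord <- order(mu)
  mu <- mu[ord]
  sg <- sqrt(rep(fit$parameters$variance$sigmasq, length.out = 2))[ord]
  w <- fit$parameters$pro[ord]
  if (diff(mu) < 1)
    return(list(threshold = NA_real_, ok = FALSE, means = mu, sds = sg,
                weights = w))
  f <- function(x) w[1] * stats::dnorm(x, mu[1], sg[1]) -
    w[2] * stats::dnorm(x, mu[2], sg[2])
  root <- tryCatch(stats::uniroot(f, lower = mu[1], upper = mu[2])$root,
                   error = function(e) NA_real_)
  list(threshold = root, ok = !is.na(root), means = mu, sds = sg,
       weights = w)
}

#' Nucleotide enrichment around TEPs
#'
#' Per transcript offset -50..+50, the fold change of each base's frequency
#' among TEPs over the background frequency, where the background is the
#' position-averaged base frequency over the same windows at `random_n`
#' uniformly drawn seeded random positions (both strands).
#'
#' @param teps TEP data.frame with contig/position/strand.
#' @param genome a `termscape_genome`.
#' @param random_n number of random background positions (default 10000).
#' @param seed RNG seed for the background draw.
#' @param halfwidth offset half-width (default 50).
#' @return list with `fold` (4 x offsets matrix, rows A/C/G/U),
#'   `background` (named base frequencies summing to 1) and `offsets`.
#' @export
nucleotide_enrichment <- function(teps, genome, random_n = 10000, seed = 1,
                                  halfwidth = 50) {
  if (!nrow(teps)) stop("nucleotide_enrichment: empty TEP set")
  offs <- -halfwidth:halfwidth
  tep_mat <- window_char_matrix(genome, teps$contig, teps$position,
                                teps$strand, offs)
  bg <- local_seeded(seed, random_positions(genome, random_n))
  bg_mat <- window_char_matrix(genome, bg$contig, bg$position, bg$strand,
                               offs)
  bases <- c("A", "C", "G", "U")
  bg_counts <- table(factor(bg_mat, levels = bases))
  background <- as.numeric(bg_counts) / sum(bg_counts)
  names(background) <- bases
  fold <- matrix(NA_real_, nrow = 4, ncol = length(offs),
                 dimnames = list(bases, offs))
  for (k in seq_along(offs)) {
    col <- tep_mat[, k]
    col <- col[col %in% bases]
    if (!length(col)) next
    fr <- as.numeric(table(factor(col, levels = bases))) / length(col)
    fold[, k] <- fr / background
  }
  list(fold = fold, background = background, offsets = offs)
}

# matrix of transcript-orientation bases (rows = sites, cols = offsets);
# out-of-bounds cells are NA
window_char_matrix <- function(genome, contig, position, strand, offsets) {
  n <- length(position)
  out <- matrix(NA_character_, nrow = n, ncol = length(offsets))
  for (i in seq_len(n)) {
    s <- window_seq(genome, contig[i], position[i], strand[i],
                    min(offsets), max(offsets), rna = TRUE)
    if (nchar(s) != length(offsets)) next  # clipped windows skipped
    out[i, ] <- strsplit(s, "")[[1]]
  }
  out
}

random_positions <- function(genome, n) {
  contig <- sample(names(genome$lengths), n, replace = TRUE,
                   prob = genome$lengths / sum(genome$lengths))
  position <- vapply(contig, function(ct)
    sample.int(genome$lengths[[ct]], 1) - 1L, 0L)
  data.frame(contig = contig, position = position,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Base-pair interaction frequency upstream of TEPs
#'
#' Folds the 100-nt upstream window of every TEP and reports, for each pair
#' of window offsets, the fraction of TEPs whose MFE structure pairs those
#' two positions.
#'
#' @param teps TEP data.frame.
#' @param genome a `termscape_genome`.
#' @param window upstream window length (default 100).
#' @param temperature folding temperature (default 30).
#' @return `window x window` symmetric matrix of frequencies in `[0, 1]`;
#'   row/column `k` is upstream offset `-(window - k + 1)`.
#' @export
interaction_matrix <- function(teps, genome, window = 100,
                               temperature = 30) {
  if (!nrow(teps)) stop("interaction_matrix: empty TEP set")
  M <- matrix(0, window, window)
  seqs <- character(nrow(teps))
  keep <- logical(nrow(teps))
  for (i in seq_len(nrow(teps))) {
    s <- window_seq(genome, teps$contig[i], teps$position[i],
                    teps$strand[i], -window, -1, rna = TRUE)
    keep[i] <- nchar(s) == window
    seqs[i] <- s
  }
  seqs <- seqs[keep]
  if (!length(seqs)) stop("interaction_matrix: no full-length windows")
  folds <- fold_mfe_batch(seqs, temperature)
  for (db in folds$dot_bracket) {
    pt <- pair_table(db)
    i <- which(pt > seq_along(pt))
    if (length(i)) {
      M[cbind(i, pt[i])] <- M[cbind(i, pt[i])] + 1
      M[cbind(pt[i], i)] <- M[cbind(pt[i], i)] + 1
    }
  }
  M / length(seqs)
}

#' Classify a called TEP set
#'
#' Runs the full structure pipeline over a TEP table: upstream folding at
#' the configured window and temperature, stem-loop parsing, U-tract
#' counting and class assignment. Internal TEPs keep their row but are
#' classified too (downstream summaries exclude them).
#'
#' @param teps TEP data.frame (from [call_teps()] / [categorize_teps()]).
#' @param genome a `termscape_genome`.
#' @param config a [pipeline_config()].
#' @return the TEP data.frame with columns `delta_g`, `dot_bracket`,
#'   `stem_len`, `loop_len`, `stem_end_offset`, `u_count`, `class` added.
#' @export
classify_teps <- function(teps, genome, config = pipeline_config()) {
  n <- nrow(teps)
  teps$delta_g <- NA_real_
  teps$dot_bracket <- NA_character_
  teps$stem_len <- NA_integer_
  teps$loop_len <- NA_integer_
  teps$stem_end_offset <- NA_integer_
  teps$u_count <- NA_integer_
  teps$class <- NA_character_
  if (!n) return(teps)
  seqs <- vapply(seq_len(n), function(i)
    upstream_rna(genome, teps$contig[i], teps$position[i], teps$strand[i],
                 config$fold_window), "")
  ok <- !is.na(seqs)
  if (any(ok)) {
    folds <- fold_mfe_batch(seqs[ok], config$fold_temperature)
    teps$delta_g[ok] <- folds$delta_g
    teps$dot_bracket[ok] <- folds$dot_bracket
  }
  for (i in which(ok)) {
    stem <- parse_stem_loop(teps$dot_bracket[i])
    if (!is.null(stem)) {
      teps$stem_len[i] <- stem$stem_len
      teps$loop_len[i] <- stem$loop_len
      teps$stem_end_offset[i] <- stem$stem_end_offset
    }
    teps$u_count[i] <- count_u_tract(genome, teps$contig[i],
                                     teps$position[i], teps$strand[i],
                                     stem, config$utract_window)
    teps$class[i] <- classify_tep(teps$delta_g[i], teps$u_count[i],
                                  config$hs_threshold, config$utract_min_u)
  }
  teps
}

# run expr with a local, restored RNG state
local_seeded <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
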