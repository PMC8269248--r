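test_that("candidate pairs respect strand, orientation and span bound", {
  tss <- data.frame(contig = "c1", position = 100L, strand = "+",
                    category = "primary", gene_id = "gA",
                    stringsAsFactors = FALSE)
  teps <- data.frame(contig = "c1", position = c(500L, 900L, 50L, 30000L),
                     strand = c("+", "-", "+", "+"),
                     stringsAsFactors = FALSE)
  pr <- candidate_pairs(tss, teps, 20000)
  expect_equal(nrow(pr), 1)          # opposite strand, upstream and
  expect_equal(pr$tep, 500L)         # over-span TEPs all excluded
  expect_equal(pr$span, 401L)
})

test_that("pair evaluation reproduces the analytic window cases", {
  cfg <- pipeline_config()
  L <- 3000
  flat_raw <- toy_track(L, "+", fill = 10)
  gap_raw <- toy_track(L, "+", fill = 10)
  gap_raw[["c1"]]$plus[1201:1500] <- 0   # 300-nt zero gap at [1200,1500)
  low_raw <- toy_track(L, "+", fill = 4)
  pair <- list(contig = "c1", strand = "+", tss = 100L, tep = 1600L,
               span = 1501L)
  ev_flat <- evaluate_pair(pair, list(normalize_rpm(flat_raw)),
                           list(flat_raw), cfg)
  expect_true(ev_flat$is_tu)
  expect_equal(ev_flat$passing_phases, 1L)
  # a 300-nt zero gap breaks both the 5% and the raw-count criteria
  ev_gap <- evaluate_pair(pair, list(normalize_rpm(gap_raw)),
                          list(gap_raw), cfg)
  expect_false(ev_gap$is_tu)
  # constant raw coverage 4 < 5: candidate excluded in that phase
  ev_low <- evaluate_pair(pair, list(normalize_rpm(low_raw)),
                          list(low_raw), cfg)
  expect_false(ev_low$is_tu)
  # multi-phase: one passing phase suffices
  ev_mix <- evaluate_pair(pair,
                          lapply(list(low_raw, flat_raw), normalize_rpm),
                          list(low_raw, flat_raw), cfg)
  expect_true(ev_mix$is_tu)
  expect_equal(ev_mix$passing_phases, 2L)
})

test_that("short pairs are evaluated over the full region without trimming", {
  cfg <- pipeline_config()
  raw <- toy_track(1000, "+", fill = 10)
  short <- list(contig = "c1", strand = "+", tss = 100L, tep = 250L,
                span = 151L)
  reg <- termscape:::evaluation_region(100L, 250L, "+", cfg$tss_offset,
                                       cfg$tep_offset,
                                       cfg$short_pair_cutoff)
  expect_equal(range(reg), c(100L, 250L))
  expect_true(evaluate_pair(short, list(normalize_rpm(raw)), list(raw),
                            cfg)$is_tu)
  # long pair trims 100 bp at each end
  reg2 <- termscape:::evaluation_region(100L, 900L, "+", 100, 100, 200)
  expect_equal(range(reg2), c(200L, 800L))
  # minus strand: trimming follows transcript orientation
  reg3 <- termscape:::evaluation_region(900L, 100L, "-", 100, 100, 200)
  expect_equal(range(reg3), c(200L, 800L))
})

test_that("pair evaluation equals a literal window scan on random regions", {
  cfg <- pipeline_config()
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(150:2000, 1)
    raw <- stats::rpois(n, sample(c(3, 6, 12), 1)) *
      sample(c(0, 1), n, replace = TRUE, prob = c(0.05, 0.95))
    vn <- raw * (1e6 / max(sum(raw), 1))
    got <- termscape:::phase_passes(vn, raw, cfg)
    ref <- bf_phase_passes(vn, raw, min(cfg$tu_window, length(vn)),
                           cfg$tu_frac, cfg$tu_min_raw)
    expect_identical(got, ref)
    # lenient window rule agrees with its reference too
    cfg2 <- pipeline_config(tu_window_rule = "skip-window")
    expect_identical(termscape:::phase_passes(vn, raw, cfg2),
                     bf_phase_passes(vn, raw,
                                     min(cfg$tu_window, length(vn)),
                                     cfg$tu_frac, cfg$tu_min_raw,
                                     rule = "skip-window"))
  }
})

test_that("TU categories count fully contained same-strand genes", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), contig = "c1",
                      strand = c("+", "+", "-"),
                      cds_start = c(100L, 700L, 1200L),
                      cds_end = c(400L, 1000L, 1500L),
                      cog = NA, smbgc = NA, stringsAsFactors = FALSE)
  two <- categorize_tu(list(contig = "c1", strand = "+", start = 50L,
                            end = 1100L), genes, "P")
  expect_equal(two$category, "Poly")
  expect_equal(sort(two$gene_ids), c("gA", "gB"))
  one <- categorize_tu(list(contig = "c1", strand = "+", start = 50L,
                            end = 500L), genes, "P")
  expect_equal(one$category, "Mono")
  # a half-overlapping gene does not count
  half <- categorize_tu(list(contig = "c1", strand = "+", start = 50L,
                             end = 300L), genes, "P")
  expect_equal(half$category, "Inter")
  pre <- categorize_tu(list(contig = "c1", strand = "+", start = 50L,
                            end = 90L), genes, "Pre")
  expect_equal(pre$category, "Pre")
  # opposite-strand gene inside the span does not count
  anti <- categorize_tu(list(contig = "c1", strand = "+", start = 1100L,
                             end = 1600L), genes, "P")
  expect_equal(anti$category, "Inter")
})

test_that("TUC construction is connected-component clustering of overlaps", {
  mk_tus <- function(spans, strand = "+") {
    data.frame(tu_id = sprintf("TU%02d", seq_along(spans)),
               contig = "c1", strand = strand,
               tss = vapply(spans, `[`, 0L, 1),
               tep = vapply(spans, `[`, 0L, 2) - 1L,
               start = vapply(spans, `[`, 0L, 1),
               end = vapply(spans, `[`, 0L, 2),
               stringsAsFactors = FALSE)
  }
  # overlap joins; a shared half-open boundary does not
  r1 <- build_tucs(mk_tus(list(c(0L, 500L), c(400L, 900L))))
  expect_equal(nrow(r1$tucs), 1)
  expect_equal(r1$tucs$start, 0L)
  expect_equal(r1$tucs$end, 900L)
  r2 <- build_tucs(mk_tus(list(c(0L, 500L), c(500L, 900L))))
  expect_equal(nrow(r2$tucs), 2)
  # chain A-B, B-C with A,C disjoint still forms one TUC
  r3 <- build_tucs(mk_tus(list(c(0L, 300L), c(250L, 600L), c(550L, 800L))))
  expect_equal(nrow(r3$tucs), 1)
  expect_equal(r3$tucs$n_tus, 3)
  # membership is a partition with member spans inside the TUC span
  run <- default_run()
  expect_false(any(is.na(run$tus$tuc_id)))
  for (k in seq_len(nrow(run$tucs))) {
    m <- run$tus[run$tus$tuc_id == run$tucs$tuc_id[k], ]
    expect_true(all(m$start >= run$tucs$start[k] &
                    m$end <= run$tucs$end[k]))
  }
  expect_equal(sum(run$tucs$n_tus), nrow(run$tus))
})

test_that("chained overlap components match a brute-force reference", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(3:40, 1)
    starts <- sample.int(2000, n)
    ends <- starts + sample(50:400, n, replace = TRUE)
    tus <- data.frame(tu_id = sprintf("TU%02d", 1:n), contig = "c1",
                      strand = "+", tss = starts, tep = ends - 1L,
                      start = starts, end = ends,
                      stringsAsFactors = FALSE)
    got <- build_tucs(tus)
    # union-find over the explicit overlap graph
    parent <- 1:n
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in 1:n) for (j in 1:n)
      if (starts[i] < ends[j] && starts[j] < ends[i]) {
        ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <- rj
      }
    roots <- vapply(1:n, find, 1L)
    expect_equal(length(unique(roots)), nrow(got$tucs))
    # same partition
    got_part <- split(got$tus$tu_id, got$tus$tuc_id)
    ref_part <- split(tus$tu_id, roots)
    canon <- function(p) unname(lapply(p[order(vapply(p, min, ""))], sort))
    expect_equal(canon(got_part), canon(ref_part))
  }
})

test_that("terminality marks TUs sharing the TUC's 3'-most TEP", {
  tus <- data.frame(
    tu_id = c("TU01", "TU02", "TU03", "TU04"),
    contig = "c1", strand = c("+", "+", "+", "-"),
    tss = c(0L, 50L, 100L, 900L), tep = c(799L, 799L, 500L, 600L),
    start = c(0L, 50L, 100L, 600L), end = c(800L, 800L, 501L, 901L),
    stringsAsFactors = FALSE)
  lab <- assign_terminality(build_tucs(tus)$tus)
  expect_equal(lab$terminality[lab$tu_id %in% c("TU01", "TU02")],
               c("terminal", "terminal"))  # tie at the 3' end
  expect_equal(lab$terminality[lab$tu_id == "TU03"], "nonterminal")
  # singleton TUC (and minus strand 3'-most = smallest coordinate)
  expect_equal(lab$terminality[lab$tu_id == "TU04"], "terminal")
})

test_that("planted TUs are recovered from the default simulation", {
  run <- default_run()
  sim <- default_sim()
  m <- recovery_metrics(run, sim$truth)
  expect_gte(m$tu_recall, 0.9)
  # no reported TU spans a >= 300-nt zero-coverage gap in every phase
  raw <- default_sim()$rnaseq
  for (i in seq_len(nrow(run$tus))) {
    pos <- run$tus$start[i]:(run$tus$end[i] - 1)
    all_zero_len <- vapply(raw, function(tr) {
      v <- track_values(tr, run$tus$contig[i], run$tus$strand[i], pos)
      r <- rle(v == 0)
      if (any(r$values)) max(r$lengths[r$values]) else 0L
    }, 0L)
    expect_lt(min(all_zero_len), 300)
  }
})
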