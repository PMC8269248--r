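test_that("peak clustering follows the <100 bp single-linkage rule", {
  expect_equal(cluster_peaks(c(100, 150, 260), 100),
               list(c(100L, 150L), 260L))
  expect_equal(cluster_peaks(c(100, 190, 280), 100),
               list(c(100L, 190L, 280L)))
  expect_equal(cluster_peaks(42, 100), list(42L))
  expect_equal(cluster_peaks(integer(0), 100), list())
})

test_that("clustering agrees with an O(n^2) union-find reference", {
  set.seed(5)
  for (rep in 1:20) {
    pos <- sort(sample.int(3000, sample(2:400, 1)))
    got <- cluster_peaks(pos, 100)
    ref <- bf_cluster(pos, 100)
    canon <- function(cl) cl[order(vapply(cl, min, 0))]
    expect_equal(lapply(canon(got), as.integer),
                 lapply(canon(ref), as.integer))
  }
})

test_that("subclustering splits on positional sd and picks max-count reps", {
  sc <- subcluster_peaks(c(100, 101, 102), c(3, 9, 2), 25, "+")
  expect_equal(length(unique(sc$subcluster)), 1)
  expect_equal(sc$position[sc$representative], 101)
  # population sd of {100, 160} is 30 >= 25: two subclusters
  sc2 <- subcluster_peaks(c(100, 160), c(5, 5), 25, "+")
  expect_equal(length(unique(sc2$subcluster)), 2)
  # count tie resolves 5'-most in transcript orientation
  tie_p <- subcluster_peaks(c(10, 11), c(7, 7), 25, "+")
  expect_equal(tie_p$position[tie_p$representative], 10)
  tie_m <- subcluster_peaks(c(10, 11), c(7, 7), 25, "-")
  expect_equal(tie_m$position[tie_m$representative], 11)
})

test_that("every subcluster is sd-maximal under the greedy extension", {
  set.seed(8)
  for (rep in 1:10) {
    pos <- sort(sample.int(2000, 60))
    sc <- subcluster_peaks(pos, rep(1, 60), 25, "+")
    for (s in unique(sc$subcluster)) {
      member <- sc$position[sc$subcluster == s]
      expect_lt(sqrt(mean((member - mean(member))^2)), 25)
      nxt <- sc$position[sc$subcluster == s + 1][1]
      if (!is.na(nxt)) {
        ext <- c(member, nxt)
        expect_gte(sqrt(mean((ext - mean(ext))^2)), 25)
      }
    }
  }
})

test_that("intensity and replicate-presence filters apply at boundaries", {
  t1 <- toy_track(1000, "+", c(100, 200, 300), c(3, 10, 4))
  t2 <- toy_track(1000, "+", c(101, 301), c(1, 2))  # nothing near 200
  reps <- data.frame(contig = "c1", position = c(100L, 200L, 300L),
                     strand = "+", count = c(3, 10, 4),
                     stringsAsFactors = FALSE)
  kept <- filter_candidates(reps, list(t1, t2), 1, 4, 2)
  # 100: count 3 < 4 discarded; 200: absent in rep2 discarded;
  # 300: count 4 with 2 at +/-2 in rep2 kept
  expect_equal(kept$position, 300L)
})

test_that("peak Z-score uses flank statistics with the sd floor", {
  tr <- toy_track(1000, "+", 500, 100)
  expect_equal(peak_zscore(tr, "c1", 500, "+", 50), 100)
  # x equal to every flank count: no enrichment
  tr2 <- toy_track(1000, "+", fill = 7)
  expect_equal(peak_zscore(tr2, "c1", 500, "+", 50), 0)
  # one flank position carries an equal peak: z = 99/sqrt(99)
  tr3 <- toy_track(1000, "+", c(500, 520), c(100, 100))
  expect_equal(peak_zscore(tr3, "c1", 500, "+", 50),
               99 / sqrt(99), tolerance = 1e-12)
})

test_that("training sets pair each positive with its offset negatives", {
  tr <- toy_track(5000, "+", seq(500, 4500, by = 100),
                  rep(50, 41))
  cand <- data.frame(contig = "c1",
                     position = seq(500L, 4500L, by = 100L),
                     strand = "+", count = 50,
                     zscore = 10, readthrough = 0.1,
                     stringsAsFactors = FALSE)
  ts <- build_training_sets(cand, tr, pipeline_config())
  expect_equal(sum(ts$labels == "positive"), 41)
  expect_equal(sum(ts$labels == "negative"), 41 * 20)
  expect_true(all(ncol(ts$features) == 21))
  # a negative landing on another positive is dropped
  cand2 <- cand
  cand2$position[2] <- 505L  # within +/-10 of positive 1
  ts2 <- build_training_sets(cand2, tr, pipeline_config())
  expect_lt(sum(ts2$labels == "negative"), 41 * 20)
  # fewer than 10 positives is a training error
  few <- cand[1:5, ]
  expect_error(build_training_sets(few, tr, pipeline_config()),
               "training error")
})

test_that("KNN labels an exact training replica positively", {
  tr <- toy_track(5000, "+", seq(500, 2500, by = 100), rep(60, 21))
  cand <- data.frame(contig = "c1",
                     position = seq(500L, 2500L, by = 100L),
                     strand = "+", count = 60, zscore = 10,
                     readthrough = 0.1, stringsAsFactors = FALSE)
  ts <- build_training_sets(cand, tr, pipeline_config())
  fit <- train_and_call(ts, cand, tr, pipeline_config(cv_reps = 10),
                        seed = 1)
  expect_true(all(fit$labels == "positive"))
  expect_true(fit$cv_accuracy > 0.9)
  # cv_reps = 0: calling proceeds, accuracy undefined
  fit0 <- train_and_call(ts, cand, tr, pipeline_config(cv_reps = 0))
  expect_true(is.na(fit0$cv_accuracy))
  expect_equal(length(fit0$labels), nrow(cand))
})

test_that("TEP categories follow the positional precedence rules", {
  genes <- data.frame(gene_id = c("gA", "gB"), contig = "c1",
                      strand = c("+", "-"),
                      cds_start = c(4000L, 9000L), cds_end = c(5000L, 9600L),
                      cog = NA, smbgc = NA, stringsAsFactors = FALSE)
  tss <- data.frame(contig = "c1", position = c(3900L, 9700L),
                    strand = c("+", "-"), category = "primary",
                    gene_id = c("gA", "gB"), stringsAsFactors = FALSE)
  teps <- data.frame(
    contig = "c1",
    position = c(5100L, 5200L, 4500L, 9300L, 3930L, 3985L, 2000L),
    strand = c("+", "+", "+", "+", "+", "+", "+"),
    count = c(50, 20, 9, 5, 8, 8, 3), stringsAsFactors = FALSE)
  out <- categorize_teps(teps, genes, tss, pipeline_config())
  expect_equal(out$category[1:2], c("P", "S"))    # downstream window
  expect_equal(out$category[3], "Internal")       # inside own CDS
  expect_equal(out$category[4], "A")              # inside opposite CDS
  # 3930 is 30 nt past the primary TSS (< 70): NOT premature, falls to N
  expect_equal(out$category[5], "N")
  # 3985 sits in [TSS+70, start codon): premature
  expect_equal(out$category[6], "Pre")
  expect_equal(out$category[7], "N")
  # minus-strand mirror: P/S downstream means decreasing coordinates
  teps_m <- data.frame(contig = "c1", position = c(8900L, 8800L),
                       strand = "-", count = c(40, 60),
                       stringsAsFactors = FALSE)
  out_m <- categorize_teps(teps_m, genes, tss, pipeline_config())
  expect_equal(out_m$category, c("S", "P"))
  expect_equal(out_m$gene_id, c("gB", "gB"))
})

test_that("categories partition the call set with P unique per gene", {
  run <- default_run()
  teps <- run$teps
  expect_true(all(teps$category %in% c("P", "S", "Pre", "A", "N",
                                       "Internal")))
  p <- teps[teps$category == "P", ]
  expect_false(anyDuplicated(p$gene_id) > 0)
  # every called TEP carries enough raw signal in some replicate
  sim <- default_sim()
  cfg <- pipeline_config()
  for (i in seq_len(nrow(teps))) {
    mx <- max(vapply(sim$termseq, function(tr)
      track_values(tr, teps$contig[i], teps$strand[i], teps$position[i]),
      0))
    expect_gte(mx, cfg$min_peak_count)
  }
})

test_that("called representatives match a literal re-evaluation on a small track", {
  # brute-force reference: enumerate clusters and subclusters by scanning
  # positions left to right with explicit loops, then apply the filters
  set.seed(21)
  L <- 8000
  t1 <- new_track(c(c1 = L))
  peaks <- sort(sample(seq(100, L - 100, by = 37), 40))
  t1[["c1"]]$plus[peaks + 1] <- sample(1:30, 40, replace = TRUE)
  t2 <- t1
  cfg <- pipeline_config()
  cand <- termscape:::candidate_table(t1, cfg)
  # reference
  nz <- which(t1[["c1"]]$plus > 0) - 1
  cnt <- t1[["c1"]]$plus[nz + 1]
  ref <- c()
  cl_id <- cumsum(c(0, diff(nz) >= cfg$cluster_gap))
  for (cl in unique(cl_id)) {
    p <- nz[cl_id == cl]; k <- cnt[cl_id == cl]
    start <- 1
    bounds <- c()
    for (i in seq_along(p)) {
      m <- p[start:i]
      if (sqrt(mean((m - mean(m))^2)) >= cfg$subcluster_sd) {
        bounds <- c(bounds, i); start <- i
      }
    }
    sub <- rep(1, length(p))
    for (b in bounds) sub[b:length(p)] <- sub[b:length(p)] + 1
    for (s in unique(sub)) {
      pp <- p[sub == s]; kk <- k[sub == s]
      ref <- c(ref, pp[which.max(kk)])
    }
  }
  expect_equal(sort(cand$position), sort(ref))
})
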