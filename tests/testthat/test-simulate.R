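test_that("generated genome hits GC target with well-formed genes", {
  sim <- generate_genome(n_genes = 10, gc = 0.72, seed = 1)
  chars <- strsplit(sim$genome$contigs[[1]], "")[[1]]
  gc <- mean(chars %in% c("G", "C"))
  expect_lt(abs(gc - 0.72), 0.02)
  expect_true(all((sim$genes$cds_end - sim$genes$cds_start) %% 3 == 0))
  stops <- c("TGA", "TAA", "TAG")
  for (i in seq_len(nrow(sim$genes))) {
    g <- sim$genes[i, ]
    cds <- substr(sim$genome$contigs[[1]], g$cds_start + 1, g$cds_end)
    if (g$strand == "-") cds <- chartr("ACGT", "TGCA",
                                       paste(rev(strsplit(cds, "")[[1]]),
                                             collapse = ""))
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in% stops)
  }
  # primary TSS 20-150 nt upstream of the start codon
  off <- ifelse(sim$genes$strand == "+",
                sim$genes$cds_start - sim$tss$position,
                sim$tss$position - (sim$genes$cds_end - 1))
  expect_true(all(off >= 20 & off <= 150))
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- generate_genome(n_genes = 5, seed = 7)
  b <- generate_genome(n_genes = 5, seed = 7)
  expect_identical(a$genome$contigs, b$genome$contigs)
  expect_identical(a$genes, b$genes)
  fa1 <- tempfile(); fa2 <- tempfile()
  write_genome(a$genome, fa1); write_genome(b$genome, fa2)
  expect_identical(readLines(fa1), readLines(fa2))
  p1 <- plant_terminators(a, seed = 3)
  p2 <- plant_terminators(b, seed = 3)
  expect_identical(p1$genome$contigs, p2$genome$contigs)
  expect_identical(p1$truth, p2$truth)
})

test_that("planted cassettes satisfy the folding-engine oracle", {
  sim <- generate_genome(n_genes = 12, seed = 5)
  planted <- plant_terminators(sim,
                               class_mix = c("HS-U-rich" = 0.4,
                                             "HS-U-lack" = 0.3,
                                             "LS" = 0.3), seed = 5)
  cfg <- pipeline_config()
  for (i in seq_len(nrow(planted$truth))) {
    tr <- planted$truth[i, ]
    win <- window_seq(planted$genome, tr$contig, tr$position, tr$strand,
                      -cfg$fold_window, -1, rna = TRUE)
    dg <- fold_mfe(win, cfg$fold_temperature)$delta_g
    if (tr$class %in% c("HS-U-rich", "HS-U-lack")) {
      expect_lt(dg, cfg$hs_threshold)
    } else {
      expect_gt(dg, cfg$hs_threshold)
    }
  }
})

test_that("degenerate class mix plants a single class", {
  sim <- generate_genome(n_genes = 4, seed = 2)
  planted <- plant_terminators(sim, class_mix = c("HS-U-rich" = 1,
                                                  "HS-U-lack" = 0,
                                                  "LS" = 0), seed = 2)
  expect_true(all(planted$truth$class == "HS-U-rich"))
  expect_error(plant_terminators(sim, class_mix = c("HS-U-rich" = 0.5,
                                                    "HS-U-lack" = 0.1,
                                                    "LS" = 0.1)),
               "sum to 1")
})

test_that("noiseless shadow-free term-seq is nonzero only at true TEPs", {
  sim <- generate_genome(n_genes = 4, seed = 3)
  planted <- plant_terminators(sim, seed = 3)
  tracks <- simulate_termseq(planted$truth, planted$genome$lengths,
                             replicates = 2, shadow_sd = 0, n_shadows = 0,
                             noise_rate = 0, seed = 1)
  for (tr in tracks) {
    nz_plus <- which(tr[["chr"]]$plus > 0) - 1
    nz_minus <- which(tr[["chr"]]$minus > 0) - 1
    truth_plus <- planted$truth$position[planted$truth$strand == "+"]
    truth_minus <- planted$truth$position[planted$truth$strand == "-"]
    expect_true(all(nz_plus %in% truth_plus))
    expect_true(all(nz_minus %in% truth_minus))
  }
})

test_that("main-peak counts are Poisson around the requested height", {
  # >= 100 planted sites pooled over replicates; mean within 3 SEs
  sim <- generate_genome(n_genes = 60, seed = 11)
  planted <- plant_terminators(sim, class_mix = c("HS-U-rich" = 1,
                                                  "HS-U-lack" = 0,
                                                  "LS" = 0), seed = 11)
  height <- 50
  tracks <- simulate_termseq(planted$truth, planted$genome$lengths,
                             replicates = 2, peak_height = height,
                             shadow_sd = 0, n_shadows = 0, noise_rate = 0,
                             seed = 4)
  counts <- unlist(lapply(tracks, function(tr)
    vapply(seq_len(nrow(planted$truth)), function(i)
      track_values(tr, "chr", planted$truth$strand[i],
                   planted$truth$position[i]), 0)))
  expect_gte(length(counts), 100)
  se <- sqrt(height / length(counts))
  expect_lt(abs(mean(counts) - height), 3 * se)
  # replicates share truth but differ in noise
  expect_false(identical(tracks[[1]], tracks[[2]]))
})

test_that("noiseless RNA-seq reproduces the planted read-through ratios", {
  sim <- generate_genome(n_genes = 6, seed = 9)
  planted <- plant_terminators(sim, seed = 9)
  ratios <- c("HS-U-rich" = 0.1, "HS-U-lack" = 0.4, "LS" = 0.9)
  cov <- simulate_rnaseq(planted$truth, planted$genome$lengths,
                         phases = 2, depth = 100,
                         readthrough_by_class = ratios, noise = FALSE)
  cov_norm <- lapply(cov, normalize_rpm)
  for (i in seq_len(nrow(planted$truth))) {
    tr <- planted$truth[i, ]
    rt <- readthrough_fraction(cov_norm, tr$contig, tr$position,
                               tr$strand, 300)
    expect_equal(rt$fraction, unname(ratios[tr$class]), tolerance = 1e-6)
  }
  # zero depth yields all-zero tracks
  z <- simulate_rnaseq(planted$truth, planted$genome$lengths, phases = 1,
                       depth = 0, noise = FALSE)
  expect_equal(track_total(z[[1]]), 0)
})

test_that("RPF enrichment marks coding and designated regions only", {
  sim <- generate_genome(n_genes = 4, seed = 13)
  planted <- plant_terminators(sim, seed = 13)
  cov <- simulate_rnaseq(planted$truth, planted$genome$lengths,
                         phases = 1, depth = 100, noise = FALSE)[[1]]
  sp <- data.frame(contig = "chr", start = 10L, end = 160L, strand = "+",
                   stringsAsFactors = FALSE)
  rpf <- simulate_rpf(cov, planted$genes, planted$genome$lengths,
                      coding_boost = 3, small_protein_spans = sp,
                      noise = FALSE)
  g <- planted$genes[1, ]
  cds_pos <- g$cds_start:(g$cds_end - 1)
  rna <- track_values(cov, "chr", g$strand, cds_pos)
  expect_true(all(track_values(rpf, "chr", g$strand, cds_pos) ==
                  3 * rna))
  # designated intergenic span boosted over its RNA
  expect_true(mean(track_values(rpf, "chr", "+", 10:159)) >
              mean(track_values(cov, "chr", "+", 10:159)))
  # elsewhere background
  far <- setdiff(300:600, unlist(lapply(seq_len(nrow(planted$genes)),
    function(i) planted$genes$cds_start[i]:planted$genes$cds_end[i])))
  expect_true(all(track_values(rpf, "chr", "-", far) <= 0.5))
  r1 <- simulate_rpf(cov, planted$genes, planted$genome$lengths, seed = 2)
  r2 <- simulate_rpf(cov, planted$genes, planted$genome$lengths, seed = 2)
  expect_identical(r1, r2)
})
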