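#' Run the full pipeline on in-memory inputs
#'
#' Chains TEP calling, categorization, structural classification,
#' read-through annotation, TU assembly, TUC construction, terminality
#' labelling and Bi-TEP detection.
#'
#' @param genome a `termscape_genome`.
#' @param genes,tss annotation tables.
#' @param termseq list of replicate term-seq tracks.
#' @param rnaseq list of per-phase coverage tracks.
#' @param config a [pipeline_config()].
#' @param seed RNG seed for the stochastic stages (KNN CV splits).
#' @return list with `teps`, `tus`, `tucs`, `biteps`, `cv_accuracy`,
#'   `report`.
#' @export
run_pipeline <- function(genome, genes, tss, termseq, rnaseq,
                         config = pipeline_config(),
                         seed = config$rng_seed) {
  calls <- call_teps(termseq, rnaseq, config, seed = seed)
  teps <- categorize_teps(calls$teps, genes, tss, config)
  teps <- classify_teps(teps, genome, config)
  cov_norm <- lapply(rnaseq, normalize_rpm)
  teps$readthrough <- vapply(seq_len(nrow(teps)), function(i)
    readthrough_fraction(cov_norm, teps$contig[i], teps$position[i],
                         teps$strand[i],
                         config$readthrough_flank)$fraction, 0)
  tus <- assemble_tus(tss, teps, rnaseq, genes, config)
  tc <- build_tucs(tus)
  tus <- assign_terminality(tc$tus)
  biteps <- detect_biteps(teps[teps$category != "Internal", ,
                               drop = FALSE],
                          config$bitep_max_overlap)
  rep <- report_summary(teps, tus, tc$tucs, biteps)
  list(teps = teps, tus = tus, tucs = tc$tucs, biteps = biteps,
       cv_accuracy = calls$cv_accuracy, report = rep)
}

#' Recovery of planted truth by a pipeline run
#'
#' Matches called TEPs to planted ones within a positional tolerance and
#' reports precision, recall, class-label agreement (on matched planted
#' ends) and planted-TU recall (a planted TU counts as recovered when a
#' reported TU uses its TSS and a TEP within tolerance).
#'
#' @param result output of [run_pipeline()].
#' @param truth planted-TEP table from the generator.
#' @param tol positional tolerance, nt (default 2).
#' @return list with `precision`, `recall`, `class_agreement`,
#'   `tu_recall`, `n_called`, `n_planted`.
#' @export
recovery_metrics <- function(result, truth, tol = 2) {
  teps <- result$teps
  matched_planted <- logical(nrow(truth))
  matched_class <- logical(nrow(truth))
  called_match <- logical(nrow(teps))
  for (i in seq_len(nrow(truth))) {
    hit <- which(teps$contig == truth$contig[i] &
                 teps$strand == truth$strand[i] &
                 abs(teps$position - truth$position[i]) <= tol)
    if (length(hit)) {
      matched_planted[i] <- TRUE
      called_match[hit] <- TRUE
      matched_class[i] <- any(teps$class[hit] == truth$class[i],
                              na.rm = TRUE)
    }
  }
  tus <- result$tus
  tu_hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(tus$strand == truth$strand[i] & tus$tss == truth$tss[i] &
        abs(tus$tep - truth$position[i]) <= tol)
  }, TRUE)
  list(precision = if (nrow(teps)) mean(called_match) else NA_real_,
       recall = mean(matched_planted),
       class_agreement = if (any(matched_planted))
         mean(matched_class[matched_planted]) else NA_real_,
       tu_recall = mean(tu_hit),
       n_called = nrow(teps),
       n_planted = nrow(truth))
}
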