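#' Pipeline configuration
#'
#' Builds the validated record of every numeric threshold used by the
#' pipeline. Defaults are the values of the published analysis workflow:
#' term-seq peaks closer than 100 bp are clustered and subclustered at a
#' positional standard deviation of 25, peaks with fewer than 4 raw counts
#' are discarded, training positives require a Z-score above 6, upstream
#' windows of 40 nt are folded at 30 degrees C and split at -23 kcal/mol,
#' a U-tract is 3+ uridines in the 8 nt downstream of the stem, read-through
#' uses 300-bp flanks, TU assembly slides 200-bp windows requiring 5% of the
#' region mean and a raw mean of at least 5, and bidirectional TEPs overlap
#' by fewer than 60 bp.
#'
#' @param ... named overrides for any of the fields listed below.
#'
#' @section Fields:
#' \describe{
#'   \item{cluster_gap}{bp; peaks closer than this share a cluster (100)}
#'   \item{subcluster_sd}{maximum positional population sd within a
#'     subcluster (25)}
#'   \item{min_peak_count}{minimum raw count of a representative peak (4)}
#'   \item{zscore_min}{Z-score cutoff for training positives (6)}
#'   \item{knn_window_halfwidth}{half-width of the count-profile feature
#'     window (10, giving 21 features)}
#'   \item{downstream_assoc_window}{bp downstream of a stop codon searched
#'     for primary/secondary TEPs (500)}
#'   \item{premature_offset}{bp downstream of a primary TSS where the
#'     premature region starts (70)}
#'   \item{fold_window}{nt of upstream sequence folded (40)}
#'   \item{fold_temperature}{folding temperature, degrees C (30)}
#'   \item{hs_threshold}{kcal/mol; minimum-free-energy below this is
#'     highly structured (-23)}
#'   \item{utract_window}{nt downstream of the stem inspected for
#'     uridines (8)}
#'   \item{utract_min_u}{uridines needed for the U-rich class (3)}
#'   \item{readthrough_flank}{bp on each side of a TEP for the
#'     read-through fraction (300)}
#'   \item{tu_window}{bp; sliding-window length for TU continuity (200)}
#'   \item{tu_frac}{each window's normalized mean must exceed this
#'     fraction of the region mean (0.05)}
#'   \item{tu_min_raw}{minimum raw window mean (5)}
#'   \item{tss_offset, tep_offset}{bp trimmed from the TSS/TEP ends of the
#'     evaluation region (100 each)}
#'   \item{short_pair_cutoff}{bp; pairs shorter than this are evaluated
#'     without end trimming (200)}
#'   \item{bitep_max_overlap}{bp; convergent 3' ends overlapping by less
#'     than this form a Bi-TEP (60)}
#'   \item{max_span}{bp; upper bound on TSS-TEP candidate spans (20000)}
#'   \item{zscore_flank}{bp flank half-width for the peak Z-score (50)}
#'   \item{replicate_tol}{nt tolerance for replicate presence and for
#'     matching calls across replicates (2)}
#'   \item{knn_k}{neighbours for the KNN peak classifier (5)}
#'   \item{cv_reps}{random 50/50 cross-validation splits (1000)}
#'   \item{readthrough_cutoff}{maximum read-through fraction of a training
#'     positive (0.5)}
#'   \item{random_n}{random genomic positions for background profiles
#'     (10000)}
#'   \item{rpf_median_default}{fallback median CDS RPF RPKM (18.75)}
#'   \item{rpf_rna_log_ratio_default}{fallback median CDS log2 RPF/RNA
#'     RPKM ratio (0.74)}
#'   \item{tu_window_rule}{"exclude-candidate" (default) drops a candidate
#'     pair in a phase whose raw window mean falls below \code{tu_min_raw};
#'     "skip-window" only skips that window}
#'   \item{rng_seed}{base seed for all stochastic operations (1)}
#' }
#'
#' @return a list of class \code{termscape_config}.
#' @examples
#' cfg <- pipeline_config()
#' cfg$hs_threshold
#' pipeline_config(hs_threshold = -20)$hs_threshold
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    cluster_gap = 100,
    subcluster_sd = 25,
    min_peak_count = 4,
    zscore_min = 6,
    knn_window_halfwidth = 10,
    downstream_assoc_window = 500,
    premature_offset = 70,
    fold_window = 40,
    fold_temperature = 30,
    hs_threshold = -23,
    utract_window = 8,
    utract_min_u = 3,
    readthrough_flank = 300,
    tu_window = 200,
    tu_frac = 0.05,
    tu_min_raw = 5,
    tss_offset = 100,
    tep_offset = 100,
    short_pair_cutoff = 200,
    bitep_max_overlap = 60,
    max_span = 20000,
    zscore_flank = 50,
    replicate_tol = 2,
    knn_k = 5,
    cv_reps = 1000,
    readthrough_cutoff = 0.5,
    random_n = 10000,
    rpf_median_default = 18.75,
    rpf_rna_log_ratio_default = 0.74,
    tu_window_rule = "exclude-candidate",
    rng_seed = 1
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  validate_config(cfg)
  class(cfg) <- "termscape_config"
  cfg
}

validate_config <- function(cfg) {
  bad <- character(0)
  pos_keys <- c("cluster_gap", "subcluster_sd", "min_peak_count",
                "knn_window_halfwidth", "downstream_assoc_window",
                "premature_offset", "fold_window", "utract_window",
                "readthrough_flank", "tu_window", "short_pair_cutoff",
                "bitep_max_overlap", "max_span", "zscore_flank", "knn_k")
  for (k in pos_keys)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] <= 0)
      bad <- c(bad, k)
  if (!(cfg$tu_frac > 0 && cfg$tu_frac < 1)) bad <- c(bad, "tu_frac")
  if (!(cfg$hs_threshold < 0)) bad <- c(bad, "hs_threshold")
  if (cfg$tss_offset < 0) bad <- c(bad, "tss_offset")
  if (cfg$tep_offset < 0) bad <- c(bad, "tep_offset")
  if (cfg$replicate_tol < 0) bad <- c(bad, "replicate_tol")
  if (cfg$cv_reps < 0) bad <- c(bad, "cv_reps")
  if (cfg$random_n < 1) bad <- c(bad, "random_n")
  if (!cfg$tu_window_rule %in% c("exclude-candidate", "skip-window"))
    bad <- c(bad, "tu_window_rule")
  if (length(bad))
    stop("configuration error: invalid value for key(s): ",
         paste(unique(bad), collapse = ", "))
  invisible(cfg)
}

#' Load configuration from a flat YAML file
#'
#' Absent keys take the documented defaults; present keys override them and
#' the combined record is validated.
#'
#' @param path path to a flat YAML file, or `NULL` for pure defaults.
#' @param quiet suppress the config echo.
#' @return a `termscape_config` list.
#' @export
load_config <- function(path = NULL, quiet = TRUE) {
  overrides <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    overrides <- yaml::read_yaml(path)
    if (is.null(overrides)) overrides <- list()
  }
  cfg <- do.call(pipeline_config, overrides)
  if (!quiet) {
    message("pipeline configuration:")
    for (k in names(cfg)) message("  ", k, " = ", cfg[[k]])
  }
  cfg
}
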