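#' Write called features to BED and TSV
#'
#' TEPs go to BED6 (one-base intervals, name = `category:class`, score =
#' count) plus a TSV with every numeric attribute; TUs and TUCs go to
#' BED-like files plus TSVs. All coordinates stay 0-based half-open, the
#' native BED convention.
#'
#' @param teps,tus,tucs result tables (any may be NULL or empty).
#' @param out_dir output directory, created if needed.
#' @return invisible character vector of written paths.
#' @export
write_features <- function(teps, tus, tucs, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create ", out_dir)
  paths <- character(0)
  bed_path <- file.path(out_dir, "teps.bed")
  con <- file(bed_path, "w")
  writeLines("# BED6: TEP positions; name = category:class", con)
  if (!is.null(teps) && nrow(teps)) {
    nm <- paste0(ifelse(is.na(teps$category), "NA", teps$category), ":",
                 ifelse(is.na(teps$class), "NA", teps$class))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", teps$contig,
                       teps$position, teps$position + 1, nm,
                       formatC(teps$count, format = "g"), teps$strand),
               con)
  }
  close(con)
  paths <- c(paths, bed_path)
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(if (is.null(df)) data.frame() else df, p,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(paths, tsv(teps, "teps.tsv"))
  bed_span <- function(df, name) {
    p <- file.path(out_dir, name)
    con <- file(p, "w")
    writeLines(paste0("# BED: ", sub("[.]bed$", "", name),
                      " spans (0-based half-open)"), con)
    if (!is.null(df) && nrow(df)) {
      id <- if ("tu_id" %in% names(df)) df$tu_id else df$tuc_id
      writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", df$contig, df$start,
                         df$end, id, df$strand), con)
    }
    close(con)
    p
  }
  paths <- c(paths, bed_span(tus, "tus.bed"), tsv(tus, "tus.tsv"),
             bed_span(tucs, "tucs.bed"), tsv(tucs, "tucs.tsv"))
  invisible(paths)
}

#' Read back feature TSVs written by [write_features()]
#'
#' @param out_dir directory written by [write_features()].
#' @return list with `teps`, `tus`, `tucs` data.frames.
#' @export
read_features <- function(out_dir) {
  rd <- function(name) {
    p <- file.path(out_dir, name)
    if (!file.exists(p)) return(NULL)
    info <- file.info(p)
    if (info$size <= 1) return(data.frame())
    utils::read.table(p, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  list(teps = rd("teps.tsv"), tus = rd("tus.tsv"), tucs = rd("tucs.tsv"))
}

#' Read all pipeline inputs from disk
#'
#' @param genome_path FASTA; `annotation_path` GFF3; `tss_path` TSV;
#'   `termseq_paths` list of `c(plus, minus)` BedGraph pairs, one per
#'   replicate; `rnaseq_paths` likewise per phase.
#' @return list with `genome`, `genes`, `tss`, `termseq`, `rnaseq`.
#' @export
read_inputs <- function(genome_path, annotation_path, tss_path,
                        termseq_paths, rnaseq_paths) {
  genome <- read_genome(genome_path)
  genes <- read_genes(annotation_path)
  tss <- read_tss(tss_path)
  termseq <- lapply(termseq_paths, function(pp)
    read_bedgraph_track(pp[[1]], pp[[2]], genome$lengths))
  rnaseq <- lapply(rnaseq_paths, function(pp)
    read_bedgraph_track(pp[[1]], pp[[2]], genome$lengths))
  list(genome = genome, genes = genes, tss = tss, termseq = termseq,
       rnaseq = rnaseq)
}
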