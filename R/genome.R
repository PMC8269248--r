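#' Genome container
#'
#' A genome is a named set of contig sequences plus their lengths. All
#' coordinates in this package are 0-based half-open on the forward strand;
#' strand only changes the reading orientation, never the coordinate system.
#'
#' @param contigs named character vector of uppercase A/C/G/T/N sequences.
#' @return an object of class `termscape_genome` with fields `contigs`
#'   (named character) and `lengths` (named integer).
#' @examples
#' g <- new_genome(c(c1 = "ACGTACGT"))
#' g$lengths
#' @export
new_genome <- function(contigs) {
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("contigs must be named")
  contigs <- vapply(contigs, function(s) toupper(as.character(s)), "")
  if (any(nchar(contigs) == 0)) stop("empty contig sequence")
  if (any(grepl("[^ACGTN]", contigs)))
    stop("genome alphabet restricted to A/C/G/T/N")
  structure(list(contigs = contigs,
                 lengths = stats::setNames(nchar(contigs), names(contigs))),
            class = "termscape_genome")
}

#' @export
print.termscape_genome <- function(x, ...) {
  cat("termscape genome:", length(x$contigs), "contig(s),",
      sum(x$lengths), "bp total\n")
  invisible(x)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return a `termscape_genome`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  new_genome(seqs)
}

#' Write a genome to FASTA
#' @param genome a `termscape_genome`.
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert between 1-based closed (GFF3) and 0-based half-open intervals
#'
#' GFF3 stores `[start, end]` 1-based closed; internally this package uses
#' `[start, end)` 0-based half-open. These converters are the single place
#' the two conventions meet.
#'
#' @param start,end interval endpoints in the source convention.
#' @return a list with `start` and `end` in the target convention.
#' @export
gff_to_zero_based <- function(start, end) {
  if (any(start < 1) || any(end < start))
    stop("invalid 1-based closed interval")
  list(start = start - 1L, end = end)
}

#' @rdname gff_to_zero_based
#' @export
zero_based_to_gff <- function(start, end) {
  if (any(start < 0) || any(end <= start))
    stop("invalid 0-based half-open interval")
  list(start = start + 1L, end = end)
}

# Genomic positions at transcript offsets around `position` (offset 0 = the
# position itself). Positive offsets are downstream in transcript
# orientation: increasing coordinates on +, decreasing on -.
tx_positions <- function(position, strand, offsets) {
  if (strand == "+") position + offsets else position - offsets
}

# Transcript-orientation sequence covering offsets from..to (inclusive)
# around `position`. Returns the sequence 5'->3' of the transcript; out of
# bounds portions are clipped. rna=TRUE transcribes T->U.
window_seq <- function(genome, contig, position, strand, from, to,
                       rna = TRUE) {
  stopifnot(from <= to)
  len <- genome$lengths[[contig]]
  if (strand == "+") {
    g0 <- max(0, position + from)
    g1 <- min(len, position + to + 1)  # half-open
    if (g1 <= g0) return("")
    s <- substr(genome$contigs[[contig]], g0 + 1, g1)
  } else {
    g0 <- max(0, position - to)
    g1 <- min(len, position - from + 1)
    if (g1 <= g0) return("")
    s <- revcomp(substr(genome$contigs[[contig]], g0 + 1, g1))
  }
  if (rna) s <- chartr("T", "U", s)
  s
}

#' Read a gene table from GFF3
#'
#' Consumes CDS/gene features; 1-based closed GFF3 coordinates are converted
#' to the internal 0-based half-open convention. Optional `cog` and `smbgc`
#' attributes are carried through.
#'
#' @param path GFF3 file.
#' @return data.frame with columns gene_id, contig, strand, cds_start,
#'   cds_end (0-based half-open), cog, smbgc.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("annotation GFF3 not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type %in% c("CDS", "gene")]
  if (!length(gr)) stop("no CDS/gene features in ", path)
  ids <- if (!is.null(gr$ID)) gr$ID else as.character(seq_along(gr))
  conv <- gff_to_zero_based(GenomicRanges::start(gr), GenomicRanges::end(gr))
  df <- data.frame(
    gene_id = as.character(ids),
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    cds_start = conv$start,
    cds_end = conv$end,
    cog = if (!is.null(gr$cog)) as.character(gr$cog) else NA_character_,
    smbgc = if (!is.null(gr$smbgc)) as.character(gr$smbgc) else NA_character_,
    stringsAsFactors = FALSE
  )
  validate_genes(df)
}

validate_genes <- function(df) {
  if (any(!df$strand %in% c("+", "-")))
    stop("gene strand must be + or -")
  if (any(df$cds_start >= df$cds_end))
    stop("gene with cds_start >= cds_end")
  df
}

#' Write a gene table to GFF3
#' @param genes gene data.frame (see [read_genes()]).
#' @param genome a `termscape_genome` (for contig lengths).
#' @param path output file.
#' @export
write_genes <- function(genes, genome, path) {
  conv <- zero_based_to_gff(genes$cds_start, genes$cds_end)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = conv$start, end = conv$end),
    strand = genes$strand
  )
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  gr$cog <- genes$cog
  gr$smbgc <- genes$smbgc
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a TSS table
#'
#' Tab-separated with columns contig, position (0-based), strand, category
#' (primary/secondary/internal/antisense/orphan) and gene_id.
#'
#' @param path TSV file.
#' @return data.frame of TSS records.
#' @export
read_tss <- function(path) {
  if (!file.exists(path)) stop("TSS table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(position = "integer"))
  need <- c("contig", "position", "strand", "category", "gene_id")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("TSS table missing column(s): ", paste(missing, collapse = ", "))
  if (any(!df$strand %in% c("+", "-"))) stop("TSS strand must be + or -")
  prim <- df[df$category == "primary" & !is.na(df$gene_id), ]
  if (anyDuplicated(prim$gene_id))
    stop("primary TSS must be unique per gene")
  df
}

#' Write a TSS table
#' @param tss TSS data.frame.
#' @param path output TSV.
#' @export
write_tss <- function(tss, path) {
  utils::write.table(tss, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
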