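#' @name io
#' @title Readers and writers for the pipeline's tabular formats
#'
#' @description
#' All tables travel as TSV with a header; intervals in files follow the BED
#' convention (0-based half-open), matching the in-memory representation, so
#' round trips are exact. BED and bedGraph themselves go through rtracklayer;
#' the 1-based GRanges coordinates it produces are converted back to 0-based
#' at this boundary.
NULL

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, colClasses = NA) {
  utils::read.delim(path, sep = "\t", header = TRUE, colClasses = colClasses,
                    stringsAsFactors = FALSE)
}

#' @rdname io
#' @param exons Exon table.
#' @param path File path.
#' @export
write_exon_table <- function(exons, path) .write_tsv(exons, path)

#' @rdname io
#' @export
read_exon_table <- function(path) {
  df <- .read_tsv(path, colClasses = c(
    exon_id = "character", gene_id = "character", index = "integer",
    chrom = "character", start = "numeric", end = "numeric",
    strand = "character", up_start = "numeric", up_end = "numeric",
    down_start = "numeric", down_end = "numeric", constitutive = "logical"
  ))
  validate_exon_table(df)
  class(df) <- c("exon_table", "data.frame")
  df
}

#' @rdname io
#' @param genes Gene table (gene_id, chrom, start, end, strand, n_exons).
#' @export
write_gene_table <- function(genes, path) .write_tsv(genes, path)

#' @rdname io
#' @export
read_gene_table <- function(path) {
  .read_tsv(path, colClasses = c(
    gene_id = "character", chrom = "character", start = "numeric",
    end = "numeric", strand = "character", n_exons = "integer"
  ))
}

#' @rdname io
#' @param regulation Regulation table (factor, sample_id, exon_id, direction).
#' @export
write_regulation_table <- function(regulation, path) .write_tsv(regulation, path)

#' @rdname io
#' @export
read_regulation_table <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  need <- c("factor", "sample_id", "exon_id", "direction")
  if (!all(need %in% names(df))) {
    stop("regulation table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!df$direction %in% c("activated", "repressed"))) {
    stop("direction must be 'activated' or 'repressed'")
  }
  df[need]
}

#' @rdname io
#' @param domains Domain table (domain_id, kind, chrom, start, end, gc_percent).
#' @export
write_domain_table <- function(domains, path) .write_tsv(domains, path)

#' @rdname io
#' @export
read_domain_table <- function(path) {
  .read_tsv(path, colClasses = c(
    domain_id = "character", kind = "character", chrom = "character",
    start = "numeric", end = "numeric", gc_percent = "numeric"
  ))
}

#' @rdname io
#' @param intervals data.frame with chrom, start, end and optional name,
#'   score, strand columns.
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1, end = intervals$end),
    strand = if (is.null(intervals$strand)) "*" else intervals$strand
  )
  if (!is.null(intervals$name)) gr$name <- intervals$name
  if (!is.null(intervals$score)) gr$score <- intervals$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname io
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  df$strand[df$strand == "*"] <- "+"
  if (!is.null(gr$name)) df$name <- gr$name
  if (!is.null(gr$score)) df$score <- gr$score
  df
}
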