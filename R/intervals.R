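#' Construct a table of genomic intervals
#'
#' Intervals are 0-based half-open throughout the package; 1-based inputs
#' (GFF-style) must be converted at the reader boundary.
#'
#' @param chrom Chromosome names.
#' @param start 0-based inclusive starts.
#' @param end Exclusive ends.
#' @param strand `"+"` or `"-"` (recycled; default `"+"`).
#' @return data.frame with columns chrom, start, end, strand.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  df <- data.frame(
    chrom = as.character(chrom), start = as.numeric(start),
    end = as.numeric(end), strand = rep_len(strand, length(chrom)),
    stringsAsFactors = FALSE
  )
  if (any(df$start < 0 | df$start >= df$end)) {
    stop("invalid interval: need 0 <= start < end")
  }
  if (any(!df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df
}

#' Length of the intersection of two intervals
#'
#' Vectorized over rows; intervals on different chromosomes are disjoint.
#'
#' @param a,b data.frames with columns chrom, start, end (rows recycled).
#' @return Integer vector of overlap lengths (0 when disjoint).
#' @export
overlap_length <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmax(0, pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi]))
  ov * (a$chrom[ai] == b$chrom[bi])
}

#' Size of the smallest intron flanking each exon
#'
#' Defined as the minimum of the upstream and downstream intron lengths, and
#' only when both introns exist: terminal exons yield NA and are excluded
#' from any median computed over this feature.
#'
#' @param exons Exon table (see [exon_table()]).
#' @return Numeric vector (NA for terminal exons), one value per row.
#' @export
smallest_flanking_intron <- function(exons) {
  up <- exons$up_end - exons$up_start
  dn <- exons$down_end - exons$down_start
  out <- pmin(up, dn)
  out[is.na(up) | is.na(dn)] <- NA_real_
  out
}

#' Assemble an exon table
#'
#' The central annotation carrier: one row per exon with its interval, its
#' ordinal index within the gene (1-based, transcript order), the flanking
#' intron intervals (NA for terminal exons), and a constitutive flag used to
#' build control sets.
#'
#' @param exon_id,gene_id Identifier columns.
#' @param index 1-based ordinal of the exon within its gene.
#' @param chrom,start,end,strand Exon interval (0-based half-open).
#' @param up_start,up_end Upstream-intron interval (transcript orientation);
#'   NA for first exons.
#' @param down_start,down_end Downstream-intron interval; NA for last exons.
#' @param constitutive Logical flag (default FALSE).
#' @return data.frame of class `exon_table`.
#' @export
exon_table <- function(exon_id, gene_id, index, chrom, start, end, strand,
                       up_start = NA, up_end = NA,
                       down_start = NA, down_end = NA,
                       constitutive = FALSE) {
  n <- length(exon_id)
  df <- data.frame(
    exon_id = as.character(exon_id), gene_id = as.character(gene_id),
    index = as.integer(index), chrom = as.character(chrom),
    start = as.numeric(start), end = as.numeric(end),
    strand = rep_len(strand, n),
    up_start = rep_len(as.numeric(up_start), n),
    up_end = rep_len(as.numeric(up_end), n),
    down_start = rep_len(as.numeric(down_start), n),
    down_end = rep_len(as.numeric(down_end), n),
    constitutive = rep_len(as.logical(constitutive), n),
    stringsAsFactors = FALSE
  )
  validate_exon_table(df)
  class(df) <- c("exon_table", "data.frame")
  df
}

#' Validate exon-table invariants
#'
#' Checks coordinates, uniqueness of exon ids, that flanking introns abut the
#' exon in transcript orientation, and that exons of one gene are ordered and
#' non-overlapping.
#'
#' @param exons Exon table.
#' @return Invisibly TRUE; stops on violation.
#' @export
validate_exon_table <- function(exons) {
  if (anyDuplicated(exons$exon_id)) stop("duplicate exon ids")
  if (any(exons$start < 0 | exons$start >= exons$end)) {
    stop("invalid exon interval")
  }
  # introns must abut the exon: on '+' the upstream intron ends at the exon
  # start; on '-' it begins at the exon end (transcript orientation).
  plus <- exons$strand == "+"
  has_up <- !is.na(exons$up_start)
  has_dn <- !is.na(exons$down_start)
  ok_up <- ifelse(plus, exons$up_end == exons$start, exons$up_start == exons$end)
  ok_dn <- ifelse(plus, exons$down_start == exons$end, exons$down_end == exons$start)
  if (any(has_up & !ok_up, na.rm = TRUE)) stop("upstream intron does not abut exon")
  if (any(has_dn & !ok_dn, na.rm = TRUE)) stop("downstream intron does not abut exon")
  if (any(exons$index == 1 & has_up)) stop("first exon cannot have an upstream intron")
  for (g in split(exons, exons$gene_id)) {
    g <- g[order(g$index), ]
    o <- order(g$start)
    if (is.unsorted(g$start[o], strictly = TRUE)) stop("exon starts not distinct")
    if (any(g$start[o][-1] < g$end[o][-nrow(g)])) {
      stop("overlapping exons within gene ", g$gene_id[1])
    }
  }
  invisible(TRUE)
}
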