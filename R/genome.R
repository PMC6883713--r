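#' Read a genome FASTA into a named character vector
#'
#' Sequence names are truncated at the first whitespace, matching the usual
#' FASTA header convention. Bases are uppercased; the working alphabet is
#' A, C, G, T, N.
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return Named character vector, one element per chromosome.
#' @export
read_genome <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(dss))
  names(g) <- sub("\\s.*$", "", names(dss))
  g
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome Named character vector of chromosome sequences.
#' @return Named integer vector of lengths.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(nchar(genome), names(genome))
}

#' Reverse complement of DNA sequences
#'
#' @param x Character vector of sequences over A, C, G, T, N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Extract sequence for genomic intervals, in transcript orientation
#'
#' Coordinates are 0-based half-open (BED convention). For minus-strand
#' intervals the reverse complement is returned, so downstream feature windows
#' ("last 100 nt of the upstream intron", "first 50 nt of the exon", ...) can
#' always be taken from the string left-to-right in 5' to 3' transcript order.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom,start,end Interval coordinates (vectors, recycled to the
#'   longest length). `start` is 0-based inclusive, `end` exclusive.
#' @param strand `"+"` or `"-"` (vector, recycled).
#' @return Character vector of sequences.
#' @export
extract_sequence <- function(genome, chrom, start, end, strand = "+") {
  n <- max(length(chrom), length(start), length(end), length(strand))
  chrom <- rep_len(chrom, n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  strand <- rep_len(strand, n)
  bad <- !(chrom %in% names(genome))
  if (any(bad)) {
    stop("unknown chromosome(s): ", paste(unique(chrom[bad]), collapse = ", "))
  }
  if (any(!strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  len <- chrom_lengths(genome)[chrom]
  if (any(start < 0 | start >= end | end > len)) {
    stop("interval out of bounds or empty (need 0 <= start < end <= chrom length)")
  }
  seqs <- substring(genome[chrom], start + 1, end)
  neg <- strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  unname(seqs)
}
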