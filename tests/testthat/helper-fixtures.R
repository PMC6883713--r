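# Shared fixtures. The default bundle is simulated once per test run and
# cached; tests that need different generator settings build their own.

.fixture_cache <- new.env()

default_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    .fixture_cache$bundle <- simulate_bundle(simulation_config(seed = 1))
  }
  .fixture_cache$bundle
}

# a single-exon annotation with controllable junction sequences: upstream
# intron (100 nt), exon (50 nt), downstream intron (100 nt), embedded in
# padding so minus-strand placement is exercised too
junction_exon_fixture <- function(up_seq, exon_seq, down_seq, strand = "+",
                                  pad = 30) {
  tseq <- paste0(up_seq, exon_seq, down_seq)
  gseq <- if (strand == "+") tseq else as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(tseq)))
  chrom_seq <- paste0(strrep("A", pad), gseq, strrep("A", pad))
  genome <- stats::setNames(chrom_seq, "chrT")
  L <- nchar(tseq)
  lu <- nchar(up_seq); le <- nchar(exon_seq); ld <- nchar(down_seq)
  # transcript intervals -> genomic (0-based, within chrom after padding)
  tg <- function(a, b) {
    if (strand == "+") c(pad + a, pad + b) else c(pad + L - b, pad + L - a)
  }
  up <- tg(0, lu); ex <- tg(lu, lu + le); dn <- tg(lu + le, L)
  exons <- exon_table(
    exon_id = "e1", gene_id = "g1", index = 2, chrom = "chrT",
    start = ex[1], end = ex[2], strand = strand,
    up_start = up[1], up_end = up[2], down_start = dn[1], down_end = dn[2]
  )
  list(genome = genome, exons = exons)
}

# n tandem intron+exon blocks on one plus-strand chromosome, one row per
# exon, each with a 100-nt upstream intron and 50-nt exon
tandem_junction_fixture <- function(region_seqs) {
  stopifnot(all(nchar(region_seqs) == 150))
  chrom_seq <- paste(region_seqs, collapse = "")
  genome <- stats::setNames(chrom_seq, "chrT")
  off <- (seq_along(region_seqs) - 1) * 150
  exons <- exon_table(
    exon_id = paste0("e", seq_along(region_seqs)),
    gene_id = paste0("g", seq_along(region_seqs)),
    index = 2, chrom = "chrT",
    start = off + 100, end = off + 150, strand = "+",
    up_start = off, up_end = off + 100,
    down_start = NA, down_end = NA
  )
  list(genome = genome, exons = exons)
}
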