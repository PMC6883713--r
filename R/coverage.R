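#' Coverage tracks
#'
#' A coverage track holds one non-negative numeric vector per chromosome
#' (position -> depth, 0-based indexing at the interface). Positions outside
#' a stored vector, and chromosomes absent from the track, read as 0.
#'
#' @param values Named list of numeric vectors, one per chromosome.
#' @return Object of class `coverage_track`.
#' @export
coverage_track <- function(values) {
  stopifnot(is.list(values), !is.null(names(values)))
  if (any(vapply(values, function(v) any(v < 0), logical(1)))) {
    stop("coverage values must be non-negative")
  }
  structure(list(values = values), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$values), "chromosome(s)\n")
  for (nm in names(x$values)) {
    cat(" ", nm, ":", length(x$values[[nm]]), "bp, mean",
        signif(mean(x$values[[nm]]), 4), "\n")
  }
  invisible(x)
}

#' Fetch coverage over a window, transcript-oriented
#'
#' Out-of-range positions are padded with 0 so callers can anchor fixed-width
#' windows at splice sites near chromosome edges.
#'
#' @param track A [coverage_track()].
#' @param chrom,start,end Window (0-based half-open).
#' @param strand If `"-"`, the vector is reversed (transcript orientation).
#' @return Numeric vector of length `end - start`.
#' @export
coverage_window <- function(track, chrom, start, end, strand = "+") {
  stopifnot(end > start)
  v <- track$values[[chrom]]
  n <- end - start
  out <- numeric(n)
  if (!is.null(v)) {
    lo <- max(start, 0)
    hi <- min(end, length(v))
    if (hi > lo) out[(lo - start + 1):(hi - start)] <- v[(lo + 1):hi]
  }
  if (strand == "-") out <- rev(out)
  out
}

#' Read a bedGraph file into a coverage track
#'
#' @param path bedGraph path.
#' @param chrom_lengths Named integer vector giving the full length of each
#'   chromosome (e.g. from [chrom_lengths()]).
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, chrom_lengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  vals <- lapply(names(chrom_lengths), function(ch) numeric(chrom_lengths[[ch]]))
  names(vals) <- names(chrom_lengths)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    score = gr$score
  )
  for (ch in unique(df$chrom)) {
    if (is.null(vals[[ch]])) next
    sub <- df[df$chrom == ch, , drop = FALSE]
    lens <- sub$end - sub$start
    pos <- sequence(lens) + rep(sub$start, lens)
    vals[[ch]][pos] <- rep(sub$score, lens)
  }
  coverage_track(vals)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal depth are merged into single records; zero runs are kept so
#' the round trip reproduces the track exactly.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  recs <- lapply(names(track$values), function(ch) {
    r <- rle(track$values[[ch]])
    ends <- cumsum(r$lengths)
    data.frame(chrom = ch, start = ends - r$lengths, end = ends,
               score = r$values, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, recs)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    score = df$score
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Binary coverage track marking peak intervals
#'
#' @param peaks data.frame with chrom, start, end (0-based half-open).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return A [coverage_track()] with 1 inside any peak and 0 elsewhere.
#' @export
peaks_track <- function(peaks, chrom_lengths) {
  vals <- lapply(names(chrom_lengths), function(ch) numeric(chrom_lengths[[ch]]))
  names(vals) <- names(chrom_lengths)
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]
    if (is.null(vals[[ch]])) next
    lo <- max(peaks$start[i], 0)
    hi <- min(peaks$end[i], length(vals[[ch]]))
    if (hi > lo) vals[[ch]][(lo + 1):hi] <- 1
  }
  coverage_track(vals)
}
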