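#' Per-sequence base frequencies
#'
#' Percentages of A, C, G and T over the non-N positions of a sequence.
#' N bases are excluded from the denominator rather than being attributed a
#' composition. Thymine stands for both T and U: composition features are
#' defined identically at the DNA and RNA level.
#'
#' @param seq A single nucleotide string.
#' @return Named numeric vector (A, C, G, T) summing to 100.
#' @export
base_frequencies <- function(seq) {
  cnt <- seq_base_counts(seq)
  tot <- sum(cnt)
  if (tot == 0) stop("sequence has no A/C/G/T content")
  100 * cnt / tot
}

seq_base_counts <- function(seqs) {
  m <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs),
                                   letters = c("A", "C", "G", "T"))
  if (length(seqs) == 1) m[1, ] else m
}

#' Composite base-set percentage of sequences
#'
#' The composition statistic behind every heatmap and threshold in the
#' pipeline: the percentage of a base pair (GC by default, GA or CT for the
#' purine/pyrimidine generalizations) over the non-N positions, per sequence.
#'
#' @param seqs Character vector of sequences.
#' @param base_set String naming the bases to pool, e.g. `"GC"`, `"AT"`,
#'   `"GA"`, `"CT"`, or a single base `"G"`.
#' @return Numeric vector of percentages (NA for all-N sequences).
#' @export
base_set_percent <- function(seqs, base_set = "GC") {
  bases <- strsplit(toupper(base_set), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) stop("base_set must use A/C/G/T")
  m <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs),
                                   letters = c("A", "C", "G", "T"))
  tot <- rowSums(m)
  out <- 100 * rowSums(m[, bases, drop = FALSE]) / tot
  out[tot == 0] <- NA_real_
  out
}

#' Relative median feature value of an exon set versus a control set
#'
#' `100 * (median(d_s) - median(d_c)) / median(d_c)`: the percentage shift of
#' a set's median feature value relative to the control median. This is the
#' cell statistic of all composition heatmaps.
#'
#' @param d_s Feature values for the set of interest.
#' @param d_c Feature values for the control set.
#' @param na.rm Drop NA values before taking medians (default TRUE).
#' @return Relative value in percent.
#' @export
rfreq <- function(d_s, d_c, na.rm = TRUE) {
  .rfreq_core(d_s, d_c, stats::median, na.rm)
}

#' Mean-based variant of [rfreq()]
#'
#' Identical contract with the mean replacing the median; used for the
#' position-window heatmaps where per-exon counts are small and medians
#' degenerate.
#'
#' @inheritParams rfreq
#' @return Relative value in percent.
#' @export
rfreq_mean <- function(d_s, d_c, na.rm = TRUE) {
  .rfreq_core(d_s, d_c, mean, na.rm)
}

.rfreq_core <- function(d_s, d_c, fun, na.rm) {
  if (na.rm) {
    d_s <- d_s[!is.na(d_s)]
    d_c <- d_c[!is.na(d_c)]
  }
  if (length(d_s) == 0 || length(d_c) == 0) stop("empty feature vector")
  mc <- fun(d_c)
  if (mc == 0) stop("control location is zero; relative value undefined")
  100 * (fun(d_s) - mc) / mc
}

#' Sliding-window composition profile across splice junctions
#'
#' For the 3' splice site the profiled region is the last `intron_flank`
#' (default 100) nt of the upstream intron followed by the first `exon_flank`
#' (default 50) nt of the exon; for the 5' splice site, the last 50 nt of the
#' exon followed by the first 100 nt of the downstream intron. Windows of
#' `window` nt advance by `step` nt; each window's base-set percentage is
#' averaged across exons and reported at the window's center position
#' (left-of-center for even window sizes). Offsets are negative upstream of
#' the splice site and positive downstream, with no position 0. Exons whose
#' relevant intron or exon is shorter than the requested flank are dropped
#' with a warning.
#'
#' @param exons Exon table.
#' @param genome Genome (named character vector).
#' @param anchor `"3ss"` or `"5ss"`.
#' @param base_set Base set to profile (see [base_set_percent()]).
#' @param window,step Window size and step in nt.
#' @param intron_flank,exon_flank Region geometry in nt.
#' @return data.frame (offset, value) of class `window_profile` with
#'   attributes `anchor`, `base_set`, `n` (exons used), `window`, `step`.
#' @export
junction_profile <- function(exons, genome, anchor = c("3ss", "5ss"),
                             base_set = "GC", window = 20, step = 1,
                             intron_flank = 100, exon_flank = 50) {
  anchor <- match.arg(anchor)
  if (nrow(exons) == 0) stop("empty exon list")
  seqs <- junction_region_seq(exons, genome, anchor, intron_flank, exon_flank)
  if (length(seqs) == 0) stop("no exon has the required flanks")
  L <- intron_flank + exon_flank
  regpos <- if (anchor == "3ss") {
    c(-(intron_flank:1), seq_len(exon_flank))
  } else {
    c(-(exon_flank:1), seq_len(intron_flank))
  }
  bases <- strsplit(toupper(base_set), "")[[1]]
  ch <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
               nrow = length(seqs), ncol = L, byrow = TRUE)
  memb <- matrix(as.numeric(ch %in% bases), nrow = nrow(ch))
  memb[ch == "N"] <- NA
  starts <- seq(1, L - window + 1, by = step)
  vals <- vapply(starts, function(j) {
    per_exon <- rowMeans(memb[, j:(j + window - 1), drop = FALSE], na.rm = TRUE)
    100 * mean(per_exon, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(offset = regpos[starts + (window - 1L) %/% 2L], value = vals)
  structure(out, anchor = anchor, base_set = base_set, n = length(seqs),
            window = window, step = step,
            class = c("window_profile", "data.frame"))
}

junction_region_seq <- function(exons, genome, anchor, intron_flank, exon_flank) {
  ex_len <- exons$end - exons$start
  if (anchor == "3ss") {
    intr_len <- exons$up_end - exons$up_start
    ok <- !is.na(intr_len) & intr_len >= intron_flank & ex_len >= exon_flank
  } else {
    intr_len <- exons$down_end - exons$down_start
    ok <- !is.na(intr_len) & intr_len >= intron_flank & ex_len >= exon_flank
  }
  if (any(!ok)) {
    warning(sum(!ok), " exon(s) dropped: flank shorter than requested region")
  }
  ex <- exons[ok, , drop = FALSE]
  if (nrow(ex) == 0) return(character(0))
  if (anchor == "3ss") {
    intron <- extract_sequence(genome, ex$chrom, ex$up_start, ex$up_end, ex$strand)
    exonic <- extract_sequence(genome, ex$chrom, ex$start, ex$end, ex$strand)
    paste0(substring(intron, nchar(intron) - intron_flank + 1, nchar(intron)),
           substring(exonic, 1, exon_flank))
  } else {
    intron <- extract_sequence(genome, ex$chrom, ex$down_start, ex$down_end, ex$strand)
    exonic <- extract_sequence(genome, ex$chrom, ex$start, ex$end, ex$strand)
    paste0(substring(exonic, nchar(exonic) - exon_flank + 1, nchar(exonic)),
           substring(intron, 1, intron_flank))
  }
}

#' Matrix of relative feature values per factor set
#'
#' Rows are factor exon sets, columns are features; each cell is the relative
#' (median- or mean-based) value of the feature in the set compared to the
#' control set, as computed by [rfreq()] / [rfreq_mean()].
#'
#' @param feature_values data.frame with an `exon_id` column and one numeric
#'   column per feature.
#' @param sets Named list of exon-id vectors (one per factor).
#' @param control_ids Exon ids of the control set.
#' @param stat `"median"` (default) or `"mean"`.
#' @return Numeric matrix, factors x features.
#' @export
heatmap_matrix <- function(feature_values, sets, control_ids,
                           stat = c("median", "mean")) {
  stat <- match.arg(stat)
  fun <- if (stat == "median") rfreq else rfreq_mean
  feats <- setdiff(names(feature_values), "exon_id")
  if (any(lengths(sets) == 0)) stop("empty factor exon set")
  ctrl <- feature_values[feature_values$exon_id %in% control_ids, , drop = FALSE]
  if (nrow(ctrl) == 0) stop("control set matches no feature rows")
  m <- matrix(NA_real_, nrow = length(sets), ncol = length(feats),
              dimnames = list(names(sets), feats))
  for (s in seq_along(sets)) {
    rows <- feature_values[feature_values$exon_id %in% sets[[s]], , drop = FALSE]
    if (nrow(rows) == 0) stop("set '", names(sets)[s], "' matches no feature rows")
    for (f in feats) m[s, f] <- fun(rows[[f]], ctrl[[f]])
  }
  m
}
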