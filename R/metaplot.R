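#' Metaplot region specification
#'
#' Defines which gene parts a binned coverage metaprofile is built over and
#' its binning geometry: regions are concatenated per gene in genomic order
#' (reversed to transcript orientation for minus-strand genes), resampled to
#' `n_bins` bins, and averaged across genes. The promoter spans -1500/+500
#' around the TSS. For the `internal_exons` and `introns` kinds the first 199
#' bins are dropped before cross-gene averaging, to avoid displaying signal
#' dominated by the promoter-proximal end.
#'
#' @param kind One of `promoter`, `first_exon`, `internal_exons`, `introns`,
#'   `whole_gene`.
#' @param n_bins Number of bins (default 1000).
#' @param drop_first Bins removed from the start (default 199 for
#'   `internal_exons` and `introns`, else 0).
#' @param promoter_up,promoter_down Promoter geometry in nt.
#' @return List of class `metaplot_spec`.
#' @export
metaplot_spec <- function(kind = c("promoter", "first_exon", "internal_exons",
                                   "introns", "whole_gene"),
                          n_bins = 1000,
                          drop_first = NULL,
                          promoter_up = 1500, promoter_down = 500) {
  kind <- match.arg(kind)
  if (is.null(drop_first)) {
    drop_first <- if (kind %in% c("internal_exons", "introns")) 199 else 0
  }
  if (!(n_bins > drop_first && drop_first >= 0)) {
    stop("need n_bins > drop_first >= 0")
  }
  structure(list(kind = kind, n_bins = n_bins, drop_first = drop_first,
                 promoter_up = promoter_up, promoter_down = promoter_down),
            class = "metaplot_spec")
}

#' Per-gene region lists for a metaplot kind
#'
#' @param exons Exon table.
#' @param genes Gene table (gene_id, chrom, start, end, strand).
#' @param spec A [metaplot_spec()].
#' @return Named list (per gene) of data.frames (chrom, start, end, strand)
#'   sorted in genomic order.
#' @export
gene_region_list <- function(exons, genes, spec) {
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene_id
  ex_split <- split(as.data.frame(exons), exons$gene_id)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- ex_split[[g$gene_id]]
    regions <- switch(spec$kind,
      promoter = {
        tss <- if (g$strand == "+") g$start else g$end
        if (g$strand == "+") {
          data.frame(chrom = g$chrom, start = tss - spec$promoter_up,
                     end = tss + spec$promoter_down, strand = g$strand)
        } else {
          data.frame(chrom = g$chrom, start = tss - spec$promoter_down,
                     end = tss + spec$promoter_up, strand = g$strand)
        }
      },
      first_exon = {
        fe <- ex[ex$index == 1, , drop = FALSE]
        data.frame(chrom = fe$chrom, start = fe$start, end = fe$end,
                   strand = fe$strand)
      },
      internal_exons = {
        int <- ex[ex$index > 1 & ex$index < max(ex$index), , drop = FALSE]
        data.frame(chrom = int$chrom, start = int$start, end = int$end,
                   strand = int$strand)
      },
      introns = {
        up <- ex[!is.na(ex$up_start), c("chrom", "up_start", "up_end", "strand")]
        names(up) <- c("chrom", "start", "end", "strand")
        unique(up)
      },
      whole_gene = data.frame(chrom = g$chrom, start = g$start, end = g$end,
                              strand = g$strand)
    )
    regions$start <- pmax(regions$start, 0)
    regions <- regions[regions$end > regions$start, , drop = FALSE]
    out[[i]] <- regions[order(regions$start), , drop = FALSE]
  }
  out
}

#' Binned coverage metaprofile across genes
#'
#' Per gene, region coverages are concatenated in genomic order, flipped to
#' transcript orientation for minus-strand genes, resampled into `n_bins`
#' bins (bin b averages positions `[floor((b-1)L/n), floor(bL/n))` of the
#' length-L concatenation; bins left empty by genes shorter than `n_bins`
#' are filled by linear interpolation between neighboring bins), the first
#' `drop_first` bins are removed, and the remaining bins are averaged across
#' genes with equal weight per gene.
#'
#' @param region_list Output of [gene_region_list()].
#' @param coverage A [coverage_track()].
#' @param spec A [metaplot_spec()].
#' @return data.frame (bin, value) of class `meta_profile`, attribute `n`
#'   = number of genes averaged.
#' @export
binned_profile <- function(region_list, coverage, spec) {
  nb <- spec$n_bins
  profiles <- list()
  for (gene in names(region_list)) {
    regions <- region_list[[gene]]
    if (is.null(regions) || nrow(regions) == 0) {
      warning("gene ", gene, " has no regions; skipped")
      next
    }
    segs <- lapply(seq_len(nrow(regions)), function(r) {
      coverage_window(coverage, regions$chrom[r], regions$start[r],
                      regions$end[r], strand = "+")
    })
    v <- unlist(segs, use.names = FALSE)
    if (regions$strand[1] == "-") v <- rev(v)
    L <- length(v)
    if (L == 0) {
      warning("gene ", gene, " has zero-length concatenation; skipped")
      next
    }
    lo <- floor((seq_len(nb) - 1) * L / nb)
    hi <- floor(seq_len(nb) * L / nb)
    bins <- rep(NA_real_, nb)
    nz <- hi > lo
    cs <- c(0, cumsum(v))
    bins[nz] <- (cs[hi[nz] + 1] - cs[lo[nz] + 1]) / (hi[nz] - lo[nz])
    if (anyNA(bins)) {
      known <- which(!is.na(bins))
      bins <- stats::approx(known, bins[known], xout = seq_len(nb),
                            rule = 2)$y
    }
    profiles[[gene]] <- bins[(spec$drop_first + 1):nb]
  }
  if (length(profiles) == 0) stop("no usable genes for metaprofile")
  m <- do.call(rbind, profiles)
  out <- data.frame(bin = (spec$drop_first + 1):nb, value = colMeans(m))
  structure(out, n = nrow(m), spec = spec,
            class = c("meta_profile", "data.frame"))
}

#' Exon-centered windows
#'
#' @param exons Exon table.
#' @param flank Half-width in nt (default 100: a 200-nt window around the
#'   exon center).
#' @return data.frame (exon_id, chrom, start, end, strand).
#' @export
exon_center_windows <- function(exons, flank = 100) {
  center <- floor((exons$start + exons$end) / 2)
  data.frame(exon_id = exons$exon_id, chrom = exons$chrom,
             start = pmax(center - flank, 0), end = center + flank,
             strand = exons$strand, stringsAsFactors = FALSE)
}

#' Mean coverage per window and group average
#'
#' @param windows data.frame with chrom, start, end (and optionally exon_id).
#' @param coverage A [coverage_track()].
#' @return List: `per_window` (data.frame with a `mean_coverage` column) and
#'   `group_mean` (the average of per-window means; NA with a warning for an
#'   empty group).
#' @export
mean_coverage <- function(windows, coverage) {
  if (nrow(windows) == 0) {
    warning("empty window group; group mean undefined")
    return(list(per_window = cbind(windows, mean_coverage = numeric(0)),
                group_mean = NA_real_))
  }
  mc <- vapply(seq_len(nrow(windows)), function(i) {
    mean(coverage_window(coverage, windows$chrom[i], windows$start[i],
                         windows$end[i]))
  }, numeric(1))
  list(per_window = cbind(windows, mean_coverage = mc),
       group_mean = mean(mc))
}

#' GC-minus-AT coverage ratio
#'
#' `(mean_gc - mean_at) / max(mean_gc, mean_at)`, the signed, max-normalized
#' difference of group mean coverages, in [-1, 1].
#'
#' @param mean_gc,mean_at Group mean coverages.
#' @return The ratio.
#' @export
gc_at_ratio <- function(mean_gc, mean_at) {
  m <- max(mean_gc, mean_at)
  if (m <= 0) stop("ratio undefined: max of the means must be positive")
  (mean_gc - mean_at) / m
}

#' CLIP peak positional-proportion map around splice sites
#'
#' For each position of the splice-site region (200 nt into the intron and
#' 50 nt into the exon, 251 positions), the fraction of exons having at
#' least one peak overlapping that genomic position. Offset 0 is the first
#' base after the junction in transcript direction (the first exonic base at
#' the 3' ss, the first intronic base at the 5' ss); negative offsets are
#' before the junction. Window positions beyond chromosome ends count as
#' no-signal while the exon stays in the denominator.
#'
#' @param exons Exon table (exons lacking the flanking intron on the
#'   anchored side are kept; their intronic positions read no-signal).
#' @param peaks Peak data.frame (chrom, start, end).
#' @param chrom_lengths Named chromosome lengths.
#' @param anchor `"3ss"` or `"5ss"`.
#' @param intron_flank,exon_flank Region geometry (defaults 200 and 50).
#' @return data.frame (offset, proportion) with attributes `anchor`, `n`.
#' @export
clip_positional_proportion <- function(exons, peaks, chrom_lengths,
                                       anchor = c("3ss", "5ss"),
                                       intron_flank = 200, exon_flank = 50) {
  anchor <- match.arg(anchor)
  if (nrow(exons) == 0) stop("empty exon set")
  track <- peaks_track(peaks, chrom_lengths)
  offsets <- if (anchor == "3ss") {
    (-intron_flank):exon_flank
  } else {
    (-exon_flank):intron_flank
  }
  hit <- numeric(length(offsets))
  for (i in seq_len(nrow(exons))) {
    v <- track$values[[exons$chrom[i]]]
    if (exons$strand[i] == "+") {
      a <- if (anchor == "3ss") exons$start[i] else exons$end[i]
      pos <- a + offsets
    } else {
      a <- if (anchor == "3ss") exons$end[i] - 1 else exons$start[i] - 1
      pos <- a - offsets
    }
    ok <- !is.null(v) & pos >= 0 & pos < length(v)
    here <- numeric(length(offsets))
    here[ok] <- v[pos[ok] + 1] > 0
    hit <- hit + here
  }
  structure(data.frame(offset = offsets, proportion = hit / nrow(exons)),
            anchor = anchor, n = nrow(exons),
            class = c("clip_profile", "data.frame"))
}
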