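#' Assign exons to genomic domains of one kind
#'
#' Each exon is assigned to the domain (isochore, TAD or LAD) with the
#' largest overlap; ties break toward the domain with the smaller start, and
#' exons overlapping no domain stay unassigned. Domains of one kind must not
#' overlap.
#'
#' @param exons Exon table.
#' @param domains Domain table; if it carries several kinds, pass `kind`.
#' @param kind Optional kind filter (`"isochore"`, `"TAD"`, `"LAD"`).
#' @return data.frame (exon_id, domain_id) with NA for unassigned exons.
#' @export
assign_domains <- function(exons, domains, kind = NULL) {
  if (!is.null(kind)) domains <- domains[domains$kind == kind, , drop = FALSE]
  if (length(unique(domains$kind)) > 1) {
    stop("domains of several kinds supplied; pass `kind`")
  }
  for (ch in unique(domains$chrom)) {
    d <- domains[domains$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("overlapping domains of one kind on ", ch)
    }
  }
  assigned <- rep(NA_character_, nrow(exons))
  for (ch in unique(exons$chrom)) {
    ei <- which(exons$chrom == ch)
    d <- domains[domains$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) next
    d <- d[order(d$start), , drop = FALSE]
    for (i in ei) {
      ov <- pmax(0, pmin(exons$end[i], d$end) - pmax(exons$start[i], d$start))
      if (max(ov) > 0) {
        # which.max returns the first maximum; rows are start-sorted, so ties
        # already break toward the smaller domain start
        assigned[i] <- d$domain_id[which.max(ov)]
      }
    }
  }
  data.frame(exon_id = exons$exon_id, domain_id = assigned,
             stringsAsFactors = FALSE)
}

#' Per-domain GC/AT exon counts
#'
#' Counts, for every domain, the GC- and AT-labeled exons assigned to it and
#' flags domains reaching at least `min_count` exons of either class (the
#' display filter used for per-domain clustering figures).
#'
#' @param labels data.frame (exon_id, label).
#' @param assignment Output of [assign_domains()].
#' @param domains Domain table of the matching kind.
#' @param min_count Filter threshold (default 5).
#' @return data.frame: domain_id, kind, gc_percent, n_gc_exons, n_at_exons,
#'   passes_min_filter.
#' @export
domain_exon_counts <- function(labels, assignment, domains, min_count = 5) {
  lab <- labels$label[match(assignment$exon_id, labels$exon_id)]
  n_gc <- tapply(lab == "GC", assignment$domain_id, sum, default = 0)
  n_at <- tapply(lab == "AT", assignment$domain_id, sum, default = 0)
  out <- data.frame(
    domain_id = domains$domain_id, kind = domains$kind,
    gc_percent = domains$gc_percent,
    n_gc_exons = as.integer(ifelse(is.na(n_gc[domains$domain_id]), 0,
                                   n_gc[domains$domain_id])),
    n_at_exons = as.integer(ifelse(is.na(n_at[domains$domain_id]), 0,
                                   n_at[domains$domain_id])),
    stringsAsFactors = FALSE
  )
  out$passes_min_filter <- out$n_gc_exons >= min_count |
    out$n_at_exons >= min_count
  out
}

#' Proportion of each exon class inside domains of one kind
#'
#' For each class, `100 * (# class exons assigned to any domain of the kind)
#' / (# class exons)`.
#'
#' @param labels data.frame (exon_id, label).
#' @param assignment Output of [assign_domains()] for that kind.
#' @param classes Class labels to report (default GC and AT).
#' @return Named numeric vector of percentages.
#' @export
class_proportion_in_kind <- function(labels, assignment,
                                     classes = c("GC", "AT")) {
  inside <- !is.na(assignment$domain_id[match(labels$exon_id,
                                              assignment$exon_id)])
  vapply(classes, function(cl) {
    sel <- labels$label == cl
    if (sum(sel) == 0) stop("no exons of class ", cl)
    100 * sum(inside & sel) / sum(sel)
  }, numeric(1))
}

#' Pearson correlation between exon GC and hosting-domain GC
#'
#' @param exon_gc,domain_gc Paired percentages (pairs with NA dropped).
#' @return Pearson correlation coefficient.
#' @export
exon_domain_gc_correlation <- function(exon_gc, domain_gc) {
  ok <- !is.na(exon_gc) & !is.na(domain_gc)
  x <- exon_gc[ok]; y <- domain_gc[ok]
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  stats::cor(x, y)
}

#' Fill in domain GC content from the genome
#'
#' Domains supplied without a `gc_percent` get it computed from the genome
#' sequence (N-free denominator).
#'
#' @param domains Domain table.
#' @param genome Genome.
#' @return Domain table with `gc_percent` completed.
#' @export
domain_gc <- function(domains, genome) {
  if (is.null(domains$gc_percent)) domains$gc_percent <- NA_real_
  todo <- is.na(domains$gc_percent)
  if (any(todo)) {
    seqs <- extract_sequence(genome, domains$chrom[todo], domains$start[todo],
                             domains$end[todo])
    domains$gc_percent[todo] <- base_set_percent(seqs, "GC")
  }
  domains
}
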