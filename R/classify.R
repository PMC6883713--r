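#' Classification thresholds for factor and exon classes
#'
#' The two-threshold rule that splits splicing factors into a GC class and an
#' AT class: a factor is GC-class when the median composition of its
#' activated exons exceeds `gc_threshold` AND the median size of their
#' smallest flanking intron is below `intron_threshold`; AT-class when both
#' comparisons flip. The defaults (49.3 % GC, 691 bp) are the genome-wide
#' control medians the rule was calibrated on; set `gc_threshold = NULL` to
#' recompute the composition threshold from a supplied control set. For the
#' purine/pyrimidine generalizations (`base_set = "GA"` or `"CT"`) the intron
#' criterion is off by default and classification uses composition alone.
#'
#' @param gc_threshold Composition threshold in percent (default 49.3), or
#'   NULL to derive it from the control set at classification time.
#' @param intron_threshold Smallest-flanking-intron threshold in bp
#'   (default 691).
#' @param base_set Base pair defining the composition axis (`"GC"`, `"GA"`,
#'   `"CT"`).
#' @param use_intron Apply the intron-size criterion (default TRUE for GC,
#'   FALSE otherwise).
#' @return List of class `class_thresholds`.
#' @export
class_thresholds <- function(gc_threshold = 49.3, intron_threshold = 691,
                             base_set = "GC",
                             use_intron = identical(base_set, "GC")) {
  if (!is.null(gc_threshold) && gc_threshold <= 0) stop("thresholds must be positive")
  if (intron_threshold <= 0) stop("thresholds must be positive")
  structure(list(gc_threshold = gc_threshold,
                 intron_threshold = intron_threshold,
                 base_set = base_set, use_intron = use_intron),
            class = "class_thresholds")
}

high_low_labels <- function(base_set) {
  switch(base_set,
         GC = c("GC", "AT"), GA = c("GA", "CT"), CT = c("CT", "GA"),
         stop("unsupported base_set: ", base_set))
}

#' Build per-factor activated exon sets from a regulation table
#'
#' An exon belongs to a factor's activated set iff it is activated by that
#' factor in at least one sample and never repressed by the same factor in
#' any sample: exons regulated in opposite directions by one factor across
#' samples are eliminated. Conflicting duplicate records for one
#' (factor, sample, exon) triple are an input error.
#'
#' @param regulation data.frame with columns factor, sample_id, exon_id,
#'   direction (`"activated"`/`"repressed"`).
#' @param factors Optional character vector restricting which factors to
#'   build sets for (e.g. the auxiliary splicing factors, keeping
#'   spliceosome-component knockdowns out of the class definition).
#' @return Named list of exon-id character vectors.
#' @export
build_activated_sets <- function(regulation, factors = NULL) {
  if (nrow(regulation) == 0) return(stats::setNames(list(), character(0)))
  if (any(!regulation$direction %in% c("activated", "repressed"))) {
    stop("direction must be 'activated' or 'repressed'")
  }
  key <- paste(regulation$factor, regulation$sample_id, regulation$exon_id, sep = "\r")
  ndir <- tapply(regulation$direction, key, function(d) length(unique(d)))
  if (any(ndir > 1)) {
    stop("conflicting duplicate records for the same (factor, sample, exon)")
  }
  if (!is.null(factors)) {
    regulation <- regulation[regulation$factor %in% factors, , drop = FALSE]
  }
  out <- lapply(split(regulation, regulation$factor), function(df) {
    act <- unique(df$exon_id[df$direction == "activated"])
    rep_ <- unique(df$exon_id[df$direction == "repressed"])
    setdiff(act, rep_)
  })
  out[order(names(out))]
}

#' Classify one factor from its set medians
#'
#' Strict inequalities on both axes; equality at a threshold, or discordant
#' axes (GC-rich exons flanked by large introns and vice versa), leave the
#' factor unclassified.
#'
#' @param median_comp Median composition (percent, on the thresholds'
#'   base set) of the factor's activated exons.
#' @param median_min_intron Median smallest-flanking-intron size (bp).
#' @param thresholds A [class_thresholds()].
#' @return `"GC"`, `"AT"` (or the base-set equivalents), or
#'   `"unclassified"`.
#' @export
classify_factor <- function(median_comp, median_min_intron,
                            thresholds = class_thresholds()) {
  if (is.na(median_comp)) stop("median composition undefined (empty set?)")
  lab <- high_low_labels(thresholds$base_set)
  comp_hi <- median_comp > thresholds$gc_threshold
  comp_lo <- median_comp < thresholds$gc_threshold
  if (!thresholds$use_intron) {
    return(if (comp_hi) lab[1] else if (comp_lo) lab[2] else "unclassified")
  }
  if (is.na(median_min_intron)) return("unclassified")
  if (comp_hi && median_min_intron < thresholds$intron_threshold) return(lab[1])
  if (comp_lo && median_min_intron > thresholds$intron_threshold) return(lab[2])
  "unclassified"
}

#' Per-factor summary and class table
#'
#' Computes each factor set's median exon composition and median smallest
#' flanking intron from the annotation and genome, then applies
#' [classify_factor()]. When `thresholds$gc_threshold` is NULL the
#' composition threshold is the control-set median (requires `control_ids`).
#'
#' @param sets Named list of exon-id vectors from [build_activated_sets()].
#' @param exons Exon table.
#' @param genome Genome.
#' @param thresholds A [class_thresholds()].
#' @param control_ids Control exon ids (only needed to derive a NULL
#'   composition threshold).
#' @return data.frame: factor, n_exons, median_comp, median_min_intron, class.
#' @export
factor_class_table <- function(sets, exons, genome,
                               thresholds = class_thresholds(),
                               control_ids = NULL) {
  if (length(sets) == 0) stop("no factor sets supplied")
  comp <- base_set_percent(
    extract_sequence(genome, exons$chrom, exons$start, exons$end, exons$strand),
    thresholds$base_set
  )
  names(comp) <- exons$exon_id
  min_intron <- stats::setNames(smallest_flanking_intron(exons), exons$exon_id)
  if (is.null(thresholds$gc_threshold)) {
    if (is.null(control_ids)) stop("control_ids needed to derive the threshold")
    thresholds$gc_threshold <- stats::median(comp[control_ids], na.rm = TRUE)
  }
  rows <- lapply(names(sets), function(f) {
    ids <- intersect(sets[[f]], exons$exon_id)
    if (length(ids) == 0) stop("factor '", f, "' has no annotated exons")
    mg <- stats::median(comp[ids], na.rm = TRUE)
    mi <- stats::median(min_intron[ids], na.rm = TRUE)
    data.frame(factor = f, n_exons = length(ids), median_comp = mg,
               median_min_intron = mi,
               class = classify_factor(mg, mi, thresholds),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Label exons from factor classes
#'
#' An exon is labeled with a class iff it is activated by at least one factor
#' of that class and by no factor of the opposite class; exons claimed by
#' both classes are excluded (`"excluded_overlap"`), and exons activated only
#' by unclassified factors get `"none"`.
#'
#' @param class_table Output of [factor_class_table()].
#' @param sets Named list of exon-id vectors (same factors).
#' @param all_exon_ids Optional universe of exon ids; ids not in any set are
#'   labeled `"none"`.
#' @return data.frame (exon_id, label) with labels in
#'   high/low/`excluded_overlap`/`none`.
#' @export
assemble_class_exons <- function(class_table, sets, all_exon_ids = NULL) {
  classes <- setdiff(unique(class_table$class), "unclassified")
  ids <- unique(c(unlist(sets, use.names = FALSE), all_exon_ids))
  label <- rep("none", length(ids))
  hits <- matrix(FALSE, nrow = length(ids), ncol = length(classes))
  for (k in seq_along(classes)) {
    members <- unlist(sets[class_table$factor[class_table$class == classes[k]]],
                      use.names = FALSE)
    hits[, k] <- ids %in% members
  }
  n_claims <- rowSums(hits)
  for (k in seq_along(classes)) {
    label[hits[, k] & n_claims == 1] <- classes[k]
  }
  label[n_claims > 1] <- "excluded_overlap"
  data.frame(exon_id = ids, label = label, stringsAsFactors = FALSE)
}

#' Control exon set
#'
#' Constitutive coding internal exons (both flanking introns present) minus
#' every exon activated by any analyzed factor.
#'
#' @param exons Exon table (with its `constitutive` flag).
#' @param sets Named list of activated exon-id vectors.
#' @return Character vector of control exon ids (warns when empty).
#' @export
build_control_set <- function(exons, sets) {
  internal <- !is.na(exons$up_start) & !is.na(exons$down_start)
  pool <- exons$exon_id[exons$constitutive & internal]
  activated <- unique(unlist(sets, use.names = FALSE))
  ctrl <- setdiff(pool, activated)
  if (length(ctrl) == 0) warning("control set is empty")
  ctrl
}

#' U1- and U2-dependent exon sets
#'
#' Unions of the activated sets of the U1 snRNP-associated factors (SNRPC,
#' SNRNP70, DDX5/17 by default) and of the U2 snRNP-associated factors
#' (SF1, U2AF2, SF3A3, SF3B4). An exon activated by members of both groups
#' belongs to both sets.
#'
#' @param sets Named list of activated exon-id vectors.
#' @param u1_factors,u2_factors Factor names defining each group; every name
#'   must be present in `sets`.
#' @return List with elements `u1` and `u2` (character vectors).
#' @export
build_u1_u2_sets <- function(sets,
                             u1_factors = c("SNRPC", "SNRNP70", "DDX5_17"),
                             u2_factors = c("U2AF2", "SF3B4", "SF1", "SF3A3")) {
  missing <- setdiff(c(u1_factors, u2_factors), names(sets))
  if (length(missing) > 0) {
    stop("unknown factor name(s) in group table: ", paste(missing, collapse = ", "))
  }
  list(u1 = unique(unlist(sets[u1_factors], use.names = FALSE)),
       u2 = unique(unlist(sets[u2_factors], use.names = FALSE)))
}
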