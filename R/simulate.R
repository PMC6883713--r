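#' Configuration for the synthetic-genome generator
#'
#' The generator emulates the compositional architecture the pipeline is
#' designed to detect: a chromosome tiled by isochores at fixed GC levels;
#' genes inheriting their isochore's GC with small jitter and exons sitting
#' a few points above their gene; small introns in GC-rich context and large
#' introns in AT-rich context; splicing-factor regulation tables whose GC
#' factors activate exons of GC-context genes and AT factors exons of
#' AT-context genes; planted decoy splice signals (extra branch-point
#' consensus sites, TNA motifs, T-rich runs) upstream of AT-class exons;
#' complementary G/C-rich flanks able to base-pair across the 5' ss of
#' GC-class exons; CLIP-like peaks enriched upstream of AT-class exons; and
#' nucleosome-like coverage enrichment on GC-class exons. Intergenic and
#' intronic background follows the isochore GC level; introns carry GT/AG
#' ends, one canonical branch point and a pyrimidine tract whose T content
#' tracks the AT level of the host gene.
#'
#' @param seed Integer seed; every random draw flows from it.
#' @param n_isochores Number of planted isochores.
#' @param isochore_gc_levels GC levels (percent) recycled across isochores.
#' @param isochore_context Optional `"GC"`/`"AT"` context per isochore
#'   (recycled); default derives it from the level (`>= gc_context_min`).
#' @param gc_context_min Level at or above which an isochore counts as
#'   GC context.
#' @param genes_per_isochore Genes hosted by each isochore.
#' @param exons_per_gene Range (min, max) of exons per gene.
#' @param exon_length_meanlog,exon_length_sdlog Lognormal exon lengths
#'   (median about 120 nt).
#' @param intron_length_meanlog Named vector of lognormal meanlogs per
#'   context (`GC` median below, `AT` above, `CTRL` near the 691-bp
#'   genome-wide median).
#' @param intron_length_sdlog Lognormal sdlog for intron lengths.
#' @param exon_gc_offset Percentage points added to the gene GC for exons.
#' @param gene_gc_jitter_sd SD of the gene-level GC jitter.
#' @param gc_factor_names,at_factor_names Auxiliary splicing factors
#'   activating GC-/AT-context exons.
#' @param u1_factor_names,u2_factor_names Spliceosome-associated factor
#'   groups.
#' @param exons_activated_per_factor Exons drawn (per auxiliary factor) from
#'   its context pool.
#' @param samples_per_factor Samples over which activation records spread.
#' @param repressed_per_factor Control-gene exons each auxiliary factor
#'   represses (exercises the opposite-regulation elimination path).
#' @param u1_rate_gc,u1_rate_at,u2_rate_gc,u2_rate_at Per-exon probability
#'   that a planted GC/AT exon is activated by at least one factor of the
#'   U1/U2 group (defaults 28/14 and 17/27 percent).
#' @param decoy_enrichment Multiplier for planted decoys upstream of
#'   AT-class exons (0 disables planting).
#' @param hairpin_rate Probability that a GC-class exon gets complementary
#'   5'-ss flanks (0 disables).
#' @param clip_rate_at,clip_rate_gc Per-exon CLIP-peak probabilities.
#' @param clip_peak_width Peak width in nt.
#' @param coverage_exon_boost_gc Multiplicative coverage boost on GC-class
#'   exons.
#' @param base_depth,coverage_block Background coverage depth and the block
#'   size of its piecewise-constant noise.
#' @param n_control_isochores,control_gc Isochores of unregulated,
#'   constitutive genes providing the control exon pool.
#' @param intergenic_length Spacer length between genes and at isochore
#'   boundaries.
#' @param chrom_name Chromosome name.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_isochores = 10,
                              isochore_gc_levels = c(35, 42, 48, 55),
                              isochore_context = NULL,
                              gc_context_min = 46,
                              genes_per_isochore = 5,
                              exons_per_gene = c(12, 16),
                              exon_length_meanlog = log(120),
                              exon_length_sdlog = 0.25,
                              intron_length_meanlog = c(GC = log(300),
                                                        AT = log(1500),
                                                        CTRL = log(700)),
                              intron_length_sdlog = 0.35,
                              exon_gc_offset = 5,
                              gene_gc_jitter_sd = 1.5,
                              gc_factor_names = c("SRSF9", "PCBP1", "RBFOX2"),
                              at_factor_names = c("TRA2A", "PTBP1", "MBNL1"),
                              u1_factor_names = c("SNRPC", "SNRNP70", "DDX5_17"),
                              u2_factor_names = c("SF1", "U2AF2", "SF3A3", "SF3B4"),
                              exons_activated_per_factor = 150,
                              samples_per_factor = 2,
                              repressed_per_factor = 5,
                              u1_rate_gc = 0.28, u1_rate_at = 0.14,
                              u2_rate_gc = 0.17, u2_rate_at = 0.27,
                              decoy_enrichment = 1,
                              hairpin_rate = 1,
                              clip_rate_at = 0.6, clip_rate_gc = 0.1,
                              clip_peak_width = 50,
                              coverage_exon_boost_gc = 3,
                              base_depth = 20, coverage_block = 100,
                              n_control_isochores = 2, control_gc = 46,
                              intergenic_length = 2000,
                              chrom_name = "chrS") {
  cfg <- as.list(environment())
  probs <- unlist(cfg[c("u1_rate_gc", "u1_rate_at", "u2_rate_gc", "u2_rate_at",
                        "clip_rate_at", "clip_rate_gc", "hairpin_rate")])
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (any(cfg$isochore_gc_levels <= 0 | cfg$isochore_gc_levels >= 100)) {
    stop("GC levels must be in (0, 100)")
  }
  if (cfg$decoy_enrichment < 0) stop("decoy_enrichment must be >= 0")
  if (cfg$exons_per_gene[1] < 3) stop("genes need at least 3 exons")
  structure(cfg, class = "simulation_config")
}

rand_bases <- function(n, gc) {
  p <- c(gc / 2, gc / 2, (100 - gc) / 2, (100 - gc) / 2) / 100
  sample(c("G", "C", "A", "T"), n, replace = TRUE, prob = p)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# decorate one intron (transcript-orientation character vector): splice
# dinucleotides, canonical branch point, pyrimidine tract; then decoys when
# the downstream exon is a planted AT-class exon.
decorate_intron <- function(s, gene_gc, plant_decoys, decoy_enrichment) {
  L <- length(s)
  s[1:2] <- c("G", "T")
  s[(L - 1):L] <- c("A", "G")
  t_prob <- clamp(1.3 - 1.6 * gene_gc / 100, 0.15, 0.9)
  py <- (L - 19):(L - 8)                      # offsets -20..-9
  s[py] <- ifelse(stats::runif(length(py)) < t_prob, "T", "C")
  s[(L - 25):(L - 21)] <- c("C", "T", "G", "A", "C")  # canonical BP, A at -23
  if (plant_decoys && decoy_enrichment > 0 && L >= 120) {
    d <- decoy_enrichment
    bp_at <- sample(c(-96, -90, -84, -78), min(max(1, round(2 * d)), 4))
    for (o in bp_at) {
      idx <- L + 1 + o
      s[(idx - 3):(idx + 1)] <- c("C", "T", "A", "A", "C")
    }
    tr_at <- sample(seq(-72, -48, by = 6), min(round(3 * d), 5))
    for (o in tr_at) s[(L + 1 + o):(L + 4 + o)] <- "T"
    tna_at <- sample(seq(-42, -30, by = 3), min(round(4 * d), 5))
    for (o in tna_at) s[(L + 1 + o):(L + 3 + o)] <- c("T", "G", "A")
  }
  s
}

#' Generate a synthetic bundle
#'
#' Deterministic given `config$seed`. See [simulation_config()] for the
#' planted structure. Returns genome, annotation, regulation, peaks,
#' coverage, domains (isochores, TADs as split isochores, LADs as the
#' lowest-GC isochores) and per-exon ground-truth class labels.
#'
#' @param config A [simulation_config()].
#' @return List of class `synthetic_bundle` with elements genome, genes,
#'   exons, regulation, peaks, coverage, domains, truth, factor_groups,
#'   config.
#' @export
simulate_bundle <- function(config = simulation_config()) {
  set.seed(config$seed)
  ch <- config$chrom_name

  levels <- c(rep_len(config$isochore_gc_levels, config$n_isochores),
              rep(config$control_gc, config$n_control_isochores))
  context <- if (is.null(config$isochore_context)) {
    ifelse(levels >= config$gc_context_min, "GC", "AT")
  } else {
    rep_len(config$isochore_context, config$n_isochores)
  }
  context <- c(context[seq_len(config$n_isochores)],
               rep("CTRL", config$n_control_isochores))

  # ---- gene skeletons -------------------------------------------------
  skel <- list()
  gid <- 0
  for (iso in seq_along(levels)) {
    for (g in seq_len(config$genes_per_isochore)) {
      gid <- gid + 1
      n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1)
      ex_len <- pmax(70, round(stats::rlnorm(n_ex, config$exon_length_meanlog,
                                             config$exon_length_sdlog)))
      ctx <- context[iso]
      ml <- config$intron_length_meanlog[[ctx]]
      in_len <- pmax(120, round(stats::rlnorm(n_ex - 1, ml,
                                              config$intron_length_sdlog)))
      if (any(in_len < 1)) stop("impossible geometry: intron shorter than 1 nt")
      gene_gc <- clamp(levels[iso] + stats::rnorm(1, 0, config$gene_gc_jitter_sd),
                       5, 95)
      skel[[gid]] <- list(
        gene_id = sprintf("g%03d", gid), iso = iso, context = ctx,
        strand = sample(c("+", "-"), 1), n_ex = n_ex, ex_len = ex_len,
        in_len = in_len, gene_gc = gene_gc,
        exon_gc = clamp(gene_gc + config$exon_gc_offset, 5, 95),
        exon_id = sprintf("g%03d_e%02d", gid, seq_len(n_ex))
      )
    }
  }

  # ---- regulation plan ------------------------------------------------
  internal_ids <- function(s) s$exon_id[2:(s$n_ex - 1)]
  pool <- list(
    GC = unlist(lapply(Filter(function(s) s$context == "GC", skel), internal_ids)),
    AT = unlist(lapply(Filter(function(s) s$context == "AT", skel), internal_ids)),
    CTRL = unlist(lapply(Filter(function(s) s$context == "CTRL", skel), internal_ids))
  )
  pool <- lapply(pool, function(p) if (is.null(p)) character(0) else p)
  aux_sets <- list()
  for (f in config$gc_factor_names) {
    aux_sets[[f]] <- sample(pool$GC, min(config$exons_activated_per_factor,
                                         length(pool$GC)))
  }
  for (f in config$at_factor_names) {
    aux_sets[[f]] <- sample(pool$AT, min(config$exons_activated_per_factor,
                                         length(pool$AT)))
  }
  truth_gc <- unique(unlist(aux_sets[config$gc_factor_names]))
  truth_at <- unique(unlist(aux_sets[config$at_factor_names]))

  snp_sets <- list()
  draw_group <- function(ids, rate, factors) {
    if (length(ids) == 0) return(list())
    hit <- ids[stats::runif(length(ids)) < rate]
    if (length(hit) == 0) return(list())
    split(hit, sample(factors, length(hit), replace = TRUE))
  }
  add_sets <- function(sets, extra) {
    for (f in names(extra)) sets[[f]] <- c(sets[[f]], extra[[f]])
    sets
  }
  snp_sets <- add_sets(snp_sets, draw_group(truth_gc, config$u1_rate_gc,
                                            config$u1_factor_names))
  snp_sets <- add_sets(snp_sets, draw_group(truth_at, config$u1_rate_at,
                                            config$u1_factor_names))
  snp_sets <- add_sets(snp_sets, draw_group(truth_gc, config$u2_rate_gc,
                                            config$u2_factor_names))
  snp_sets <- add_sets(snp_sets, draw_group(truth_at, config$u2_rate_at,
                                            config$u2_factor_names))
  # every spliceosome factor appears in the table, even if a rate rounded
  # its draw down to nothing
  for (f in c(config$u1_factor_names, config$u2_factor_names)) {
    if (is.null(snp_sets[[f]])) snp_sets[[f]] <- character(0)
  }

  rec <- function(factor, exon_id, direction) {
    if (length(exon_id) == 0) return(NULL)
    data.frame(factor = factor,
               sample_id = paste0(factor, "_s",
                                  sample.int(config$samples_per_factor,
                                             length(exon_id), replace = TRUE)),
               exon_id = exon_id, direction = direction,
               stringsAsFactors = FALSE)
  }
  reg <- list()
  for (f in names(aux_sets)) {
    reg[[length(reg) + 1]] <- rec(f, aux_sets[[f]], "activated")
    reg[[length(reg) + 1]] <- rec(
      f, sample(pool$CTRL, min(config$repressed_per_factor, length(pool$CTRL))),
      "repressed"
    )
  }
  for (f in names(snp_sets)) {
    reg[[length(reg) + 1]] <- rec(f, snp_sets[[f]], "activated")
  }
  regulation <- do.call(rbind, reg)

  # ---- sequences and assembly ----------------------------------------
  truth_class <- function(id) {
    if (id %in% truth_gc) "GC" else if (id %in% truth_at) "AT" else "none"
  }
  chrom_parts <- list()
  pos <- 0
  exon_rows <- list()
  gene_rows <- list()
  iso_bounds <- matrix(0, nrow = length(levels), ncol = 2)
  spacer <- function(gc) paste(rand_bases(config$intergenic_length, gc),
                               collapse = "")
  for (iso in seq_along(levels)) {
    iso_bounds[iso, 1] <- pos
    for (s in Filter(function(x) x$iso == iso, skel)) {
      sp <- spacer(levels[iso])
      chrom_parts[[length(chrom_parts) + 1]] <- sp
      pos <- pos + nchar(sp)

      n_ex <- s$n_ex
      cls <- vapply(s$exon_id, truth_class, character(1))
      ex_seqs <- lapply(s$ex_len, rand_bases, gc = s$exon_gc)
      in_seqs <- lapply(seq_len(n_ex - 1), function(k) {
        decorate_intron(rand_bases(s$in_len[k], s$gene_gc), s$gene_gc,
                        plant_decoys = cls[k + 1] == "AT",
                        config$decoy_enrichment)
      })
      # complementary flanks across the 5' ss of planted GC exons
      for (k in seq_len(n_ex - 1)) {
        if (cls[k] == "GC" && stats::runif(1) < config$hairpin_rate) {
          Lx <- s$ex_len[k]
          ex_seqs[[k]][(Lx - 17):(Lx - 10)] <-
            c("G", "C", "C", "G", "C", "C", "G", "C")
          in_seqs[[k]][6:13] <- c("G", "C", "G", "G", "C", "G", "G", "C")
        }
      }
      parts <- vector("list", 2 * n_ex - 1)
      parts[seq(1, 2 * n_ex - 1, by = 2)] <- ex_seqs
      parts[seq(2, 2 * n_ex - 2, by = 2)] <- in_seqs
      tseq <- unlist(parts, use.names = FALSE)
      Lg <- length(tseq)
      gseq <- if (s$strand == "+") {
        paste(tseq, collapse = "")
      } else {
        revcomp(paste(tseq, collapse = ""))
      }
      gene_start <- pos
      chrom_parts[[length(chrom_parts) + 1]] <- gseq
      pos <- pos + Lg

      # transcript-coordinate part boundaries -> genomic intervals
      lens <- vapply(parts, length, integer(1))
      tstart <- cumsum(c(0, lens[-length(lens)]))
      tend <- tstart + lens
      to_genomic <- function(a, b) {
        if (s$strand == "+") c(gene_start + a, gene_start + b)
        else c(gene_start + Lg - b, gene_start + Lg - a)
      }
      ex_iv <- lapply(seq_len(n_ex), function(k) {
        to_genomic(tstart[2 * k - 1], tend[2 * k - 1])
      })
      in_iv <- lapply(seq_len(n_ex - 1), function(k) {
        to_genomic(tstart[2 * k], tend[2 * k])
      })
      na2 <- c(NA_real_, NA_real_)
      exon_rows[[length(exon_rows) + 1]] <- data.frame(
        exon_id = s$exon_id, gene_id = s$gene_id, index = seq_len(n_ex),
        chrom = ch,
        start = vapply(ex_iv, `[`, numeric(1), 1),
        end = vapply(ex_iv, `[`, numeric(1), 2),
        strand = s$strand,
        up_start = vapply(seq_len(n_ex), function(k) {
          if (k == 1) NA_real_ else in_iv[[k - 1]][1]
        }, numeric(1)),
        up_end = vapply(seq_len(n_ex), function(k) {
          if (k == 1) NA_real_ else in_iv[[k - 1]][2]
        }, numeric(1)),
        down_start = vapply(seq_len(n_ex), function(k) {
          if (k == n_ex) NA_real_ else in_iv[[k]][1]
        }, numeric(1)),
        down_end = vapply(seq_len(n_ex), function(k) {
          if (k == n_ex) NA_real_ else in_iv[[k]][2]
        }, numeric(1)),
        constitutive = s$context == "CTRL",
        stringsAsFactors = FALSE
      )
      gene_rows[[length(gene_rows) + 1]] <- data.frame(
        gene_id = s$gene_id, chrom = ch, start = gene_start,
        end = gene_start + Lg, strand = s$strand, n_exons = n_ex,
        context = s$context, stringsAsFactors = FALSE
      )
    }
    sp <- spacer(levels[iso])
    chrom_parts[[length(chrom_parts) + 1]] <- sp
    pos <- pos + nchar(sp)
    iso_bounds[iso, 2] <- pos
  }

  genome <- stats::setNames(paste(unlist(chrom_parts), collapse = ""), ch)
  exons <- do.call(rbind, exon_rows)
  class(exons) <- c("exon_table", "data.frame")
  genes <- do.call(rbind, gene_rows)
  genes$gc_percent <- base_set_percent(
    extract_sequence(genome, genes$chrom, genes$start, genes$end), "GC"
  )

  # ---- domains --------------------------------------------------------
  iso_dom <- data.frame(
    domain_id = sprintf("iso%02d", seq_along(levels)), kind = "isochore",
    chrom = ch, start = iso_bounds[, 1], end = iso_bounds[, 2],
    gc_percent = NA_real_, stringsAsFactors = FALSE
  )
  mid <- floor((iso_bounds[, 1] + iso_bounds[, 2]) / 2)
  tad_dom <- data.frame(
    domain_id = sprintf("tad%02d", seq_len(2 * length(levels))), kind = "TAD",
    chrom = ch,
    start = as.vector(rbind(iso_bounds[, 1], mid)),
    end = as.vector(rbind(mid, iso_bounds[, 2])),
    gc_percent = NA_real_, stringsAsFactors = FALSE
  )
  lad_idx <- which(levels == min(levels[seq_len(config$n_isochores)]))
  lad_dom <- if (length(lad_idx) > 0) {
    data.frame(
      domain_id = sprintf("lad%02d", seq_along(lad_idx)), kind = "LAD",
      chrom = ch, start = iso_bounds[lad_idx, 1], end = iso_bounds[lad_idx, 2],
      gc_percent = NA_real_, stringsAsFactors = FALSE
    )
  }
  domains <- domain_gc(rbind(iso_dom, tad_dom, lad_dom), genome)

  # ---- coverage -------------------------------------------------------
  L <- nchar(genome)
  nb <- ceiling(L / config$coverage_block)
  depth <- rep(config$base_depth * stats::runif(nb, 0.7, 1.3),
               each = config$coverage_block)[seq_len(L)]
  for (i in which(exons$exon_id %in% truth_gc)) {
    idx <- (exons$start[i] + 1):exons$end[i]
    depth[idx] <- depth[idx] * config$coverage_exon_boost_gc
  }
  coverage <- coverage_track(stats::setNames(list(round(depth, 3)), ch))

  # ---- CLIP-like peaks upstream of the 3' ss --------------------------
  peak_rows <- list()
  for (i in seq_len(nrow(exons))) {
    cls <- truth_class(exons$exon_id[i])
    rate <- if (cls == "AT") config$clip_rate_at else if (cls == "GC") {
      config$clip_rate_gc
    } else 0
    if (rate > 0 && stats::runif(1) < rate) {
      u <- sample(seq(-200, -60 - config$clip_peak_width), 1)
      ivl <- if (exons$strand[i] == "+") {
        c(exons$start[i] + u, exons$start[i] + u + config$clip_peak_width)
      } else {
        c(exons$end[i] - u - config$clip_peak_width, exons$end[i] - u)
      }
      peak_rows[[length(peak_rows) + 1]] <- data.frame(
        chrom = ch, start = ivl[1], end = ivl[2], name = "U2AF2_synthetic",
        strand = exons$strand[i], stringsAsFactors = FALSE
      )
    }
  }
  peaks <- if (length(peak_rows) > 0) do.call(rbind, peak_rows) else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               name = character(0), strand = character(0))
  }

  truth <- data.frame(
    exon_id = exons$exon_id,
    class = vapply(exons$exon_id, truth_class, character(1)),
    stringsAsFactors = FALSE
  )
  factor_groups <- data.frame(
    factor = c(config$gc_factor_names, config$at_factor_names,
               config$u1_factor_names, config$u2_factor_names),
    group = c(rep("aux_gc", length(config$gc_factor_names)),
              rep("aux_at", length(config$at_factor_names)),
              rep("u1", length(config$u1_factor_names)),
              rep("u2", length(config$u2_factor_names))),
    stringsAsFactors = FALSE
  )

  validate_exon_table(exons)
  structure(list(genome = genome, genes = genes, exons = exons,
                 regulation = regulation, peaks = peaks, coverage = coverage,
                 domains = domains, truth = truth,
                 factor_groups = factor_groups, config = config),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic_bundle:", sum(chrom_lengths(x$genome)), "bp genome,",
      nrow(x$genes), "genes,", nrow(x$exons), "exons,",
      nrow(x$regulation), "regulation records,", nrow(x$peaks), "peaks\n")
  cat("  truth:", sum(x$truth$class == "GC"), "GC /",
      sum(x$truth$class == "AT"), "AT planted exons\n")
  invisible(x)
}

#' Write / read a bundle as plain-text files
#'
#' FASTA for the genome, TSV for annotations and truth labels, BED for
#' peaks, bedGraph for coverage. `read_bundle()` restores everything except
#' the generating config.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if missing).
#' @return The directory (write) or a bundle-like list (read), invisibly for
#'   the writer.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_genome(bundle$genome, p("genome.fa"))
  write_exon_table(bundle$exons, p("exons.tsv"))
  write_gene_table(bundle$genes, p("genes.tsv"))
  write_regulation_table(bundle$regulation, p("regulation.tsv"))
  write_domain_table(bundle$domains, p("domains.tsv"))
  .write_tsv(bundle$truth, p("truth.tsv"))
  .write_tsv(bundle$factor_groups, p("factor_groups.tsv"))
  write_bed(bundle$peaks, p("peaks.bed"))
  write_bedgraph(bundle$coverage, p("coverage.bedGraph"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  genome <- read_genome(p("genome.fa"))
  structure(list(
    genome = genome,
    genes = read_gene_table(p("genes.tsv")),
    exons = read_exon_table(p("exons.tsv")),
    regulation = read_regulation_table(p("regulation.tsv")),
    peaks = read_bed(p("peaks.bed")),
    coverage = read_bedgraph(p("coverage.bedGraph"), chrom_lengths(genome)),
    domains = read_domain_table(p("domains.tsv")),
    truth = .read_tsv(p("truth.tsv"), colClasses = "character"),
    factor_groups = .read_tsv(p("factor_groups.tsv"), colClasses = "character"),
    config = NULL
  ), class = "synthetic_bundle")
}
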