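#' Pipeline configuration
#'
#' Collects every stage's inputs and tunables with full defaulting. The
#' pipeline either consumes a bundle directory written by [write_bundle()]
#' (`input_dir`) or generates one in memory from `simulate`.
#'
#' @param out_dir Output directory.
#' @param input_dir Optional bundle directory to analyze.
#' @param simulate A [simulation_config()] used when `input_dir` is NULL.
#' @param thresholds A [class_thresholds()].
#' @param windows A [feature_windows()].
#' @param n_iter Randomization iterations for the V values.
#' @param seed Integer seed recorded in the manifest and driving the V-value
#'   randomizations (and the simulation, via `simulate$seed`, when no input
#'   directory is given).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, input_dir = NULL,
                            simulate = simulation_config(),
                            thresholds = class_thresholds(),
                            windows = feature_windows(),
                            n_iter = 10000, seed = 1) {
  structure(list(out_dir = out_dir, input_dir = input_dir,
                 simulate = simulate, thresholds = thresholds,
                 windows = windows, n_iter = n_iter, seed = seed),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the whole pipeline
#'
#' Executes simulate (optional), classify, features, vvalue, metaplot and
#' domains in order, writing one TSV per result plus a run manifest naming
#' the seed and a hash of the configuration. Deterministic given fixed
#' inputs and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_all <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)

  bundle <- stage("simulate", {
    if (!is.null(config$input_dir)) {
      read_bundle(config$input_dir)
    } else {
      sim <- config$simulate
      sim$seed <- config$seed
      b <- simulate_bundle(sim)
      write_bundle(b, p("bundle"))
      b
    }
  })

  res <- stage("classify", {
    groups <- bundle$factor_groups
    aux <- groups$factor[groups$group %in% c("aux_gc", "aux_at")]
    sets <- build_activated_sets(bundle$regulation, factors = aux)
    all_sets <- build_activated_sets(bundle$regulation)
    ct <- factor_class_table(sets, bundle$exons, bundle$genome,
                             config$thresholds)
    labels <- assemble_class_exons(ct, sets)
    control <- build_control_set(bundle$exons, all_sets)
    u12 <- build_u1_u2_sets(all_sets,
                            u1_factors = groups$factor[groups$group == "u1"],
                            u2_factors = groups$factor[groups$group == "u2"])
    write_exon_table(bundle$exons, p("exons.tsv"))
    .write_tsv(ct, p("factor_classes.tsv"))
    .write_tsv(labels, p("exon_labels.tsv"))
    .write_tsv(data.frame(exon_id = control), p("control_exons.tsv"))
    list(sets = sets, all_sets = all_sets, class_table = ct, labels = labels,
         control = control, u1 = u12$u1, u2 = u12$u2)
  })

  features <- stage("features", {
    ft <- exon_feature_table(bundle$exons, bundle$genome, config$windows,
                             labels = res$labels)
    .write_tsv(ft, p("features.tsv"))
    ft
  })

  vv <- stage("vvalue", {
    gc_ids <- res$labels$exon_id[res$labels$label == "GC"]
    at_ids <- res$labels$exon_id[res$labels$label == "AT"]
    groups <- bundle$factor_groups
    snp <- groups$factor[groups$group %in% c("u1", "u2")]
    tab <- vvalue_table(res$all_sets, gc_ids, at_ids,
                        factors = intersect(snp, names(res$all_sets)),
                        n_iter = config$n_iter, seed = config$seed)
    .write_tsv(tab, p("vvalues.tsv"))
    tab
  })

  meta <- stage("metaplot", {
    if (is.null(bundle$coverage)) stop("no coverage track available")
    gc_ids <- res$labels$exon_id[res$labels$label == "GC"]
    at_ids <- res$labels$exon_id[res$labels$label == "AT"]
    w_gc <- exon_center_windows(bundle$exons[bundle$exons$exon_id %in% gc_ids, ])
    w_at <- exon_center_windows(bundle$exons[bundle$exons$exon_id %in% at_ids, ])
    mc_gc <- mean_coverage(w_gc, bundle$coverage)
    mc_at <- mean_coverage(w_at, bundle$coverage)
    ratio <- gc_at_ratio(mc_gc$group_mean, mc_at$group_mean)
    cl <- chrom_lengths(bundle$genome)
    clip_gc <- clip_positional_proportion(
      bundle$exons[bundle$exons$exon_id %in% gc_ids, ], bundle$peaks, cl,
      anchor = "3ss", intron_flank = config$windows$clip_intron,
      exon_flank = config$windows$clip_exon)
    clip_at <- clip_positional_proportion(
      bundle$exons[bundle$exons$exon_id %in% at_ids, ], bundle$peaks, cl,
      anchor = "3ss", intron_flank = config$windows$clip_intron,
      exon_flank = config$windows$clip_exon)
    spec <- metaplot_spec("internal_exons")
    prof <- binned_profile(gene_region_list(bundle$exons, bundle$genes, spec),
                           bundle$coverage, spec)
    .write_tsv(data.frame(group = c("GC", "AT"),
                          mean_coverage = c(mc_gc$group_mean,
                                            mc_at$group_mean),
                          gc_at_ratio = ratio),
               p("coverage_groups.tsv"))
    .write_tsv(cbind(set = "GC", as.data.frame(clip_gc)), p("clip_gc.tsv"))
    .write_tsv(cbind(set = "AT", as.data.frame(clip_at)), p("clip_at.tsv"))
    .write_tsv(as.data.frame(prof), p("metaprofile_internal_exons.tsv"))
    list(mean_gc = mc_gc$group_mean, mean_at = mc_at$group_mean,
         ratio = ratio, clip_gc = clip_gc, clip_at = clip_at, profile = prof)
  })

  dom <- stage("domains", {
    exon_gc <- base_set_percent(
      extract_sequence(bundle$genome, bundle$exons$chrom, bundle$exons$start,
                       bundle$exons$end, bundle$exons$strand), "GC")
    out <- list()
    for (kind in unique(bundle$domains$kind)) {
      asg <- assign_domains(bundle$exons, bundle$domains, kind = kind)
      cnt <- domain_exon_counts(res$labels, asg,
                                bundle$domains[bundle$domains$kind == kind, ])
      .write_tsv(asg, p(paste0("assignment_", kind, ".tsv")))
      .write_tsv(cnt, p(paste0("domain_counts_", kind, ".tsv")))
      out[[kind]] <- list(assignment = asg, counts = cnt)
    }
    iso <- out[["isochore"]]$assignment
    dgc <- bundle$domains$gc_percent[match(iso$domain_id,
                                           bundle$domains$domain_id)]
    lab <- res$labels$label[match(iso$exon_id, res$labels$exon_id)]
    keep <- !is.na(lab) & lab %in% c("GC", "AT")
    egc <- exon_gc[match(iso$exon_id, bundle$exons$exon_id)]
    out$iso_correlation <- exon_domain_gc_correlation(egc[keep], dgc[keep])
    out$lad_proportion <- class_proportion_in_kind(res$labels,
                                                   out[["LAD"]]$assignment)
    .write_tsv(data.frame(statistic = c("iso_gc_correlation",
                                        "lad_percent_gc", "lad_percent_at"),
                          value = c(out$iso_correlation,
                                    out$lad_proportion["GC"],
                                    out$lad_proportion["AT"])),
               p("domain_stats.tsv"))
    out
  })

  cfg_file <- tempfile()
  dput(config[setdiff(names(config), "out_dir")], file = cfg_file)
  manifest <- c(
    paste0("package: gcatex ", as.character(utils::packageVersion("gcatex"))),
    paste0("seed: ", config$seed),
    paste0("config_hash: ", unname(tools::md5sum(cfg_file))),
    paste0("outputs: ", paste(sort(list.files(config$out_dir)), collapse = " "))
  )
  unlink(cfg_file)
  writeLines(manifest, p("manifest.txt"))

  invisible(list(bundle = bundle, classify = res, features = features,
                 vvalues = vv, metaplot = meta, domains = dom,
                 out_dir = config$out_dir))
}
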