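test_that("simulation is deterministic given the seed", {
  cfg <- simulation_config(seed = 9, n_isochores = 2, genes_per_isochore = 2,
                           n_control_isochores = 1)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$exons, b2$exons)
  expect_identical(b1$regulation, b2$regulation)
  expect_identical(b1$peaks, b2$peaks)
  expect_identical(b1$coverage$values, b2$coverage$values)
  expect_identical(b1$truth, b2$truth)
  b3 <- simulate_bundle(simulation_config(seed = 10, n_isochores = 2,
                                          genes_per_isochore = 2,
                                          n_control_isochores = 1))
  expect_false(identical(b1$genome, b3$genome))
})

test_that("gene counts follow the configuration", {
  b <- simulate_bundle(simulation_config(
    seed = 2, n_isochores = 4, genes_per_isochore = 5, n_control_isochores = 0,
    exons_activated_per_factor = 30
  ))
  expect_equal(nrow(b$genes), 20)
  expect_equal(length(unique(b$exons$gene_id)), 20)
  expect_equal(sum(b$domains$kind == "isochore"), 4)
  expect_equal(sum(b$domains$kind == "TAD"), 8)
})

test_that("generated annotation satisfies the exon-table invariants", {
  b <- default_bundle()
  expect_true(validate_exon_table(b$exons))
  # exons inside their gene span
  g <- b$genes[match(b$exons$gene_id, b$genes$gene_id), ]
  expect_true(all(b$exons$start >= g$start & b$exons$end <= g$end))
  # intervals inside the chromosome
  expect_true(all(b$exons$end <= chrom_lengths(b$genome)[b$exons$chrom]))
  # isochores tile the chromosome without overlap
  iso <- b$domains[b$domains$kind == "isochore", ]
  iso <- iso[order(iso$start), ]
  expect_true(all(iso$start[-1] >= iso$end[-nrow(iso)]))
})

test_that("planted composition structure is recovered", {
  b <- default_bundle()
  ex_gc <- base_set_percent(extract_sequence(
    b$genome, b$exons$chrom, b$exons$start, b$exons$end, b$exons$strand))
  gene_gc <- b$genes$gc_percent[match(b$exons$gene_id, b$genes$gene_id)]
  expect_gt(cor(ex_gc, gene_gc), 0.5)
  mfi <- smallest_flanking_intron(b$exons)
  ok <- !is.na(mfi)
  expect_lt(cor(ex_gc[ok], mfi[ok]), 0)
})

test_that("planted class sizes support the recovery analyses", {
  b <- default_bundle()
  expect_gte(sum(b$truth$class == "GC"), 200)
  expect_gte(sum(b$truth$class == "AT"), 200)
  expect_gte(sum(b$truth$class == "AT"), sum(b$truth$class == "GC"))
})

test_that("a null generator plants no distinguishable decoy features", {
  # same composition, same intron lengths, no decoys, no hairpins: the two
  # context groups differ only in which factor names activate them
  cfg <- simulation_config(
    seed = 13, isochore_gc_levels = rep(45, 4),
    isochore_context = c("AT", "GC"),
    intron_length_meanlog = c(GC = log(700), AT = log(700), CTRL = log(700)),
    decoy_enrichment = 0, hairpin_rate = 0
  )
  b <- simulate_bundle(cfg)
  ids_gc <- b$truth$exon_id[b$truth$class == "GC"]
  ids_at <- b$truth$exon_id[b$truth$class == "AT"]
  set.seed(14)
  pick <- c(sample(ids_gc, 200), sample(ids_at, 200))
  ex <- b$exons[b$exons$exon_id %in% pick, ]
  lab <- data.frame(exon_id = b$truth$exon_id, label = b$truth$class)
  ft <- exon_feature_table(ex, b$genome, labels = lab)
  for (feat in c("n_bp", "n_tna", "n_trich", "mfe_5ss")) {
    p <- stats::wilcox.test(ft[[feat]][ft$class == "GC"],
                            ft[[feat]][ft$class == "AT"], exact = FALSE)$p.value
    expect_gt(p, 0.01)
  }
})

test_that("disabling planting removes the decoy excess", {
  cfg0 <- simulation_config(seed = 15, n_isochores = 4,
                            genes_per_isochore = 3, n_control_isochores = 0,
                            exons_activated_per_factor = 60,
                            decoy_enrichment = 0)
  b0 <- simulate_bundle(cfg0)
  cfg1 <- cfg0
  cfg1$decoy_enrichment <- 2
  b1 <- simulate_bundle(cfg1)
  mean_strong <- function(b) {
    ids <- b$truth$exon_id[b$truth$class == "AT"]
    ex <- b$exons[b$exons$exon_id %in% ids, ]
    ft <- exon_feature_table(ex, b$genome)
    mean(ft$n_bp_strong, na.rm = TRUE)
  }
  expect_gt(mean_strong(b1), mean_strong(b0) + 1)
})

test_that("impossible geometry is rejected", {
  expect_error(simulation_config(exons_per_gene = c(2, 2)), "at least 3")
  expect_error(simulation_config(clip_rate_at = 1.5), "probabilities")
  expect_error(simulation_config(isochore_gc_levels = c(0, 50)), "GC levels")
})
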