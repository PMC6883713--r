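# two small two-exon genes on one chromosome, opposite strands
meta_fixture <- function(chrom_len = 12000) {
  exons <- exon_table(
    exon_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    gene_id = c("gA", "gA", "gA", "gB", "gB", "gB"),
    index = c(1, 2, 3, 1, 2, 3),
    chrom = "c1",
    start = c(2000, 2600, 3300, 9000, 8200, 7300),
    end   = c(2200, 2800, 3500, 9200, 8400, 7500),
    strand = c("+", "+", "+", "-", "-", "-"),
    up_start   = c(NA, 2200, 2800, NA, 8400, 7500),
    up_end     = c(NA, 2600, 3300, NA, 9000, 8200),
    down_start = c(2200, 2800, NA, 8400, 7500, NA),
    down_end   = c(2600, 3300, NA, 9000, 8200, NA)
  )
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = "c1", start = c(2000, 7300),
    end = c(3500, 9200), strand = c("+", "-"), n_exons = 3
  )
  list(exons = exons, genes = genes, chrom_len = chrom_len)
}

const_track <- function(value, len = 12000) {
  coverage_track(list(c1 = rep(value, len)))
}

test_that("constant coverage yields flat profiles for every region kind", {
  fx <- meta_fixture()
  for (kind in c("promoter", "first_exon", "internal_exons", "introns",
                 "whole_gene")) {
    spec <- metaplot_spec(kind)
    prof <- binned_profile(gene_region_list(fx$exons, fx$genes, spec),
                           const_track(3), spec)
    expect_true(all(abs(prof$value - 3) < 1e-9), info = kind)
  }
})

test_that("the drop-199 rule fixes internal-exon and intron profile lengths", {
  fx <- meta_fixture()
  spec <- metaplot_spec("internal_exons")
  expect_equal(spec$drop_first, 199)
  prof <- binned_profile(gene_region_list(fx$exons, fx$genes, spec),
                         const_track(1), spec)
  expect_equal(nrow(prof), 801)
  expect_equal(prof$bin[1], 200)
  spec2 <- metaplot_spec("promoter")
  expect_equal(spec2$drop_first, 0)
  prof2 <- binned_profile(gene_region_list(fx$exons, fx$genes, spec2),
                          const_track(1), spec2)
  expect_equal(nrow(prof2), 1000)
})

test_that("genes average with equal weight", {
  fx <- meta_fixture()
  tr <- coverage_track(list(c1 = c(rep(2, 6000), rep(4, 6000))))
  spec <- metaplot_spec("whole_gene")
  prof <- binned_profile(gene_region_list(fx$exons, fx$genes, spec), tr, spec)
  expect_true(all(abs(prof$value - 3) < 1e-9))
  expect_equal(attr(prof, "n"), 2)
})

test_that("mean coverage averages depth over windows and groups", {
  tr <- const_track(5)
  w <- data.frame(chrom = "c1", start = c(100, 300), end = c(300, 500))
  mc <- mean_coverage(w, tr)
  expect_equal(mc$per_window$mean_coverage, c(5, 5))
  expect_equal(mc$group_mean, 5)
  half <- coverage_track(list(c1 = c(rep(10, 100), rep(0, 100))))
  mc2 <- mean_coverage(data.frame(chrom = "c1", start = 0, end = 200), half)
  expect_equal(mc2$group_mean, 5)
  expect_warning(mc3 <- mean_coverage(w[0, ], tr), "empty")
  expect_true(is.na(mc3$group_mean))
})

test_that("gc_at_ratio is the max-normalized difference and antisymmetric", {
  expect_equal(gc_at_ratio(4, 2), 0.5)
  expect_equal(gc_at_ratio(2, 4), -0.5)
  expect_equal(gc_at_ratio(3, 3), 0)
  expect_error(gc_at_ratio(0, 0), "undefined")
  set.seed(51)
  for (i in 1:20) {
    a <- runif(1, 0.1, 9); b <- runif(1, 0.1, 9)
    expect_equal(gc_at_ratio(a, b), -gc_at_ratio(b, a))
    expect_lte(abs(gc_at_ratio(a, b)), 1)
  }
})

test_that("clip proportions count exons with overlapping peaks per position", {
  ex <- exon_table(
    exon_id = paste0("e", 1:4), gene_id = paste0("h", 1:4), index = 2,
    chrom = "c1", start = seq(1000, 4000, by = 1000),
    end = seq(1100, 4100, by = 1000), strand = "+",
    up_start = seq(700, 3700, by = 1000), up_end = seq(1000, 4000, by = 1000),
    down_start = NA, down_end = NA
  )
  cl <- c(c1 = 12000)
  # peaks covering offset -10 (genomic start - 10) for exons 1 and 2 only
  peaks <- data.frame(chrom = "c1", start = c(985, 1985), end = c(995, 1995))
  p <- clip_positional_proportion(ex, peaks, cl, anchor = "3ss")
  expect_equal(nrow(p), 251)
  expect_equal(p$proportion[p$offset == -10], 0.5)
  expect_equal(p$proportion[p$offset == 0], 0)
  expect_true(all(clip_positional_proportion(ex, peaks[0, ], cl)$proportion == 0))
  big <- data.frame(chrom = "c1", start = 0, end = 12000)
  expect_true(all(clip_positional_proportion(ex, big, cl)$proportion == 1))
})

test_that("clip maps are strand-aware", {
  ex <- exon_table("m1", "gm", 2, "c1", 1000, 1100, "-",
                   up_start = 1100, up_end = 1400,
                   down_start = NA, down_end = NA)
  # upstream (transcript) of the 3' ss lies genomically to the right
  peaks <- data.frame(chrom = "c1", start = 1104, end = 1110)  # offsets -5..-11
  p <- clip_positional_proportion(ex, peaks, c(c1 = 5000), anchor = "3ss")
  expect_equal(p$proportion[p$offset == -6], 1)
  expect_equal(p$proportion[p$offset == -12], 0)
  expect_equal(p$proportion[p$offset == 3], 0)
})
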