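test_that("consensus branch-point caller scores and retains as specified", {
  # CTGAC in context: Y, T, N, A, Y all match -> score 2, retained
  s <- paste0(strrep("G", 40), "CTGAC", strrep("G", 10))
  calls <- predict_branch_points(s)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$score, 2)
  expect_equal(calls$offset, 44 - nchar(s) - 1)  # A at string position 44
  expect_equal(nchar(calls$context), 9)
  # AAGAA: only the branch A matches -> score -1, not retained
  expect_equal(nrow(predict_branch_points(
    paste0(strrep("G", 40), "AAGAA", strrep("G", 10)))), 0)
  expect_equal(nrow(predict_branch_points(strrep("G", 60))), 0)
  expect_equal(nrow(predict_branch_points("CTGA")), 0)  # shorter than context
})

test_that("branch-point counting and the >=k rule behave", {
  none <- predict_branch_points(strrep("G", 30))
  expect_equal(count_branch_points(none), 0)
  expect_false(has_multiple_bps(none))
  two <- predict_branch_points(paste0(strrep("G", 20), "CTGAC",
                                      strrep("G", 10), "CTGAC",
                                      strrep("G", 10)))
  expect_equal(count_branch_points(two), 2)
  expect_true(has_multiple_bps(two, k = 2))
  expect_false(has_multiple_bps(two, k = 3))
})

test_that("branch-point caller matches a positional brute-force scan", {
  set.seed(31)
  for (i in 1:300) {
    s <- random_seq(sample(5:100, 1), runif(1, 25, 70))
    got <- predict_branch_points(s)
    want <- oracle_bp_offsets(s)
    expect_equal(got$offset, want$offset)
    expect_equal(got$score, want$score)
  }
})

test_that("U2 duplex bonds reproduce the enumerated optima", {
  expect_equal(as.integer(u2_binding_bonds("TACTACAC")), 19)
  expect_equal(as.integer(u2_binding_bonds("AAAAAAAA")), 6)
  expect_equal(as.integer(u2_binding_bonds("CCCCCCCC")), 9)
  short <- u2_binding_bonds("CCC")
  expect_true(attr(short, "partial"))
  expect_equal(as.integer(short), 9)
  full <- u2_binding_bonds("GCGCGCGC")
  expect_false(attr(full, "partial"))
  set.seed(32)
  for (i in 1:150) {
    tg <- random_seq(sample(1:8, 1), runif(1, 20, 80))
    expect_equal(as.integer(u2_binding_bonds(tg)), as.integer(oracle_duplex(tg)),
                 info = tg)
  }
})

test_that("the duplex target drops the branch adenine from its context", {
  expect_equal(bp_duplex_target("CCCCCAGGG"), "CCCCCGGG")
  expect_equal(nchar(bp_duplex_target("CCCCCAGGG")), 8)
  expect_equal(bp_duplex_target("CCAGG", before = 2), "CCGG")
})

test_that("TNA and T-rich counters match brute-force scans", {
  expect_equal(count_tna("TCA"), 1)
  expect_equal(count_tna("TAATGATTAC"), 3)
  expect_equal(count_tna("GGGG"), 0)
  expect_equal(count_t_rich(strrep("T", 41)), 38)
  expect_equal(count_t_rich(paste0("TTTT", strrep("A", 37))), 2)
  expect_equal(count_t_rich(strrep("A", 41)), 0)
  expect_warning(short <- count_t_rich("TTT"), "shorter")
  expect_equal(short, 0)
  set.seed(33)
  for (i in 1:300) {
    s <- random_seq(sample(3:60, 1), runif(1, 20, 80))
    expect_equal(count_tna(s), oracle_tna(s), info = s)
    if (nchar(s) >= 4) {
      expect_equal(count_t_rich(s), oracle_trich(s), info = s)
    }
  }
})

test_that("default folding engine maximizes bonds with the loop constraint", {
  expect_equal(junction_mfe(strrep("A", 50)), 0)
  expect_equal(junction_mfe(paste0("GGGGAAACCCC", strrep("A", 39))), -12)
  expect_lte(junction_mfe(paste0("GCGCAAAGCGC", strrep("A", 39))), -8)
  # pairs must enclose at least min_loop unpaired bases
  expect_equal(junction_mfe("GAAC"), 0)    # only 2 bases enclosed
  expect_equal(junction_mfe("GAAAC"), -3)  # exactly 3 enclosed
  set.seed(34)
  for (i in 1:120) {
    s <- random_seq(sample(5:14, 1), runif(1, 20, 80))
    expect_equal(junction_mfe(s), oracle_fold(s), info = s)
  }
})

test_that("a plugged-in engine overrides the default", {
  expect_equal(junction_mfe("GGGGCCCC", engine = function(s) -1.5), -1.5)
})

test_that("feature table handles terminal exons and external calls", {
  up <- paste0(random_seq(60, 50), "CTGAC", strrep("G", 15),
               "CTGAC", strrep("C", 15))
  fx <- junction_exon_fixture(up, random_seq(50, 50), random_seq(100, 50))
  ft <- exon_feature_table(fx$exons, fx$genome)
  expect_gte(ft$n_bp, 2)
  expect_true(ft$has_2bp)
  expect_gte(ft$n_bp_strong, 2)
  expect_false(is.na(ft$mfe_5ss))
  expect_false(is.na(ft$mfe_3ss))
  expect_lte(ft$mfe_5ss, 0)

  # first exon: no upstream intron -> intronic features NA
  ex1 <- exon_table("f1", "g9", 1, names(fx$genome), 30, 80, "+",
                    down_start = 80, down_end = 180)
  ft1 <- exon_feature_table(ex1, fx$genome)
  expect_true(is.na(ft1$n_bp) && is.na(ft1$n_tna) && is.na(ft1$mfe_3ss))
  expect_false(is.na(ft1$mfe_5ss))

  # external calls replace the consensus caller
  ext <- data.frame(exon_id = "e1", offset = c(-30L, -60L), score = c(1.2, -0.5))
  ft2 <- exon_feature_table(fx$exons, fx$genome, bp_calls = ext)
  expect_equal(ft2$n_bp, 1)   # only the positive-score call
  expect_false(ft2$has_2bp)
})

test_that("minus-strand exons yield the same features as their plus-strand twin", {
  up <- random_seq(100, 40)
  exon <- random_seq(50, 60)
  down <- random_seq(100, 40)
  fp <- junction_exon_fixture(up, exon, down, strand = "+")
  fm <- junction_exon_fixture(up, exon, down, strand = "-")
  tp <- exon_feature_table(fp$exons, fp$genome)
  tm <- exon_feature_table(fm$exons, fm$genome)
  expect_equal(tp[-1], tm[-1])
})
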