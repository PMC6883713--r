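reg_row <- function(factor, sample_id, exon_id, direction) {
  data.frame(factor = factor, sample_id = sample_id, exon_id = exon_id,
             direction = direction, stringsAsFactors = FALSE)
}

test_that("activated sets honor at-least-one-sample and opposite-regulation removal", {
  reg <- rbind(
    reg_row("F1", "s1", "e1", "activated"),
    reg_row("F1", "s1", "e2", "activated"),
    reg_row("F1", "s2", "e2", "repressed"),
    reg_row("F2", "s1", "e3", "repressed")
  )
  sets <- build_activated_sets(reg)
  expect_equal(sets$F1, "e1")      # e2 regulated in opposite ways -> out
  expect_equal(sets$F2, character(0))
  expect_equal(build_activated_sets(reg[0, ]), setNames(list(), character(0)))
  # same exon, same factor, conflicting directions in ONE sample is an error
  bad <- rbind(reg_row("F1", "s1", "e1", "activated"),
               reg_row("F1", "s1", "e1", "repressed"))
  expect_error(build_activated_sets(bad), "conflicting")
  # the factor filter keeps spliceosome knockdowns out of the class step
  expect_named(build_activated_sets(reg, factors = "F1"), "F1")
})

test_that("factor classification applies both thresholds strictly", {
  th <- class_thresholds()
  expect_equal(classify_factor(55, 300, th), "GC")
  expect_equal(classify_factor(40, 2500, th), "AT")
  expect_equal(classify_factor(55, 2500, th), "unclassified")
  expect_equal(classify_factor(40, 300, th), "unclassified")
  expect_equal(classify_factor(49.3, 300, th), "unclassified")  # equality
  expect_equal(classify_factor(55, 691, th), "unclassified")
})

test_that("classification is monotone in both medians", {
  th <- class_thresholds()
  rank <- c(AT = -1, unclassified = 0, GC = 1)
  set.seed(21)
  for (i in 1:50) {
    gc1 <- runif(1, 30, 70); gc2 <- gc1 + runif(1, 0, 20)
    mi <- runif(1, 100, 3000)
    expect_gte(rank[classify_factor(gc2, mi, th)],
               rank[classify_factor(gc1, mi, th)])
    mi2 <- mi + runif(1, 0, 2000)
    expect_lte(rank[classify_factor(gc1, mi2, th)],
               rank[classify_factor(gc1, mi, th)])
  }
})

test_that("exon labels partition into class, overlap and none", {
  ct <- data.frame(factor = c("G1", "G2", "A1", "U"),
                   class = c("GC", "GC", "AT", "unclassified"))
  sets <- list(G1 = c("e1", "e2"), G2 = c("e2", "e3"),
               A1 = c("e3", "e4"), U = c("e5"))
  lab <- assemble_class_exons(ct, sets, all_exon_ids = paste0("e", 1:6))
  got <- setNames(lab$label, lab$exon_id)
  expect_equal(unname(got[c("e1", "e2")]), c("GC", "GC"))
  expect_equal(unname(got["e3"]), "excluded_overlap")
  expect_equal(unname(got["e4"]), "AT")
  expect_equal(unname(got[c("e5", "e6")]), c("none", "none"))
  expect_true(all(table(lab$exon_id) == 1))
})

test_that("control set is constitutive internal exons minus activated", {
  ex <- exon_table(
    exon_id = paste0("e", 1:10), gene_id = "g", index = 1:10,
    chrom = "c", start = seq(0, 9000, by = 1000),
    end = seq(100, 9100, by = 1000), strand = "+",
    up_start = c(NA, seq(100, 8100, by = 1000)),
    up_end = c(NA, seq(1000, 9000, by = 1000)),
    down_start = c(seq(100, 8100, by = 1000), NA),
    down_end = c(seq(1000, 9000, by = 1000), NA),
    constitutive = TRUE
  )
  expect_equal(build_control_set(ex, list()), paste0("e", 2:9))
  expect_equal(build_control_set(ex, list(F = "e5")),
               setdiff(paste0("e", 2:9), "e5"))
  expect_warning(ctrl <- build_control_set(ex, list(F = paste0("e", 1:10))),
                 "empty")
  expect_length(ctrl, 0)
})

test_that("U1/U2 sets are unions over the named groups and may overlap", {
  sets <- list(SNRPC = c("e1", "e2"), SNRNP70 = "e3", DDX5_17 = character(0),
               SF1 = c("e2", "e4"), U2AF2 = "e5", SF3A3 = character(0),
               SF3B4 = character(0))
  u12 <- build_u1_u2_sets(sets)
  expect_setequal(u12$u1, c("e1", "e2", "e3"))
  expect_setequal(u12$u2, c("e2", "e4", "e5"))
  expect_true("e2" %in% u12$u1 && "e2" %in% u12$u2)
  expect_error(build_u1_u2_sets(sets["SNRPC"]), "unknown factor")
})

test_that("GA/CT generalization classifies on composition alone by default", {
  th <- class_thresholds(gc_threshold = 50, base_set = "GA")
  expect_false(th$use_intron)
  expect_equal(classify_factor(60, NA, th), "GA")
  expect_equal(classify_factor(40, NA, th), "CT")
  expect_equal(classify_factor(50, NA, th), "unclassified")
})

test_that("a NULL composition threshold is recomputed from the control set", {
  fx <- tandem_junction_fixture(c(strrep("G", 150), strrep("A", 150),
                                  paste0(strrep("G", 75), strrep("A", 75))))
  sets <- list(F = "e1")
  th <- class_thresholds(gc_threshold = NULL, use_intron = FALSE)
  ct <- factor_class_table(sets, fx$exons, fx$genome, th,
                           control_ids = c("e2", "e3"))
  # control median GC = 25 %; the all-G factor set sits above it
  expect_equal(ct$class, "GC")
  expect_error(factor_class_table(sets, fx$exons, fx$genome, th), "control_ids")
})
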