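test_that("the count-to-V formulas reproduce the printed corner cases", {
  r <- gcatex:::.vvalue_from_counts(0, 10000, 10000)
  expect_equal(r$p_emp, 1e-4)
  expect_equal(r$s, -1)
  expect_equal(r$v, 4)
  r <- gcatex:::.vvalue_from_counts(10000, 0, 10000)
  expect_equal(r$p_emp, 1e-4)
  expect_equal(r$s, 1)
  expect_equal(r$v, -4)
  r <- gcatex:::.vvalue_from_counts(5000, 5000, 10000)
  expect_equal(r$p_emp, 0.5)
  expect_equal(r$s, -1)                 # s = 1 only when k > l
  expect_equal(r$v, 0.30103, tolerance = 1e-5)
})

test_that("extreme separations reach the p-value floor with the right sign", {
  gc <- paste0("g", 1:50)
  at <- paste0("a", 1:200)
  hi <- v_value(gc, gc, at, n_iter = 10000, seed = 7)
  expect_equal(hi$k, 0)
  expect_equal(hi$v, 4)
  expect_equal(hi$s, -1)
  lo <- v_value(at, gc, at, n_iter = 10000, seed = 7)
  expect_equal(lo$l, 0)
  expect_equal(lo$v, -4)
  expect_equal(lo$s, 1)
})

test_that("ties increment both k and l", {
  # factor empty: every subsample count equals the observed count (0)
  r <- v_value(character(0), paste0("g", 1:20), paste0("a", 1:80),
               n_iter = 500, seed = 3)
  expect_equal(r$k, 500)
  expect_equal(r$l, 500)
  expect_equal(r$p_emp, 1)
  expect_equal(r$v, 0)
})

test_that("identical seeds give identical results, different seeds differ", {
  set.seed(41)
  at <- paste0("a", 1:400)
  gc <- paste0("g", 1:100)
  fac <- c(sample(gc, 28), sample(at, 100))   # observed prop near the center
  r1 <- v_value(fac, gc, at, n_iter = 400, seed = 10)
  r2 <- v_value(fac, gc, at, n_iter = 400, seed = 10)
  expect_identical(r1[c("k", "l", "p_emp", "v")], r2[c("k", "l", "p_emp", "v")])
  r3 <- v_value(fac, gc, at, n_iter = 400, seed = 11)
  expect_false(identical(c(r1$k, r1$l), c(r3$k, r3$l)))
})

test_that("subsample counts follow the hypergeometric law", {
  # independent cross-check of the resampling machinery: the fraction of
  # subsamples at or above the observed count must match the hypergeometric
  # upper tail for the AT pool composition
  at <- paste0("a", 1:1000)
  gc <- paste0("g", 1:100)
  fac <- c(at[1:200], gc[1:20])         # 200 of 1000 AT, obs count 20
  r <- v_value(fac, gc, at, n_iter = 20000, seed = 12)
  want_k <- 1 - stats::phyper(19, 200, 800, 100)  # P(X >= 20)
  expect_equal(r$k / r$n_iter, want_k, tolerance = 0.02)
  want_l <- stats::phyper(20, 200, 800, 100)      # P(X <= 20)
  expect_equal(r$l / r$n_iter, want_l, tolerance = 0.02)
})

test_that("planted enrichment recovers the expected sign", {
  set.seed(42)
  gc <- paste0("g", 1:200)
  at <- paste0("a", 1:600)
  for (i in 1:20) {
    fac <- c(sample(gc, 60), sample(at, 60))   # 30 % of GC, 10 % of AT
    r <- v_value(fac, gc, at, n_iter = 1000, seed = 100 + i)
    expect_gt(r$v, 0)
    expect_equal(r$s, -1)
    fac2 <- c(sample(gc, 20), sample(at, 180)) # 10 % of GC, 30 % of AT
    r2 <- v_value(fac2, gc, at, n_iter = 1000, seed = 200 + i)
    expect_lt(r2$v, 0)
  }
})

test_that("preconditions are enforced", {
  expect_error(v_value("x", character(0), paste0("a", 1:10)), "empty GC")
  expect_error(v_value("x", paste0("g", 1:20), paste0("a", 1:10)),
               "at least as large")
  expect_error(v_value("x", paste0("g", 1:5), paste0("a", 1:10), n_iter = 0),
               "n_iter")
})

test_that("significance threshold is the absolute log10 alpha line", {
  expect_equal(significance_threshold(0.05), 1.30103, tolerance = 1e-5)
  expect_equal(significance_threshold(0.01), 2)
  expect_true(is_significant(4))
  expect_true(is_significant(-4))
  expect_false(is_significant(0.3))
})

test_that("the factor table is reproducible and flags significance", {
  sets <- list(U1F = paste0("g", 1:40), U2F = paste0("a", 1:80))
  gc <- paste0("g", 1:100)
  at <- paste0("a", 1:300)
  t1 <- vvalue_table(sets, gc, at, n_iter = 500, seed = 5)
  t2 <- vvalue_table(sets, gc, at, n_iter = 500, seed = 5)
  expect_identical(t1, t2)
  expect_gt(t1$v[t1$factor == "U1F"], 0)
  expect_lt(t1$v[t1$factor == "U2F"], 0)
  expect_true(all(c("p_bh", "significant") %in% names(t1)))
})
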