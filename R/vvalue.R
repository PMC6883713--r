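#' V value: subsampling test of GC- versus AT-exon regulation preference
#'
#' For a spliceosome-associated factor, draws `n_iter` subsamples of AT exons
#' of the same size as the GC exon set (without replacement within each draw,
#' independently across draws) and compares the proportion of each subsample
#' activated by the factor with the observed proportion among GC exons.
#' With `k` subsamples reaching a proportion greater than or equal to the
#' observed one and `l` subsamples at or below it (ties increment both), the
#' empirical p-value is `max(min(k, l) / n_iter, 1 / n_iter)` and the V value
#' is `log10(p_emp) * s` with `s = 1` if `k > l` and `s = -1` otherwise.
#' A positive V therefore means the factor's regulation is concentrated in GC
#' exons (few AT subsamples reach the GC proportion); a negative V, in AT
#' exons.
#'
#' @param factor_exons Exon ids activated by the factor.
#' @param gc_exons,at_exons GC- and AT-class exon id sets; the AT set must be
#'   at least as large as the GC set.
#' @param n_iter Number of subsamples (default 10,000, giving the 1e-4
#'   p-value floor).
#' @param seed Optional integer seed; the RNG state is restored on exit.
#' @param factor Optional factor name carried into the result.
#' @return Object of class `vvalue_result`: list with factor, n_iter, k, l,
#'   p_emp, s, v, observed_prop.
#' @export
v_value <- function(factor_exons, gc_exons, at_exons, n_iter = 10000,
                    seed = NULL, factor = NA_character_) {
  gc_exons <- unique(gc_exons)
  at_exons <- unique(at_exons)
  n_gc <- length(gc_exons)
  n_at <- length(at_exons)
  if (n_gc < 1) stop("empty GC exon set")
  if (n_at < n_gc) stop("AT set must be at least as large as the GC set")
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  obs_cnt <- sum(gc_exons %in% factor_exons)
  member <- at_exons %in% factor_exons
  cnt <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    cnt[i] <- sum(member[sample.int(n_at, n_gc)])
  }
  # proportions share the denominator n_gc: compare integer counts exactly
  k <- sum(cnt >= obs_cnt)
  l <- sum(cnt <= obs_cnt)
  out <- .vvalue_from_counts(k, l, n_iter)
  structure(c(list(factor = factor), out,
              list(observed_prop = obs_cnt / n_gc)),
            class = "vvalue_result")
}

# the printed formulas: ties-inclusive k and l, floored empirical p, signed
# log10; s = 1 only when k strictly exceeds l
.vvalue_from_counts <- function(k, l, n_iter) {
  p_emp <- max(min(k, l) / n_iter, 1 / n_iter)
  s <- if (k > l) 1 else -1
  list(n_iter = n_iter, k = k, l = l, p_emp = p_emp, s = s,
       v = log10(p_emp) * s)
}

#' @export
print.vvalue_result <- function(x, ...) {
  cat(sprintf(
    "V value%s: v = %.4f (p_emp = %.4g, k = %d, l = %d, n_iter = %d, obs GC prop = %.3f)\n",
    if (is.na(x$factor)) "" else paste0(" [", x$factor, "]"),
    x$v, x$p_emp, x$k, x$l, x$n_iter, x$observed_prop
  ))
  invisible(x)
}

#' Significance threshold line for V-value plots
#'
#' Returns `-log10(alpha)` (about 1.301 for alpha = 0.05): a V value is
#' called significant when its magnitude reaches this line, i.e. when
#' `p_emp <= alpha`. The sign of V is not part of the significance call.
#'
#' @param alpha Significance level in (0, 1).
#' @return The threshold on `|v|`.
#' @export
significance_threshold <- function(alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  -log10(alpha)
}

#' @rdname significance_threshold
#' @param v A V value (or vector of them).
#' @export
is_significant <- function(v, alpha = 0.05) {
  abs(v) >= significance_threshold(alpha)
}

#' V values for a set of factors
#'
#' Runs [v_value()] for each factor set and collects a table. Seeds for the
#' individual randomizations are derived from `seed` so the table is
#' reproducible as a whole. A Benjamini-Hochberg adjusted column is appended
#' for convenience; the randomization procedure itself applies no
#' multiple-testing correction, so significance flags use the raw empirical
#' p-values.
#'
#' @param sets Named list of activated exon-id vectors.
#' @param factors Factor names to test (default all of `sets`).
#' @param gc_exons,at_exons Class exon sets.
#' @param n_iter Subsamples per factor.
#' @param seed Integer seed for the whole table.
#' @param alpha Significance level.
#' @return data.frame: factor, n_iter, k, l, p_emp, v, significant, p_bh.
#' @export
vvalue_table <- function(sets, gc_exons, at_exons, factors = names(sets),
                         n_iter = 10000, seed = 1, alpha = 0.05) {
  rows <- lapply(seq_along(factors), function(i) {
    f <- factors[i]
    if (is.null(sets[[f]])) stop("unknown factor: ", f)
    r <- v_value(sets[[f]], gc_exons, at_exons, n_iter = n_iter,
                 seed = seed + i, factor = f)
    data.frame(factor = f, n_iter = r$n_iter, k = r$k, l = r$l,
               p_emp = r$p_emp, v = r$v,
               significant = is_significant(r$v, alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_emp, method = "BH")
  out
}
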