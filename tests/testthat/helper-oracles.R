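# Independent brute-force oracles. These deliberately avoid the package's
# algorithms: positional loops instead of vectorized scans, and a
# pair-the-left-end interval recursion instead of the row-by-row dynamic
# programs, so agreement is a real cross-check.

random_seq <- function(n, gc = 50) {
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (100 - gc) / 2, (100 - gc) / 2) / 100),
        collapse = "")
}

oracle_tna <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- 0L
  for (i in seq_len(max(0, length(ch) - 2))) {
    if (ch[i] == "T" && ch[i + 2] == "A") n <- n + 1L
  }
  n
}

oracle_trich <- function(seq, window = 4, min_t = 3) {
  ch <- strsplit(seq, "")[[1]]
  n <- 0L
  for (i in seq_len(max(0, length(ch) - window + 1))) {
    if (sum(ch[i:(i + window - 1)] == "T") >= min_t) n <- n + 1L
  }
  n
}

# every A with a full YTNAY window, scored as consensus matches minus 2
oracle_bp_offsets <- function(seq, min_score = 0) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  out <- integer(0)
  scores <- integer(0)
  is_y <- function(x) x %in% c("C", "T")
  for (i in seq_len(L)) {
    if (ch[i] != "A" || i < 4 || i > L - 1) next
    sc <- is_y(ch[i - 3]) + (ch[i - 2] == "T") + 1L + is_y(ch[i + 1]) - 2L
    if (sc > min_score) {
      out <- c(out, i - L - 1L)
      scores <- c(scores, sc)
    }
  }
  data.frame(offset = out, score = scores)
}

.oracle_bond <- function(x, y) {
  key <- paste0(x, y)
  if (key %in% c("GC", "CG")) return(3L)
  if (key %in% c("AT", "TA", "GT", "TG")) return(2L)
  0L
}

# maximum-weight non-crossing matching of two strands, enumerated by an
# interval recursion on the first strand (memoized on the (i, j) frontier)
oracle_duplex <- function(target, u2 = "GUGUAGUA") {
  a <- strsplit(toupper(chartr("U", "T", target)), "")[[1]]
  b <- rev(strsplit(toupper(chartr("U", "T", u2)), "")[[1]])
  n <- length(a)
  m <- length(b)
  memo <- array(NA_integer_, dim = c(n + 1, m + 1))
  g <- function(i, j) {
    if (i > n || j > m) return(0L)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- g(i + 1, j)                  # a[i] unpaired
    for (k in j:m) {                     # a[i] paired with b[k]
      w <- .oracle_bond(a[i], b[k])
      if (w > 0) best <- max(best, w + g(i + 1, k + 1))
    }
    memo[i, j] <<- best
    best
  }
  if (n == 0) return(0L)
  g(1, 1)
}

# single-strand maximum-bond folding: recursion pairing the LEFT end (the
# implementation pairs the right end), min_loop unpaired bases inside a pair
oracle_fold <- function(seq, min_loop = 3) {
  a <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  n <- length(a)
  memo <- new.env()
  f <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- f(i + 1, j)                  # i unpaired
    for (k in (i + min_loop + 1):j) {
      w <- .oracle_bond(a[i], a[k])
      if (w > 0) {
        right <- if (k < j) f(k + 1, j) else 0L
        best <- max(best, w + f(i + 1, k - 1) + right)
      }
    }
    memo[[key]] <- best
    best
  }
  if (n < min_loop + 2) return(0)
  -as.numeric(f(1, n))
}

# per-position sliding-window base-set means across region strings
oracle_profile <- function(region_seqs, base_set = "GC", window = 20) {
  bases <- strsplit(base_set, "")[[1]]
  L <- nchar(region_seqs[1])
  vals <- numeric(L - window + 1)
  for (j in seq_along(vals)) {
    per <- vapply(region_seqs, function(s) {
      ch <- strsplit(substr(s, j, j + window - 1), "")[[1]]
      ch <- ch[ch != "N"]
      if (length(ch) == 0) return(NA_real_)
      mean(ch %in% bases)
    }, numeric(1))
    vals[j] <- 100 * mean(per, na.rm = TRUE)
  }
  vals
}
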