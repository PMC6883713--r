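#' Feature window geometry for splice-signal scoring
#'
#' All windows are in transcript orientation relative to the splice sites.
#' Defaults: branch points are searched in the last 100 nt of the upstream
#' intron; the branch-point context carries 5 nt before and 3 nt after the
#' branch adenine; TNA motifs are counted in the last 50 intronic nt; T-rich
#' low-complexity windows (4 nt, >= 3 Ts) between positions -75 and -35
#' upstream of the 3' ss; folding windows take 25 nt on each side of a splice
#' site; CLIP positional maps cover 200 intronic and 50 exonic nt.
#'
#' @param bp_search,bp_context_before,bp_context_after,tna_window,trich_from,trich_to,trich_window,trich_min_t,mfe_flank,clip_intron,clip_exon
#'   Window parameters, see Description.
#' @return List of class `feature_windows`.
#' @export
feature_windows <- function(bp_search = 100, bp_context_before = 5,
                            bp_context_after = 3, tna_window = 50,
                            trich_from = -75, trich_to = -35,
                            trich_window = 4, trich_min_t = 3,
                            mfe_flank = 25, clip_intron = 200, clip_exon = 50) {
  if (trich_from >= trich_to) stop("trich region must be ordered (from < to)")
  w <- list(bp_search = bp_search, bp_context_before = bp_context_before,
            bp_context_after = bp_context_after, tna_window = tna_window,
            trich_from = trich_from, trich_to = trich_to,
            trich_window = trich_window, trich_min_t = trich_min_t,
            mfe_flank = mfe_flank, clip_intron = clip_intron,
            clip_exon = clip_exon)
  if (any(unlist(w[c("bp_search", "tna_window", "trich_window", "mfe_flank",
                     "clip_intron", "clip_exon")]) <= 0)) {
    stop("window sizes must be positive")
  }
  structure(w, class = "feature_windows")
}

#' Predict branch-point candidates with the consensus caller
#'
#' The built-in caller scans the 3'-terminal intron sequence for adenines in
#' a full YTNAY 5-mer context (Y = C or T, N = any base; the candidate base
#' itself must be A) and scores each as the number of consensus matches among
#' the four constrained positions minus 2, so a perfect consensus scores 2
#' and two mismatches fail. Candidates with score > 0 are retained, mirroring
#' the positive-score cutoff used with external support-vector callers, whose
#' output can be substituted via `bp_calls` tables downstream. N bases never
#' match a consensus position.
#'
#' @param seq 3'-terminal intron sequence (its last base abuts the 3' ss, at
#'   offset -1).
#' @param windows A [feature_windows()] (context widths for the reported
#'   9-nt branch-point context).
#' @param min_score Retain calls with score strictly above this (default 0).
#' @return data.frame (offset, score, context): offset is the branch adenine
#'   position relative to the 3' ss (negative); context is the surrounding
#'   sequence, 9 nt when both flanks fit in `seq`.
#' @export
predict_branch_points <- function(seq, windows = feature_windows(),
                                  min_score = 0) {
  L <- nchar(seq)
  empty <- data.frame(offset = integer(0), score = numeric(0),
                      context = character(0), stringsAsFactors = FALSE)
  if (L < 5) return(empty)
  ch <- strsplit(toupper(seq), "")[[1]]
  # candidate A at i needs the full 5-mer [i-3, i+1]
  idx <- which(ch == "A")
  idx <- idx[idx >= 4 & idx <= L - 1]
  if (length(idx) == 0) return(empty)
  is_y <- ch %in% c("C", "T")
  score <- 1L +                       # the branch A itself matches
    is_y[idx - 3] + (ch[idx - 2] == "T") + is_y[idx + 1] - 2L
  keep <- score > min_score
  idx <- idx[keep]
  if (length(idx) == 0) return(empty)
  b <- windows$bp_context_before
  a <- windows$bp_context_after
  data.frame(
    offset = idx - L - 1L,
    score = score[keep],
    context = substring(seq, pmax(1, idx - b), pmin(L, idx + a)),
    stringsAsFactors = FALSE
  )
}

#' @rdname predict_branch_points
#' @param calls A branch-point call table.
#' @export
count_branch_points <- function(calls) nrow(calls)

#' @rdname predict_branch_points
#' @param k Minimum number of calls (default 2).
#' @export
has_multiple_bps <- function(calls, k = 2) nrow(calls) >= k

.BOND_LOOKUP <- local({
  m <- matrix(0L, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T")))
  m["G", "C"] <- m["C", "G"] <- 3L
  m["A", "T"] <- m["T", "A"] <- 2L
  m["G", "T"] <- m["T", "G"] <- 2L   # G:U wobble
  m
})

.base_int <- function(ch) match(ch, c("A", "C", "G", "T"))  # NA for N

#' Hydrogen bonds of the best U2 snRNA / branch-point duplex
#'
#' Scores the pairing between the 8-nt sequence surrounding a branch point
#' (its 9-nt context with the branch adenine removed) and the branch-point
#' binding sequence of the U2 snRNA (GUGUAGUA): the antiparallel,
#' non-crossing set of base pairs from \{G:C = 3, A:U = 2, G:U wobble = 2\}
#' hydrogen bonds that maximizes the total bond count, with unpaired bases
#' and interior loops unpenalized. Computed by dynamic programming over the
#' target and the reversed U2 sequence. Targets shorter than 8 nt are scored
#' over the available bases and flagged with a `partial` attribute.
#'
#' @param target Target sequence, 5'->3' (T stands for U).
#' @param u2_bbs U2 branch-point binding sequence (default `"GUGUAGUA"`).
#' @return Integer bond total; attribute `partial` is TRUE when the target
#'   was shorter than 8 nt.
#' @export
u2_binding_bonds <- function(target, u2_bbs = "GUGUAGUA") {
  a <- .base_int(strsplit(chartr("Uu", "Tt", toupper(target)), "")[[1]])
  b <- rev(.base_int(strsplit(chartr("U", "T", toupper(u2_bbs)), "")[[1]]))
  n <- length(a); m <- length(b)
  if (n == 0) return(structure(0L, partial = TRUE))
  M <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      pair <- if (is.na(a[i]) || is.na(b[j])) 0L else .BOND_LOOKUP[a[i], b[j]]
      M[i + 1, j + 1] <- max(M[i, j + 1], M[i + 1, j], M[i, j] + pair)
    }
  }
  structure(M[n + 1, m + 1], partial = n < 8)
}

#' Drop the branch adenine from a 9-nt branch-point context
#'
#' @param context Branch-point context (5 nt + A + 3 nt when complete).
#' @param before Number of bases before the branch adenine in the context.
#' @return The duplex target (context without the branch base).
#' @export
bp_duplex_target <- function(context, before = 5) {
  n <- nchar(context)
  # short contexts at the window edge keep the branch base at position
  # min(before + 1, n - after): derive it from the actual length
  pos <- pmin(before + 1L, n)
  paste0(substring(context, 1, pos - 1L), substring(context, pos + 1L, n))
}

#' Count TNA motifs (SF1-site decoys)
#'
#' Positions i with T at i and A at i + 2, overlaps allowed; counted over the
#' 3'-terminal intron window (last 50 nt by default).
#'
#' @param seq Nucleotide string.
#' @return Integer count.
#' @export
count_tna <- function(seq) {
  L <- nchar(seq)
  if (L < 3) return(0L)
  ch <- strsplit(toupper(seq), "")[[1]]
  sum(ch[1:(L - 2)] == "T" & ch[3:L] == "A")
}

#' Count T-rich low-complexity windows (U2AF2-site decoys)
#'
#' Number of `window`-nt windows (step 1) containing at least `min_t` Ts,
#' over the region between -75 and -35 nt upstream of the 3' ss. Regions
#' shorter than one window return 0 with a warning.
#'
#' @param seq Region sequence.
#' @param window Window size (default 4).
#' @param min_t Minimum T count per window (default 3).
#' @return Integer count.
#' @export
count_t_rich <- function(seq, window = 4, min_t = 3) {
  L <- nchar(seq)
  if (L < window) {
    warning("region shorter than one window; returning 0")
    return(0L)
  }
  is_t <- as.integer(strsplit(toupper(seq), "")[[1]] == "T")
  cs <- c(0L, cumsum(is_t))
  wt <- cs[(window + 1):(L + 1)] - cs[1:(L - window + 1)]
  sum(wt >= min_t)
}

#' Folding stability of a splice-junction window
#'
#' The default engine maximizes hydrogen bonds over non-crossing base pairs
#' (G:C = 3, A:U = 2, G:U = 2) with a minimum hairpin loop of 3 unpaired
#' bases, Nussinov-style, and returns the negated bond total, so lower values
#' mean more stably paired windows and an unpairable window scores 0. A
#' thermodynamic engine can be plugged in via `engine` (any function mapping
#' a sequence to a free energy in the same orientation).
#'
#' @param seq Junction window sequence (by convention 25 nt on each side of
#'   the splice site).
#' @param min_loop Minimum number of unpaired bases enclosed by a pair.
#' @param engine Optional replacement folding function.
#' @return Numeric energy, <= 0.
#' @export
junction_mfe <- function(seq, min_loop = 3, engine = NULL) {
  if (!is.null(engine)) return(engine(seq))
  a <- .base_int(strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1]])
  n <- length(a)
  if (n < min_loop + 2) return(0)
  M <- matrix(0L, n, n)
  for (span in (min_loop + 1):(n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i, j - 1]
      ks <- i:(j - min_loop - 1)
      bj <- a[j]
      if (!is.na(bj)) {
        bonds <- ifelse(is.na(a[ks]), 0L, .BOND_LOOKUP[cbind(a[ks], bj)])
        ok <- which(bonds > 0L)
        for (kk in ok) {
          k <- ks[kk]
          left <- if (k > i) M[i, k - 1] else 0L
          cand <- bonds[kk] + left + M[k + 1, j - 1]
          if (cand > best) best <- cand
        }
      }
      M[i, j] <- best
    }
  }
  -as.numeric(M[1, n])
}
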