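#' Per-exon splice-signal feature table
#'
#' Computes, for every exon with the required flank, the branch-point count
#' in the last 100 nt of the upstream intron (and whether it reaches
#' `bp_k` calls), the U2 duplex bond total of the best-scoring branch point,
#' the TNA motif count in the last 50 intronic nt, the number of T-rich
#' low-complexity windows between -75 and -35, and the default-engine
#' folding energies of the 50-nt windows centered on the 5' and 3' splice
#' sites. Features whose window is unavailable (terminal exons, short
#' introns or exons) are NA.
#'
#' External branch-point calls (e.g. from a support-vector caller) can be
#' supplied as a data.frame (exon_id, offset, score) and are then used in
#' place of the consensus caller, with contexts recovered from the genome.
#'
#' @param exons Exon table.
#' @param genome Genome.
#' @param windows A [feature_windows()].
#' @param labels Optional data.frame (exon_id, label) merged into the output.
#' @param bp_calls Optional external branch-point call table.
#' @param bp_k Call count defining `has_2bp` (default 2: "two or more").
#' @param strong_score Score at or above which a call counts as strong
#'   (default 2: a perfect consensus under the built-in caller). The
#'   permissive score-above-zero retention keeps every one-mismatch
#'   consensus, which on genomic background yields many calls per window;
#'   the strong-call columns preserve the class contrast that a selective
#'   caller produces.
#' @return data.frame: exon_id, class, n_bp, has_2bp, n_bp_strong,
#'   has_2bp_strong, u2_bonds_best, n_tna, n_trich, mfe_5ss, mfe_3ss.
#' @export
exon_feature_table <- function(exons, genome, windows = feature_windows(),
                               labels = NULL, bp_calls = NULL, bp_k = 2,
                               strong_score = 2) {
  n <- nrow(exons)
  up_len <- exons$up_end - exons$up_start
  dn_len <- exons$down_end - exons$down_start
  ex_len <- exons$end - exons$start

  has_up <- !is.na(up_len)
  up_seq <- rep(NA_character_, n)
  if (any(has_up)) {
    full <- extract_sequence(genome, exons$chrom[has_up], exons$up_start[has_up],
                             exons$up_end[has_up], exons$strand[has_up])
    up_seq[has_up] <- substring(full, pmax(1, nchar(full) - windows$bp_search + 1),
                                nchar(full))
  }

  n_bp <- rep(NA_integer_, n)
  has2 <- rep(NA, n)
  n_bp_strong <- rep(NA_integer_, n)
  has2_strong <- rep(NA, n)
  u2b <- rep(NA_integer_, n)
  n_tna <- rep(NA_integer_, n)
  n_trich <- rep(NA_integer_, n)

  ext <- !is.null(bp_calls)
  for (i in which(has_up)) {
    s <- up_seq[i]
    L <- nchar(s)
    if (ext) {
      calls <- bp_calls[bp_calls$exon_id == exons$exon_id[i] &
                          bp_calls$score > 0, , drop = FALSE]
      if (nrow(calls) > 0) {
        idx <- L + 1L + calls$offset
        calls$context <- substring(s, pmax(1, idx - windows$bp_context_before),
                                   pmin(L, idx + windows$bp_context_after))
      }
    } else {
      calls <- predict_branch_points(s, windows)
    }
    n_bp[i] <- count_branch_points(calls)
    has2[i] <- has_multiple_bps(calls, k = bp_k)
    strong <- calls[calls$score >= strong_score, , drop = FALSE]
    n_bp_strong[i] <- count_branch_points(strong)
    has2_strong[i] <- has_multiple_bps(strong, k = bp_k)
    if (nrow(calls) > 0) {
      best <- which.max(calls$score + calls$offset * 1e-9)  # tie: nearest 3' ss
      u2b[i] <- u2_binding_bonds(
        bp_duplex_target(calls$context[best], windows$bp_context_before)
      )
    }
    n_tna[i] <- count_tna(substring(s, max(1, L - windows$tna_window + 1), L))
    # region [trich_from, trich_to] relative to the 3' ss; offset o sits at
    # string index L + 1 + o
    lo <- L + 1 + windows$trich_from
    hi <- L + 1 + windows$trich_to
    if (hi >= 1) {
      n_trich[i] <- suppressWarnings(
        count_t_rich(substring(s, max(1, lo), hi),
                     windows$trich_window, windows$trich_min_t)
      )
    }
  }

  fl <- windows$mfe_flank
  mfe5 <- rep(NA_real_, n)
  ok5 <- !is.na(dn_len) & dn_len >= fl & ex_len >= fl
  if (any(ok5)) {
    ex_seq <- extract_sequence(genome, exons$chrom[ok5], exons$start[ok5],
                               exons$end[ok5], exons$strand[ok5])
    in_seq <- extract_sequence(genome, exons$chrom[ok5], exons$down_start[ok5],
                               exons$down_end[ok5], exons$strand[ok5])
    win <- paste0(substring(ex_seq, nchar(ex_seq) - fl + 1, nchar(ex_seq)),
                  substring(in_seq, 1, fl))
    mfe5[ok5] <- vapply(win, junction_mfe, numeric(1), USE.NAMES = FALSE)
  }
  mfe3 <- rep(NA_real_, n)
  ok3 <- has_up & up_len >= fl & ex_len >= fl
  if (any(ok3)) {
    ex_seq <- extract_sequence(genome, exons$chrom[ok3], exons$start[ok3],
                               exons$end[ok3], exons$strand[ok3])
    in_seq <- extract_sequence(genome, exons$chrom[ok3], exons$up_start[ok3],
                               exons$up_end[ok3], exons$strand[ok3])
    win <- paste0(substring(in_seq, nchar(in_seq) - fl + 1, nchar(in_seq)),
                  substring(ex_seq, 1, fl))
    mfe3[ok3] <- vapply(win, junction_mfe, numeric(1), USE.NAMES = FALSE)
  }

  out <- data.frame(
    exon_id = exons$exon_id, class = NA_character_, n_bp = n_bp,
    has_2bp = has2, n_bp_strong = n_bp_strong, has_2bp_strong = has2_strong,
    u2_bonds_best = u2b, n_tna = n_tna, n_trich = n_trich,
    mfe_5ss = mfe5, mfe_3ss = mfe3, stringsAsFactors = FALSE
  )
  if (!is.null(labels)) {
    out$class <- labels$label[match(out$exon_id, labels$exon_id)]
  }
  out
}

#' Read an external branch-point call table
#'
#' @param path TSV with columns exon_id, offset, score.
#' @return data.frame suitable for `bp_calls` in [exon_feature_table()].
#' @export
read_bp_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("exon_id", "offset", "score")
  if (!all(need %in% names(df))) {
    stop("branch-point table must have columns: ", paste(need, collapse = ", "))
  }
  df[need]
}
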