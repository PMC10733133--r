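# Scoring windows by microdissected-chromosome (WGA) evidence: the
# uniqueness filter on multimapped alignments, mappability-normalized
# coverage breadth, and the square-root score that corroborates L-class
# windows.

#' Enumerate candidate placements of WGA reads on the reference
#'
#' Synthetic stand-in for a multi-mapping aligner: every candidate locus of
#' each fragment (by known origin and shared-sequence analysis) yields two
#' read placements (one per mate), with 0 edits.
#'
#' @param wga a `read_set` from [simulate_wga_library()].
#' @param sub the `subgenome_set`.
#' @param ref the `reference_assembly`.
#' @return data.frame (read, scaffold, pos, end, edits, n_hits).
#' @export
wga_alignments <- function(wga, sub, ref) {
  tr <- wga$truth
  rl <- wga$params$read_length
  # candidate loci are determined per mate (each read maps by its own
  # 100-bp sequence, not by the whole fragment)
  mates <- rbind(
    data.frame(read = paste0(tr$read_id, "/1"), copy = tr$copy, hap = tr$hap,
               chrom = tr$chrom, frag_start = tr$frag_start,
               frag_end = tr$frag_start + rl - 1L, flipped = FALSE),
    data.frame(read = paste0(tr$read_id, "/2"), copy = tr$copy, hap = tr$hap,
               chrom = tr$chrom, frag_start = tr$frag_end - rl + 1L,
               frag_end = tr$frag_end, flipped = FALSE))
  pseudo <- wga
  pseudo$truth <- cbind(read_id = mates$read,
                        mates[, c("copy", "hap", "chrom", "frag_start",
                                  "frag_end", "flipped")])
  pl <- place_fragments(pseudo, sub, ref, mode = "all")
  if (!nrow(pl))
    return(data.frame(read = character(0), scaffold = character(0),
                      pos = integer(0), end = integer(0), edits = integer(0),
                      n_hits = integer(0)))
  out <- data.frame(read = pseudo$truth$read_id[pl$frag],
                    scaffold = pl$scaffold, pos = pl$start, end = pl$end,
                    edits = 0L, n_hits = pl$n_candidates,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Uniqueness filter for multimapped WGA alignments
#'
#' A read is retained when, after dropping placements with more than
#' `max_edits` edits, it has between 1 and `max_hits` placements and all of
#' them lie on a single scaffold. All placements of retained reads are
#' returned (any of them marks its span covered).
#'
#' @param alignments data.frame (read, scaffold, pos, end, edits, ...),
#'   e.g. from [wga_alignments()] or an external SAM-derived table.
#' @param max_hits maximum number of placements (default 10).
#' @param max_edits maximum edits per placement (default 1).
#' @return the retained placements.
#' @export
filter_unique_alignments <- function(alignments, max_hits = 10L,
                                     max_edits = 1L) {
  a <- alignments[alignments$edits <= max_edits, , drop = FALSE]
  if (!nrow(a)) return(a[0, , drop = FALSE])
  per <- split(seq_len(nrow(a)), a$read)
  keep <- unlist(lapply(per, function(i) {
    if (length(i) < 1 || length(i) > max_hits) return(integer(0))
    if (length(unique(a$scaffold[i])) != 1) return(integer(0))
    i
  }), use.names = FALSE)
  out <- a[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' WGA score per genomic window
#'
#' Breadth of coverage by retained reads over scaffold-specific
#' (mappability 1) positions, normalized by the number of such positions
#' in the window and square-root transformed to spread near-zero values.
#' Windows with no mappable positions are undefined (NA).
#'
#' @param retained retained placements from [filter_unique_alignments()].
#' @param mappability tracks from [scaffold_mappability()].
#' @param windows output of [make_windows()].
#' @return numeric vector of scores in [0, 1] (or NA), one per window.
#' @export
wga_window_score <- function(retained, mappability, windows) {
  out <- rep(NA_real_, nrow(windows))
  for (sc in unique(windows$scaffold)) {
    wi <- which(windows$scaffold == sc)
    L <- max(windows$end[wi])
    p <- retained[retained$scaffold == sc, , drop = FALSE]
    cov <- if (nrow(p)) {
      as.integer(IRanges::coverage(
        IRanges::IRanges(start = pmax(p$pos, 1L), end = pmin(p$end, L)),
        width = L)) > 0
    } else rep(FALSE, L)
    m <- mappability[[sc]]
    mp <- rep(FALSE, L)
    if (!is.null(m) && length(m)) mp[seq_along(m)] <- m == 1L
    for (k in wi) {
      i <- windows$start[k]:windows$end[k]
      nm <- sum(mp[i])
      out[k] <- if (nm > 0) sqrt(sum(cov[i] & mp[i]) / nm) else NA_real_
    }
  }
  out
}

#' Concordance of WGA scores with window classes
#'
#' Per class: mean score, fraction of windows with a positive score; plus a
#' rank-based effect size (the probability that a random L window outscores
#' a random S window) and the share of positive-score windows that are
#' L-class. S-class windows with positive scores (unexpected under a pure
#' L-derived library) are listed separately.
#'
#' @param scores output of [wga_window_score()].
#' @param wt a classified [window_table()].
#' @return list: `per_class`, `auc_L_vs_S`, `positive_L_fraction`,
#'   `unexpected_S` (indices), `no_signal` flag.
#' @export
wga_class_concordance <- function(scores, wt) {
  cls <- wt$class
  ok <- !is.na(scores)
  per <- do.call(rbind, lapply(split(which(ok), cls[ok]), function(i)
    data.frame(class = cls[i[1]], n = length(i),
               mean_score = mean(scores[i]),
               frac_positive = mean(scores[i] > 0))))
  rownames(per) <- NULL
  sL <- scores[ok & cls == "L"]; sS <- scores[ok & cls == "S"]
  auc <- if (length(sL) && length(sS)) {
    r <- rank(c(sL, sS))
    (sum(r[seq_along(sL)]) - length(sL) * (length(sL) + 1) / 2) /
      (length(sL) * length(sS))
  } else NA_real_
  pos <- which(ok & scores > 0)
  list(per_class = per,
       auc_L_vs_S = auc,
       positive_L_fraction = if (length(pos)) mean(cls[pos] == "L") else NA_real_,
       unexpected_S = pos[cls[pos] == "S"],
       no_signal = !any(scores[ok] > 0))
}
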