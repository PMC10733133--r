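# Window-level evidence: known-origin placement of simulated fragments on
# the reference (the synthetic stand-in for an external mapper), fragment
# counts and base depth per fixed-size window, median-of-ratios depth
# normalization, and the two log-ratio metrics (read-coverage RRC and
# subgenome-specific k-mer RKC).

#' Non-overlapping genomic windows over a reference
#'
#' @param scaffold_lengths named integer vector.
#' @param window window size in bp (default 5000).
#' @param min_tail windows shorter than this (scaffold tails) are flagged
#'   `short` and excluded from rank statistics downstream.
#' @return data.frame (scaffold, start, end, width, short).
#' @export
make_windows <- function(scaffold_lengths, window = 5000L,
                         min_tail = window %/% 2L) {
  out <- lapply(names(scaffold_lengths), function(sc) {
    L <- scaffold_lengths[[sc]]
    start <- seq(1L, L, by = window)
    end <- pmin(start + window - 1L, L)
    data.frame(scaffold = sc, start = start, end = end,
               width = end - start + 1L, stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, out)
  w$short <- w$width < min_tail
  w$window_id <- seq_len(nrow(w))
  w
}

#' Place simulated fragments on the reference by known origin
#'
#' The synthetic substitute for an external read mapper: each fragment is
#' assigned to the reference locus of its true origin, except that
#' fragments whose sequence is identical across several haplovariants
#' (no distinguishing variant within the fragment span) are distributed
#' among the homologous loci — uniformly sampled (`mode = "sample"`, one
#' locus per fragment, mass-conserving) or enumerated (`mode = "all"`,
#' one row per candidate locus). Fragments from a collapsed region whose
#' own haplovariant is absent from the reference are lifted to the
#' retained homolog. Sequencing errors do not affect placement.
#'
#' @param reads a `read_set` (its `truth` table is used).
#' @param sub the `subgenome_set` the reads were simulated from.
#' @param ref the `reference_assembly`.
#' @param mode `"sample"` or `"all"`.
#' @param seed RNG seed for the sampled mode.
#' @return data.frame (frag, scaffold, start, end, n_candidates).
#' @export
place_fragments <- function(reads, sub, ref, mode = c("sample", "all"),
                            seed = sub$params$seed + 4L) {
  mode <- match.arg(mode)
  set.seed(seed)
  tr <- reads$truth
  if (!nrow(tr))
    return(data.frame(frag = integer(0), scaffold = character(0),
                      start = integer(0), end = integer(0),
                      n_candidates = integer(0)))
  n <- nrow(tr)

  # fragment spans on the common s coordinate system
  flip1 <- flip_chain(sub$alignments$s_L1)  # L1 -> s
  flip2 <- flip_chain(sub$alignments$s_L2)
  s_start <- s_end <- integer(n)
  for (hap in unique(tr$hap)) {
    idx <- which(tr$hap == hap)
    if (hap == "s") {
      off <- sub$s_offsets[tr$chrom[idx]]
      s_start[idx] <- off + tr$frag_start[idx] - 1L
      s_end[idx] <- off + tr$frag_end[idx] - 1L
    } else {
      ch <- if (hap == "L1") flip1 else flip2
      s_start[idx] <- as.integer(project_t2q(ch, tr$frag_start[idx]))
      s_end[idx] <- as.integer(project_t2q(ch, tr$frag_end[idx]))
    }
  }

  # distinguishing variants per branch, on s coordinates
  v <- sub$variants
  vpos <- function(branch) sort(v$pos[v$branch == branch])
  n_in_span <- function(pos) {
    if (!length(pos)) return(integer(n))
    findInterval(s_end, pos) - findInterval(s_start - 1L, pos)
  }
  n_sh <- n_in_span(vpos("shared"))
  n_p1 <- n_in_span(vpos("L1"))
  n_p2 <- n_in_span(vpos("L2"))

  # candidate haplovariants: the origin plus every haplovariant whose
  # sequence over the span is indistinguishable from the origin's
  cand <- matrix(FALSE, n, 3, dimnames = list(NULL, c("S", "L1", "L2")))
  o <- tr$hap
  cand[cbind(seq_len(n), match(ifelse(o == "s", "S", o),
                               c("S", "L1", "L2")))] <- TRUE
  cand[, "S"] <- cand[, "S"] |
    (o == "L1" & n_sh + n_p1 == 0L) | (o == "L2" & n_sh + n_p2 == 0L)
  cand[, "L1"] <- cand[, "L1"] |
    (o == "s" & n_sh + n_p1 == 0L) | (o == "L2" & n_p1 + n_p2 == 0L)
  cand[, "L2"] <- cand[, "L2"] |
    (o == "s" & n_sh + n_p2 == 0L) | (o == "L1" & n_p1 + n_p2 == 0L)

  # positions of the span start on each haplovariant's own coordinates
  hap_pos <- matrix(NA_integer_, n, 3, dimnames = list(NULL, c("S", "L1", "L2")))
  hap_pos[, "S"] <- s_start
  hap_pos[, "L1"] <- as.integer(project_t2q(sub$alignments$s_L1, s_start))
  hap_pos[, "L2"] <- as.integer(project_t2q(sub$alignments$s_L2, s_start))
  span <- tr$frag_end - tr$frag_start + 1L

  # candidate reference loci from the composition table
  comp <- ref$composition
  rows <- vector("list", 3L)
  for (ci in 1:3) {
    hap <- c("S", "L1", "L2")[ci]
    sel <- which(cand[, hap] & !is.na(hap_pos[, hap]))
    if (!length(sel)) next
    pieces <- comp[comp$src_hap == hap, , drop = FALSE]
    if (!nrow(pieces)) next
    found <- vector("list", nrow(pieces))
    for (pi in seq_len(nrow(pieces))) {
      p <- pieces[pi, ]
      pos_h <- hap_pos[sel, hap]
      chrom_ok <- if (hap == "S") {
        # src coordinates of S pieces are chromosome-local
        loc <- pos_h - sub$s_offsets[p$src_chrom] + 1L
        loc >= p$src_start & loc + span[sel] - 1L <= p$src_end
      } else {
        pos_h >= p$src_start & pos_h + span[sel] - 1L <= p$src_end
      }
      hit <- which(chrom_ok)
      if (!length(hit)) next
      loc_start <- if (hap == "S") {
        hap_pos[sel[hit], hap] - sub$s_offsets[p$src_chrom] + 1L
      } else hap_pos[sel[hit], hap]
      found[[pi]] <- data.frame(
        frag = sel[hit], scaffold = p$scaffold,
        start = p$ref_start + (loc_start - p$src_start),
        stringsAsFactors = FALSE)
    }
    rows[[ci]] <- do.call(rbind, found)
  }
  all_cand <- do.call(rbind, rows)
  if (is.null(all_cand) || !nrow(all_cand))
    return(data.frame(frag = integer(0), scaffold = character(0),
                      start = integer(0), end = integer(0),
                      n_candidates = integer(0)))
  # fragments from collapsed regions: origin locus missing -> lift L2<->L1
  missing <- setdiff(seq_len(n), unique(all_cand$frag))
  if (length(missing)) {
    lifted <- lift_collapsed(missing, tr, hap_pos, span, sub, comp)
    if (!is.null(lifted)) all_cand <- rbind(all_cand, lifted)
  }
  ncand <- table(factor(all_cand$frag, levels = seq_len(n)))
  all_cand$n_candidates <- as.integer(ncand[as.character(all_cand$frag)])
  all_cand$end <- all_cand$start + span[all_cand$frag] - 1L
  if (mode == "all") {
    rownames(all_cand) <- NULL
    return(all_cand[order(all_cand$frag), ])
  }
  # sample one locus per fragment
  all_cand <- all_cand[order(all_cand$frag, runif(nrow(all_cand))), ]
  picked <- all_cand[!duplicated(all_cand$frag), ]
  rownames(picked) <- NULL
  picked
}

# fragments whose own locus is absent (collapsed): map L1<->L2 through the
# truth alignment and retry on the homolog's pieces
lift_collapsed <- function(missing, tr, hap_pos, span, sub, comp) {
  out <- list()
  for (hap in c("L1", "L2")) {
    idx <- missing[tr$hap[missing] == hap]
    if (!length(idx)) next
    other <- if (hap == "L1") "L2" else "L1"
    pos_o <- hap_pos[idx, other]
    pieces <- comp[comp$src_hap == other, , drop = FALSE]
    for (pi in seq_len(nrow(pieces))) {
      p <- pieces[pi, ]
      hit <- which(pos_o >= p$src_start & pos_o + span[idx] - 1L <= p$src_end)
      if (!length(hit)) next
      out[[length(out) + 1]] <- data.frame(
        frag = idx[hit], scaffold = p$scaffold,
        start = p$ref_start + (pos_o[hit] - p$src_start),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Fragment counts per genomic window
#'
#' Each placed fragment is counted in the window containing its start.
#'
#' @param placements output of [place_fragments()] (or any data.frame with
#'   scaffold and start columns).
#' @param windows output of [make_windows()].
#' @return integer vector of counts, one per window row.
#' @export
window_counts <- function(placements, windows) {
  counts <- integer(nrow(windows))
  if (!nrow(placements)) return(counts)
  if (!all(placements$scaffold %in% windows$scaffold))
    stop("window_counts: placements reference scaffolds absent from the window grid")
  for (sc in unique(placements$scaffold)) {
    wi <- which(windows$scaffold == sc)
    p <- placements$start[placements$scaffold == sc]
    bin <- findInterval(p, windows$start[wi])
    tab <- tabulate(bin, nbins = length(wi))
    counts[wi] <- counts[wi] + tab
  }
  counts
}

#' Fragment counts per arbitrary disjoint intervals
#'
#' Like [window_counts()] but for any set of disjoint intervals per
#' scaffold (e.g. paralogous-block member intervals); a fragment is counted
#' in the interval containing its start.
#'
#' @param placements output of [place_fragments()].
#' @param intervals data.frame (scaffold, start, end), disjoint per scaffold.
#' @return the `intervals` table with a `count` column.
#' @export
count_fragments_per_interval <- function(placements, intervals) {
  intervals$count <- 0
  for (sc in unique(intervals$scaffold)) {
    ii <- which(intervals$scaffold == sc)
    o <- order(intervals$start[ii])
    p <- placements$start[placements$scaffold == sc]
    if (!length(p)) next
    bin <- findInterval(p, intervals$start[ii][o])
    keep <- bin >= 1
    tab <- tabulate(bin[keep], nbins = length(ii))
    intervals$count[ii[o]] <- tab
  }
  intervals
}

#' Mean per-base depth per window, optionally over masked positions
#'
#' @param placements output of [place_fragments()].
#' @param windows output of [make_windows()].
#' @param mask optional named list (per scaffold) of 0/1 integer vectors;
#'   when given, depth is averaged over mask==1 positions only and windows
#'   without masked positions get NA.
#' @return numeric vector of mean depths, one per window.
#' @export
window_depth <- function(placements, windows, mask = NULL) {
  out <- rep(NA_real_, nrow(windows))
  for (sc in unique(windows$scaffold)) {
    wi <- which(windows$scaffold == sc)
    L <- max(windows$end[wi])
    p <- placements[placements$scaffold == sc, , drop = FALSE]
    cov <- if (nrow(p)) {
      as.integer(IRanges::coverage(
        IRanges::IRanges(start = p$start, end = pmin(p$end, L)), width = L))
    } else integer(L)
    m <- if (is.null(mask)) rep(1L, L) else {
      mm <- mask[[sc]]
      if (length(mm) < L) mm <- c(mm, rep(0L, L - length(mm)))
      mm[seq_len(L)]
    }
    for (k in wi) {
      i <- windows$start[k]:windows$end[k]
      sel <- m[i] == 1L
      out[k] <- if (any(sel)) mean(cov[i][sel]) else NA_real_
    }
  }
  out
}

#' Coverage contrast between S- and L-class windows at unique positions
#'
#' Demonstrates that the multimapping compression of the S : L coverage
#' contrast disappears when only reference positions whose K-mer occurs
#' once genome-wide are counted: places the reads (known-origin engine),
#' masks multimappable positions, computes the mean per-window depth over
#' the remaining positions, and reports the ratio of the kernel-density
#' modes of the S-truth and L-truth window depth distributions.
#'
#' @param reads a `read_set` (e.g. the disomic-line library).
#' @param sub the `subgenome_set`.
#' @param ref the `reference_assembly` (error-free composition expected for
#'   a clean truth split).
#' @param K uniqueness window length (default 100).
#' @param window window size (default 5000).
#' @param seed placement seed.
#' @return list with `ratio`, `mode_S`, `mode_L` and the window table.
#' @export
unique_position_coverage_ratio <- function(reads, sub, ref, K = 100L,
                                           window = 5000L,
                                           seed = sub$params$seed + 5L) {
  lens <- vapply(ref$scaffolds, nchar, integer(1))
  wins <- make_windows(lens, window)
  mask <- genome_unique_positions(ref$scaffolds, K)
  pl <- place_fragments(reads, sub, ref, "sample", seed = seed)
  depth <- window_depth(pl, wins, mask)
  src <- setNames(ref$composition$src_hap, ref$composition$scaffold)
  truth <- ifelse(src[wins$scaffold] == "S", "S", "L")
  ok <- !is.na(depth) & !wins$short
  kde_mode <- function(x) {
    d <- density(x)
    d$x[which.max(d$y)]
  }
  mode_S <- kde_mode(depth[ok & truth == "S"])
  mode_L <- kde_mode(depth[ok & truth == "L"])
  list(ratio = mode_S / mode_L, mode_S = mode_S, mode_L = mode_L,
       windows = cbind(wins, depth = depth, truth = truth))
}

#' Median-of-ratios normalization of two window count vectors
#'
#' Size factors are medians of count / geometric-mean ratios over the
#' windows in the upper (S) coverage mode of library A, so the S peak is
#' centred at ratio 1 after normalization.
#'
#' @param covA,covB window counts of the two libraries.
#' @return list with `size_factors`, `normA`, `normB`, `s_mode` (logical).
#' @export
normalize_median_of_ratios <- function(covA, covB) {
  ok <- covA > 0 & covB > 0
  if (sum(ok) < 100)
    stop("normalize_median_of_ratios: need >= 100 windows with counts in both libraries")
  if (all(covA == 0) || all(covB == 0))
    stop("normalize_median_of_ratios: all-zero library")
  # upper mode of the A coverage distribution
  la <- log2(covA[ok])
  d <- density(la)
  dm <- which(diff(sign(diff(d$y))) == -2) + 1
  dm <- dm[d$y[dm] > 0.1 * max(d$y)]
  s_mode <- ok
  if (length(dm) >= 2) {
    m2 <- sort(d$x[dm[order(-d$y[dm])][1:2]])
    midpoint <- mean(m2)
    s_mode <- ok & log2(pmax(covA, 1e-9)) > midpoint
  }
  geo <- sqrt(as.numeric(covA) * as.numeric(covB))
  sfA <- median(covA[s_mode] / geo[s_mode])
  sfB <- median(covB[s_mode] / geo[s_mode])
  list(size_factors = c(A = sfA, B = sfB),
       normA = covA / sfA, normB = covB / sfB, s_mode = s_mode)
}

#' Centred log2 read-coverage ratio (RRC)
#'
#' log2(normA / normB), centred at the midpoint between the summits of the
#' two kernel-density modes, so that the sign separates S- from L-class
#' windows. Windows with a zero count on either side are flagged and
#' excluded from centring.
#'
#' @param normA,normB normalized window counts.
#' @return list with `log2_rrc` (centred; NA where undefined), `center`,
#'   `modes` and `bimodal`.
#' @export
compute_rrc <- function(normA, normB) {
  raw <- ifelse(normA > 0 & normB > 0, log2(normA / normB), NA_real_)
  fin <- raw[is.finite(raw)]
  d <- density(fin)
  dm <- which(diff(sign(diff(d$y))) == -2) + 1
  dm <- dm[d$y[dm] > 0.1 * max(d$y)]
  if (length(dm) >= 2) {
    top2 <- sort(d$x[dm[order(-d$y[dm])][1:2]])
    center <- mean(top2)
    bimodal <- TRUE
  } else {
    warning("compute_rrc: coverage ratio distribution not bimodal; centring at the median")
    top2 <- rep(median(fin), 2)
    center <- median(fin)
    bimodal <- FALSE
  }
  list(log2_rrc = raw - center, center = center, modes = top2,
       bimodal = bimodal)
}

#' Log2 ratio of subgenome-specific k-mer counts (RKC)
#'
#' Counts are normalized by each subset's total mapped k-mers; zero
#' denominators give signed infinity, and windows with both counts zero
#' are undefined (NA, later unclassified).
#'
#' @param kS,kL per-window counts of S- and L-specific k-mer matches.
#' @param totS,totL totals of mapped k-mers per subset (defaults: sums).
#' @return numeric vector (may contain +/-Inf and NA).
#' @export
compute_rkc <- function(kS, kL, totS = sum(kS), totL = sum(kL)) {
  nS <- kS / totS
  nL <- kL / totL
  out <- log2(nS / nL)
  out[kS == 0 & kL == 0] <- NA_real_
  out[kS > 0 & kL == 0] <- Inf
  out[kS == 0 & kL > 0] <- -Inf
  out
}

#' Exact-match counts of a k-mer subset per window
#'
#' Positions of the reference whose canonical k-mer belongs to the subset,
#' tallied per window (exact matching only).
#'
#' @param subset a `kmer_table` (e.g. one label from [extract_subset()]).
#' @param ref_seqs named character vector of scaffold sequences.
#' @param windows output of [make_windows()].
#' @return integer vector of counts per window.
#' @export
window_kmer_counts <- function(subset, ref_seqs, windows) {
  hits <- cpp_ref_kmer_hits(unname(ref_seqs), subset$k,
                            subset$w0, subset$w1, subset$w2)
  df <- data.frame(scaffold = names(ref_seqs)[hits$seq], start = hits$pos)
  window_counts(df, windows)
}
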