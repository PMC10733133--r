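# Synthetic haploid reference assembly: by default the exact concatenation
# of the S chromosomes, L1 and L2, tiled into scaffolds; optional injected
# assembly errors emulate the failure modes of real polyploid assemblies
# (collapsed or expanded haplovariants, chimeric scaffolds).

#' Assemble a synthetic haploid reference from a subgenome set
#'
#' @param sub a `subgenome_set` from [simulate_subgenomes()].
#' @param params a [sim_params()] object (defaults to the one in `sub`);
#'   `collapse_rate`, `expand_rate`, `chimera_rate` and `scaffold_length`
#'   are used here.
#' @param seed optional RNG seed override for the error processes.
#' @return an object of class `reference_assembly`: named scaffold
#'   sequences and a `composition` truth table with one row per scaffold
#'   piece (`scaffold`, `part`, `ref_start`, `ref_end`, `src_hap`,
#'   `src_chrom`, `src_start`, `src_end`, `flag`).
#' @export
assemble_reference <- function(sub, params = sub$params, seed = params$seed + 1L) {
  set.seed(seed)
  segs <- tile_sources(sub, params$scaffold_length)

  # collapse: drop the L2 counterpart of an L1 segment
  if (params$collapse_rate > 0) {
    l1 <- which(segs$src_hap == "L1")
    hit <- l1[runif(length(l1)) < params$collapse_rate]
    for (i in hit) {
      j <- which(segs$src_hap == "L2" & segs$seg_idx == segs$seg_idx[i])
      if (length(j) == 1) {
        segs <- segs[-j, , drop = FALSE]
        segs$flag[segs$src_hap == "L1" &
                  segs$seg_idx == segs$seg_idx[i]] <- "collapsed"
      }
    }
    rownames(segs) <- NULL
  }
  # expansion: duplicate a segment
  if (params$expand_rate > 0) {
    hit <- which(runif(nrow(segs)) < params$expand_rate)
    if (length(hit)) {
      dup <- segs[hit, , drop = FALSE]
      dup$flag <- "expanded"
      segs <- rbind(segs, dup)
    }
  }
  # chimerism: pair selected segments from different haplotype classes and
  # swap their second halves
  segs$partner <- NA_integer_
  if (params$chimera_rate > 0) {
    cand <- which(runif(nrow(segs)) < params$chimera_rate & segs$len >= 4)
    cand <- sample(cand)
    used <- logical(nrow(segs))
    for (i in cand) {
      if (used[i]) next
      mate <- cand[!used[cand] & cand != i &
                     segs$src_hap[cand] != segs$src_hap[i]]
      if (!length(mate)) next
      m <- mate[1]
      segs$partner[i] <- m; segs$partner[m] <- i
      used[i] <- TRUE; used[m] <- TRUE
    }
  }

  seqs <- c(sub$haplotypes$s, sub$haplotypes$L1, sub$haplotypes$L2)
  piece_seq <- function(row) substring(seqs[[row$src_chrom]], row$src_start,
                                       row$src_end)
  scaffolds <- character(0)
  comp <- list()
  for (i in seq_len(nrow(segs))) {
    name <- sprintf("scaffold_%03d", i)
    r <- segs[i, ]
    if (!is.na(r$partner)) {
      m <- segs[r$partner, ]
      cut_r <- r$src_start + r$len %/% 2 - 1L
      cut_m <- m$src_start + m$len %/% 2 - 1L
      seq1 <- substring(seqs[[r$src_chrom]], r$src_start, cut_r)
      seq2 <- substring(seqs[[m$src_chrom]], cut_m + 1L, m$src_end)
      scaffolds[name] <- paste0(seq1, seq2)
      comp[[length(comp) + 1]] <- data.frame(
        scaffold = name, part = 1:2,
        ref_start = c(1L, nchar(seq1) + 1L),
        ref_end = c(nchar(seq1), nchar(seq1) + nchar(seq2)),
        src_hap = c(r$src_hap, m$src_hap),
        src_chrom = c(r$src_chrom, m$src_chrom),
        src_start = c(r$src_start, cut_m + 1L),
        src_end = c(cut_r, m$src_end), flag = "chimeric")
    } else {
      scaffolds[name] <- piece_seq(r)
      comp[[length(comp) + 1]] <- data.frame(
        scaffold = name, part = 1L, ref_start = 1L, ref_end = r$len,
        src_hap = r$src_hap, src_chrom = r$src_chrom,
        src_start = r$src_start, src_end = r$src_end, flag = r$flag)
    }
  }
  comp <- do.call(rbind, comp)
  if (!length(scaffolds)) stop("assemble_reference: empty reference")
  structure(list(scaffolds = scaffolds, composition = comp,
                 params = params),
            class = "reference_assembly")
}

# Tile every chromosome of every haplotype into scaffold-sized segments.
# seg_idx pairs up homologous L1/L2 segments (same ordinal tile).
tile_sources <- function(sub, scaffold_length) {
  out <- list()
  for (hap in c("s", "L1", "L2")) {
    chroms <- sub$haplotypes[[hap]]
    hapname <- if (hap == "s") "S" else hap
    for (cn in names(chroms)) {
      len <- nchar(chroms[[cn]])
      n_seg <- max(1L, round(len / scaffold_length))
      bounds <- round(seq(0, len, length.out = n_seg + 1))
      for (k in seq_len(n_seg)) {
        out[[length(out) + 1]] <- data.frame(
          src_hap = hapname, src_chrom = cn,
          src_start = bounds[k] + 1L, src_end = bounds[k + 1],
          len = bounds[k + 1] - bounds[k], seg_idx = k, flag = "normal")
      }
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Lift the pairwise truth alignments onto the reference scaffolds
#'
#' Produces the self-homology chains of the synthetic reference: for each
#' pair of scaffold pieces originating from homologous haplotypes, the
#' corresponding slice of the truth alignment, in scaffold-local
#' coordinates. This substitutes for an external self-aligner when running
#' the paralogous-block analysis on synthetic data.
#'
#' @param sub a `subgenome_set`.
#' @param ref a `reference_assembly` built from `sub`.
#' @return list of [chain_alignment()] objects between reference scaffolds.
#' @export
reference_truth_chains <- function(sub, ref) {
  comp <- ref$composition
  # piece coordinates on the common s scale (approximate for L1/L2 ends is
  # not acceptable here: we clip the exact chains instead)
  lens <- vapply(ref$scaffolds, nchar, integer(1))
  pieces <- comp
  pieces$id <- seq_len(nrow(pieces))
  # map haplotype-pair -> truth chain with that pair's coordinates
  get_chain <- function(hapA, hapB) {
    key <- paste(sort(c(hapA, hapB)), collapse = "_")
    if (key == "L1_L2") return(sub$alignments$L1_L2)
    if (key == "L1_S") return(s_chain_for(sub, "s_L1"))
    if (key == "L2_S") return(s_chain_for(sub, "s_L2"))
    NULL
  }
  out <- list()
  for (i in seq_len(nrow(pieces))) {
    for (j in seq_len(nrow(pieces))) {
      if (j <= i) next
      pi <- pieces[i, ]; pj <- pieces[j, ]
      if (pi$src_hap == pj$src_hap) {
        # expanded duplicates: identical source intervals align end-to-end
        ov <- interval_intersect(pi$src_start, pi$src_end, pj$src_start, pj$src_end)
        if (pi$src_chrom == pj$src_chrom && !is.null(ov)) {
          len <- ov[2] - ov[1] + 1L
          blocks <- data.frame(
            tstart = ov[1] - pi$src_start + pi$ref_start,
            qstart = ov[1] - pj$src_start + pj$ref_start, len = len)
          out[[length(out) + 1]] <- chain_alignment(
            pi$scaffold, pj$scaffold, lens[[pi$scaffold]],
            lens[[pj$scaffold]], blocks)
        }
        next
      }
      ch <- get_chain(pi$src_hap, pj$src_hap)
      if (is.null(ch)) next
      # orient: chain target must be pi's haplotype
      tgt_hap <- if (ch$target == "s") "S" else ch$target
      if (tgt_hap != pi$src_hap) { tmp <- pi; pi <- pj; pj <- tmp }
      sub_ch <- clip_chain_both(ch, pi, pj, sub)
      if (is.null(sub_ch)) next
      b <- sub_ch$blocks
      toff <- piece_t_offset(pi, sub)
      b$tstart <- b$tstart - toff + pi$ref_start
      qoff <- piece_t_offset(pj, sub)
      b$qstart <- b$qstart - qoff + pj$ref_start
      out[[length(out) + 1]] <- chain_alignment(
        pi$scaffold, pj$scaffold, lens[[pi$scaffold]], lens[[pj$scaffold]], b)
    }
  }
  out
}

# chain s->L expressed with target coordinates on the full s sequence
s_chain_for <- function(sub, pair) sub$alignments[[pair]]

# offset of a piece's source interval on its chain coordinate system:
# for S pieces the chain target is the full s, so add the chromosome offset.
piece_t_offset <- function(piece, sub) {
  if (piece$src_hap == "S")
    sub$s_offsets[[piece$src_chrom]] + piece$src_start - 1L
  else piece$src_start
}

interval_intersect <- function(a1, a2, b1, b2) {
  lo <- max(a1, b1); hi <- min(a2, b2)
  if (lo > hi) NULL else c(lo, hi)
}

# Clip a chain to the (chain-coordinate) source intervals of two pieces:
# target side to pi, query side to pj.
clip_chain_both <- function(ch, pi, pj, sub) {
  tlo <- piece_t_offset(pi, sub)
  thi <- tlo + (pi$src_end - pi$src_start)
  cl <- clip_chain_target(ch, tlo, thi)
  if (is.null(cl)) return(NULL)
  qlo <- piece_t_offset(pj, sub)
  qhi <- qlo + (pj$src_end - pj$src_start)
  cl2 <- clip_chain_target(flip_chain(cl), qlo, qhi)
  if (is.null(cl2)) return(NULL)
  flip_chain(cl2)
}
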