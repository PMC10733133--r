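# Synthetic three-subgenome generator. An ancestral sequence s is the
# common scaffold; L1 and L2 are derived from it under a star phylogeny
# with one shared (s -> L ancestor) branch and two private branches, so
# both pairwise divergence targets are simultaneously achievable:
#   P(s != Li)  ~ a + b   and   P(L1 != L2) ~ 2 b
# with a = div_SL - div_L1L2/2 and b = div_L1L2/2.
# Every mutation event is recorded, and exact truth alignments (gapless
# blocks split at injected indels) are built alongside the sequences.

#' Simulate the S / L1 / L2 subgenome set
#'
#' Draws an ancestral sequence uniformly over A/C/G/T, partitions it into
#' small chromosomes for the S subgenome, and derives the two haplovariants
#' L1 and L2 of the fused chromosome by per-site substitution and indel
#' processes whose expected pairwise divergences match `div_SL` and
#' `div_L1L2`. Ground-truth variant lists and pairwise truth alignments are
#' returned with the sequences.
#'
#' @param params a [sim_params()] object.
#' @param seed optional override of `params$seed`.
#' @return an object of class `subgenome_set`: sequences per haplotype,
#'   `variants` (branch, position on s, type, alleles), and `alignments`
#'   (truth chains for the pairs s-L1, s-L2, L1-L2 in full-s coordinates).
#' @export
simulate_subgenomes <- function(params, seed = params$seed) {
  validate_sim_params(params)
  set.seed(seed)
  L <- params$ancestral_length
  s_chars <- sample(DNA_BASES, L, replace = TRUE)
  if (params$repeat_fraction > 0) {
    unit <- sample(DNA_BASES, 50, replace = TRUE)
    rep_len <- round(params$repeat_fraction * L)
    start <- sample.int(L - rep_len, 1)
    s_chars[start:(start + rep_len - 1)] <-
      rep_len_out <- rep(unit, length.out = rep_len)
  }

  a <- params$div_SL - params$div_L1L2 / 2
  b <- params$div_L1L2 / 2

  subs_at <- function(rate, ref_chars) {
    pos <- which(runif(L) < rate)
    data.frame(pos = pos, ref = ref_chars[pos],
               alt = if (length(pos)) mutate_base(ref_chars[pos]) else character(0),
               stringsAsFactors = FALSE)
  }
  sub_sh <- subs_at(a, s_chars)
  anc_L <- s_chars
  anc_L[sub_sh$pos] <- sub_sh$alt
  sub_1 <- subs_at(b, anc_L)
  sub_2 <- subs_at(b, anc_L)
  sub_S2 <- subs_at(params$het_S, s_chars)

  indels <- draw_indels(params, L)

  variants <- rbind(
    var_rows("shared", sub_sh, "sub"), var_rows("L1", sub_1, "sub"),
    var_rows("L2", sub_2, "sub"), var_rows("S2", sub_S2, "sub"),
    indels)
  if (is.null(variants))
    variants <- data.frame(branch = character(0), pos = integer(0),
                           type = character(0), ref = character(0),
                           alt = character(0), len = integer(0))
  variants <- variants[order(variants$pos), , drop = FALSE]
  rownames(variants) <- NULL

  ev <- function(branches, types = c("sub", "ins", "del")) {
    variants[variants$branch %in% branches & variants$type %in% types, ,
             drop = FALSE]
  }
  d1 <- apply_edits(s_chars, ev(c("shared", "L1")))
  d2 <- apply_edits(s_chars, ev(c("shared", "L2")))
  al12 <- compose_L1_L2(variants, L, nchar(d1$seq), nchar(d2$seq))

  n_chr <- params$n_small_chromosomes
  bounds <- round(seq(0, L, length.out = n_chr + 1))
  s_offsets <- bounds[-(n_chr + 1)] + 1L
  s_lens <- diff(bounds)
  s_full <- paste(s_chars, collapse = "")
  s_seqs <- setNames(substring(s_full, s_offsets, s_offsets + s_lens - 1L),
                     paste0("S", seq_len(n_chr)))
  s2_full <- NULL
  if (params$het_S > 0) {
    x <- s_chars; x[sub_S2$pos] <- sub_S2$alt
    s2_full <- paste(x, collapse = "")
  }

  structure(list(
    haplotypes = list(s = s_seqs, L1 = c(L1 = d1$seq), L2 = c(L2 = d2$seq)),
    s_full = s_full, s2_full = s2_full,
    s_offsets = setNames(s_offsets, names(s_seqs)),
    variants = variants,
    alignments = list(
      s_L1 = chain_alignment("s", "L1", L, nchar(d1$seq), d1$blocks),
      s_L2 = chain_alignment("s", "L2", L, nchar(d2$seq), d2$blocks),
      L1_L2 = al12),
    params = params, seed = seed), class = "subgenome_set")
}

var_rows <- function(branch, df, type) {
  if (!nrow(df)) return(NULL)
  data.frame(branch = branch, pos = df$pos, type = type, ref = df$ref,
             alt = df$alt, len = 1L, stringsAsFactors = FALSE)
}

# Indel events on the shared and private branches; positions kept mutually
# separated (and clear of the sequence ends) so truth chains are unambiguous.
draw_indels <- function(params, L) {
  half <- params$indel_rate / 2
  rows <- list()
  for (br in c("shared", "L1", "L2")) {
    n <- rbinom(1, L, half)
    if (n == 0) next
    len <- rgeom(n, params$indel_length_p) + 1L
    type <- sample(c("ins", "del"), n, replace = TRUE)
    pos <- sample(seq(params$read_length + 10L, L - params$read_length - 10L),
                  n)
    alt <- ifelse(type == "ins",
                  vapply(len, random_dna, character(1)), "")
    rows[[br]] <- data.frame(branch = br, pos = pos, type = type,
                             ref = "", alt = alt, len = as.integer(len),
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, rows)
  df <- df[order(df$pos), , drop = FALSE]
  # greedy separation: keep an event only if it is clear of the last kept one
  keep <- logical(nrow(df))
  last_end <- -Inf
  for (i in seq_len(nrow(df))) {
    if (df$pos[i] > last_end + 10) {
      keep[i] <- TRUE
      last_end <- df$pos[i] + df$len[i]
    }
  }
  df[keep, , drop = FALSE]
}

# Apply substitution + indel events (on s coordinates) to the ancestral
# character vector; returns the derived sequence and the gapless truth
# blocks of the alignment s (target) vs derived (query).
apply_edits <- function(s_chars, events) {
  x <- s_chars
  subs <- events[events$type == "sub", , drop = FALSE]
  if (nrow(subs)) x[subs$pos] <- subs$alt
  ind <- events[events$type != "sub", , drop = FALSE]
  ind <- ind[order(ind$pos), , drop = FALSE]
  L <- length(s_chars)
  pieces <- character(0)
  blocks <- list()
  cur_s <- 1L; cur_d <- 1L
  add_block <- function(ts, qs, len) {
    if (len > 0) blocks[[length(blocks) + 1]] <<-
        data.frame(tstart = ts, qstart = qs, len = len)
  }
  for (i in seq_len(nrow(ind))) {
    p <- ind$pos[i]; d <- ind$len[i]
    if (ind$type[i] == "del") {
      seg <- p - cur_s
      add_block(cur_s, cur_d, seg)
      if (seg > 0) pieces <- c(pieces, paste(x[cur_s:(p - 1L)], collapse = ""))
      cur_d <- cur_d + seg
      cur_s <- p + d
    } else { # insertion after s[p]
      seg <- p - cur_s + 1L
      add_block(cur_s, cur_d, seg)
      pieces <- c(pieces, paste(x[cur_s:p], collapse = ""), ind$alt[i])
      cur_d <- cur_d + seg + d
      cur_s <- p + 1L
    }
  }
  seg <- L - cur_s + 1L
  add_block(cur_s, cur_d, seg)
  if (seg > 0) pieces <- c(pieces, paste(x[cur_s:L], collapse = ""))
  list(seq = paste(pieces, collapse = ""), blocks = do.call(rbind, blocks))
}

# Truth alignment between the two derived haplotypes: walk the union of
# indel events on s; shared indels are common to both haplotypes (aligned),
# private indels open gaps. Adjacent blocks left contiguous by shared
# deletions are merged by normalize_chains().
compose_L1_L2 <- function(variants, L, len1, len2) {
  ind <- variants[variants$type != "sub", , drop = FALSE]
  ind <- ind[order(ind$pos), , drop = FALSE]
  blocks <- list()
  cur_s <- 1L; c1 <- 1L; c2 <- 1L
  add <- function(t1, q2, len) {
    if (len > 0) blocks[[length(blocks) + 1]] <<-
        data.frame(tstart = t1, qstart = q2, len = len)
  }
  for (i in seq_len(nrow(ind))) {
    p <- ind$pos[i]; d <- ind$len[i]; br <- ind$branch[i]; ty <- ind$type[i]
    if (ty == "ins") {
      seg <- p - cur_s + 1L
      add(c1, c2, seg); c1 <- c1 + seg; c2 <- c2 + seg; cur_s <- p + 1L
      if (br == "shared") { add(c1, c2, d); c1 <- c1 + d; c2 <- c2 + d }
      else if (br == "L1") c1 <- c1 + d
      else if (br == "L2") c2 <- c2 + d
    } else { # deletion of s[p .. p+d-1]
      seg <- p - cur_s
      add(c1, c2, seg); c1 <- c1 + seg; c2 <- c2 + seg; cur_s <- p + d
      if (br == "L1") c2 <- c2 + d
      else if (br == "L2") c1 <- c1 + d
      # shared deletion: both skip; blocks stay contiguous and merge later
    }
  }
  add(c1, c2, L - cur_s + 1L)
  ch <- chain_alignment("L1", "L2", len1, len2, do.call(rbind, blocks))
  normalize_chains(ch)
}

#' Realized pairwise SNP divergence from truth alignments
#'
#' Mismatch fraction over aligned columns of the truth alignment of a pair,
#' computed directly from the emitted sequences.
#'
#' @param sub a `subgenome_set`.
#' @param pair one of `"s_L1"`, `"s_L2"`, `"L1_L2"`.
#' @return a list with `mismatches`, `columns` and `divergence`.
#' @export
pairwise_divergence <- function(sub, pair = c("s_L1", "s_L2", "L1_L2")) {
  pair <- match.arg(pair)
  ch <- sub$alignments[[pair]]
  tseq <- if (ch$target == "s") sub$s_full else sub$haplotypes[[ch$target]][[1]]
  qseq <- sub$haplotypes[[ch$query]][[1]]
  mc <- cpp_count_mismatches(tseq, qseq, ch$blocks$tstart - 1L,
                             ch$blocks$qstart - 1L, ch$blocks$len,
                             ch$strand == "-")
  list(mismatches = mc[1], columns = mc[2], divergence = mc[1] / mc[2])
}

#' Serialize the truth alignments of a subgenome set as PSL
#'
#' Each pairwise truth alignment becomes one PSL record per chromosome pair
#' (the s-side chains are split at the S chromosome boundaries), with
#' gapless blocks split exactly at the injected indels and match/mismatch
#' counts recomputed from the sequences. The records round-trip losslessly
#' through [read_psl()].
#'
#' @param sub a `subgenome_set`.
#' @param path optional output PSL file.
#' @return the list of `chain_alignment` records, invisibly if written.
#' @export
emit_truth_chains <- function(sub, path = NULL) {
  chains <- list()
  lens <- nchar(sub$haplotypes$s)
  for (pair in c("s_L1", "s_L2")) {
    full <- sub$alignments[[pair]]
    for (i in seq_along(sub$s_offsets)) {
      off <- sub$s_offsets[[i]]
      hi <- off + lens[[i]] - 1L
      cl <- clip_chain_target(full, off, hi)
      if (is.null(cl)) next
      b <- cl$blocks
      b$tstart <- b$tstart - off + 1L
      chains[[length(chains) + 1]] <- chain_alignment(
        names(sub$s_offsets)[i], full$query, lens[[i]], full$qsize, b)
    }
  }
  chains[[length(chains) + 1]] <- sub$alignments$L1_L2
  seqs <- c(sub$haplotypes$s, sub$haplotypes$L1, sub$haplotypes$L2)
  # recompute match counts against per-chromosome sequences
  if (!is.null(path)) {
    write_psl(chains, path, sequences = as.list(seqs))
    return(invisible(chains))
  }
  chains
}
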