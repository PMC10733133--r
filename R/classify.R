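# Subgenome classification of windows, scaffolds and paralogous blocks
# from the combined coverage-ratio and k-mer evidence.

#' Assemble the per-window evidence table
#'
#' Convenience constructor: normalizes the two coverage vectors
#' (median-of-ratios), computes the centred log2 read-coverage ratio and
#' the log2 S/L k-mer-count ratio, and returns one table.
#'
#' @param windows output of [make_windows()].
#' @param covA,covB raw fragment counts per window (disomic / tetrasomic
#'   library).
#' @param kS,kL per-window S- and L-specific k-mer counts.
#' @return data.frame of class `window_table`.
#' @export
window_table <- function(windows, covA, covB, kS, kL) {
  norm <- normalize_median_of_ratios(covA, covB)
  rrc <- compute_rrc(norm$normA, norm$normB)
  wt <- cbind(windows,
              covA = covA, covB = covB,
              normA = norm$normA, normB = norm$normB,
              kS = kS, kL = kL,
              log2_RRC = rrc$log2_rrc,
              log2_RKC = compute_rkc(kS, kL))
  attr(wt, "size_factors") <- norm$size_factors
  attr(wt, "rrc_center") <- rrc$center
  attr(wt, "rrc_modes") <- rrc$modes
  class(wt) <- c("window_table", class(wt))
  wt
}

#' Classify genomic windows into subgenome classes S and L
#'
#' The decision rule: S-class windows must be in the top `rank_frac_s`
#' windows ranked by S-specific k-mer coverage, have `log2_RKC >=
#' rkc_threshold` and positive `log2_RRC`; L-class windows must be in the
#' top `rank_frac_l` windows ranked by L-specific k-mer coverage, have
#' `log2_RKC <= -rkc_threshold` and negative `log2_RRC`. Everything else
#' (including short scaffold-tail windows, which are excluded from the
#' ranking) is unclassified. Windows with infinite `log2_RKC` participate
#' through their sign.
#'
#' @param wt a [window_table()].
#' @param rkc_threshold absolute log2 RKC threshold (default 1).
#' @param rank_frac_s,rank_frac_l rank fractions (defaults 1/3 and 2/3).
#' @return the table with a `class` column (`"S"`, `"L"`, `"unclassified"`).
#' @export
classify_windows <- function(wt, rkc_threshold = 1,
                             rank_frac_s = 1 / 3, rank_frac_l = 2 / 3) {
  n_rank <- sum(!wt$short)
  rank_s <- rank(-wt$kS, ties.method = "first")
  rank_l <- rank(-wt$kL, ties.method = "first")
  in_top_s <- !wt$short & rank_s <= ceiling(rank_frac_s * n_rank)
  in_top_l <- !wt$short & rank_l <= ceiling(rank_frac_l * n_rank)
  rkc <- wt$log2_RKC
  rrc <- wt$log2_RRC
  is_s <- in_top_s & !is.na(rkc) & rkc >= rkc_threshold &
    !is.na(rrc) & rrc > 0
  is_l <- in_top_l & !is.na(rkc) & rkc <= -rkc_threshold &
    !is.na(rrc) & rrc < 0
  wt$class <- ifelse(is_s, "S", ifelse(is_l, "L", "unclassified"))
  wt
}

#' Classify scaffolds from their window classes
#'
#' A scaffold is S (or L) when at least `min_frac` of its classified
#' windows carry that class and the minority class has fewer than
#' `min_chimera` windows; it is chimeric when both classes have at least
#' `min_chimera` windows; scaffolds without classified windows are
#' unclassified.
#'
#' @param wt a classified [window_table()] (after [classify_windows()]).
#' @param min_frac majority fraction required for a pure class.
#' @param min_chimera minimum windows of each class for a chimera call.
#' @return list with `scaffolds` (scaffold, length, class, n_S, n_L) and
#'   `summary` (per class: n, total length).
#' @export
classify_scaffolds <- function(wt, min_frac = 0.9, min_chimera = 2L) {
  per <- split(wt, wt$scaffold)
  rows <- lapply(per, function(df) {
    n_s <- sum(df$class == "S"); n_l <- sum(df$class == "L")
    ncl <- n_s + n_l
    cls <- if (n_s >= min_chimera && n_l >= min_chimera) "chimeric"
    else if (ncl == 0) "unclassified"
    else if (n_s / ncl >= min_frac && n_l < min_chimera) "S"
    else if (n_l / ncl >= min_frac && n_s < min_chimera) "L"
    else "unclassified"
    data.frame(scaffold = df$scaffold[1], length = sum(df$width),
               class = cls, n_S = n_s, n_L = n_l, n_windows = nrow(df),
               stringsAsFactors = FALSE)
  })
  sc <- do.call(rbind, rows)
  rownames(sc) <- NULL
  summary <- do.call(rbind, lapply(split(sc, sc$class), function(d)
    data.frame(class = d$class[1], n = nrow(d), length = sum(d$length))))
  rownames(summary) <- NULL
  list(scaffolds = sc, summary = summary)
}

#' Compare subgenome divergences over strictly selected PB triplets
#'
#' Keeps 3-copy paralogous blocks whose members all lie in nonchimeric
#' classified scaffolds with exactly one S and two L members, and reports
#' the mean SNP rate and length-weighted divergence separately for the two
#' S-L pairs and the L-L pair, with seeded bootstrap confidence intervals.
#' With a synthetic `reference_assembly` the two L members are labelled L1
#' and L2 from the composition truth; otherwise the pair is reported as
#' "L-L".
#'
#' @param pbs a `paralogous_blocks` object.
#' @param scaffold_classes the `scaffolds` table from [classify_scaffolds()].
#' @param sequences named vector/list of scaffold sequences.
#' @param ref optional `reference_assembly` for truth L1/L2 labels.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @return list with `triplets` (per-PB, per-pair rates), `summary`
#'   (pair type, mean rates, CIs) and `ratio` (S-L over L-L SNP rate).
#' @export
classify_blocks <- function(pbs, scaffold_classes, sequences, ref = NULL,
                            n_boot = 1000L, seed = 1L) {
  cls <- setNames(scaffold_classes$class, scaffold_classes$scaffold)
  rows <- list()
  for (pb in pbs$blocks) {
    if (pb$copy_number != 3) next
    mcls <- cls[pb$members$scaffold]
    if (any(is.na(mcls)) || any(!mcls %in% c("S", "L"))) next
    if (sum(mcls == "S") != 1 || sum(mcls == "L") != 2) next
    hap <- if (!is.null(ref)) member_src_hap(pb$members, ref) else
      ifelse(mcls == "S", "S", "L")
    for (key in names(pb$pair_chains)) {
      e <- pb$pair_chains[[key]]
      ch <- e$chain
      ia <- match(ch$target, pb$members$scaffold)
      ib <- match(ch$query, pb$members$scaffold)
      pair <- paste(sort(c(hap[ia], hap[ib])), collapse = "-")
      type <- if (all(c(hap[ia], hap[ib]) %in% c("L", "L1", "L2"))) "L-L"
              else "S-L"
      st <- pair_rates(ch, sequences, pb)
      rows[[length(rows) + 1]] <- data.frame(
        block = pb$id, pair = pair, type = type,
        snp_rate = st$snp_rate,
        length_weighted_divergence = st$length_weighted_divergence,
        aligned = sum(ch$blocks$len), stringsAsFactors = FALSE)
    }
  }
  triplets <- if (length(rows)) do.call(rbind, rows) else
    data.frame(block = character(0), pair = character(0), type = character(0),
               snp_rate = numeric(0), length_weighted_divergence = numeric(0),
               aligned = numeric(0))
  set.seed(seed)
  summ <- do.call(rbind, lapply(split(triplets, triplets$type), function(d) {
    boot <- replicate(n_boot, {
      i <- sample.int(nrow(d), replace = TRUE)
      c(mean(d$snp_rate[i]), mean(d$length_weighted_divergence[i]))
    })
    data.frame(type = d$type[1], n_pairs = nrow(d),
               snp_rate = mean(d$snp_rate),
               snp_ci_lo = quantile(boot[1, ], 0.025),
               snp_ci_hi = quantile(boot[1, ], 0.975),
               length_weighted_divergence = mean(d$length_weighted_divergence),
               lw_ci_lo = quantile(boot[2, ], 0.025),
               lw_ci_hi = quantile(boot[2, ], 0.975))
  }))
  rownames(summ) <- NULL
  ratio <- if (all(c("S-L", "L-L") %in% summ$type))
    summ$snp_rate[summ$type == "S-L"] / summ$snp_rate[summ$type == "L-L"]
  else NA_real_
  list(triplets = triplets, summary = summ, ratio = ratio)
}

# majority source haplotype of each member interval, from the composition
member_src_hap <- function(members, ref) {
  comp <- ref$composition
  vapply(seq_len(nrow(members)), function(i) {
    p <- comp[comp$scaffold == members$scaffold[i] &
                comp$ref_start <= members$end[i] &
                comp$ref_end >= members$start[i], , drop = FALSE]
    if (!nrow(p)) return(NA_character_)
    ov <- pmin(p$ref_end, members$end[i]) - pmax(p$ref_start, members$start[i])
    p$src_hap[which.max(ov)]
  }, character(1))
}

#' Write classified windows as BED
#'
#' Name is the class; score is 1000 * |log2 RKC| capped at 1000.
#' @param wt a classified [window_table()].
#' @param path output file.
#' @export
write_window_bed <- function(wt, path) {
  score <- pmin(1000, round(1000 * abs(ifelse(is.finite(wt$log2_RKC),
                                              wt$log2_RKC, 1))))
  score[is.na(score)] <- 0
  write.table(data.frame(wt$scaffold, wt$start - 1L, wt$end, wt$class,
                         score, "+"),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
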