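# Closed-form expectations used to interpret the joint spectrum and the
# window coverage: which multiplicity pairs the peak lattice can contain,
# and how multimapping compresses the coverage contrast between subgenome
# classes.

#' Expected peak multiplicity pairs of a two-configuration design
#'
#' A k-mer present in exactly the subset U of haplovariants appears at
#' frequency proportional to (copies of U in configuration A, copies in B).
#' Enumerates all non-empty haplovariant subsets and returns the
#' deduplicated multiplicity pairs; pairs with a zero coordinate
#' (configuration-specific k-mers) are retained and flagged.
#'
#' @param configA,configB character vectors of haplotype labels (repeats =
#'   extra copies), e.g. `c("s","s","L1","L2")`.
#' @return data.frame (multA, multB, config_specific), sorted.
#' @export
expected_peak_multiplicities <- function(configA, configB) {
  alphabet <- sort(unique(c(configA, configB)))
  nA <- vapply(alphabet, function(h) sum(configA == h), integer(1))
  nB <- vapply(alphabet, function(h) sum(configB == h), integer(1))
  n <- length(alphabet)
  pairs <- list()
  for (mask in seq_len(2^n - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    pairs[[mask]] <- c(sum(nA[sel]), sum(nB[sel]))
  }
  df <- unique(do.call(rbind, pairs))
  out <- data.frame(multA = df[, 1], multB = df[, 2])
  out$config_specific <- out$multA == 0 | out$multB == 0
  out <- out[order(out$multA, out$multB), ]
  rownames(out) <- NULL
  out
}

#' Expected coverage ratio between S- and L-class loci under multimapping
#'
#' A fraction `f` of reads is equally similar to all haplovariants and is
#' placed uniformly on the reference copies (placement probability `1/R`
#' per locus for `R` reference copies); the rest map uniquely to their
#' locus of origin. Origin probabilities follow the copy numbers of the
#' sample configuration. Returns the expected per-window coverage of
#' S-class and L-class loci (in units of per-copy depth) and their ratio.
#'
#' @param reference_config haplovariant labels present in the reference
#'   (one locus each), default `c("s","L1","L2")`.
#' @param sample_config copy configuration of the sequenced line, default
#'   `c("s","s","L1","L2")`.
#' @param f fraction of fully shared (multimapping) reads, in [0, 1].
#' @return list with `ratio`, `cov_S`, `cov_L`, `placement_prob` (1/R) and
#'   `origin_probs` (per haplovariant of the sample).
#' @export
expected_mapping_bias <- function(reference_config = c("s", "L1", "L2"),
                                  sample_config = c("s", "s", "L1", "L2"),
                                  f = 0) {
  if (f < 0 || f > 1) stop("expected_mapping_bias: f must be in [0, 1]")
  refs <- unique(reference_config)
  R <- length(refs)
  total <- length(sample_config)
  n <- vapply(refs, function(h) sum(sample_config == h), numeric(1))
  # per-locus expected coverage in units of per-copy depth
  cov <- f * total / R + (1 - f) * n
  names(cov) <- refs
  s_loci <- refs == "s"
  cov_S <- mean(cov[s_loci])
  cov_L <- mean(cov[!s_loci])
  list(ratio = cov_S / cov_L, cov_S = cov_S, cov_L = cov_L,
       placement_prob = 1 / R,
       origin_probs = setNames(n / total, refs))
}
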