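#' Simulation parameters for the synthetic three-subgenome design
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study design the pipeline was built for: a diploid homozygous
#' subgenome S plus two haplovariants L1/L2 of a fused chromosome, with
#' pairwise SNP divergences of 1.6% (S vs either L) and 1.4% (L1 vs L2),
#' 100-bp paired reads at 12-fold coverage per genome copy, and a whole
#' genome amplification library covering about 1% of its target chromosome.
#'
#' @param seed integer seed controlling every stochastic generator.
#' @param ancestral_length length (bp) of the ancestral sequence s.
#' @param n_small_chromosomes number of small chromosomes the S subgenome is
#'   partitioned into.
#' @param div_SL expected SNP divergence (substitutions/site) between s and
#'   each of L1, L2.
#' @param div_L1L2 expected SNP divergence between L1 and L2. Must satisfy
#'   `div_L1L2 <= 2 * div_SL` (star-phylogeny feasibility).
#' @param het_S within-copy heterozygosity of the S subgenome (default 0:
#'   the two S copies are identical).
#' @param indel_rate indel events per site per haplotype pair (split evenly
#'   between the shared s-to-L branch and the private branches).
#' @param indel_length_p geometric parameter of the indel length
#'   distribution; mean length is `1/indel_length_p`.
#' @param read_length read length (bp).
#' @param insert_mean,insert_sd fragment (insert) size distribution (bp).
#' @param error_rate per-base substitution error rate of simulated reads.
#' @param depth_per_copy sequencing depth (fold base coverage, both mates)
#'   contributed by each genome copy. The default of 50 puts the per-copy
#'   depth of the counted k-mer data (first mates only) at about 16.5,
#'   the regime in which the joint spectrum resolves the full five-peak
#'   lattice; much below that, the Poisson widths of neighbouring
#'   multiplicity clouds merge.
#' @param collapse_rate probability per L1 reference segment that its L2
#'   counterpart is dropped (assembly collapse).
#' @param expand_rate probability per reference segment of being duplicated.
#' @param chimera_rate probability per reference segment of being spliced
#'   with a segment from another subgenome (chimeric scaffold).
#' @param scaffold_length target scaffold length (bp) of the synthetic
#'   reference assembly.
#' @param wga_breadth fraction of the target chromosome covered by the
#'   simulated whole-genome-amplification library.
#' @param wga_sites number of amplification seed loci.
#' @param wga_lognormal_sd log-sd of the per-site amplification factors
#'   (0 gives even amplification).
#' @param repeat_fraction optional fraction of the ancestral sequence made
#'   of a seeded tandem repeat (off by default; no repeat annotation is
#'   performed downstream).
#'
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(seed = 1L,
                       ancestral_length = 500000L,
                       n_small_chromosomes = 3L,
                       div_SL = 0.016,
                       div_L1L2 = 0.014,
                       het_S = 0,
                       indel_rate = 1e-4,
                       indel_length_p = 0.4,
                       read_length = 100L,
                       insert_mean = 350,
                       insert_sd = 50,
                       error_rate = 0.001,
                       depth_per_copy = 50,
                       collapse_rate = 0,
                       expand_rate = 0,
                       chimera_rate = 0,
                       scaffold_length = 25000L,
                       wga_breadth = 0.01,
                       wga_sites = 30L,
                       wga_lognormal_sd = 1.5,
                       repeat_fraction = 0) {
  p <- list(
    seed = as.integer(seed),
    ancestral_length = as.integer(ancestral_length),
    n_small_chromosomes = as.integer(n_small_chromosomes),
    div_SL = div_SL, div_L1L2 = div_L1L2, het_S = het_S,
    indel_rate = indel_rate, indel_length_p = indel_length_p,
    read_length = as.integer(read_length),
    insert_mean = insert_mean, insert_sd = insert_sd,
    error_rate = error_rate, depth_per_copy = depth_per_copy,
    collapse_rate = collapse_rate, expand_rate = expand_rate,
    chimera_rate = chimera_rate,
    scaffold_length = as.integer(scaffold_length),
    wga_breadth = wga_breadth, wga_sites = as.integer(wga_sites),
    wga_lognormal_sd = wga_lognormal_sd,
    repeat_fraction = repeat_fraction
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  rates <- c("div_SL", "div_L1L2", "het_S", "indel_rate", "indel_length_p",
             "error_rate", "collapse_rate", "expand_rate", "chimera_rate",
             "wga_breadth", "repeat_fraction")
  for (r in rates) {
    if (!is.numeric(p[[r]]) || p[[r]] < 0 || p[[r]] > 1)
      stop(sprintf("sim_params: '%s' must be a rate in [0, 1]", r))
  }
  if (p$div_L1L2 > 2 * p$div_SL)
    stop("sim_params: infeasible divergence targets (div_L1L2 > 2 * div_SL)")
  if (p$ancestral_length < 10 * p$read_length)
    stop("sim_params: ancestral_length must be >= 10 * read_length")
  if (p$depth_per_copy < 0) stop("sim_params: depth_per_copy must be >= 0")
  if (p$n_small_chromosomes < 1) stop("sim_params: need >= 1 small chromosome")
  if (p$indel_length_p <= 0) stop("sim_params: indel_length_p must be > 0")
  invisible(p)
}

#' Serialize simulation parameters to JSON
#' @param params a `sim_params` object.
#' @param path optional output file; if `NULL`, the JSON string is returned.
#' @export
write_sim_params <- function(params, path = NULL) {
  js <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read simulation parameters from JSON
#' @param path JSON file written by [write_sim_params()].
#' @export
read_sim_params <- function(path) {
  do.call(sim_params, jsonlite::fromJSON(path))
}
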