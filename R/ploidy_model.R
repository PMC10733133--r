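# Joint tetraploid/hexaploid k-mer spectrum model. Each marginal spectrum
# is a negative-binomial mixture with components at means j * kmercov
# (j = 1..p); heterozygosity enters through per-site rates of allele-class
# topologies, converted to k-mer scale as rho_t = 1 - (1 - r_t)^k under the
# standard at-most-one-heterozygous-site-per-k-mer approximation. The two
# spectra share one parameter vector: the tetraploid topology rates are
# fixed combinations of the hexaploid ones, with proportion parameters
# eps1/eps2 distributing the one-subgenome-differs classes.

# Canonical topology order. r1..r8 of the hexaploid model bind to these
# partitions (class sizes of p homologous copies); the two topologies with
# 5+ distinct alleles (aabcde, abcdef) are omitted because at most 4
# allelic states can coexist in the studied genome.
HEXAPLOID_TOPOLOGIES <- list(
  aaaaab = c(5, 1), aaaabb = c(4, 2), aaabbb = c(3, 3),
  aaaabc = c(4, 1, 1), aaabbc = c(3, 2, 1), aabbcc = c(2, 2, 2),
  aaabcd = c(3, 1, 1, 1), aabbcd = c(2, 2, 1, 1))

TETRAPLOID_TOPOLOGIES <- list(
  aaab = c(3, 1), aabb = c(2, 2), aabc = c(2, 1, 1), abcd = c(1, 1, 1, 1))

topologies_for <- function(p) {
  switch(as.character(p), "4" = TETRAPLOID_TOPOLOGIES,
         "6" = HEXAPLOID_TOPOLOGIES,
         stop("ploidy must be 4 or 6"))
}

#' Component weights of the polyploid k-mer spectrum mixture
#'
#' A topology with per-site rate r and class sizes (c1..cm) contributes,
#' at k-mer scale rho = 1 - (1 - r)^k, weight rho to each component cj
#' (one distinct k-mer per allele class); the homozygous remainder
#' 1 - sum(rho) sits at component p.
#'
#' @param p ploidy (4 or 6).
#' @param rates per-site topology rates, in the canonical order.
#' @param k k-mer size.
#' @return numeric vector of weights for components 1..p.
#' @export
spectrum_weights <- function(p, rates, k) {
  topo <- topologies_for(p)
  if (length(rates) != length(topo))
    stop("spectrum_weights: expected ", length(topo), " rates for p = ", p)
  if (any(rates < 0)) stop("spectrum_weights: negative rate")
  rho <- 1 - (1 - rates)^k
  if (sum(rho) > 1)
    stop("spectrum_weights: k-mer-scale topology rates exceed 1")
  w <- numeric(p)
  for (t in seq_along(topo)) {
    for (cj in topo[[t]]) w[cj] <- w[cj] + rho[t]
  }
  w[p] <- w[p] + (1 - sum(rho))
  w
}

#' Expected marginal k-mer spectrum of a polyploid
#'
#' Mixture of negative binomials at means `j * kmercov` with size
#' `j * kmercov / bias` (so `bias -> 0` approaches Poisson), weighted by
#' [spectrum_weights()] and scaled by `length`. A nonzero duplication rate
#' `d` moves that fraction of the homozygous weight to component `2 p`.
#'
#' @param p ploidy (4 or 6).
#' @param rates per-site topology rates (canonical order).
#' @param k k-mer size.
#' @param kmercov per-copy (haploid) k-mer depth.
#' @param bias overdispersion (> 0).
#' @param d duplication rate (default 0).
#' @param x integer frequency grid.
#' @param length genome length scale (number of distinct k-mer loci).
#' @return expected number of distinct k-mers at each frequency in `x`.
#' @export
predict_marginal_spectrum <- function(p, rates, k, kmercov, bias, d = 0, x,
                                      length = 1) {
  if (kmercov <= 0) stop("predict_marginal_spectrum: kmercov must be > 0")
  if (any(x <= 0)) stop("predict_marginal_spectrum: frequencies must be positive")
  w <- spectrum_weights(p, rates, k)
  comps <- seq_len(p)
  if (d > 0) {
    w <- c(w, d * w[p])
    w[p] <- (1 - d) * w[p]
    comps <- c(comps, 2L * p)
  }
  y <- numeric(base::length(x))
  for (i in seq_along(comps)) {
    j <- comps[i]
    mu <- j * kmercov
    size <- j * kmercov / max(bias, 1e-8)
    y <- y + w[i] * dnbinom(x, mu = mu, size = size)
  }
  length * y
}

#' Tetraploid topology rates from hexaploid parameters
#'
#' The shared-parameter remap of the joint model: the disomic-line
#' (tetraploid-configuration) topology rates (aaab, aabb, aabc, abcd) are
#' `(r1 + eps1 r2 + eps2 r3, (1 - eps1) r2 + (1 - eps2) r3, r4 + r5 + r6,
#' r7 + r8)`. The proportions eps1/eps2 say which fraction of the
#' one-subgenome-differs (and 3+3) hexaploid classes collapses to a
#' single-copy difference in the tetraploid configuration.
#'
#' @param rates hexaploid rates r1..r8 (canonical order).
#' @param eps1,eps2 proportions in [0, 1].
#' @return the four tetraploid rates.
#' @export
remap_tetraploid_params <- function(rates, eps1, eps2) {
  stopifnot(length(rates) == 8)
  if (eps1 < 0 || eps1 > 1 || eps2 < 0 || eps2 > 1)
    stop("remap_tetraploid_params: eps must be in [0, 1]")
  r <- as.numeric(rates)
  c(aaab = r[1] + eps1 * r[2] + eps2 * r[3],
    aabb = (1 - eps1) * r[2] + (1 - eps2) * r[3],
    aabc = r[4] + r[5] + r[6],
    abcd = r[7] + r[8])
}
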