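# Joint nonlinear fit of the two marginal spectra over one shared
# parameter vector, and the decomposition of fitted topology rates into
# between-subgenome divergences.

#' Jointly fit the tetraploid/hexaploid spectrum model
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) on the stacked
#' frequency-weighted marginal spectra: the response at frequency x is
#' `x * y(x)`, which de-emphasizes the error-prone low-frequency tail. The
#' disomic-line spectrum (A) is modelled by the tetraploid predictor with
#' remapped rates, per-copy depth `kmercov * N` and overdispersion
#' `bias * N`; the tetrasomic-line spectrum (B) by the hexaploid predictor
#' with `kmercov` and `bias`. `N` absorbs the depth and genome-size
#' difference between the libraries and is initialized from the ratio of
#' total k-mer counts times 3/2 (the library genome sizes are 4 : 6 copies).
#'
#' @param spectrumA either a `kmer_spectrum_2d` (then both marginals and
#'   totals are taken from it) or a data.frame (freq, n_kmers) for the
#'   disomic-configuration library.
#' @param spectrumB data.frame (freq, n_kmers) for the tetrasomic library
#'   (ignored when `spectrumA` is a `kmer_spectrum_2d`).
#' @param k k-mer size (taken from the spectrum object when available).
#' @param kmercov_init optional per-copy depth candidates for the
#'   multi-start; by default three candidates are derived from the lowest
#'   mode of the B marginal.
#' @param fit_duplication fit the duplication parameters (default: held at 0).
#' @param max_freq cap on fitted frequencies (default 1.25 times the 99.9%
#'   mass quantile per axis).
#' @return an object of class `spectrum_fit`: fitted parameters, derived
#'   divergences (see [decompose_heterozygosity()]), residuals and
#'   convergence diagnostics.
#' @export
joint_fit <- function(spectrumA, spectrumB = NULL, k = 35L,
                      kmercov_init = NULL, fit_duplication = FALSE,
                      max_freq = NULL) {
  if (inherits(spectrumA, "kmer_spectrum_2d")) {
    sp <- spectrumA
    k <- sp$k
    A <- sp$marginalA; B <- sp$marginalB
    totalA <- sp$totalA; totalB <- sp$totalB
  } else {
    A <- spectrumA; B <- spectrumB
    if (is.null(B)) stop("joint_fit: spectrumB required")
    totalA <- sum(as.numeric(A$freq) * A$n_kmers)
    totalB <- sum(as.numeric(B$freq) * B$n_kmers)
  }
  cap <- function(df) {
    o <- order(df$freq)
    cw <- cumsum(as.numeric(df$n_kmers[o])) / sum(as.numeric(df$n_kmers))
    cp <- if (is.null(max_freq)) ceiling(1.25 * df$freq[o][which(cw >= 0.999)[1]])
          else max_freq
    df[df$freq <= cp, , drop = FALSE]
  }
  A <- cap(A); B <- cap(B)

  if (is.null(kmercov_init)) {
    # lowest substantial mode of the B marginal corresponds to 2 copies of
    # an L haplovariant in the tetrasomic line: kmercov ~ mode / 2
    sm <- stats::filter(B$n_kmers, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- 0
    locmax <- which(diff(sign(diff(sm))) == -2) + 1
    locmax <- locmax[sm[locmax] > 0.05 * max(sm)]
    base_mode <- if (length(locmax)) B$freq[locmax[1]] else
      B$freq[which.max(B$n_kmers)]
    # the lowest mode is 2 copies of an L haplovariant in a heterozygous
    # genome, but the 6-copy homozygous peak when divergence vanishes:
    # start from both hypotheses
    kmercov_init <- c(base_mode / 2 * c(0.8, 1, 1.25), base_mode / 6)
  }
  N_init <- totalA / totalB * 3 / 2
  len_init <- sum(as.numeric(B$n_kmers))

  yobs <- c(A$freq * as.numeric(A$n_kmers), B$freq * as.numeric(B$n_kmers))
  par_lower <- c(rates = rep(0, 8), eps1 = 0, eps2 = 0, kmercov = 0.1,
                 bias = 1e-4, N = 0.05, length = len_init * 0.2,
                 d = 0, d1 = 0)
  par_upper <- c(rates = rep(0.2, 8), eps1 = 1, eps2 = 1, kmercov = Inf,
                 bias = 5, N = 20, length = len_init * 5,
                 d = if (fit_duplication) 0.5 else 0,
                 d1 = if (fit_duplication) 0.5 else 0)

  predict_stacked <- function(par) {
    r <- par[1:8]
    tetra <- remap_tetraploid_params(r, par["eps1"], par["eps2"])
    rho4 <- sum(1 - (1 - tetra)^k); rho6 <- sum(1 - (1 - r)^k)
    if (rho4 > 1 || rho6 > 1) return(rep(1e12, length(yobs)))
    predA <- predict_marginal_spectrum(4, tetra, k,
                                       par["kmercov"] * par["N"],
                                       par["bias"] * par["N"], par["d"],
                                       A$freq, par["length"])
    predB <- predict_marginal_spectrum(6, r, k, par["kmercov"], par["bias"],
                                       par["d1"], B$freq, par["length"])
    c(A$freq * predA, B$freq * predB)
  }
  residfun <- function(par) yobs - predict_stacked(par)

  fits <- list()
  for (kc in kmercov_init) {
    par0 <- c(rep(0.002, 8), eps1 = 0.5, eps2 = 0.5, kmercov = kc,
              bias = 0.5, N = N_init, length = len_init, d = 0, d1 = 0)
    names(par0)[1:8] <- paste0("r", 1:8)
    fit <- try(minpack.lm::nls.lm(
      par = par0, lower = par_lower, upper = par_upper, fn = residfun,
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    if (!inherits(fit, "try-error")) fits[[length(fits) + 1]] <- fit
  }
  if (!length(fits))
    stop("joint_fit: no start converged; supply kmercov_init candidates")
  rss <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  best <- fits[[which.min(rss)]]
  par <- best$par
  out <- structure(list(
    params = as.list(par),
    rates = setNames(as.numeric(par[1:8]), names(HEXAPLOID_TOPOLOGIES)),
    tetraploid_rates = remap_tetraploid_params(par[1:8], par[["eps1"]],
                                               par[["eps2"]]),
    k = k, rss = min(rss), n_starts = length(kmercov_init),
    convergence = best$info, message = best$message,
    residuals = best$fvec,
    data = list(A = A, B = B, totalA = totalA, totalB = totalB),
    fitted = predict_stacked(par)), class = "spectrum_fit")
  out$divergence <- decompose_heterozygosity(out)
  out
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat("Joint tetraploid/hexaploid spectrum fit\n")
  cat(sprintf("  kmercov = %.2f  bias = %.3f  N = %.3f  rss = %.3g (%s)\n",
              x$params$kmercov, x$params$bias, x$params$N, x$rss, x$message))
  cat("  topology rates:\n")
  print(round(x$rates, 5))
  cat(sprintf("  eps1 = %.3f  eps2 = %.3f\n", x$params$eps1, x$params$eps2))
  d <- x$divergence
  cat(sprintf("  div(L1,L2) = %.4f  div(S,L) = %.4f  total = %.4f\n",
              d$div_L1L2, d$div_S_vs_L, d$total_snp_variation))
  invisible(x)
}

#' Decompose fitted heterozygosity rates into subgenome divergences
#'
#' Under the structural constraint of the two-subline design (the two S
#' copies identical, the two copies of each L haplovariant identical in the
#' tetrasomic line), the only admissible heterozygous topologies are
#' "one subgenome differs" (aaaabb, rate r2) and "all three differ"
#' (aabbcc, r6). The proportion eps1 splits r2 into L-private
#' (an L haplovariant differs; contributes to L1-L2 divergence) and
#' S-branch (S differs from both L) parts:
#' `div(L1,L2) = eps1 r2 + eps2 r3 + r6` and
#' `div(S,L) = (1 - eps1/2) r2 + (1 - eps2/2) r3 + r6`; rates on topologies
#' that cannot arise under the constraint are reported as within-copy /
#' unconstrained signal. The total SNP variation is the sum of all rates.
#'
#' @param fit a `spectrum_fit`.
#' @return list with `div_L1L2`, `div_S_vs_L`, `within_copy`,
#'   `total_snp_variation`.
#' @export
decompose_heterozygosity <- function(fit) {
  r <- fit$rates
  eps1 <- fit$params$eps1; eps2 <- fit$params$eps2
  div_L1L2 <- eps1 * r[["aaaabb"]] + eps2 * r[["aaabbb"]] + r[["aabbcc"]]
  div_SL <- (1 - eps1 / 2) * r[["aaaabb"]] + (1 - eps2 / 2) * r[["aaabbb"]] +
    r[["aabbcc"]]
  within <- sum(r[c("aaaaab", "aaaabc", "aaabbc", "aaabcd", "aabbcd")])
  list(div_L1L2 = as.numeric(div_L1L2),
       div_S_vs_L = as.numeric(div_SL),
       within_copy = as.numeric(within),
       total_snp_variation = as.numeric(sum(r)))
}

#' Plot observed vs fitted marginal spectra
#'
#' @param x a `spectrum_fit`.
#' @param ... passed to [plot()].
#' @export
plot.spectrum_fit <- function(x, ...) {
  nA <- nrow(x$data$A)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  fitA <- x$fitted[seq_len(nA)] / x$data$A$freq
  fitB <- x$fitted[-seq_len(nA)] / x$data$B$freq
  graphics::plot(x$data$A$freq, x$data$A$n_kmers, type = "h", col = "grey60",
                 xlab = "frequency (disomic line)", ylab = "distinct k-mers", ...)
  graphics::lines(x$data$A$freq, fitA, col = "red3", lwd = 2)
  graphics::plot(x$data$B$freq, x$data$B$n_kmers, type = "h", col = "grey60",
                 xlab = "frequency (tetrasomic line)", ylab = "distinct k-mers", ...)
  graphics::lines(x$data$B$freq, fitB, col = "red3", lwd = 2)
  invisible(x)
}

#' Write a fit report as JSON
#' @param fit a `spectrum_fit`.
#' @param path output file.
#' @export
write_fit_report <- function(fit, path) {
  rep <- list(parameters = fit$params, topology_rates = as.list(fit$rates),
              tetraploid_rates = as.list(fit$tetraploid_rates),
              divergence = fit$divergence, rss = fit$rss,
              convergence = fit$convergence, message = fit$message)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
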