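# Peak detection on the joint 2D spectrum. The spectrum of a genuine
# multi-subgenome genome is a lattice of clouds at integer multiples of the
# per-copy k-mer depth; peaks are local maxima of the Gaussian-smoothed
# histogram above a prominence floor, annotated with their copy
# multiplicity on each axis.

#' Detect major peaks of a joint 2D k-mer spectrum
#'
#' The 2D histogram is smoothed with a separable Gaussian kernel and local
#' maxima (8-neighbour test) with smoothed height at least
#' `prominence_frac` of the global maximum are reported. The per-copy
#' (haploid) depth is taken as the smallest detected mode on axis A;
#' multiplicities are modes divided by it, rounded. Peak mass is the number
#' of distinct k-mers nearer (in frequency space) to that peak than to any
#' other.
#'
#' @param spec a `kmer_spectrum_2d` from [joint_spectrum()].
#' @param smoothing_bandwidth Gaussian kernel sd in histogram bins.
#' @param prominence_frac prominence floor as a fraction of the global
#'   smoothed maximum.
#' @param max_freq optional histogram cap per axis; defaults to 1.25 times
#'   the 99.9% mass quantile.
#' @return data.frame (modeA, modeB, height, mass, multA, multB), sorted by
#'   mass, with the estimated haploid depth as attribute `haploid_depth`.
#' @export
find_peaks <- function(spec, smoothing_bandwidth = 1.5,
                       prominence_frac = 0.05, max_freq = NULL) {
  df <- spec$spectrum
  if (!nrow(df)) stop("find_peaks: empty spectrum")
  wq <- function(f) {
    o <- order(f)
    cw <- cumsum(as.numeric(df$n_kmers[o])) / sum(as.numeric(df$n_kmers))
    f[o][which(cw >= 0.999)[1]]
  }
  if (is.null(max_freq))
    max_freq <- ceiling(1.25 * max(wq(df$freqA), wq(df$freqB)))
  capA <- min(max(df$freqA), max_freq)
  capB <- min(max(df$freqB), max_freq)
  sel <- df$freqA <= capA & df$freqB <= capB
  M <- matrix(0, capA, capB)
  M[cbind(df$freqA[sel], df$freqB[sel])] <- df$n_kmers[sel]

  S <- gauss_smooth_2d(M, smoothing_bandwidth)
  gmax <- max(S)
  floor_h <- prominence_frac * gmax
  nr <- nrow(S); nc <- ncol(S)
  is_peak <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    h <- S[i, j]
    if (h < floor_h) next
    nb <- S[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    if (h >= max(nb) && sum(nb == h) == 1) is_peak[i, j] <- TRUE
  }
  idx <- which(is_peak, arr.ind = TRUE)
  if (!nrow(idx)) {
    warning("find_peaks: no peak above prominence floor")
    return(data.frame(modeA = integer(0), modeB = integer(0),
                      height = numeric(0), mass = numeric(0),
                      multA = integer(0), multB = integer(0)))
  }
  peaks <- data.frame(modeA = idx[, 1], modeB = idx[, 2],
                      height = S[idx])
  # mass: nearest-peak assignment of the raw histogram
  d2 <- outer(df$freqA[sel], peaks$modeA, "-")^2 +
    outer(df$freqB[sel], peaks$modeB, "-")^2
  nearest <- max.col(-d2)
  peaks$mass <- as.numeric(tapply(df$n_kmers[sel],
                                  factor(nearest, seq_len(nrow(peaks))), sum))
  peaks$mass[is.na(peaks$mass)] <- 0
  haploid <- min(peaks$modeA)
  peaks$multA <- as.integer(round(peaks$modeA / haploid))
  peaks$multB <- as.integer(round(peaks$modeB / haploid))
  peaks <- peaks[order(-peaks$mass), ]
  rownames(peaks) <- NULL
  attr(peaks, "haploid_depth") <- haploid
  peaks
}

gauss_smooth_2d <- function(M, bw) {
  if (bw <= 0) return(M)
  r <- ceiling(3 * bw)
  kern <- dnorm(-r:r, sd = bw)
  kern <- kern / sum(kern)
  pad_conv <- function(X, k) {
    # convolve each row with kernel k, zero-padded
    n <- ncol(X)
    out <- matrix(0, nrow(X), n)
    for (d in -r:r) {
      w <- k[d + r + 1]
      src <- seq_len(n) + d
      ok <- src >= 1 & src <= n
      out[, ok] <- out[, ok] + w * X[, src[ok], drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(M, kern)), kern))
}

#' Default frequency rectangles from detected peaks
#'
#' Places an S-specific rectangle around the peak with multiplicity (2, 2)
#' and L-specific rectangles around the (2, 4) and (1, 2) peaks, each
#' spanning the mode +/- `half_width` (relative). This reproduces, at any
#' sequencing depth, the role of the fixed frequency ranges used at the
#' original study's depth.
#'
#' @param peaks output of [find_peaks()].
#' @param half_width relative half-width of each rectangle.
#' @return list of [frequency_rectangle()] objects.
#' @export
rectangles_from_peaks <- function(peaks, half_width = 0.3) {
  pick <- function(mA, mB) {
    i <- which(peaks$multA == mA & peaks$multB == mB)
    if (!length(i)) return(NULL)
    peaks[i[1], ]
  }
  mk <- function(p, lab) {
    if (is.null(p)) return(NULL)
    # inward rounding keeps rectangles of different labels disjoint
    frequency_rectangle(lab,
                        ceiling(p$modeA * (1 - half_width)),
                        floor(p$modeA * (1 + half_width)),
                        ceiling(p$modeB * (1 - half_width)),
                        floor(p$modeB * (1 + half_width)))
  }
  rects <- list(mk(pick(2, 2), "S"), mk(pick(2, 4), "L"), mk(pick(1, 2), "L"))
  rects <- rects[!vapply(rects, is.null, logical(1))]
  labs <- vapply(rects, `[[`, character(1), "label")
  if (!all(c("S", "L") %in% labs))
    stop("rectangles_from_peaks: need a (2,2) peak for S and a (2,4) or ",
         "(1,2) peak for L; detected multiplicities: ",
         paste(sprintf("(%d,%d)", peaks$multA, peaks$multB), collapse = " "))
  rects
}
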