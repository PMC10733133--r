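# Canonical k-mer counting and joint 2D frequency spectra. Tables are
# 2-bit packed, canonicalized (lexicographic minimum of a k-mer and its
# reverse complement) and kept as sorted arrays; the contract is the count
# table, not the data structure.

#' Count canonical k-mers of a read set
#'
#' Every length-`k` substring of the selected reads is counted under
#' canonicalization; windows containing non-ACGT bases are skipped. By
#' default only first mates are used, which avoids double counting the
#' overlap of paired reads.
#'
#' @param reads a `read_set`, a character vector of sequences, or the path
#'   of a FASTQ file.
#' @param k odd k-mer size between 11 and 63 (default 35).
#' @param canonical count the lexicographic minimum of each k-mer and its
#'   reverse complement (default TRUE).
#' @param first_mate_only for `read_set` input, use only `read1`.
#' @param min_count drop k-mers seen fewer times (default 1 = keep all).
#' @return an object of class `kmer_table`.
#' @export
count_kmers <- function(reads, k = 35L, canonical = TRUE,
                        first_mate_only = TRUE, min_count = 1L) {
  if (k %% 2 == 0 || k < 11 || k > 63)
    stop("count_kmers: k must be odd and in [11, 63]")
  seqs <- if (inherits(reads, "read_set")) {
    if (first_mate_only) reads$read1 else c(reads$read1, reads$read2)
  } else if (is.character(reads) && length(reads) == 1 && file.exists(reads) &&
             grepl("\\.(fastq|fq)(\\.gz)?$", reads)) {
    unname(read_fastq(reads))
  } else as.character(reads)
  if (length(seqs) && all(nchar(seqs) < k))
    warning("count_kmers: all reads shorter than k; empty table")
  tab <- cpp_count_kmers(seqs, as.integer(k), canonical)
  res <- structure(list(w0 = tab$w0, w1 = tab$w1, w2 = tab$w2,
                        count = tab$count, gc = tab$gc, k = as.integer(k),
                        canonical = canonical,
                        first_mate_only = first_mate_only,
                        min_count = 1L, n_instances = tab$n_instances),
                   class = "kmer_table")
  if (min_count > 1) res <- filter_kmer_table(res, min_count)
  res
}

filter_kmer_table <- function(tab, min_count) {
  keep <- tab$count >= min_count
  tab$w0 <- tab$w0[keep]; tab$w1 <- tab$w1[keep]; tab$w2 <- tab$w2[keep]
  tab$count <- tab$count[keep]; tab$gc <- tab$gc[keep]
  tab$min_count <- as.integer(min_count)
  tab
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: %d distinct %d-mers (%s), %.0f instances, min_count=%d\n",
              length(x$count), x$k,
              if (x$canonical) "canonical" else "stranded",
              x$n_instances, x$min_count))
  invisible(x)
}

#' Distinct k-mers of a table as strings
#' @param tab a `kmer_table` (or label subset).
#' @param idx optional indices.
#' @export
kmer_strings <- function(tab, idx = seq_along(tab$w0)) {
  cpp_decode_kmers(tab$w0[idx], tab$w1[idx], tab$w2[idx], tab$k)
}

#' 1D k-mer frequency spectrum
#' @param tab a `kmer_table`.
#' @return data.frame (freq, n_kmers).
#' @export
spectrum_1d <- function(tab) {
  t1 <- table(tab$count)
  data.frame(freq = as.integer(names(t1)), n_kmers = as.integer(t1))
}

#' Joint 2D k-mer spectrum of two libraries
#'
#' Intersects two count tables after requiring at least `min_count`
#' occurrences in each, tabulates the joint frequency histogram and reports
#' the shared fraction (percentage of the union of filtered k-mer sets that
#' is in the intersection).
#'
#' @param tableA,tableB `kmer_table` objects with the same k (A is the
#'   tetraploid-configuration library by convention).
#' @param min_count per-library minimum count (default 2, which removes the
#'   bulk of erroneous k-mers).
#' @return an object of class `kmer_spectrum_2d` with elements `spectrum`
#'   (freqA, freqB, n_kmers), `marginalA`/`marginalB`, `shared_fraction`
#'   (percent) and the joint per-k-mer table.
#' @export
joint_spectrum <- function(tableA, tableB, min_count = 2L) {
  if (tableA$k != tableB$k) stop("joint_spectrum: mismatched k")
  a <- filter_kmer_table(tableA, min_count)
  b <- filter_kmer_table(tableB, min_count)
  j <- cpp_join_tables(a$w0, a$w1, a$w2, b$w0, b$w1, b$w2)
  n_int <- length(j$ia)
  n_union <- length(a$count) + length(b$count) - n_int
  freqA <- a$count[j$ia]; freqB <- b$count[j$ib]
  key <- paste(freqA, freqB)
  tt <- table(key)
  parts <- do.call(rbind, strsplit(names(tt), " "))
  spec <- data.frame(freqA = as.integer(parts[, 1]),
                     freqB = as.integer(parts[, 2]),
                     n_kmers = as.integer(tt))
  spec <- spec[order(spec$freqA, spec$freqB), ]
  rownames(spec) <- NULL
  marg <- function(f) {
    t1 <- tapply(spec$n_kmers, f, sum)
    data.frame(freq = as.integer(names(t1)), n_kmers = as.integer(t1))
  }
  structure(list(
    spectrum = spec,
    marginalA = marg(spec$freqA), marginalB = marg(spec$freqB),
    shared_fraction = 100 * n_int / n_union,
    n_intersection = n_int, n_union = n_union,
    totalA = sum(as.numeric(a$count)), totalB = sum(as.numeric(b$count)),
    joint = list(w0 = a$w0[j$ia], w1 = a$w1[j$ia], w2 = a$w2[j$ia],
                 gc = a$gc[j$ia], freqA = freqA, freqB = freqB,
                 k = tableA$k),
    k = tableA$k, min_count = as.integer(min_count)),
    class = "kmer_spectrum_2d")
}

#' @export
print.kmer_spectrum_2d <- function(x, ...) {
  cat(sprintf("kmer_spectrum_2d: k=%d, %d shared k-mers (%.2f%% of union), min_count=%d\n",
              x$k, x$n_intersection, x$shared_fraction, x$min_count))
  invisible(x)
}

#' GC-stratified k-mer spectra
#'
#' Partitions k-mers by GC fraction into bins and returns a 1D spectrum per
#' bin (diagnostic: GC-rich k-mers resolve coverage peaks more sharply).
#'
#' @param tab a `kmer_table`.
#' @param n_bins number of GC bins over [0, 1].
#' @return list with `bins` (breaks) and `spectra` (one data.frame per bin).
#' @export
gc_stratified_spectrum <- function(tab, n_bins = 5L) {
  gcf <- tab$gc / tab$k
  bin <- pmin(floor(gcf * n_bins) + 1L, n_bins)
  spectra <- lapply(seq_len(n_bins), function(bi) {
    cnt <- tab$count[bin == bi]
    if (!length(cnt)) return(data.frame(freq = integer(0), n_kmers = integer(0)))
    t1 <- table(cnt)
    data.frame(freq = as.integer(names(t1)), n_kmers = as.integer(t1))
  })
  list(bins = seq(0, 1, length.out = n_bins + 1), spectra = spectra,
       occupancy = as.integer(table(factor(bin, levels = seq_len(n_bins)))))
}

#' Frequency rectangle for subgenome-specific k-mer extraction
#'
#' @param label subset label (e.g. `"S"` or `"L"`).
#' @param loA,hiA,loB,hiB inclusive frequency bounds on the two libraries.
#' @export
frequency_rectangle <- function(label, loA, hiA, loB, hiB) {
  if (loA > hiA || loB > hiB) stop("frequency_rectangle: lo > hi")
  list(label = label, loA = loA, hiA = hiA, loB = loB, hiB = hiB)
}

#' Extract subgenome-specific k-mer subsets by frequency rectangles
#'
#' Each shared k-mer whose (freqA, freqB) falls in a rectangle is assigned
#' that rectangle's label; k-mers outside all rectangles are dropped.
#' Rectangles of different labels must be disjoint.
#'
#' @param tableA,tableB `kmer_table` objects (same k).
#' @param rectangles list of [frequency_rectangle()] objects.
#' @param min_count per-library min count used for the joint table.
#' @return named list (per label) of `kmer_table`-like subsets.
#' @export
extract_subset <- function(tableA, tableB, rectangles, min_count = 2L) {
  labs <- vapply(rectangles, `[[`, character(1), "label")
  if (length(rectangles) > 1) {
    for (i in seq_along(rectangles)) for (j in seq_along(rectangles)) {
      if (j <= i || labs[i] == labs[j]) next
      ri <- rectangles[[i]]; rj <- rectangles[[j]]
      if (ri$loA <= rj$hiA && rj$loA <= ri$hiA &&
          ri$loB <= rj$hiB && rj$loB <= ri$hiB)
        stop("extract_subset: rectangles of labels '", labs[i], "' and '",
             labs[j], "' overlap")
    }
  }
  js <- joint_spectrum(tableA, tableB, min_count)
  jt <- js$joint
  out <- list()
  for (lab in unique(labs)) {
    sel <- rep(FALSE, length(jt$freqA))
    for (r in rectangles[labs == lab]) {
      sel <- sel | (jt$freqA >= r$loA & jt$freqA <= r$hiA &
                      jt$freqB >= r$loB & jt$freqB <= r$hiB)
    }
    out[[lab]] <- structure(list(w0 = jt$w0[sel], w1 = jt$w1[sel],
                                 w2 = jt$w2[sel], count = jt$freqA[sel],
                                 gc = jt$gc[sel], k = jt$k,
                                 canonical = TRUE, first_mate_only = NA,
                                 min_count = as.integer(min_count),
                                 n_instances = NA_real_, label = lab),
                            class = "kmer_table")
  }
  out
}

#' Write a k-mer table as a two-column dump (sequence TAB count)
#' @param tab a `kmer_table`.
#' @param path output file.
#' @export
write_kmer_dump <- function(tab, path) {
  writeLines(paste(kmer_strings(tab), tab$count, sep = "\t"), path)
  invisible(path)
}

#' Read a two-column k-mer dump
#' @param path dump file (sequence TAB count).
#' @param canonical whether to canonicalize the sequences.
#' @export
read_kmer_dump <- function(path, canonical = TRUE) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("kmer", "count"),
                   stringsAsFactors = FALSE)
  k <- nchar(df$kmer[1])
  enc <- cpp_encode_kmers(df$kmer, k, canonical)
  o <- order(enc$w2, enc$w1, enc$w0)
  gc <- vapply(strsplit(df$kmer, ""), function(ch)
    sum(ch %in% c("G", "C", "g", "c")), integer(1))
  structure(list(w0 = enc$w0[o], w1 = enc$w1[o], w2 = enc$w2[o],
                 count = as.integer(df$count[o]), gc = gc[o],
                 k = as.integer(k), canonical = canonical,
                 first_mate_only = NA, min_count = 1L,
                 n_instances = sum(as.numeric(df$count))),
            class = "kmer_table")
}

#' Write a 2D spectrum as TSV (freqA, freqB, n_kmers)
#' @param spec a `kmer_spectrum_2d` (or its `spectrum` data.frame).
#' @param path output file.
#' @export
write_spectrum <- function(spec, path) {
  df <- if (inherits(spec, "kmer_spectrum_2d")) spec$spectrum else spec
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
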