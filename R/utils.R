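#' @useDynLib hexaphase, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats density dnbinom dnorm median quantile rbinom rgeom
#'   rlnorm rnorm runif sd setNames
#' @importFrom utils read.table write.table head tail
NULL

# Round half-up to `digits` decimals (printed-table convention; R's round()
# uses banker's rounding).
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement of DNA strings
#'
#' @param x character vector of DNA sequences (ACGT/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write paired reads to a pair of FASTQ files
#'
#' Files are suffixed `_1.fastq` and `_2.fastq`. Qualities are constant
#' (the simulator models errors, not quality scores).
#'
#' @param reads a read set from [simulate_reads()] or [simulate_wga_library()].
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    seqs <- reads[[paste0("read", m)]]
    ids <- paste0(reads$truth$read_id, "/", m)
    x <- Biostrings::DNAStringSet(setNames(seqs, ids))
    q <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
      paste(rep("I", n), collapse = ""), character(1)))
    Biostrings::writeXStringSet(x, paths[m], format = "fastq", qualities = q)
  }
  invisible(paths)
}

#' Read a FASTQ file into a character vector of sequences
#'
#' @param path FASTQ file.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

# Random DNA of length n using the current RNG stream.
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Substitute base: a uniformly chosen base different from `ref`.
mutate_base <- function(ref) {
  idx <- match(ref, DNA_BASES)
  DNA_BASES[((idx - 1 + sample.int(3, length(ref), replace = TRUE)) %% 4) + 1]
}
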