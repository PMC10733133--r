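# Scaffold-specific mappability tracks: per position, whether the K-mer
# starting there occurs only within its own scaffold (any number of times),
# considering both strands.

#' Scaffold-specific mappability track
#'
#' Position i of a scaffold gets 1 when the K-mer starting there occurs
#' (within the error budget E) only within that scaffold, else 0. E = 0 is
#' exact (k-mer indexing); E > 0 uses pigeonhole seeds with Hamming
#' verification (substitutions only) and is flagged approximate — intended
#' for desk-scale genomes.
#'
#' @param ref a `reference_assembly` or named character vector of sequences.
#' @param K window length (default 100).
#' @param E error budget (default 0).
#' @return named list of integer 0/1 vectors (length scaffold_length -
#'   K + 1; positions within K-1 of the end are undefined). Attributes `K`,
#'   `E`, `approximate`.
#' @export
scaffold_mappability <- function(ref, K = 100L, E = 0L) {
  seqs <- if (inherits(ref, "reference_assembly")) ref$scaffolds else ref
  short <- nchar(seqs) < K
  if (any(short))
    warning("scaffold_mappability: scaffold(s) shorter than K: ",
            paste(names(seqs)[short], collapse = ", "))
  tracks <- if (E == 0) cpp_mappability(unname(seqs), as.integer(K), "scaffold")
            else cpp_mappability_approx(unname(seqs), as.integer(K),
                                        as.integer(E), "scaffold")
  names(tracks) <- names(seqs)
  attr(tracks, "K") <- as.integer(K)
  attr(tracks, "E") <- as.integer(E)
  attr(tracks, "approximate") <- E > 0
  tracks
}

#' Genome-wide unique positions
#'
#' Positions whose K-mer occurs exactly once in the whole reference
#' (canonical, both strands) — the mask used to remove multimappable
#' positions from coverage comparisons.
#'
#' @inheritParams scaffold_mappability
#' @return named list of 0/1 integer vectors.
#' @export
genome_unique_positions <- function(ref, K = 100L) {
  seqs <- if (inherits(ref, "reference_assembly")) ref$scaffolds else ref
  tracks <- cpp_mappability(unname(seqs), as.integer(K), "unique")
  names(tracks) <- names(seqs)
  attr(tracks, "K") <- as.integer(K)
  tracks
}

#' Write a mappability track as wiggle-style TSV
#' @param tracks output of [scaffold_mappability()].
#' @param path output file.
#' @export
write_mappability <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sc in names(tracks)) {
    writeLines(sprintf("fixedStep chrom=%s start=1 step=1", sc), con)
    writeLines(as.character(tracks[[sc]]), con)
  }
  invisible(path)
}
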