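# Paired-end read simulation from an arbitrary copy configuration of the
# subgenome haplotypes, and the uneven whole-genome-amplification library.

#' Simulate paired-end reads from a copy configuration
#'
#' Draws fragments uniformly from each listed genome copy at
#' `depth_per_copy` fold base coverage (both mates together), with
#' per-base substitution errors. The two study configurations are
#' `c("s","s","L1","L2")` (disomic large chromosome) and
#' `c("s","s","L1","L1","L2","L2")` (tetrasomic).
#'
#' @param sub a `subgenome_set`.
#' @param copy_config character vector of haplotype labels in
#'   `{"s", "L1", "L2"}` (repeats denote extra copies; with
#'   `het_S > 0` the second `"s"` copy uses the heterozygous S sequence).
#' @param params a [sim_params()] object.
#' @param seed RNG seed (default derives from `params$seed`).
#' @return an object of class `read_set`: `read1`, `read2` (character
#'   vectors), and `truth` (read_id, copy, hap, chrom, frag_start,
#'   frag_end, flipped).
#' @export
simulate_reads <- function(sub, copy_config, params = sub$params,
                           seed = params$seed + 2L) {
  if (!length(copy_config)) stop("simulate_reads: empty copy configuration")
  bad <- setdiff(copy_config, c("s", "L1", "L2"))
  if (length(bad)) stop("simulate_reads: unknown haplotype label: ",
                        paste(bad, collapse = ", "))
  set.seed(seed)
  rl <- params$read_length
  truth <- list(); r1 <- list(); r2 <- list()
  n_s_seen <- 0L
  for (ci in seq_along(copy_config)) {
    hap <- copy_config[ci]
    if (hap == "s") {
      n_s_seen <- n_s_seen + 1L
      chroms <- sub$haplotypes$s
      if (n_s_seen == 2L && !is.null(sub$s2_full)) {
        # second S copy carries the within-copy heterozygous variant
        chroms <- split_like(sub$s2_full, sub$haplotypes$s, sub$s_offsets)
      }
    } else chroms <- sub$haplotypes[[hap]]
    lens <- nchar(chroms)
    n_frag <- round(params$depth_per_copy * sum(lens) / (2 * rl))
    if (n_frag == 0) next
    chrom_i <- sample.int(length(lens), n_frag, replace = TRUE,
                          prob = lens / sum(lens))
    ins <- pmax(rl, round(rnorm(n_frag, params$insert_mean, params$insert_sd)))
    ins <- pmin(ins, lens[chrom_i])
    start <- floor(runif(n_frag) * (lens[chrom_i] - ins + 1)) + 1L
    flipped <- runif(n_frag) < 0.5
    s1 <- ifelse(flipped, start + ins - rl, start)
    s2 <- ifelse(flipped, start, start + ins - rl)
    r1[[ci]] <- cpp_extract_reads(unname(chroms), chrom_i, s1, rl, flipped,
                                  params$error_rate)
    r2[[ci]] <- cpp_extract_reads(unname(chroms), chrom_i, s2, rl, !flipped,
                                  params$error_rate)
    truth[[ci]] <- data.frame(
      copy = ci, hap = hap, chrom = names(chroms)[chrom_i],
      frag_start = start, frag_end = start + ins - 1L, flipped = flipped)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(copy = integer(0), hap = character(0), chrom = character(0),
               frag_start = integer(0), frag_end = integer(0),
               flipped = logical(0))
  truth <- cbind(read_id = if (nrow(truth))
    sprintf("read_%07d", seq_len(nrow(truth))) else character(0), truth)
  structure(list(read1 = unlist(r1, use.names = FALSE) %||% character(0),
                 read2 = unlist(r2, use.names = FALSE) %||% character(0),
                 truth = truth, copy_config = copy_config, params = params),
            class = "read_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

split_like <- function(full, chroms, offsets) {
  lens <- nchar(chroms)
  setNames(substring(full, offsets, offsets + lens - 1L), names(chroms))
}

#' Simulate an uneven whole-genome-amplification (WGA) library
#'
#' Emulates isothermal amplification of minute DNA: reads come only from a
#' small number of amplification seed loci with lognormal amplification
#' factors, so the covered breadth is a small fraction of the target
#' chromosome and coverage is highly multimodal.
#'
#' @param sub a `subgenome_set`.
#' @param target `"L1"`, `"L2"` or `"both"`.
#' @param params a [sim_params()] object; uses `wga_breadth`, `wga_sites`,
#'   `wga_lognormal_sd`, `depth_per_copy` and the read geometry.
#' @param seed RNG seed.
#' @return a `read_set` whose truth table also carries the amplicon index.
#' @export
simulate_wga_library <- function(sub, target = "L1", params = sub$params,
                                 seed = params$seed + 3L) {
  if (!target %in% c("L1", "L2", "both"))
    stop("simulate_wga_library: target must be 'L1', 'L2' or 'both'")
  if (params$wga_breadth > 1) stop("simulate_wga_library: wga_breadth > 1")
  set.seed(seed)
  haps <- if (target == "both") c("L1", "L2") else target
  rl <- params$read_length
  out <- list()
  for (hap in haps) {
    seqlen <- nchar(sub$haplotypes[[hap]][[1]])
    breadth_bp <- params$wga_breadth * seqlen
    # only as many amplification sites as the breadth budget can hold at
    # the minimum amplicon span of one fragment
    n_sites <- max(1L, min(params$wga_sites,
                           floor(breadth_bp / (2 * rl))))
    w <- rlnorm(n_sites, 0, params$wga_lognormal_sd)
    extra <- max(0, breadth_bp - n_sites * 2 * rl)
    span <- 2L * rl + round(extra * w / sum(w))
    # amplification seeds are stratified along the chromosome: jittered
    # within equal strata, so high-breadth settings tile it evenly
    bounds <- round(seq(0, seqlen, length.out = n_sites + 1))
    site <- vapply(seq_len(n_sites), function(i) {
      lo <- bounds[i] + 1L
      hi <- max(lo, bounds[i + 1] - span[i] + 1L)
      lo + floor(runif(1) * (hi - lo + 1))
    }, numeric(1))
    span <- pmin(span, seqlen - site + 1L)
    depth <- params$depth_per_copy * rlnorm(n_sites, 0, params$wga_lognormal_sd)
    n_frag <- pmax(0L, round(depth * span / (2 * rl)))
    amp <- rep(seq_len(n_sites), n_frag)
    tot <- sum(n_frag)
    if (tot == 0) next
    ins <- pmax(rl, round(rnorm(tot, params$insert_mean, params$insert_sd)))
    ins <- pmin(ins, span[amp])
    start <- site[amp] + floor(runif(tot) * (span[amp] - ins + 1))
    flipped <- runif(tot) < 0.5
    s1 <- ifelse(flipped, start + ins - rl, start)
    s2 <- ifelse(flipped, start, start + ins - rl)
    out[[hap]] <- list(
      r1 = cpp_extract_reads(unname(sub$haplotypes[[hap]]), rep(1L, tot),
                             s1, rl, flipped, params$error_rate),
      r2 = cpp_extract_reads(unname(sub$haplotypes[[hap]]), rep(1L, tot),
                             s2, rl, !flipped, params$error_rate),
      truth = data.frame(copy = 1L, hap = hap, chrom = hap,
                         frag_start = start, frag_end = start + ins - 1L,
                         flipped = flipped, amplicon = amp))
  }
  truth <- do.call(rbind, lapply(out, `[[`, "truth"))
  if (is.null(truth))
    truth <- data.frame(copy = integer(0), hap = character(0),
                        chrom = character(0), frag_start = integer(0),
                        frag_end = integer(0), flipped = logical(0),
                        amplicon = integer(0))
  rownames(truth) <- NULL
  truth <- cbind(read_id = if (nrow(truth))
    sprintf("wga_%07d", seq_len(nrow(truth))) else character(0), truth)
  structure(list(read1 = unlist(lapply(out, `[[`, "r1"), use.names = FALSE) %||% character(0),
                 read2 = unlist(lapply(out, `[[`, "r2"), use.names = FALSE) %||% character(0),
                 truth = truth, copy_config = haps, params = params),
            class = "read_set")
}
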