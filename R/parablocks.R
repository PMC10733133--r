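# Paralogous blocks (PBs): slice a haploid assembly into fragments such
# that any two alignment spans on a scaffold are identical or disjoint,
# then group homologous fragments. Each PB is a target fragment together
# with all of its fully aligned homologs, so its copy number is the member
# count. Copy number is validated independently by read coverage (FPK),
# and per-PB divergence statistics are computed from the chained
# alignments.

#' Slice a genome into paralogous blocks
#'
#' Every alignment endpoint is projected onto every overlapping alignment,
#' iterated to a fixed point, so that after splitting, any two alignment
#' spans on a scaffold coincide or are disjoint. Homologous fragments are
#' grouped by transitive closure of full-length alignment (or strict
#' cliques), unaligned sequence becomes 1-copy blocks, and the member
#' intervals of all blocks partition the genome exactly.
#'
#' @param chains list of [chain_alignment()] objects (self-alignments of
#'   the assembly); normalized internally.
#' @param scaffold_lengths named integer vector of scaffold lengths.
#' @param min_segment fragments shorter than this many bp are absorbed into
#'   their left neighbour (the first fragment of a scaffold into its right
#'   neighbour).
#' @param group_mode `"transitive"` (default: homologs grouped through the
#'   closure of pairwise full-length alignment, tolerating aligner dropout)
#'   or `"clique"` (groups are split until every pair is directly aligned;
#'   requires the igraph package).
#' @return an object of class `paralogous_blocks`: a list of blocks, each
#'   with `members` (scaffold, start, end, strand), `copy_number` and the
#'   per-pair alignment slices used for divergence statistics.
#' @export
slice_into_blocks <- function(chains, scaffold_lengths, min_segment = 100,
                              group_mode = c("transitive", "clique")) {
  group_mode <- match.arg(group_mode)
  chains <- normalize_chains(chains)
  for (ch in chains) {
    for (side in c("target", "query")) {
      nm <- ch[[side]]
      if (!nm %in% names(scaffold_lengths))
        stop("slice_into_blocks: unknown scaffold in chain: ", nm)
      sz <- if (side == "target") ch$tsize else ch$qsize
      if (sz > scaffold_lengths[[nm]])
        stop("slice_into_blocks: alignment escapes scaffold bounds in chain ",
             ch$target, " vs ", ch$query)
    }
  }

  scafs <- names(scaffold_lengths)
  cuts <- lapply(scaffold_lengths, function(L) c(1L, L + 1L))
  names(cuts) <- scafs
  add_cut <- function(scaf, pos) {
    pos <- pos[pos > 1 & pos <= scaffold_lengths[[scaf]]]
    new <- setdiff(pos, cuts[[scaf]])
    if (length(new)) {
      cuts[[scaf]] <<- sort(c(cuts[[scaf]], new))
      TRUE
    } else FALSE
  }
  for (ch in chains) {
    ts <- chain_tspan(ch); qs <- chain_qspan(ch)
    add_cut(ch$target, c(ts[1], ts[2] + 1L))
    add_cut(ch$query, c(qs[1], qs[2] + 1L))
  }
  # fixed point: project cuts through every chain in both directions
  repeat {
    changed <- FALSE
    for (ch in chains) {
      ts <- chain_tspan(ch); qs <- chain_qspan(ch)
      tc <- cuts[[ch$target]]
      tc <- tc[tc > ts[1] & tc <= ts[2]]
      if (length(tc) && add_cut(ch$query, project_cut_t2q(ch, tc)))
        changed <- TRUE
      qc <- cuts[[ch$query]]
      qc <- qc[qc > qs[1] & qc <= qs[2]]
      if (length(qc) && add_cut(ch$target, project_cut_q2t(ch, qc)))
        changed <- TRUE
    }
    if (!changed) break
  }

  # segments and ids
  seg_tab <- do.call(rbind, lapply(scafs, function(sc) {
    cc <- cuts[[sc]]
    data.frame(scaffold = sc, start = cc[-length(cc)],
               end = cc[-1] - 1L, stringsAsFactors = FALSE)
  }))
  seg_tab$id <- seq_len(nrow(seg_tab))
  seg_by_scaf <- split(seg_tab, seg_tab$scaffold)
  seg_of <- function(scaf, pos) {
    st <- seg_by_scaf[[scaf]]
    id <- st$id[findInterval(pos, st$start)]
    if (any(is.na(id))) stop("slice_into_blocks: internal segmentation error")
    id
  }

  # edges: each chain decomposes exactly into (target segment, query segment)
  edges <- list()
  for (ch in chains) {
    ts <- chain_tspan(ch)
    tc <- cuts[[ch$target]]
    tc <- tc[tc >= ts[1] & tc <= ts[2] + 1L]
    for (k in seq_len(length(tc) - 1L)) {
      a <- tc[k]; b <- tc[k + 1L] - 1L
      sl <- clip_chain_target(ch, a, b)
      if (is.null(sl)) next
      qsp <- chain_qspan(sl)
      # the query side must be exactly one segment (fixed point guarantees it)
      qseg <- seg_of(ch$query, qsp[1])
      tseg <- seg_of(ch$target, a)
      edges[[length(edges) + 1]] <- list(t = tseg, q = qseg, chain = sl,
                                         strand = ch$strand)
    }
  }

  # grouping: union-find over segments
  parent <- seq_len(nrow(seg_tab))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (e in edges) {
    a <- find(e$t); b <- find(e$q)
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(nrow(seg_tab)), find, integer(1))

  if (group_mode == "clique") {
    if (!requireNamespace("igraph", quietly = TRUE))
      stop("group_mode='clique' requires the igraph package")
    comp <- clique_groups(seg_tab, edges, comp)
  }

  # absorb sub-threshold slivers into the left neighbour
  seg_tab$group <- comp
  seg_tab <- absorb_slivers(seg_tab, min_segment)

  pbs <- build_blocks(seg_tab, edges)
  structure(list(blocks = pbs, scaffold_lengths = scaffold_lengths,
                 min_segment = min_segment, group_mode = group_mode),
            class = "paralogous_blocks")
}

# project "cut before position c" on the target to the query coordinate
project_cut_t2q <- function(ch, c) {
  if (ch$strand == "+") {
    b <- ch$blocks
    tend <- b$tstart + b$len - 1
    idx <- findInterval(c, b$tstart)
    out <- numeric(length(c))
    for (i in seq_along(c)) {
      if (idx[i] >= 1 && c[i] <= tend[idx[i]])
        out[i] <- b$qstart[idx[i]] + (c[i] - b$tstart[idx[i]])
      else if (idx[i] < nrow(b)) out[i] <- b$qstart[idx[i] + 1]
      else out[i] <- b$qstart[nrow(b)] + b$len[nrow(b)]
    }
    as.integer(out)
  } else {
    # target is ascending while query descends: the boundary before c pairs
    # with the boundary before q(c) + 1 on the + strand of the query
    as.integer(project_t2q(ch, c) + 1L)
  }
}

project_cut_q2t <- function(ch, c) project_cut_t2q(flip_chain(ch), c)

clique_groups <- function(seg_tab, edges, comp) {
  el <- unique(do.call(rbind, lapply(edges, function(e) {
    cbind(min(e$t, e$q), max(e$t, e$q))
  })))
  g <- igraph::graph_from_edgelist(matrix(as.character(el), ncol = 2),
                                   directed = FALSE)
  g <- igraph::add_vertices(
    g, sum(!as.character(seg_tab$id) %in% igraph::V(g)$name),
    name = setdiff(as.character(seg_tab$id), igraph::V(g)$name))
  memb <- rep(NA_integer_, nrow(seg_tab))
  next_grp <- 1L
  remaining <- g
  while (igraph::vcount(remaining) > 0) {
    cl <- igraph::largest_cliques(remaining)[[1]]
    ids <- as.integer(igraph::V(remaining)$name[as.integer(cl)])
    memb[ids] <- next_grp
    next_grp <- next_grp + 1L
    remaining <- igraph::delete_vertices(remaining, cl)
  }
  memb
}

absorb_slivers <- function(seg_tab, min_segment) {
  out <- seg_tab
  out$absorbed <- FALSE
  for (sc in unique(out$scaffold)) {
    idx <- which(out$scaffold == sc)
    if (length(idx) < 2) next
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (out$end[i] - out$start[i] + 1L >= min_segment) next
      left <- if (k > 1) idx[seq_len(k - 1)] else integer(0)
      left <- left[!out$absorbed[left]]
      if (length(left)) {
        out$end[left[length(left)]] <- out$end[i]
      } else if (k < length(idx)) {
        out$start[idx[k + 1]] <- out$start[i]
      } else next # nothing to absorb into
      out$absorbed[i] <- TRUE
    }
  }
  out[!out$absorbed, setdiff(names(out), "absorbed"), drop = FALSE]
}

build_blocks <- function(seg_tab, edges) {
  keep_ids <- seg_tab$id
  groups <- split(seg_tab, seg_tab$group)
  pbs <- vector("list", length(groups))
  edge_by_pair <- list()
  for (e in edges) {
    if (!(e$t %in% keep_ids && e$q %in% keep_ids)) next
    key <- paste(min(e$t, e$q), max(e$t, e$q), sep = "_")
    if (is.null(edge_by_pair[[key]])) edge_by_pair[[key]] <- e
  }
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    members <- data.frame(scaffold = g$scaffold, start = g$start,
                          end = g$end, strand = "+", seg_id = g$id,
                          stringsAsFactors = FALSE)
    pair_chains <- list()
    if (nrow(g) > 1) {
      for (a in seq_len(nrow(g) - 1)) for (b in (a + 1):nrow(g)) {
        key <- paste(min(g$id[a], g$id[b]), max(g$id[a], g$id[b]), sep = "_")
        e <- edge_by_pair[[key]]
        if (!is.null(e)) pair_chains[[key]] <- e
      }
    }
    pbs[[gi]] <- list(id = sprintf("PB_%05d", gi), members = members,
                      copy_number = nrow(g), pair_chains = pair_chains)
  }
  pbs
}

#' Member intervals of all blocks as one table
#'
#' @param pbs a `paralogous_blocks` object.
#' @return data.frame (block, scaffold, start, end, copy_number).
#' @export
pb_members <- function(pbs) {
  do.call(rbind, lapply(pbs$blocks, function(pb) {
    data.frame(block = pb$id, scaffold = pb$members$scaffold,
               start = pb$members$start, end = pb$members$end,
               copy_number = pb$copy_number, stringsAsFactors = FALSE)
  }))
}

#' Write PB member intervals as BED
#'
#' BED name is the block id and score the copy number.
#' @param pbs a `paralogous_blocks` object.
#' @param path output BED file.
#' @export
write_pb_bed <- function(pbs, path) {
  m <- pb_members(pbs)
  write.table(data.frame(m$scaffold, m$start - 1L, m$end, m$block,
                         m$copy_number, "+"),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Divergence statistics of one paralogous block
#'
#' Rates are averaged over all member pairs with an alignment slice:
#' `snp_rate` = mismatches per aligned column; `indel_event_rate` = gap
#' openings per kb of aligned columns; `edit_rate` = (mismatches + indel
#' events) / longest member length (indels of any length count as single
#' edits); `length_weighted_divergence` = (mismatches + indel bases) /
#' gapped alignment span. With `cds_intervals`, each rate is also computed
#' over the columns intersecting the CDS.
#'
#' @param pb one block from a `paralogous_blocks` object.
#' @param sequences named character vector (or list) of scaffold sequences.
#' @param cds_intervals optional data.frame (scaffold, start, end), 1-based
#'   closed, of protein-coding intervals.
#' @return a list of class `pb_stats`.
#' @export
block_divergence <- function(pb, sequences, cds_intervals = NULL) {
  if (pb$copy_number == 1 || !length(pb$pair_chains)) {
    return(structure(list(snp_rate = 0, indel_event_rate = 0, edit_rate = 0,
                          length_weighted_divergence = 0, n_pairs = 0L,
                          single_copy = pb$copy_number == 1,
                          cds = NULL), class = "pb_stats"))
  }
  per_pair <- lapply(pb$pair_chains, function(e)
    pair_rates(e$chain, sequences, pb))
  agg <- function(f) mean(vapply(per_pair, `[[`, numeric(1), f))
  cds <- NULL
  if (!is.null(cds_intervals)) {
    per_cds <- lapply(pb$pair_chains, function(e)
      cds_pair_rates(e$chain, sequences, pb, cds_intervals))
    per_cds <- per_cds[!vapply(per_cds, is.null, logical(1))]
    if (length(per_cds)) {
      aggc <- function(f) mean(vapply(per_cds, `[[`, numeric(1), f))
      cds <- list(snp_rate = aggc("snp_rate"),
                  indel_event_rate = aggc("indel_event_rate"),
                  edit_rate = aggc("edit_rate"),
                  length_weighted_divergence = aggc("length_weighted_divergence"))
    }
  }
  structure(list(snp_rate = agg("snp_rate"),
                 indel_event_rate = agg("indel_event_rate"),
                 edit_rate = agg("edit_rate"),
                 length_weighted_divergence = agg("length_weighted_divergence"),
                 n_pairs = length(per_pair), single_copy = FALSE, cds = cds),
            class = "pb_stats")
}

pair_rates <- function(ch, sequences, pb) {
  b <- ch$blocks
  mc <- cpp_count_mismatches(sequences[[ch$target]], sequences[[ch$query]],
                             b$tstart - 1L, b$qstart - 1L, b$len,
                             ch$strand == "-")
  mm <- mc[1]; cols <- mc[2]
  n <- nrow(b)
  tgaps <- if (n > 1) b$tstart[-1] - (b$tstart + b$len)[-n] else integer(0)
  qs <- if (ch$strand == "+") b$qstart else rev(b$qstart)
  ql <- if (ch$strand == "+") b$len else rev(b$len)
  qgaps <- if (n > 1) qs[-1] - (qs + ql)[-n] else integer(0)
  events <- sum(tgaps > 0) + sum(qgaps > 0)
  gapbases <- sum(tgaps[tgaps > 0]) + sum(qgaps[qgaps > 0])
  member_lens <- pb$members$end - pb$members$start + 1L
  list(snp_rate = mm / cols,
       indel_event_rate = events / (cols / 1000),
       edit_rate = (mm + events) / max(member_lens),
       length_weighted_divergence = (mm + gapbases) / (cols + gapbases))
}

cds_pair_rates <- function(ch, sequences, pb, cds) {
  cds_t <- cds[cds$scaffold == ch$target, , drop = FALSE]
  if (!nrow(cds_t)) return(NULL)
  slices <- lapply(seq_len(nrow(cds_t)), function(i)
    clip_chain_target(ch, cds_t$start[i], cds_t$end[i]))
  slices <- slices[!vapply(slices, is.null, logical(1))]
  if (!length(slices)) return(NULL)
  stats <- lapply(slices, pair_rates, sequences = sequences, pb = pb)
  n <- length(stats)
  list(snp_rate = mean(vapply(stats, `[[`, numeric(1), "snp_rate")),
       indel_event_rate = mean(vapply(stats, `[[`, numeric(1), "indel_event_rate")),
       edit_rate = mean(vapply(stats, `[[`, numeric(1), "edit_rate")),
       length_weighted_divergence =
         mean(vapply(stats, `[[`, numeric(1), "length_weighted_divergence")))
}

#' Read CDS intervals from a GFF3 file
#'
#' Convenience reader for the `cds_intervals` argument of
#' [block_divergence()]: extracts type-CDS records as a 1-based closed
#' interval table. Uses rtracklayer when available, else a minimal
#' tab-field parse.
#'
#' @param path GFF3 file.
#' @return data.frame (scaffold, start, end).
#' @export
read_cds_gff <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    g <- rtracklayer::import(path)
    g <- g[g$type == "CDS"]
    return(data.frame(scaffold = as.character(GenomicRanges::seqnames(g)),
                      start = GenomicRanges::start(g),
                      end = GenomicRanges::end(g)))
  }
  raw <- read.table(path, sep = "\t", comment.char = "#", quote = "",
                    stringsAsFactors = FALSE)
  cds <- raw[raw[[3]] == "CDS", , drop = FALSE]
  data.frame(scaffold = cds[[1]], start = as.integer(cds[[4]]),
             end = as.integer(cds[[5]]))
}

#' Coverage-based copy-number validation of paralogous blocks
#'
#' The FPK of a block is the sum of its members' fragment counts per
#' kilobase. The coverage multiplicity is the nearest integer of
#' FPK / haploid FPK; blocks whose multiplicity disagrees with the
#' assembly copy number are flagged as suspected collapse (multiplicity
#' above copy number) or expansion (below).
#'
#' @param pbs a `paralogous_blocks` object.
#' @param fragment_counts data.frame (scaffold, start, end, count) with one
#'   row per PB member interval (e.g. from [count_fragments_per_interval()]).
#' @param haploid_fpk haploid (per-copy) FPK; when `NULL`, estimated as the
#'   mode of the per-block FPK / copy_number distribution.
#' @return data.frame per block: fpk, copy_number, coverage_multiplicity,
#'   consistent, suspected flag.
#' @export
block_coverage <- function(pbs, fragment_counts, haploid_fpk = NULL) {
  key <- with(fragment_counts, paste(scaffold, start, end))
  fpk <- vapply(pbs$blocks, function(pb) {
    mk <- paste(pb$members$scaffold, pb$members$start, pb$members$end)
    idx <- match(mk, key)
    if (any(is.na(idx)))
      stop("block_coverage: missing fragment counts for members of ", pb$id)
    sum(fragment_counts$count[idx] /
          ((pb$members$end - pb$members$start + 1) / 1000))
  }, numeric(1))
  cn <- vapply(pbs$blocks, function(pb) as.numeric(pb$copy_number),
               numeric(1))
  len <- vapply(pbs$blocks, function(pb)
    sum(pb$members$end - pb$members$start + 1), numeric(1))
  if (is.null(haploid_fpk)) {
    x <- fpk / cn
    keep <- x > 0
    if (sum(keep) < 2) stop("block_coverage: cannot estimate haploid FPK")
    # length-weighted mode: the consistent majority of the assembly sets
    # the per-copy depth even when some blocks are collapsed/expanded
    d <- suppressWarnings( # bandwidth selection ignores weights; fine here
      density(x[keep], weights = len[keep] / sum(len[keep])))
    haploid_fpk <- d$x[which.max(d$y)]
  }
  if (haploid_fpk <= 0) stop("block_coverage: haploid FPK must be > 0")
  mult <- round(fpk / haploid_fpk)
  data.frame(block = vapply(pbs$blocks, `[[`, character(1), "id"),
             length = len, copy_number = cn, fpk = fpk,
             haploid_fpk = haploid_fpk,
             coverage_multiplicity = mult,
             consistent = mult == cn,
             suspected = ifelse(mult == cn, "none",
                                ifelse(mult > cn, "collapsed", "expanded")),
             stringsAsFactors = FALSE)
}

#' Assembly composition by copy-number class
#'
#' Proportion of total assembly length in copy-number classes 1, 2, 3, 4
#' and 5+, by assembly copy number (PB member count) and, when a coverage
#' table is given, by coverage multiplicity.
#'
#' @param pbs a `paralogous_blocks` object.
#' @param coverage optional output of [block_coverage()].
#' @return data.frame with class labels and length proportions.
#' @export
copy_number_summary <- function(pbs, coverage = NULL) {
  len <- vapply(pbs$blocks, function(pb)
    sum(pb$members$end - pb$members$start + 1), numeric(1))
  cn <- vapply(pbs$blocks, function(pb) as.numeric(pb$copy_number),
               numeric(1))
  cls <- function(x) ifelse(x >= 5, "5+", as.character(x))
  tot <- sum(len)
  by_cn <- tapply(len, cls(cn), sum) / tot
  out <- data.frame(class = c("1", "2", "3", "4", "5+"))
  out$by_copy_number <- as.numeric(by_cn[out$class])
  out$by_copy_number[is.na(out$by_copy_number)] <- 0
  if (!is.null(coverage)) {
    m <- pmax(coverage$coverage_multiplicity, 1)
    by_m <- tapply(coverage$length, cls(m), sum) / sum(coverage$length)
    out$by_multiplicity <- as.numeric(by_m[out$class])
    out$by_multiplicity[is.na(out$by_multiplicity)] <- 0
  }
  out
}
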