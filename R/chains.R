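# Chained pairwise local alignments: the exchange currency between the
# self-homology input (PSL / UCSC chain files) and the paralogous-block
# machinery. Internally blocks are 1-based closed intervals with query
# coordinates always on the + strand of the query sequence; PSL's 0-based
# half-open convention (and reversed query coordinates on '-' records) is
# handled at the file boundary.

#' Construct a chained pairwise alignment
#'
#' @param target,query sequence (scaffold) names.
#' @param tsize,qsize sequence lengths.
#' @param blocks data.frame with columns `tstart`, `qstart` (1-based starts;
#'   `qstart` on the + strand of the query) and `len`; gapless aligned
#'   blocks sorted by `tstart`.
#' @param strand `"+"` or `"-"`. On `"-"`, ascending target positions pair
#'   with descending query (+ strand) positions within each block.
#' @param matches,mismatches optional whole-chain match/mismatch counts.
#' @return an object of class `chain_alignment`.
#' @export
chain_alignment <- function(target, query, tsize, qsize, blocks, strand = "+",
                            matches = NA_integer_, mismatches = NA_integer_) {
  blocks <- as.data.frame(blocks)[, c("tstart", "qstart", "len")]
  ch <- structure(list(target = target, query = query,
                       tsize = as.integer(tsize), qsize = as.integer(qsize),
                       strand = strand, blocks = blocks,
                       matches = matches, mismatches = mismatches),
                  class = "chain_alignment")
  validate_chain(ch)
  ch
}

validate_chain <- function(ch) {
  b <- ch$blocks
  if (nrow(b) == 0) stop("chain_alignment: no blocks")
  if (any(b$len <= 0)) stop("chain_alignment: non-positive block length")
  if (is.unsorted(b$tstart, strictly = TRUE) && nrow(b) > 1)
    stop("chain_alignment: blocks not sorted by target start")
  if (any(b$tstart[-1] < (b$tstart + b$len)[-nrow(b)]))
    stop("chain_alignment: overlapping target blocks")
  qs <- if (ch$strand == "+") b$qstart else rev(b$qstart)
  ql <- if (ch$strand == "+") b$len else rev(b$len)
  if (nrow(b) > 1 && any(qs[-1] < (qs + ql)[-length(qs)]))
    stop("chain_alignment: overlapping query blocks")
  if (min(b$tstart) < 1 || max(b$tstart + b$len - 1) > ch$tsize)
    stop(sprintf("chain_alignment: target blocks escape bounds of %s", ch$target))
  if (min(b$qstart) < 1 || max(b$qstart + b$len - 1) > ch$qsize)
    stop(sprintf("chain_alignment: query blocks escape bounds of %s", ch$query))
  invisible(ch)
}

#' @export
print.chain_alignment <- function(x, ...) {
  b <- x$blocks
  cat(sprintf("chain %s:%d-%d %s %s:%d-%d  %d block(s), %d aligned bp\n",
              x$target, min(b$tstart), max(b$tstart + b$len - 1), x$strand,
              x$query, min(b$qstart), max(b$qstart + b$len - 1),
              nrow(b), sum(b$len)))
  invisible(x)
}

chain_tspan <- function(ch) {
  c(min(ch$blocks$tstart), max(ch$blocks$tstart + ch$blocks$len - 1))
}
chain_qspan <- function(ch) {
  c(min(ch$blocks$qstart), max(ch$blocks$qstart + ch$blocks$len - 1))
}

# Project target positions onto the query (+ strand). Positions falling in
# a target gap snap to the query boundary between the flanking blocks (the
# downstream block edge). Positions outside the chain span return NA.
project_t2q <- function(ch, pos) {
  b <- ch$blocks
  tend <- b$tstart + b$len - 1
  out <- rep(NA_real_, length(pos))
  idx <- findInterval(pos, b$tstart)
  inside <- idx >= 1 & pos <= tend[pmax(idx, 1)]
  ii <- which(inside)
  if (length(ii)) {
    o <- pos[ii] - b$tstart[idx[ii]]
    out[ii] <- if (ch$strand == "+") b$qstart[idx[ii]] + o
               else b$qstart[idx[ii]] + b$len[idx[ii]] - 1 - o
  }
  gap <- which(!inside & idx >= 1 & idx < nrow(b))
  if (length(gap)) {
    nxt <- idx[gap] + 1
    out[gap] <- if (ch$strand == "+") b$qstart[nxt]
                else b$qstart[idx[gap]] + b$len[idx[gap]] - 1
  }
  out
}

# Swap target and query roles (query coordinates stay on + strand).
flip_chain <- function(ch) {
  b <- ch$blocks
  nb <- data.frame(tstart = b$qstart, qstart = b$tstart, len = b$len)
  nb <- nb[order(nb$tstart), , drop = FALSE]
  chain_alignment(ch$query, ch$target, ch$qsize, ch$tsize, nb, ch$strand,
                  ch$matches, ch$mismatches)
}

#' Merge false zero-length indels in chained alignments
#'
#' Adjacent gapless blocks separated by a zero-length gap on both the target
#' and the query are merged, so each chain represents the same alignment
#' with the minimal number of blocks.
#'
#' @param chains a list of [chain_alignment()] objects (or a single one).
#' @return the normalized list (or single chain).
#' @export
normalize_chains <- function(chains) {
  single <- inherits(chains, "chain_alignment")
  if (single) chains <- list(chains)
  out <- lapply(chains, function(ch) {
    b <- ch$blocks
    if (nrow(b) > 1) {
      keep <- list(b[1, ])
      for (i in 2:nrow(b)) {
        last <- keep[[length(keep)]]
        t_contig <- b$tstart[i] == last$tstart + last$len
        q_contig <- if (ch$strand == "+") b$qstart[i] == last$qstart + last$len
                    else b$qstart[i] + b$len[i] == last$qstart
        if (t_contig && q_contig) {
          last$len <- last$len + b$len[i]
          if (ch$strand == "-") last$qstart <- b$qstart[i]
          keep[[length(keep)]] <- last
        } else keep[[length(keep) + 1]] <- b[i, ]
      }
      b <- do.call(rbind, keep)
      rownames(b) <- NULL
    }
    chain_alignment(ch$target, ch$query, ch$tsize, ch$qsize, b, ch$strand,
                    ch$matches, ch$mismatches)
  })
  if (single) out[[1]] else out
}

# Restrict a chain to a target interval [tlo, thi] (1-based closed),
# clipping blocks. Returns NULL if nothing remains.
clip_chain_target <- function(ch, tlo, thi) {
  b <- ch$blocks
  tend <- b$tstart + b$len - 1
  keep <- which(tend >= tlo & b$tstart <= thi)
  if (!length(keep)) return(NULL)
  b <- b[keep, , drop = FALSE]
  lo_cut <- pmax(tlo - b$tstart, 0)
  hi_cut <- pmax((b$tstart + b$len - 1) - thi, 0)
  if (ch$strand == "+") {
    b$qstart <- b$qstart + lo_cut
  } else {
    b$qstart <- b$qstart + hi_cut
  }
  b$tstart <- b$tstart + lo_cut
  b$len <- b$len - lo_cut - hi_cut
  b <- b[b$len > 0, , drop = FALSE]
  if (!nrow(b)) return(NULL)
  chain_alignment(ch$target, ch$query, ch$tsize, ch$qsize, b, ch$strand)
}

# ---- PSL ---------------------------------------------------------------

psl_cols <- c("matches", "misMatches", "repMatches", "nCount", "qNumInsert",
              "qBaseInsert", "tNumInsert", "tBaseInsert", "strand", "qName",
              "qSize", "qStart", "qEnd", "tName", "tSize", "tStart", "tEnd",
              "blockCount", "blockSizes", "qStarts", "tStarts")

#' Read a PSL alignment file
#'
#' @param path PSL file (no header, 21 columns).
#' @return a list of [chain_alignment()] objects. Query block coordinates of
#'   `-` strand records are converted to the + strand of the query.
#' @export
read_psl <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                    col.names = psl_cols)
  lapply(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    sizes <- as.integer(strsplit(r$blockSizes, ",")[[1]])
    qs <- as.integer(strsplit(r$qStarts, ",")[[1]])
    ts <- as.integer(strsplit(r$tStarts, ",")[[1]])
    if (length(sizes) != r$blockCount) stop("read_psl: malformed block lists")
    qplus <- if (r$strand == "+") qs + 1L else r$qSize - (qs + sizes) + 1L
    blocks <- data.frame(tstart = ts + 1L, qstart = qplus, len = sizes)
    blocks <- blocks[order(blocks$tstart), , drop = FALSE]
    chain_alignment(r$tName, r$qName, r$tSize, r$qSize, blocks, r$strand,
                    matches = r$matches, mismatches = r$misMatches)
  })
}

#' Write chained alignments as PSL
#'
#' @param chains list of [chain_alignment()] objects.
#' @param path output file.
#' @param sequences optional named character vector of sequences; when given,
#'   per-chain match/mismatch counts are recomputed from the sequences,
#'   otherwise stored counts (or all-match) are used.
#' @export
write_psl <- function(chains, path, sequences = NULL) {
  if (inherits(chains, "chain_alignment")) chains <- list(chains)
  lines <- vapply(chains, function(ch) {
    b <- ch$blocks
    n <- nrow(b)
    aligned <- sum(b$len)
    if (!is.null(sequences)) {
      mc <- cpp_count_mismatches(sequences[[ch$target]], sequences[[ch$query]],
                                 b$tstart - 1L, b$qstart - 1L, b$len,
                                 ch$strand == "-")
      mm <- mc[1]
    } else mm <- if (is.na(ch$mismatches)) 0L else ch$mismatches
    tgaps <- if (n > 1) b$tstart[-1] - (b$tstart + b$len)[-n] else integer(0)
    if (ch$strand == "+") {
      qgaps <- if (n > 1) b$qstart[-1] - (b$qstart + b$len)[-n] else integer(0)
      qs0 <- b$qstart - 1L
    } else {
      qgaps <- if (n > 1) b$qstart[-n] - (b$qstart + b$len)[-1] else integer(0)
      qs0 <- ch$qsize - (b$qstart - 1L + b$len)
    }
    qspan <- chain_qspan(ch); tspan <- chain_tspan(ch)
    paste(c(aligned - mm, mm, 0L, 0L,
            sum(qgaps > 0), sum(qgaps[qgaps > 0]),
            sum(tgaps > 0), sum(tgaps[tgaps > 0]),
            ch$strand, ch$query, ch$qsize, qspan[1] - 1L, qspan[2],
            ch$target, ch$tsize, tspan[1] - 1L, tspan[2],
            n, paste0(paste(b$len, collapse = ","), ","),
            paste0(paste(qs0, collapse = ","), ","),
            paste0(paste(b$tstart - 1L, collapse = ","), ",")),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a UCSC chain file
#'
#' @param path chain-format file.
#' @return a list of [chain_alignment()] objects with the chain's reference
#'   mapped to `target` and its query to `query` (+ strand coordinates).
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    h <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (h[1] != "chain") stop("read_chain: expected 'chain' header")
    tname <- h[3]; tsize <- as.integer(h[4]); tstart <- as.integer(h[6])
    qname <- h[8]; qsize <- as.integer(h[9]); qstrand <- h[10]
    qstart <- as.integer(h[11])
    i <- i + 1
    tpos <- tstart; qpos <- qstart
    tb <- integer(0); qb <- integer(0); lb <- integer(0)
    repeat {
      parts <- as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]])
      size <- parts[1]
      tb <- c(tb, tpos); qb <- c(qb, qpos); lb <- c(lb, size)
      i <- i + 1
      if (length(parts) == 1) break
      tpos <- tpos + size + parts[2]
      qpos <- qpos + size + parts[3]
    }
    qplus <- if (qstrand == "+") qb + 1L else qsize - (qb + lb) + 1L
    blocks <- data.frame(tstart = tb + 1L, qstart = qplus, len = lb)
    out[[length(out) + 1]] <- chain_alignment(
      tname, qname, tsize, qsize, blocks[order(blocks$tstart), ],
      strand = qstrand)
  }
  out
}
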