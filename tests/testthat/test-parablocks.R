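# Paralogous blocks: chain normalization, fixed-point slicing vs a
# brute-force per-position oracle, divergence statistics vs a full DP
# oracle, coverage validation and copy-number summaries.

test_that("normalize_chains merges false zero-length indels only", {
  ch <- chain_alignment("A", "B", 100, 100,
                        data.frame(tstart = c(1, 11), qstart = c(1, 11),
                                   len = c(10, 10)))
  n <- normalize_chains(ch)
  expect_equal(nrow(n$blocks), 1)
  expect_equal(n$blocks$len, 20)
  # true 5-bp target-only gap stays
  ch2 <- chain_alignment("A", "B", 100, 100,
                         data.frame(tstart = c(1, 16), qstart = c(1, 11),
                                    len = c(10, 10)))
  expect_equal(nrow(normalize_chains(ch2)$blocks), 2)
  # random fragmentation of a known alignment normalizes back
  set.seed(4)
  cuts <- sort(sample(2:59, 7))
  starts <- c(1, cuts)
  lens <- diff(c(starts, 61))
  frag <- chain_alignment("A", "B", 100, 100,
                          data.frame(tstart = starts, qstart = starts + 20,
                                     len = lens))
  n3 <- normalize_chains(frag)
  expect_equal(n3$blocks,
               data.frame(tstart = 1, qstart = 21, len = 60))
  # minus-strand merge
  chm <- chain_alignment("A", "B", 100, 100,
                         data.frame(tstart = c(1, 11), qstart = c(41, 31),
                                    len = c(10, 10)), strand = "-")
  nm <- normalize_chains(chm)
  expect_equal(nrow(nm$blocks), 1)
  expect_equal(nm$blocks$qstart, 31)
  expect_error(chain_alignment("A", "B", 100, 100,
                               data.frame(tstart = c(1, 5), qstart = c(1, 5),
                                          len = c(10, 10))), "overlap")
})

test_that("slicing handles the documented base cases", {
  # no chains -> one 1-copy block covering the scaffold
  pbs <- slice_into_blocks(list(), c(sc = 10000L))
  expect_equal(length(pbs$blocks), 1)
  expect_equal(pbs$blocks[[1]]$copy_number, 1)
  expect_equal(pbs$blocks[[1]]$members$end, 10000)
  # two overlapping alignments produce cut points {51, 101}
  ch1 <- chain_alignment("A", "B", 200, 200,
                         data.frame(tstart = 1, qstart = 1, len = 100))
  ch2 <- chain_alignment("A", "C", 200, 200,
                         data.frame(tstart = 51, qstart = 51, len = 100))
  pbs2 <- slice_into_blocks(list(ch1, ch2), c(A = 200L, B = 200L, C = 200L),
                            min_segment = 1)
  mA <- pb_members(pbs2)
  mA <- mA[mA$scaffold == "A", ]
  expect_equal(sort(mA$start), c(1, 51, 101, 151))
  expect_equal(mA$copy_number[order(mA$start)], c(2, 3, 2, 1))
  # three identical scaffolds fully aligned pairwise -> all copy number 3
  mk <- function(t, q) chain_alignment(t, q, 1000, 1000,
                                       data.frame(tstart = 1, qstart = 1,
                                                  len = 1000))
  pbs3 <- slice_into_blocks(list(mk("X", "Y"), mk("X", "Z"), mk("Y", "Z")),
                            c(X = 1000L, Y = 1000L, Z = 1000L))
  expect_equal(length(pbs3$blocks), 1)
  expect_equal(pbs3$blocks[[1]]$copy_number, 3)
  # alignment escaping scaffold bounds is refused with the chain named
  expect_error(slice_into_blocks(list(ch1), c(A = 50L, B = 200L, C = 200L)),
               "bounds|escape")
})

test_that("slicing agrees with the brute-force per-position oracle", {
  # instances come from a duplication process (each alignment is one
  # source -> copy event between different scaffolds), the structure the
  # paralogous-block model is defined for; tandem-style self-maps of a
  # region onto itself at shifted offsets are outside interval semantics
  set.seed(31)
  for (rep in 1:10) {
    # scaffolds are (possibly reversed) copies of windows of one ancestral
    # coordinate axis; every alignment links equal ancestral positions, so
    # any two alignments of the same regions agree in offset
    n_scaf <- sample(3:5, 1)
    lens <- setNames(sample(300:800, n_scaf), paste0("s", seq_len(n_scaf)))
    offs <- sample(0:400, n_scaf, replace = TRUE)
    revd <- sample(c(TRUE, FALSE), n_scaf, replace = TRUE)
    to_local <- function(j, a, b) { # ancestral [a,b] -> scaffold-j interval
      if (!revd[j]) c(a - offs[j], b - offs[j])
      else c(offs[j] + lens[j] - b + 1, offs[j] + lens[j] - a + 1)
    }
    chains <- list()
    n_chain <- sample(4:20, 1)
    tries <- 0
    while (length(chains) < n_chain && tries < 200) {
      tries <- tries + 1
      pair <- sample(n_scaf, 2)
      lo <- max(offs[pair]) + 1
      hi <- min(offs[pair] + lens[pair])
      if (hi - lo < 30) next
      len <- sample(20:min(200, hi - lo), 1)
      a <- sample(lo:(hi - len), 1)
      b <- a + len - 1
      t_iv <- to_local(pair[1], a, b)
      q_iv <- to_local(pair[2], a, b)
      strand <- if (xor(revd[pair[1]], revd[pair[2]])) "-" else "+"
      chains[[length(chains) + 1]] <- chain_alignment(
        names(lens)[pair[1]], names(lens)[pair[2]],
        lens[pair[1]], lens[pair[2]],
        data.frame(tstart = t_iv[1], qstart = q_iv[1], len = len), strand)
    }
    pbs <- slice_into_blocks(chains, lens, min_segment = 1)
    m <- pb_members(pbs)
    # partition property
    for (sc in names(lens)) {
      msc <- m[m$scaffold == sc, ]
      msc <- msc[order(msc$start), ]
      expect_equal(msc$start, c(1, head(msc$end, -1) + 1))
      expect_equal(max(msc$end), lens[[sc]])
    }
    # per-position copy number equals the union-find oracle
    oracle <- oracle_position_copy_number(chains, lens)
    for (sc in names(lens)) {
      msc <- m[m$scaffold == sc, ]
      impl <- integer(lens[[sc]])
      for (j in seq_len(nrow(msc)))
        impl[msc$start[j]:msc$end[j]] <- msc$copy_number[j]
      expect_equal(impl, oracle[[sc]],
                   label = sprintf("rep %d scaffold %s", rep, sc))
    }
  }
})

test_that("grouping is symmetric and monotone in added alignments", {
  lens <- c(X = 500L, Y = 500L, Z = 500L)
  a <- chain_alignment("X", "Y", 500, 500,
                       data.frame(tstart = 101, qstart = 201, len = 100))
  a_flip <- chain_alignment("Y", "X", 500, 500,
                            data.frame(tstart = 201, qstart = 101, len = 100))
  b <- chain_alignment("Y", "Z", 500, 500,
                       data.frame(tstart = 201, qstart = 1, len = 100))
  m1 <- pb_members(slice_into_blocks(list(a, b), lens, min_segment = 1))
  m2 <- pb_members(slice_into_blocks(list(a_flip, b), lens, min_segment = 1))
  key <- function(m) m[order(m$scaffold, m$start),
                       c("scaffold", "start", "end", "copy_number")]
  expect_equal(key(m1), key(m2), ignore_attr = TRUE)
  # transitive closure: X[101,200] grouped with Z[1,100] without a direct chain
  g1 <- key(m1)
  expect_equal(g1$copy_number[g1$scaffold == "Z" & g1$start == 1], 3)
  # adding an alignment never decreases any position's copy number
  extra <- chain_alignment("X", "Z", 500, 500,
                           data.frame(tstart = 301, qstart = 301, len = 50))
  m3 <- pb_members(slice_into_blocks(list(a, b, extra), lens, min_segment = 1))
  cn_at <- function(m, sc, pos) {
    r <- m[m$scaffold == sc & m$start <= pos & m$end >= pos, ]
    r$copy_number
  }
  for (pos in c(50, 150, 320, 450))
    expect_gte(cn_at(m3, "X", pos), cn_at(m1, "X", pos))
})

test_that("sub-threshold slivers are absorbed into the left neighbour", {
  ch <- chain_alignment("A", "B", 1000, 1000,
                        data.frame(tstart = 1, qstart = 1, len = 505))
  ch2 <- chain_alignment("A", "C", 1000, 1000,
                         data.frame(tstart = 501, qstart = 1, len = 100))
  pbs <- slice_into_blocks(list(ch, ch2), c(A = 1000L, B = 1000L, C = 1000L),
                           min_segment = 100)
  m <- pb_members(pbs)
  mA <- m[m$scaffold == "A", ]
  # the 5-bp sliver A[501,505] was merged leftwards; partition preserved
  expect_false(any(mA$end - mA$start + 1 < 100))
  expect_equal(sum(mA$end - mA$start + 1), 1000)
})

test_that("block divergence matches the DP edit-distance oracle", {
  # Counting an indel of any length as one edit makes the unconstrained
  # optimum degenerate on long windows (delete-everything + insert-
  # everything costs 2), so the alignment-derived count can only equal the
  # DP optimum where the genuine count is itself <= 2. The oracle is
  # therefore checked on short windows around single events.
  p <- sim_params(seed = 41, ancestral_length = 20000L, indel_rate = 2e-3,
                  div_SL = 0.02, div_L1L2 = 0.018)
  sub <- simulate_subgenomes(p)
  ch <- sub$alignments$L1_L2
  seqs <- list(L1 = sub$haplotypes$L1[[1]], L2 = sub$haplotypes$L2[[1]])
  tested <- 0
  for (lo in seq(1, 19000, by = 150)) {
    sl <- hexaphase:::clip_chain_target(ch, lo, lo + 119)
    if (is.null(sl)) next
    tsp <- hexaphase:::chain_tspan(sl)
    qsp <- hexaphase:::chain_qspan(sl)
    a <- substring(seqs$L1, tsp[1], tsp[2])
    b <- substring(seqs$L2, qsp[1], qsp[2])
    st <- hexaphase:::pair_rates(sl, seqs, list(members = data.frame(
      scaffold = c("L1", "L2"), start = c(tsp[1], qsp[1]),
      end = c(tsp[2], qsp[2]))))
    mm <- round(st$snp_rate * sum(sl$blocks$len))
    events <- round(st$indel_event_rate * sum(sl$blocks$len) / 1000)
    if (mm + events > 2) next # metric degenerate beyond 2 edits
    tested <- tested + 1
    expect_equal(mm + events, oracle_edit_distance(a, b),
                 label = sprintf("edit count at window %d", lo))
    if (tested >= 25) break
  }
  expect_gte(tested, 10)
})

test_that("identical members have zero divergence; known edits are counted", {
  # two substitutions and one 5-bp insertion over a 100-bp pair
  a <- strrep("ACGT", 25)
  b <- paste0(substr(a, 1, 40), "T", substr(a, 42, 60), "AAAAA",
              substr(a, 61, 100))
  stopifnot(substr(a, 41, 41) == "A")
  b <- paste0(substr(b, 1, 20), "C", substr(b, 22, nchar(b)))
  blocks <- data.frame(tstart = c(1, 61), qstart = c(1, 66), len = c(60, 40))
  ch <- chain_alignment("a", "b", 100, 105, blocks)
  pb <- list(id = "PB", copy_number = 2,
             members = data.frame(scaffold = c("a", "b"), start = c(1, 1),
                                  end = c(100, 105), strand = "+"),
             pair_chains = list(e = list(chain = ch)))
  st <- block_divergence(pb, list(a = a, b = b))
  expect_equal(st$snp_rate, 2 / 100)
  expect_equal(st$edit_rate, 3 / 105)
  expect_equal(st$length_weighted_divergence, 7 / 105)
  # identical members
  ch0 <- chain_alignment("a", "b", 100, 100,
                         data.frame(tstart = 1, qstart = 1, len = 100))
  pb0 <- list(id = "PB0", copy_number = 2,
              members = data.frame(scaffold = c("a", "b"), start = 1,
                                   end = 100, strand = "+"),
              pair_chains = list(e = list(chain = ch0)))
  st0 <- block_divergence(pb0, list(a = a, b = a))
  expect_equal(st0$snp_rate, 0)
  expect_equal(st0$length_weighted_divergence, 0)
  # single-copy blocks are flagged, zero rates
  pb1 <- list(id = "PB1", copy_number = 1,
              members = data.frame(scaffold = "a", start = 1, end = 100,
                                   strand = "+"), pair_chains = list())
  st1 <- block_divergence(pb1, list(a = a))
  expect_true(st1$single_copy)
  expect_equal(st1$snp_rate, 0)
  # CDS restriction: rates over the columns inside the interval only
  cds <- data.frame(scaffold = "a", start = 1, end = 50)
  stc <- block_divergence(pb, list(a = a, b = b), cds_intervals = cds)
  expect_equal(stc$cds$snp_rate, 2 / 50) # both substitutions are in [1,50]
  expect_equal(stc$cds$indel_event_rate, 0)
})

test_that("CDS intervals load from GFF3", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "scaf1\tsrc\tgene\t1\t900\t.\t+\t.\tID=g1",
               "scaf1\tsrc\tCDS\t11\t310\t.\t+\t0\tID=c1",
               "scaf2\tsrc\tCDS\t5\t55\t.\t-\t0\tID=c2"), f)
  cds <- read_cds_gff(f)
  expect_equal(nrow(cds), 2)
  expect_equal(cds$scaffold, c("scaf1", "scaf2"))
  expect_equal(cds$start, c(11, 5))
  expect_equal(cds$end, c(310, 55))
})

test_that("genome-wide mean SNP rate recovers the injected divergence", {
  f <- fx_small()
  pbs <- slice_into_blocks(f$chains, f$lens)
  seqs <- as.list(f$ref$scaffolds)
  cn <- vapply(pbs$blocks, `[[`, integer(1), "copy_number")
  stats <- lapply(pbs$blocks[cn == 3], block_divergence, sequences = seqs)
  snp <- vapply(stats, `[[`, numeric(1), "snp_rate")
  lens <- vapply(pbs$blocks[cn == 3], function(pb)
    sum(pb$members$end - pb$members$start + 1), numeric(1))
  mean_snp <- sum(snp * lens) / sum(lens)
  # expected mean over the three pairs: (0.016 + 0.016 + 0.014) / 3
  expect_equal(mean_snp, mean(c(0.016, 0.016, 0.014)), tolerance = 0.1)
  # ordering invariant of the three divergence scales
  lw <- vapply(stats, `[[`, numeric(1), "length_weighted_divergence")
  expect_true(all(lw - snp > -1e-9))
})

test_that("coverage multiplicity validates copy number and flags collapse", {
  members <- data.frame(scaffold = c("a", "b", "c"), start = 1, end = 1000,
                        strand = "+")
  pbs <- structure(list(blocks = list(
    list(id = "PB1", copy_number = 3, members = members, pair_chains = list()),
    list(id = "PB2", copy_number = 2, members = members[1:2, ],
         pair_chains = list())),
    scaffold_lengths = c(a = 1000L, b = 1000L, c = 1000L)),
    class = "paralogous_blocks")
  counts <- data.frame(scaffold = c("a", "b", "c"), start = 1, end = 1000,
                       count = c(10, 10, 10))
  cov <- block_coverage(pbs, counts, haploid_fpk = 10)
  expect_equal(cov$fpk[1], 30)
  expect_equal(cov$coverage_multiplicity[1], 3)
  expect_true(cov$consistent[1])
  # 2-member PB with fpk 30 at haploid 10 -> multiplicity 3, collapsed
  counts2 <- data.frame(scaffold = c("a", "b"), start = 1, end = 1000,
                        count = c(15, 15))
  pbs2 <- pbs; pbs2$blocks <- pbs$blocks[2]
  cov2 <- block_coverage(pbs2, counts2, haploid_fpk = 10)
  expect_equal(cov2$coverage_multiplicity, 3)
  expect_equal(cov2$suspected, "collapsed")
  expect_error(block_coverage(pbs2, counts2, haploid_fpk = 0), "haploid")
})

test_that("collapsed segments from assemble_reference are flagged by coverage", {
  p <- sim_params(seed = 43, ancestral_length = 200000L,
                  scaffold_length = 10000L, collapse_rate = 0.15,
                  depth_per_copy = 20)
  sub <- simulate_subgenomes(p)
  ref <- assemble_reference(sub)
  lens <- vapply(ref$scaffolds, nchar, integer(1))
  chains <- reference_truth_chains(sub, ref)
  pbs <- slice_into_blocks(chains, lens)
  # one copy per haplovariant, so per-copy (haploid) FPK is unambiguous
  rd <- simulate_reads(sub, c("s", "L1", "L2"), p)
  pl <- place_fragments(rd, sub, ref, "sample")
  m <- pb_members(pbs)
  fc <- count_fragments_per_interval(
    pl, data.frame(scaffold = m$scaffold, start = m$start, end = m$end))
  cov <- block_coverage(pbs, fc)
  # find PBs lying in collapsed scaffolds
  coll_scafs <- ref$composition$scaffold[ref$composition$flag == "collapsed"]
  expect_gt(length(coll_scafs), 0)
  in_coll <- vapply(pbs$blocks, function(pb)
    any(pb$members$scaffold %in% coll_scafs) & pb$copy_number < 3,
    logical(1))
  flagged <- cov$suspected[in_coll] == "collapsed"
  expect_gte(mean(flagged), 0.9)
})

test_that("copy-number summary proportions are exact on synthetic truth", {
  f <- fx_small()
  pbs <- slice_into_blocks(f$chains, f$lens)
  s <- copy_number_summary(pbs)
  expect_equal(sum(s$by_copy_number), 1, tolerance = 1e-12)
  # error-free S+L1+L2 reference: nearly all length is 3-copy
  expect_gt(s$by_copy_number[s$class == "3"], 0.95)
  # all-unique genome
  pbs1 <- slice_into_blocks(list(), c(x = 5000L))
  s1 <- copy_number_summary(pbs1)
  expect_equal(s1$by_copy_number[s1$class == "1"], 1)
})

test_that("UCSC chain files are read into equivalent alignments", {
  f <- tempfile(fileext = ".chain")
  writeLines(c("chain 100 tgt 1000 + 10 60 qry 800 + 20 72 1",
               "30 5 7", "15"), f)
  ch <- read_chain(f)[[1]]
  expect_equal(ch$target, "tgt")
  expect_equal(ch$blocks$tstart, c(11, 46))
  expect_equal(ch$blocks$qstart, c(21, 58))
  expect_equal(ch$blocks$len, c(30, 15))
  # minus-strand query converts to + coordinates
  f2 <- tempfile(fileext = ".chain")
  writeLines(c("chain 50 tgt 1000 + 0 20 qry 800 - 0 20 2", "20"), f2)
  ch2 <- read_chain(f2)[[1]]
  expect_equal(ch2$strand, "-")
  expect_equal(ch2$blocks$qstart, 800 - 20 + 1)
})
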