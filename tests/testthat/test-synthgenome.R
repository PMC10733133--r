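# Synthetic-genome generator: divergence targets, degenerate limits,
# determinism, conservation, truth chains, reference errors, cohort math.

test_that("zero divergence and zero indel rates give identical haplotypes", {
  p <- sim_params(seed = 3, ancestral_length = 20000L, div_SL = 0,
                  div_L1L2 = 0, indel_rate = 0)
  sub <- simulate_subgenomes(p)
  s_full <- paste(sub$haplotypes$s, collapse = "")
  expect_identical(s_full, unname(sub$haplotypes$L1[[1]]))
  expect_identical(s_full, unname(sub$haplotypes$L2[[1]]))
  expect_equal(nrow(sub$variants), 0)
  # truth chains are single gapless full-length blocks
  for (ch in sub$alignments) expect_equal(nrow(ch$blocks), 1)
  # perfect reference: one source per scaffold, exact concatenation
  ref <- assemble_reference(sub)
  expect_true(all(table(ref$composition$scaffold) == 1))
  expect_identical(paste(ref$scaffolds, collapse = ""),
                   paste(s_full, s_full, s_full, sep = ""))
})

test_that("realized SNP divergence matches the requested targets", {
  p <- sim_params(seed = 7, ancestral_length = 500000L)
  sub <- simulate_subgenomes(p)
  for (pair in c("s_L1", "s_L2", "L1_L2")) {
    target <- if (pair == "L1_L2") p$div_L1L2 else p$div_SL
    d <- pairwise_divergence(sub, pair)
    sd3 <- 3 * sqrt(target * (1 - target) / d$columns)
    expect_lt(abs(d$divergence - target), sd3,
              label = sprintf("%s divergence %.4f vs target %.4f", pair,
                              d$divergence, target))
  }
})

test_that("realized divergence is unbiased over seeds", {
  divs <- t(vapply(1:10, function(s) {
    p <- sim_params(seed = s, ancestral_length = 30000L)
    sub <- simulate_subgenomes(p)
    c(pairwise_divergence(sub, "s_L1")$divergence,
      pairwise_divergence(sub, "L1_L2")$divergence)
  }, numeric(2)))
  # mean over 10 seeds within 3 SEs of targets
  se_sl <- sd(divs[, 1]) / sqrt(10)
  se_ll <- sd(divs[, 2]) / sqrt(10)
  expect_lt(abs(mean(divs[, 1]) - 0.016), 3 * se_sl)
  expect_lt(abs(mean(divs[, 2]) - 0.014), 3 * se_ll)
})

test_that("infeasible divergence targets are rejected", {
  expect_error(sim_params(div_SL = 0.005, div_L1L2 = 0.014), "infeasible")
  expect_error(sim_params(error_rate = 1.5), "rate")
})

test_that("generators are deterministic given the seed", {
  p <- sim_params(seed = 5, ancestral_length = 20000L, depth_per_copy = 6)
  s1 <- simulate_subgenomes(p); s2 <- simulate_subgenomes(p)
  expect_identical(s1$haplotypes, s2$haplotypes)
  r1 <- simulate_reads(s1, c("s", "L1"), p)
  r2 <- simulate_reads(s2, c("s", "L1"), p)
  expect_identical(r1$read1, r2$read1)
  w1 <- simulate_wga_library(s1, "L1", p)
  w2 <- simulate_wga_library(s2, "L1", p)
  expect_identical(w1$read1, w2$read1)
  # byte-identical FASTQ on rerun
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(w1, f1); write_fastq(w2, f2)
  expect_identical(readLines(paste0(f1, "_1.fastq")),
                   readLines(paste0(f2, "_1.fastq")))
})

test_that("read simulation conserves depth per copy", {
  p <- sim_params(seed = 9, ancestral_length = 40000L, depth_per_copy = 12,
                  indel_rate = 0)
  sub <- simulate_subgenomes(p)
  rd <- simulate_reads(sub, c("s", "s", "L1", "L2"), p)
  # total bases = copies x length x depth within sampling error
  total <- sum(nchar(rd$read1)) + sum(nchar(rd$read2))
  expect_equal(total, 4 * 40000 * 12, tolerance = 0.02)
  # truth accounts for every read
  expect_equal(nrow(rd$truth), length(rd$read1))
  # mean base coverage: s positions ~ 2 x 12, L1 positions ~ 12 (3 SD)
  tr <- rd$truth
  reads_per_hap <- table(tr$hap)
  cov <- reads_per_hap * 2 * p$read_length / 40000
  expect_lt(abs(cov[["s"]] - 24), 3 * sqrt(24 * 100 / 40000) + 1)
  expect_lt(abs(cov[["L1"]] - 12), 3 * sqrt(12 * 100 / 40000) + 1)
  # zero depth: empty FASTQ is not an error
  p0 <- sim_params(seed = 9, ancestral_length = 40000L, depth_per_copy = 0)
  rd0 <- simulate_reads(sub, c("s"), p0)
  expect_length(rd0$read1, 0)
  expect_equal(nrow(rd0$truth), 0)
  expect_error(simulate_reads(sub, c("s", "bogus"), p), "unknown")
  expect_error(simulate_reads(sub, character(0), p), "empty")
})

test_that("WGA library covers the requested breadth, unevenly", {
  f <- fx_small()
  wga <- simulate_wga_library(f$sub, "L1", f$p)
  tr <- wga$truth
  L <- nchar(f$sub$haplotypes$L1[[1]])
  cov <- logical(L)
  for (i in seq_len(nrow(tr)))
    cov[tr$frag_start[i]:min(tr$frag_end[i], L)] <- TRUE
  breadth <- mean(cov)
  expect_gt(breadth, 0.005)
  expect_lt(breadth, 0.02)
  p_bad <- f$p; p_bad$wga_breadth <- 1.5
  expect_error(simulate_wga_library(f$sub, "L1", p_bad), "breadth")
  expect_error(simulate_wga_library(f$sub, "MLI9", f$p), "target")
})

test_that("near-uniform WGA coverage in the degenerate no-bias case", {
  p <- sim_params(seed = 13, ancestral_length = 30000L, wga_breadth = 1,
                  wga_sites = 60L, wga_lognormal_sd = 0)
  sub <- simulate_subgenomes(p)
  wga <- simulate_wga_library(sub, "L1", p)
  tr <- wga$truth
  L <- nchar(sub$haplotypes$L1[[1]])
  cov <- integer(L)
  for (i in seq_len(nrow(tr))) {
    idx <- tr$frag_start[i]:min(tr$frag_end[i], L)
    cov[idx] <- cov[idx] + 1L
  }
  # interior coverage roughly even: CV well below the multimodal case
  inner <- cov[2000:(L - 2000)]
  expect_lt(sd(inner) / mean(inner), 0.6)
  expect_gt(mean(inner > 0), 0.95)
})

test_that("truth chains round-trip through PSL and mark injected indels", {
  f <- fx_small()
  path <- tempfile(fileext = ".psl")
  chains <- emit_truth_chains(f$sub, path)
  reread <- read_psl(path)
  path2 <- tempfile(fileext = ".psl")
  write_psl(reread, path2)
  expect_identical(readLines(path), readLines(path2))
  # every gap in the s-L1 truth chain sits at an injected indel position
  ch <- f$sub$alignments$s_L1
  b <- ch$blocks
  ind <- f$sub$variants[f$sub$variants$type != "sub" &
                          f$sub$variants$branch %in% c("shared", "L1"), ]
  if (nrow(b) > 1) {
    gap_t <- (b$tstart + b$len)[-nrow(b)] # first t after each block
    for (g in gap_t) {
      expect_true(any(abs(ind$pos - g) <= 1),
                  label = sprintf("gap at %d matches an injected indel", g))
    }
  }
  # single known insertion produces a PSL gap at exactly that coordinate
  p <- sim_params(seed = 2, ancestral_length = 20000L, div_SL = 0,
                  div_L1L2 = 0, indel_rate = 0)
  sub <- simulate_subgenomes(p)
  # inject one 5-bp insertion in L1 after position 5000 by hand
  v <- data.frame(branch = "L1", pos = 5000L, type = "ins", ref = "",
                  alt = "ACGTA", len = 5L)
  d1 <- hexaphase:::apply_edits(strsplit(sub$s_full, "")[[1]], v)
  expect_equal(nrow(d1$blocks), 2)
  expect_equal(d1$blocks$tstart[2], 5001)
  expect_equal(d1$blocks$qstart[2], 5006)
  expect_equal(substr(d1$seq, 5001, 5005), "ACGTA")
})

test_that("reference assembly errors follow their rates and flags", {
  p <- sim_params(seed = 17, ancestral_length = 300000L,
                  scaffold_length = 6000L, chimera_rate = 0.2)
  sub <- simulate_subgenomes(p)
  ref <- assemble_reference(sub)
  comp <- ref$composition
  per_scaf <- tapply(comp$src_hap, comp$scaffold,
                     function(x) length(unique(x)))
  frac <- mean(per_scaf >= 2)
  n <- length(per_scaf)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n) + 0.02)
  # collapsed flags mark segments whose homolog was dropped
  p2 <- sim_params(seed = 18, ancestral_length = 120000L,
                   scaffold_length = 8000L, collapse_rate = 0.5)
  sub2 <- simulate_subgenomes(p2)
  ref2 <- assemble_reference(sub2)
  flags <- ref2$composition$flag
  expect_gt(sum(flags == "collapsed"), 0)
  n_l2 <- sum(ref2$composition$src_hap == "L2")
  n_l1 <- sum(ref2$composition$src_hap == "L1")
  expect_lt(n_l2, n_l1) # L2 counterparts were dropped
})

test_that("cohort summaries reproduce the printed offspring and karyotype tables", {
  tab <- read.table(system.file("extdata", "offspring_counts.tsv",
                                package = "hexaphase"),
                    header = TRUE, sep = "\t")
  s <- summarize_cohort(tab[, setdiff(names(tab), "pool")])
  d8 <- s[s$group == "DV1_8", ]
  expect_equal(d8$total, 951)
  expect_equal(d8$normal, 787)
  expect_equal(d8$normal_pct, 82.75)
  expect_equal(d8$died, 76)
  expect_equal(d8$died_pct, 7.99)
  expect_equal(d8$abnormal_morphology_pct, 8.41)
  expect_equal(d8$abnormal_behavior_pct, 0.84)
  kar <- read.table(system.file("extdata", "karyotype_counts.tsv",
                                package = "hexaphase"),
                    header = TRUE, sep = "\t")
  ks <- summarize_cohort(kar)
  expect_equal(ks$percent, c(14, 56, 28, 2))
  # degenerate and invalid inputs
  expect_equal(nrow(summarize_cohort(data.frame())), 0)
  bad <- data.frame(group = "g", total = 10, a = 3, b = 3)
  expect_error(summarize_cohort(bad), "sum to total")
  expect_error(summarize_cohort(data.frame(group = "g", total = 5, a = -1,
                                           b = 6)), "negative")
})

test_that("within-copy S heterozygosity is off by default but available", {
  p0 <- sim_params(seed = 31, ancestral_length = 20000L)
  s0 <- simulate_subgenomes(p0)
  expect_null(s0$s2_full)
  p1 <- sim_params(seed = 31, ancestral_length = 20000L, het_S = 0.01)
  s1 <- simulate_subgenomes(p1)
  expect_false(is.null(s1$s2_full))
  n_diff <- sum(strsplit(s1$s_full, "")[[1]] !=
                  strsplit(s1$s2_full, "")[[1]])
  expect_lt(abs(n_diff / 20000 - 0.01), 3 * sqrt(0.01 / 20000))
  # the second s copy in a read set draws from the heterozygous sequence
  rd <- simulate_reads(s1, c("s", "s"), p1)
  expect_equal(sort(unique(rd$truth$copy)), 1:2)
})

test_that("sim params serialize to JSON and back", {
  p <- sim_params(seed = 23, ancestral_length = 12345L, div_SL = 0.02)
  f <- tempfile(fileext = ".json")
  write_sim_params(p, f)
  p2 <- read_sim_params(f)
  expect_equal(p, p2)
})
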