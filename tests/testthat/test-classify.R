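# Window-level evidence and classification: placement engine, counts,
# normalization, the two log-ratios, the decision rule and its
# monotonicity, scaffold classes, and block triplet comparisons.

test_that("window counting matches a direct tally; empty input gives zeros", {
  wins <- make_windows(c(a = 20000L, b = 7000L), window = 5000L)
  expect_equal(nrow(wins), 6)
  expect_true(wins$short[6]) # 2-kb tail of b
  empty <- data.frame(scaffold = character(0), start = integer(0))
  expect_equal(window_counts(empty, wins), rep(0L, 6))
  set.seed(91)
  pl <- data.frame(scaffold = sample(c("a", "b"), 500, replace = TRUE),
                   start = sample(5000L, 500, replace = TRUE))
  pl$start[pl$scaffold == "a"] <- sample(20000L, sum(pl$scaffold == "a"),
                                         replace = TRUE)
  got <- window_counts(pl, wins)
  manual <- vapply(seq_len(nrow(wins)), function(i)
    sum(pl$scaffold == wins$scaffold[i] & pl$start >= wins$start[i] &
          pl$start <= wins$end[i]), integer(1))
  expect_equal(got, manual)
  expect_error(window_counts(data.frame(scaffold = "zzz", start = 1), wins),
               "absent")
})

test_that("uniform coverage yields the expected fragments per window", {
  p <- sim_params(seed = 93, ancestral_length = 120000L, div_SL = 0,
                  div_L1L2 = 0, indel_rate = 0, depth_per_copy = 10)
  sub <- simulate_subgenomes(p)
  ref <- assemble_reference(sub)
  rd <- simulate_reads(sub, "s", p)
  pl <- place_fragments(rd, sub, ref, "sample")
  wins <- make_windows(vapply(ref$scaffolds, nchar, integer(1)))
  cnt <- window_counts(pl, wins)
  # expected fragments/window = depth x window / (2 x read_length), but a
  # fully homozygous genome spreads each fragment over 3 homologous loci
  expected <- 10 * 5000 / (2 * 100) / 3
  full <- !wins$short
  expect_equal(mean(cnt[full]), expected, tolerance = 0.1)
})

test_that("known-origin placement distributes shared fragments 1/3 each", {
  p <- sim_params(seed = 95, ancestral_length = 90000L, div_SL = 0,
                  div_L1L2 = 0, indel_rate = 0, depth_per_copy = 6)
  sub <- simulate_subgenomes(p)
  ref <- assemble_reference(sub)
  rd <- simulate_reads(sub, c("s", "s", "L1", "L2"), p)
  # all fragments are fully shared: three candidates each
  alln <- place_fragments(rd, sub, ref, "all")
  tab <- table(alln$n_candidates)
  expect_gt(tab[["3"]] / sum(tab), 0.95)
  pl <- place_fragments(rd, sub, ref, "sample")
  src <- setNames(ref$composition$src_hap, ref$composition$scaffold)
  frac <- table(src[pl$scaffold]) / nrow(pl)
  expect_equal(as.numeric(frac[c("S", "L1", "L2")]), rep(1 / 3, 3),
               tolerance = 0.05)
})

test_that("median-of-ratios normalization is scale-equivariant", {
  set.seed(97)
  covA <- rpois(400, 100)
  ratio <- normalize_median_of_ratios(covA, covA)
  expect_equal(unname(ratio$size_factors["A"]),
               unname(ratio$size_factors["B"]))
  expect_equal(ratio$normA, ratio$normB)
  cov3 <- rpois(400, 300)
  r3 <- normalize_median_of_ratios(cov3, rpois(400, 100))
  expect_equal(unname(r3$size_factors["A"] / r3$size_factors["B"]), 3,
               tolerance = 0.1)
  expect_error(normalize_median_of_ratios(rpois(50, 5), rpois(50, 5)),
               ">= 100")
})

test_that("RRC centring puts the two modes symmetric around zero", {
  set.seed(99)
  # synthetic bimodal: S windows at ratio 2, L windows at ratio 1
  nS <- 300; nL <- 600
  normA <- c(rpois(nS, 200), rpois(nL, 100))
  normB <- c(rpois(nS, 100), rpois(nL, 100))
  rrc <- compute_rrc(normA, normB)
  expect_true(rrc$bimodal)
  expect_equal(sum(rrc$modes - rrc$center), 0, tolerance = 1e-9)
  expect_gt(mean(rrc$log2_rrc[seq_len(nS)] > 0), 0.95)
  expect_gt(mean(rrc$log2_rrc[nS + seq_len(nL)] < 0), 0.95)
  # zero-count windows flagged NA and excluded
  normB[1] <- 0
  rrc2 <- compute_rrc(normA, normB)
  expect_true(is.na(rrc2$log2_rrc[1]))
  # unimodal input warns and centres at the median
  expect_warning(compute_rrc(rpois(500, 100), rpois(500, 100)), "bimodal")
})

test_that("RKC arithmetic, infinities and undefined cases", {
  kS <- c(40, 0, 0, 10)
  kL <- c(5, 5, 0, 10)
  rkc <- compute_rkc(kS, kL, totS = 100, totL = 100)
  expect_equal(rkc[1], 3) # log2(40/5)
  expect_equal(rkc[2], -Inf)
  expect_true(is.na(rkc[3]))
  expect_equal(rkc[4], 0)
  # normalization by subset totals
  rkc2 <- compute_rkc(kS, kL, totS = 200, totL = 100)
  expect_equal(rkc2[1], 2)
})

test_that("the window decision rule is exactly the stated conjunction", {
  wins <- make_windows(c(x = 50000L))
  wt <- cbind(wins, covA = 100, covB = 100,
              normA = 100, normB = 100,
              kS = c(90, 80, 0, 0, 0, 5, 60, 15, 10, 20),
              kL = c(0, 5, 80, 90, 70, 60, 0, 6, 10, 20))
  wt$log2_RKC <- compute_rkc(wt$kS, wt$kL)
  wt$log2_RRC <- c(1, 1, -1, -1, -1, -1, -0.5, 1, 1, -1)
  cls <- classify_windows(wt)$class
  expect_equal(cls[1], "S")  # top-kS, RKC = +Inf, RRC > 0
  expect_equal(cls[2], "S")  # log2(80/5) = 4 >= 1
  expect_equal(cls[3], "L")
  expect_equal(cls[4], "L")
  expect_equal(cls[7], "unclassified") # S k-mers but negative RRC
  expect_equal(cls[8], "unclassified") # RKC 1.32 but outside the top 1/3
  expect_equal(cls[9], "unclassified") # RKC 0 below threshold
  # threshold boundary: RKC +0.5 is never S regardless of other metrics
  wt2 <- wt
  wt2$kS[1] <- 10; wt2$kL[1] <- 7 # log2 ~ 0.51
  wt2$log2_RKC <- compute_rkc(wt2$kS, wt2$kL)
  expect_equal(classify_windows(wt2)$class[1], "unclassified")
  # raising the threshold never adds classified windows
  for (thr in c(1, 1.5, 2, 3)) {
    cls_thr <- classify_windows(wt, rkc_threshold = thr)$class
    expect_true(all(which(cls_thr != "unclassified") %in%
                      which(cls != "unclassified")))
  }
})

test_that("scaffold classification and the chimera rule", {
  wins <- make_windows(c(pure_s = 25000L, chim = 30000L, none = 25000L))
  wt <- cbind(wins, class = c(rep("S", 5),
                              c("S", "S", "S", "L", "L", "L"),
                              rep("unclassified", 5)))
  sc <- classify_scaffolds(wt)
  cls <- setNames(sc$scaffolds$class, sc$scaffolds$scaffold)
  expect_equal(unname(cls["pure_s"]), "S")
  expect_equal(unname(cls["chim"]), "chimeric")
  expect_equal(unname(cls["none"]), "unclassified")
  # summary lengths partition the assembly
  expect_equal(sum(sc$summary$length), 80000)
  # minority below min_chimera stays pure (at the matching majority frac)
  wt2 <- wt
  wt2$class[wt2$scaffold == "chim"] <- c("S", "S", "S", "S", "S", "L")
  sc2 <- classify_scaffolds(wt2, min_frac = 0.8)
  expect_equal(sc2$scaffolds$class[sc2$scaffolds$scaffold == "chim"], "S")
  # but below the default 0.9 majority it stays unclassified
  sc3 <- classify_scaffolds(wt2)
  expect_equal(sc3$scaffolds$class[sc3$scaffolds$scaffold == "chim"],
               "unclassified")
})

test_that("synthetic chimeric scaffolds are detected end-to-end", {
  p <- sim_params(seed = 103, ancestral_length = 240000L,
                  scaffold_length = 40000L, chimera_rate = 0.35)
  sub <- simulate_subgenomes(p)
  ref <- assemble_reference(sub)
  comp <- ref$composition
  chim_scafs <- unique(comp$scaffold[comp$flag == "chimeric"])
  # need at least one S/L chimera with both halves >= 3 windows
  sl_chim <- vapply(chim_scafs, function(s) {
    h <- comp$src_hap[comp$scaffold == s]
    length(unique(h == "S")) == 2
  }, logical(1))
  expect_gt(sum(sl_chim), 0)
  rdA <- simulate_reads(sub, c("s", "s", "L1", "L2"), p, seed = 301)
  rdB <- simulate_reads(sub, c("s", "s", "L1", "L1", "L2", "L2"), p,
                        seed = 302)
  wins <- make_windows(vapply(ref$scaffolds, nchar, integer(1)))
  covA <- window_counts(place_fragments(rdA, sub, ref, "sample", seed = 303),
                        wins)
  covB <- window_counts(place_fragments(rdB, sub, ref, "sample", seed = 304),
                        wins)
  tA <- count_kmers(rdA); tB <- count_kmers(rdB)
  pk <- find_peaks(joint_spectrum(tA, tB))
  subsets <- extract_subset(tA, tB, rectangles_from_peaks(pk))
  kS <- window_kmer_counts(subsets$S, ref$scaffolds, wins)
  kL <- window_kmer_counts(subsets$L, ref$scaffolds, wins)
  wt <- classify_windows(window_table(wins, covA, covB, kS, kL))
  sc <- classify_scaffolds(wt)
  got <- setNames(sc$scaffolds$class, sc$scaffolds$scaffold)
  expect_true(all(got[chim_scafs[sl_chim]] == "chimeric"),
              label = "S/L chimeras called chimeric")
})

test_that("block triplets recover the injected divergence contrast", {
  # S-L pairs at 2.4%, L1-L2 at 1.9%: ratio ~ 1.26
  p <- sim_params(seed = 105, ancestral_length = 200000L,
                  div_SL = 0.024, div_L1L2 = 0.019, depth_per_copy = 30)
  sub <- simulate_subgenomes(p)
  ref <- assemble_reference(sub)
  lens <- vapply(ref$scaffolds, nchar, integer(1))
  pbs <- slice_into_blocks(reference_truth_chains(sub, ref), lens)
  # classify scaffolds from truth (classification is tested elsewhere)
  src <- ref$composition
  sc <- data.frame(scaffold = src$scaffold, length = lens[src$scaffold],
                   class = ifelse(src$src_hap == "S", "S", "L"))
  cmp <- classify_blocks(pbs, sc, ref$scaffolds, ref, seed = 7)
  expect_true(all(c("S-L", "L-L") %in% cmp$summary$type))
  sl <- cmp$summary[cmp$summary$type == "S-L", ]
  ll <- cmp$summary[cmp$summary$type == "L-L", ]
  n_cols <- 200000 # aligned columns order of magnitude, for the 3-SD bound
  expect_lt(abs(sl$snp_rate - 0.024), 3 * sqrt(0.024 / n_cols) + 0.001)
  expect_lt(abs(ll$snp_rate - 0.019), 3 * sqrt(0.019 / n_cols) + 0.001)
  expect_equal(cmp$ratio, 0.024 / 0.019, tolerance = 0.08)
  # L members carry truth labels L1/L2
  expect_true(all(cmp$triplets$pair[cmp$triplets$type == "L-L"] == "L1-L2"))
  # 2-member blocks are excluded by construction
  expect_true(all(vapply(cmp$triplets$block, function(b) {
    pb <- pbs$blocks[[which(vapply(pbs$blocks, `[[`, character(1), "id") == b)[1]]]
    pb$copy_number == 3
  }, logical(1))))
})
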