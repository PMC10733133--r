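# Shared fixtures, built once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- builder()
  .fx_cache[[name]]
}

# small genome with indels, for chain / divergence / placement tests
fx_small <- function() fx("small", function() {
  p <- sim_params(seed = 11, ancestral_length = 60000L,
                  scaffold_length = 10000L, indel_rate = 5e-4,
                  depth_per_copy = 12)
  sub <- simulate_subgenomes(p)
  ref <- assemble_reference(sub)
  list(p = p, sub = sub, ref = ref,
       lens = vapply(ref$scaffolds, nchar, integer(1)),
       chains = reference_truth_chains(sub, ref))
})

# full-scale two-line design at the study conditions (used by the
# acceptance tests); one build shared by every block that needs it
fx_full <- function() fx("full", function() {
  p <- sim_params(seed = 101)
  sub <- simulate_subgenomes(p)
  ref <- assemble_reference(sub)
  rdA <- simulate_reads(sub, c("s", "s", "L1", "L2"), p, seed = p$seed + 10L)
  rdB <- simulate_reads(sub, c("s", "s", "L1", "L1", "L2", "L2"), p,
                        seed = p$seed + 11L)
  tabA <- count_kmers(rdA)
  tabB <- count_kmers(rdB)
  js <- joint_spectrum(tabA, tabB)
  peaks <- find_peaks(js)
  list(p = p, sub = sub, ref = ref,
       lens = vapply(ref$scaffolds, nchar, integer(1)),
       rdA = rdA, rdB = rdB, tabA = tabA, tabB = tabB,
       js = js, peaks = peaks)
})

# classification products on the full fixture
fx_classified <- function() fx("classified", function() {
  f <- fx_full()
  wins <- make_windows(f$lens)
  plA <- place_fragments(f$rdA, f$sub, f$ref, "sample", seed = 201)
  plB <- place_fragments(f$rdB, f$sub, f$ref, "sample", seed = 202)
  covA <- window_counts(plA, wins)
  covB <- window_counts(plB, wins)
  rects <- rectangles_from_peaks(f$peaks)
  subsets <- extract_subset(f$tabA, f$tabB, rects)
  kS <- window_kmer_counts(subsets$S, f$ref$scaffolds, wins)
  kL <- window_kmer_counts(subsets$L, f$ref$scaffolds, wins)
  wt <- classify_windows(window_table(wins, covA, covB, kS, kL))
  # truth class per window from the composition (error-free reference:
  # one source piece per scaffold)
  src <- setNames(f$ref$composition$src_hap, f$ref$composition$scaffold)
  truth <- ifelse(src[wt$scaffold] == "S", "S", "L")
  list(wins = wins, wt = wt, truth = truth, plA = plA,
       scafcls = classify_scaffolds(wt))
})
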