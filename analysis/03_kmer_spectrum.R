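#!/usr/bin/env Rscript
# Stage 3 -- joint k-mer spectrum. Counts canonical 35-mers of both
# libraries (first mates only), builds the joint 2D spectrum of k-mers
# seen at least twice in each, detects its peaks and annotates them with
# copy multiplicities; also writes a GC-stratified diagnostic.

source(file.path("analysis", "00_common.R"))
out <- res_dir("spectrum")

sp <- get_spectrum()
js <- sp$js; peaks <- sp$peaks
message(sprintf("shared 35-mers: %d (%.2f%% of the union)",
                js$n_intersection, js$shared_fraction))
write_spectrum(js, file.path(out, "joint_spectrum.tsv"))
write_tsv(js$marginalA, file.path(out, "marginal_disomic.tsv"))
write_tsv(js$marginalB, file.path(out, "marginal_tetrasomic.tsv"))

message(sprintf("%d major peaks; multiplicities: %s", nrow(peaks),
                paste(sprintf("(%d,%d)", peaks$multA, peaks$multB),
                      collapse = " ")))
write_tsv(peaks, file.path(out, "peaks.tsv"))

gs <- gc_stratified_spectrum(get_tables()$B, n_bins = 5)
occ <- data.frame(bin_lo = head(gs$bins, -1), bin_hi = gs$bins[-1],
                  n_kmers = gs$occupancy)
write_tsv(occ, file.path(out, "gc_bins.tsv"))

exp_pairs <- expected_peak_multiplicities(
  c("s", "s", "L1", "L2"), c("s", "s", "L1", "L1", "L2", "L2"))
write_tsv(exp_pairs, file.path(out, "expected_multiplicities.tsv"))
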