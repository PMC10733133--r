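#!/usr/bin/env Rscript
# Stage 5 -- subgenome classification. Builds the 5-kb window evidence
# table (normalized coverage log-ratio RRC, subgenome-specific k-mer
# log-ratio RKC), applies the decision rule, rolls windows up to scaffold
# classes and compares divergences over strictly selected PB triplets.

source(file.path("analysis", "00_common.R"))
out <- res_dir("classify")

sub <- get_sub(); ref <- get_ref(); lens <- get_lens()
rd <- get_reads(); sp <- get_spectrum(); tabs <- get_tables()

wins <- make_windows(lens, 5000L)
covA <- window_counts(place_fragments(rd$A, sub, ref, "sample",
                                      seed = PARAMS$seed + 13L), wins)
covB <- window_counts(place_fragments(rd$B, sub, ref, "sample",
                                      seed = PARAMS$seed + 14L), wins)

rects <- rectangles_from_peaks(sp$peaks)
message("frequency rectangles: ",
        paste(vapply(rects, function(r)
          sprintf("%s:[%d-%d]x[%d-%d]", r$label, r$loA, r$hiA, r$loB, r$hiB),
          character(1)), collapse = "  "))
subsets <- extract_subset(tabs$A, tabs$B, rects)
message(sprintf("subgenome-specific 35-mers: S %d, L %d",
                length(subsets$S$count), length(subsets$L$count)))

kS <- window_kmer_counts(subsets$S, ref$scaffolds, wins)
kL <- window_kmer_counts(subsets$L, ref$scaffolds, wins)
wt <- classify_windows(window_table(wins, covA, covB, kS, kL))
message(sprintf("window classes: S %d, L %d, unclassified %d",
                sum(wt$class == "S"), sum(wt$class == "L"),
                sum(wt$class == "unclassified")))
write_tsv(as.data.frame(wt), file.path(out, "window_table.tsv"))
write_window_bed(wt, file.path(out, "window_classes.bed"))

sc <- classify_scaffolds(wt)
write_tsv(sc$scaffolds, file.path(out, "scaffold_classes.tsv"))
write_tsv(sc$summary, file.path(out, "scaffold_summary.tsv"))
message(paste(capture.output(print(sc$summary)), collapse = "\n"))

pbs <- slice_into_blocks(reference_truth_chains(sub, ref), lens)
cmp <- classify_blocks(pbs, sc$scaffolds, ref$scaffolds, ref,
                       seed = PARAMS$seed + 15L)
write_tsv(cmp$triplets, file.path(out, "triplet_divergence.tsv"))
write_tsv(cmp$summary, file.path(out, "triplet_summary.tsv"))
message(sprintf(
  "triplet SNP rates: S-L %.2f%% vs L1-L2 %.2f%% (ratio %.2f)",
  100 * cmp$summary$snp_rate[cmp$summary$type == "S-L"],
  100 * cmp$summary$snp_rate[cmp$summary$type == "L-L"], cmp$ratio))
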