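#!/usr/bin/env Rscript
# Stage 6 -- microdissected-chromosome (WGA) validation. Simulates the
# uneven amplification library from L1, enumerates candidate placements,
# applies the uniqueness filter, scores 5-kb windows by mappability-
# normalized coverage breadth and checks concordance with the window
# classes of stage 5.

source(file.path("analysis", "00_common.R"))
out <- res_dir("wga")

sub <- get_sub(); ref <- get_ref(); lens <- get_lens()
wt_path <- file.path("results", "classify", "window_table.tsv")
if (!file.exists(wt_path))
  stop("run analysis/05_classify.R first (needs ", wt_path, ")")
wt <- read.table(wt_path, header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE)

wga <- simulate_wga_library(sub, "L1", PARAMS)
message(sprintf("WGA library: %d read pairs from %d amplicons",
                nrow(wga$truth), length(unique(wga$truth$amplicon))))
aln <- wga_alignments(wga, sub, ref)
kept <- filter_unique_alignments(aln, max_hits = 10L, max_edits = 1L)
message(sprintf("uniqueness filter retained %d of %d reads",
                length(unique(kept$read)), 2 * nrow(wga$truth)))

mapp <- scaffold_mappability(ref, K = 100L, E = 0L)
scores <- wga_window_score(kept, mapp, wt)
write_tsv(data.frame(wt[, c("scaffold", "start", "end", "class")],
                     wga_score = scores),
          file.path(out, "wga_scores.tsv"))

conc <- wga_class_concordance(scores, wt)
write_tsv(conc$per_class, file.path(out, "concordance.tsv"))
message(sprintf(
  "positive-score windows in class L: %.1f%%; rank effect (L over S): %.2f",
  100 * conc$positive_L_fraction, conc$auc_L_vs_S))
if (length(conc$unexpected_S))
  message(sprintf("%d S-class windows with unexpected positive scores",
                  length(conc$unexpected_S)))
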