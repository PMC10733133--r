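#!/usr/bin/env Rscript
# Stage 2 -- paralogous blocks. Slices the reference along its chained
# self-alignments, groups fully aligned homologs, validates copy number by
# read coverage (FPK) and summarizes the assembly's copy-number structure
# and paralog divergence.

source(file.path("analysis", "00_common.R"))
out <- res_dir("parablocks")

sub <- get_sub(); ref <- get_ref(); lens <- get_lens()
chains <- reference_truth_chains(sub, ref)
pbs <- slice_into_blocks(chains, lens)
message(sprintf("%d paralogous blocks over %d scaffolds",
                length(pbs$blocks), length(lens)))
write_pb_bed(pbs, file.path(out, "pb_members.bed"))

pl <- place_fragments(get_reads()$A, sub, ref, "sample",
                      seed = PARAMS$seed + 12L)
m <- pb_members(pbs)
fc <- count_fragments_per_interval(
  pl, data.frame(scaffold = m$scaffold, start = m$start, end = m$end))
cov <- block_coverage(pbs, fc)
write_tsv(cov, file.path(out, "pb_coverage.tsv"))

cns <- copy_number_summary(pbs, cov)
write_tsv(cns, file.path(out, "copy_number_summary.tsv"))
message(sprintf("3-copy fraction of assembly length: %.1f%% (by coverage: %.1f%%)",
                100 * cns$by_copy_number[cns$class == "3"],
                100 * cns$by_multiplicity[cns$class == "3"]))

seqs <- as.list(ref$scaffolds)
cn <- vapply(pbs$blocks, `[[`, integer(1), "copy_number")
stats <- lapply(pbs$blocks[cn >= 2], block_divergence, sequences = seqs)
dtab <- data.frame(
  block = vapply(pbs$blocks[cn >= 2], `[[`, character(1), "id"),
  copy_number = cn[cn >= 2],
  snp_rate = vapply(stats, `[[`, numeric(1), "snp_rate"),
  indel_event_rate = vapply(stats, `[[`, numeric(1), "indel_event_rate"),
  edit_rate = vapply(stats, `[[`, numeric(1), "edit_rate"),
  length_weighted_divergence =
    vapply(stats, `[[`, numeric(1), "length_weighted_divergence"))
write_tsv(dtab, file.path(out, "pb_divergence.tsv"))
message(sprintf("mean paralog SNP rate %.4f; length-weighted %.4f",
                mean(dtab$snp_rate), mean(dtab$length_weighted_divergence)))
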