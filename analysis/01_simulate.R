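#!/usr/bin/env Rscript
# Stage 1 -- synthetic genome. Builds the three-subgenome genome (diploid
# homozygous S split into small chromosomes; L1/L2 as diverged haplovariants
# of one fused chromosome), the haploid reference and its truth chains, and
# the two sublines' paired-end libraries; reports the realized divergences.

source(file.path("analysis", "00_common.R"))
out <- res_dir("synthetic")

sub <- get_sub()
ref <- get_ref()

div <- data.frame(
  pair = c("s_L1", "s_L2", "L1_L2"),
  target = c(PARAMS$div_SL, PARAMS$div_SL, PARAMS$div_L1L2),
  realized = vapply(c("s_L1", "s_L2", "L1_L2"), function(p)
    pairwise_divergence(sub, p)$divergence, numeric(1)))
message(sprintf("Realized SNP divergences: s-L1 %.4f, s-L2 %.4f, L1-L2 %.4f",
                div$realized[1], div$realized[2], div$realized[3]))
write_tsv(div, file.path(out, "divergences.tsv"))

write_fasta(ref$scaffolds, file.path(out, "reference.fasta"))
emit_truth_chains(sub, file.path(out, "truth_chains.psl"))
write_tsv(ref$composition, file.path(out, "composition.tsv"))
write_sim_params(PARAMS, file.path(out, "sim_params.json"))

rd <- get_reads()
message(sprintf("Read sets: disomic %d pairs, tetrasomic %d pairs",
                nrow(rd$A$truth), nrow(rd$B$truth)))
counts <- data.frame(line = c("disomic_SSL1L2", "tetrasomic_SSL1L1L2L2"),
                     fragments = c(nrow(rd$A$truth), nrow(rd$B$truth)),
                     depth_per_copy = PARAMS$depth_per_copy)
write_tsv(counts, file.path(out, "read_sets.tsv"))
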