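#!/usr/bin/env Rscript
# Stage 7 -- cohort arithmetic. Summarizes the printed offspring-assessment
# and karyotype-screen tables of the two-subline design (bundled as
# package data).

source(file.path("analysis", "00_common.R"))
out <- res_dir("cohort")

off <- read.table(system.file("extdata", "offspring_counts.tsv",
                              package = "hexaphase"),
                  header = TRUE, sep = "\t")
s <- summarize_cohort(off[, setdiff(names(off), "pool")])
write_tsv(s, file.path(out, "offspring_summary.tsv"))
message(paste(capture.output(print(s)), collapse = "\n"))

kar <- read.table(system.file("extdata", "karyotype_counts.tsv",
                              package = "hexaphase"),
                  header = TRUE, sep = "\t")
ks <- summarize_cohort(kar)
write_tsv(ks, file.path(out, "karyotype_summary.tsv"))
message(paste(capture.output(print(ks)), collapse = "\n"))
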