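#!/usr/bin/env Rscript
# Stage 4 -- joint tetraploid/hexaploid model fit. Fits the two marginal
# spectra over one shared parameter vector and decomposes the fitted
# heterozygosity rates into between-subgenome divergences.

source(file.path("analysis", "00_common.R"))
out <- res_dir("fit")

sp <- get_spectrum()
fit <- joint_fit(sp$js)
print(fit)
write_fit_report(fit, file.path(out, "fit.json"))

d <- fit$divergence
message(sprintf(
  "inferred divergences: L1-L2 %.2f%%, S vs L %.2f%%, total SNP variation %.2f%%",
  100 * d$div_L1L2, 100 * d$div_S_vs_L, 100 * d$total_snp_variation))
message(sprintf("generator truth:      L1-L2 %.2f%%, S vs L %.2f%%",
                100 * PARAMS$div_L1L2, 100 * PARAMS$div_SL))

nA <- nrow(fit$data$A)
obs_fit <- rbind(
  data.frame(axis = "disomic", freq = fit$data$A$freq,
             observed = fit$data$A$n_kmers,
             fitted = fit$fitted[seq_len(nA)] / fit$data$A$freq),
  data.frame(axis = "tetrasomic", freq = fit$data$B$freq,
             observed = fit$data$B$n_kmers,
             fitted = fit$fitted[-seq_len(nA)] / fit$data$B$freq))
write_tsv(obs_fit, file.path(out, "observed_vs_fitted.tsv"))
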