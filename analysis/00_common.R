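# Shared state for the numbered analysis scripts: the study conditions
# (one seed, the default generator parameters) and lazy builders for the
# objects several scripts need. Heavy intermediates are cached as RDS under
# scratch/ (disposable; everything is a pure function of the seed).

suppressPackageStartupMessages(library(hexaphase))

STUDY_SEED <- {
  a <- commandArgs(trailingOnly = TRUE)
  if (length(a) >= 1) as.integer(a[1]) else 1L
}
PARAMS <- sim_params(seed = STUDY_SEED)

cache_dir <- file.path("scratch", "analysis_cache", paste0("seed_", STUDY_SEED))
dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)

cached <- function(name, builder) {
  f <- file.path(cache_dir, paste0(name, ".rds"))
  if (file.exists(f)) return(readRDS(f))
  x <- builder()
  saveRDS(x, f)
  x
}

get_sub <- function() cached("sub", function() simulate_subgenomes(PARAMS))
get_ref <- function() cached("ref", function() assemble_reference(get_sub(), PARAMS))
get_lens <- function() vapply(get_ref()$scaffolds, nchar, integer(1))
get_reads <- function() cached("reads", function() list(
  A = simulate_reads(get_sub(), c("s", "s", "L1", "L2"), PARAMS,
                     seed = PARAMS$seed + 10L),
  B = simulate_reads(get_sub(), c("s", "s", "L1", "L1", "L2", "L2"), PARAMS,
                     seed = PARAMS$seed + 11L)))
get_spectrum <- function() cached("spectrum", function() {
  rd <- get_reads()
  js <- joint_spectrum(count_kmers(rd$A), count_kmers(rd$B), min_count = 2)
  list(js = js, peaks = find_peaks(js))
})
get_tables <- function() cached("tables", function() {
  rd <- get_reads()
  list(A = count_kmers(rd$A), B = count_kmers(rd$B))
})

res_dir <- function(stage) {
  d <- file.path("results", stage)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
}
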