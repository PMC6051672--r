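#!/usr/bin/env Rscript
# Stage 2: library quality control for the first screen.
#
# Checks the two things a screen depends on before any fitness maths:
# (i) insertions cover the genome approximately uniformly, with coverage
# dips only over essential-gene clusters, and (ii) read counts per site are
# approximately log-normal, so downstream frequency estimates behave.

suppressPackageStartupMessages(library(tnfit))
dir.create("results", showWarnings = FALSE)

exp <- read_manifest("scratch/simdata/mmc/manifest.yaml")
lib <- exp$samples[[1L]]

# 1 kb bins resolve individual essential-gene bodies (mean gene ~0.9 kb);
# coarser bins average them with their insertion-bearing intergenic gaps
prof <- coverage_profile(lib, bin_size = 1000)
write.table(prof, "results/qc_coverage_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("coverage: %d bins, %d flagged low (candidate essential clusters)\n",
            nrow(prof), sum(prof$flagged)))

for (s in exp$samples[1:4]) {
  d <- log_count_distribution(s)
  cat(sprintf("sample %-18s: %6d sites, log10-count skewness %+0.3f\n",
              s$sample_id, d$n_sites, d$skewness))
}
d10 <- log_count_distribution(lib, min_reads = 10)
cat(sprintf("library sites with > 10 reads: %d of %d\n",
            d10$n_sites, nrow(lib$counts)))
write.table(d10$histogram, "results/qc_logcount_hist.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
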