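#!/usr/bin/env Rscript
# Stage 1: generate the three synthetic screens.
#
# Three DNA-damage treatments are emulated as three screens over the same
# kind of library: each screen's treatment hits a core of 15 shared sensitive
# genes plus 5 genes private to that screen (fitness 0.5 under treatment,
# 1 in control). Datasets (count tables, viable counts, GFF3, truth,
# manifest) are written under scratch/simdata/<screen>/ for the later stages.

suppressPackageStartupMessages(library(tnfit))

out_root <- "scratch/simdata"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

base <- simulate_genome(sim_config(seed = 1000))
pool <- base$genes$gene_id[!base$genes$essential]
set.seed(1001)
picks <- sample(pool, 30)
shared <- sort(picks[1:15])
private <- split(picks[16:30], rep(1:3, each = 5))
screens <- c("mmc", "mms", "phleo")

writeLines(c("# shared sensitive genes", shared),
           file.path(out_root, "shared_genes.txt"))

for (i in seq_along(screens)) {
  id <- screens[i]
  cfg <- sim_config(seed = 1000 + i,
                    sensitive_genes = c(shared, private[[i]]))
  dir <- file.path(out_root, id)
  exp <- simulate_experiment(cfg, dir = dir)
  cat(sprintf(
    "screen %-6s: %d sites, %d samples, %d sensitive genes (%d shared), depth %g\n",
    id, nrow(exp$truth), length(exp$samples),
    length(exp$sensitive_genes), length(shared), cfg$read_depth))
}
cat("datasets written under", out_root, "\n")
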