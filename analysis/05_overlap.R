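#!/usr/bin/env Rscript
# Stage 5: candidate selection and cross-screen overlap.
#
# From each screen's period-2 gene table: the (up to) 200 genes with the
# lowest mean relative fitness and adjusted p < 0.01. Genes recovered by all
# three screens are the general DNA-damage-response candidates; the Venn
# regions quantify screen-specific hits.

suppressPackageStartupMessages(library(tnfit))
dir.create("results", showWarnings = FALSE)

cand <- lapply(c(mmc = "mmc", mms = "mms", phleo = "phleo"), function(id) {
  gt <- read_gene_table(file.path("results", paste0("genes_", id, "_p2.tsv")))
  gt$growth_period <- 2L          # single-period table
  select_candidates(gt, growth_period = 2, top_n = 200, alpha = 0.01)$gene_id
})
for (id in names(cand)) {
  cat(sprintf("%-6s: %d candidate genes\n", id, length(cand[[id]])))
}

ov <- overlap_screens(cand)
write_overlap_report(ov, "results/screen_overlap.tsv")
print(ov$regions[c("screens", "n")], row.names = FALSE)

core <- ov$intersections[ov$intersections$screens == "mmc+mms+phleo", ]
shared_truth <- readLines("scratch/simdata/shared_genes.txt")
shared_truth <- shared_truth[!startsWith(shared_truth, "#")]
core_genes <- strsplit(core$genes, ",")[[1L]]
cat(sprintf("\n3-way overlap: %d genes; %d of the %d truly shared sensitive genes\n",
            core$n, length(intersect(core_genes, shared_truth)),
            length(shared_truth)))
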