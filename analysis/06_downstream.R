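#!/usr/bin/env Rscript
# Stage 6: downstream follow-up statistics on simulated validation data.
#
# (a) Whole-proteome spectral counting, wild type vs a mutant in which a
#     small set of proteins accumulates: per-protein fold change and t-test,
#     with the counts of significant and significant-and-up proteins.
# (b) Cell-length filamentation: proportion of cells longer than 6.75 um
#     (three 2.25 um cell lengths) per strain, binomial-proportion SD, and a
#     one-tailed two-proportion z-test mutant vs wild type.

suppressPackageStartupMessages(library(tnfit))
dir.create("results", showWarnings = FALSE)
set.seed(9000)

## (a) spectral counts: 2000 proteins, 3 + 3 replicates, 12 accumulate 3-fold
n_prot <- 2000L
base_mean <- rlnorm(n_prot, meanlog = 4, sdlog = 0.9)
up <- seq_len(12L)
wt <- sapply(1:3, function(i) rnorm(n_prot, base_mean, 0.08 * base_mean + 2))
mut_mean <- base_mean * ifelse(seq_len(n_prot) %in% up, 3, 1)
mu <- sapply(1:3, function(i) rnorm(n_prot, mut_mean, 0.08 * mut_mean + 2))
m <- pmax(cbind(wt, mu), 0)
rownames(m) <- sprintf("prot_%04d", seq_len(n_prot))
colnames(m) <- c("wt1", "wt2", "wt3", "dm1", "dm2", "dm3")

res <- differential_abundance(normalize_counts(m), 1:3, 4:6, alpha = 0.05)
s <- attr(res, "summary")
cat(sprintf("proteins detected: %d\n", s$n_proteins))
cat(sprintf("differentially represented (p < 0.05): %d\n", s$n_significant))
cat(sprintf("of those, fold change > 1 (up in mutant): %d\n",
            s$n_significant_up))
sig <- res[res$p_value < 0.05 & res$fold_change > 1, ]
sig <- sig[order(-sig$fold_change), ]
cat(sprintf("accumulating truth proteins in the top 12 by fold change: %d/12\n",
            sum(head(sig$protein_id, 12) %in% rownames(m)[up])))
write.table(res[order(res$p_value), ], "results/proteome_diff.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## (b) cell lengths: lognormal body around 2.25 um plus a filamenting tail
rlen <- function(n, frac_long) {
  body <- rlnorm(n, meanlog = log(2.25), sdlog = 0.25)
  long <- runif(n, 7, 14)
  ifelse(runif(n) < frac_long, long, body)
}
n_cells <- 900L
strains <- list(wt = rlen(n_cells, 0.07), mutant = rlen(n_cells, 0.11))
props <- lapply(strains, proportion_long, threshold = 6.75)
for (id in names(props)) {
  cat(sprintf("%-7s: p(long) = %0.4f (sd %0.4f, n = %d)\n",
              id, props[[id]]$p, props[[id]]$sd, props[[id]]$n))
}
z <- ztest_proportions_onetailed(props$wt$p, props$wt$n,
                                 props$mutant$p, props$mutant$n)
cat(sprintf("one-tailed z-test (mutant > wt): z = %0.3f, p = %0.4f\n",
            z$z, z$p_value))
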