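#' Assign insertion sites to genes
#'
#' A site belongs to gene g iff gene start <= position <= gene end on the same
#' replicon (1-based inclusive; strand is ignored). Sites inside several
#' overlapping genes are assigned to all of them (with a warning). Sites in no
#' gene are assigned to the intergenic region they fall in, labelled
#' `ig_<k>` with regions numbered along the genome.
#'
#' @param sites data.frame with columns `replicon`, `position` (rows may
#'   repeat; assignment is per distinct position)
#' @param annotation gene data.frame from [read_gff3()]
#' @return data.frame with columns `replicon`, `position`, `gene_id`
#'   (one row per assignment, so a position can appear twice under
#'   overlapping genes)
#' @export
map_insertions_to_genes <- function(sites, annotation) {
  pos <- unique(sites[c("replicon", "position")])
  site_gr <- GenomicRanges::GRanges(
    pos$replicon, IRanges::IRanges(pos$position, width = 1L))
  gene_gr <- GenomicRanges::GRanges(
    annotation$replicon,
    IRanges::IRanges(annotation$start, annotation$end))
  hits <- GenomicRanges::findOverlaps(site_gr, gene_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  if (anyDuplicated(qh)) {
    warning(sum(duplicated(qh)),
            " site(s) fall inside overlapping genes; assigned to all of them")
  }
  genic <- data.frame(
    replicon = pos$replicon[qh],
    position = pos$position[qh],
    gene_id = annotation$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)

  # intergenic regions: gaps between merged gene bodies, numbered along the
  # genome in (replicon, start) order
  out <- genic
  orphan <- setdiff(seq_len(nrow(pos)), qh)
  if (length(orphan) > 0L) {
    merged <- GenomicRanges::reduce(gene_gr, ignore.strand = TRUE)
    gaps <- GenomicRanges::gaps(merged)
    gaps <- gaps[as.character(GenomicRanges::strand(gaps)) == "*"]
    ord <- order(as.character(GenomicRanges::seqnames(gaps)),
                 GenomicRanges::start(gaps))
    gaps <- gaps[ord]
    ig_hits <- GenomicRanges::findOverlaps(site_gr[orphan], gaps,
                                           ignore.strand = TRUE)
    ig <- data.frame(
      replicon = pos$replicon[orphan][S4Vectors::queryHits(ig_hits)],
      position = pos$position[orphan][S4Vectors::queryHits(ig_hits)],
      gene_id = sprintf("ig_%d", S4Vectors::subjectHits(ig_hits)),
      stringsAsFactors = FALSE)
    # positions beyond the annotated span (no gap range) join a trailing region
    left <- setdiff(seq_along(orphan), S4Vectors::queryHits(ig_hits))
    if (length(left) > 0L) {
      ig <- rbind(ig, data.frame(
        replicon = pos$replicon[orphan][left],
        position = pos$position[orphan][left],
        gene_id = "ig_tail", stringsAsFactors = FALSE))
    }
    out <- rbind(genic, ig)
  }
  out[order(out$replicon, out$position), , drop = FALSE]
}

#' Mean relative fitness of a gene with a 95% confidence interval
#'
#' Arithmetic mean of the per-insertion relative fitness values within the
#' gene; the 95% CI is mean +/- t(0.975, n-1) * sd / sqrt(n).
#'
#' @param values per-insertion relative fitness values (n >= min_insertions)
#' @param min_insertions minimum insertions required (default 3)
#' @return list with `mean`, `ci95_low`, `ci95_high`, `n`
#' @export
gene_relative_fitness <- function(values, min_insertions = 3) {
  n <- length(values)
  if (n < min_insertions) {
    stop("insufficient data: ", n, " insertion(s), need ", min_insertions)
  }
  m <- mean(values)
  half <- stats::qt(0.975, n - 1) * stats::sd(values) / sqrt(n)
  list(mean = m, ci95_low = m - half, ci95_high = m + half, n = n)
}

#' One-sample t-test of relative fitness against neutrality
#'
#' Two-sided test of the null that the mean relative fitness equals 1. Genes
#' whose insertions all carry the identical value give p = 1 by convention
#' (no within-gene variance, no evidence scale).
#'
#' @param values per-insertion relative fitness values, n >= 2
#' @return p-value
#' @export
test_vs_neutral <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least two insertions for a t-test")
  s <- stats::sd(values)
  if (s == 0) return(1)
  tstat <- (mean(values) - 1) / (s / sqrt(n))
  2 * stats::pt(-abs(tstat), df = n - 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; values returned in input order.
#'
#' @param p p-values in \[0, 1\]
#' @return adjusted p-values
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gene-level relative fitness table
#'
#' Aggregates the per-site relative fitness of [fitness_per_period()] to
#' genes (and intergenic regions) per growth period: mean, 95% CI, two-sided
#' one-sample t-test against 1, and BH-adjusted p-values (adjusted within each
#' growth period). Genes with fewer than `min_insertions` contributing sites
#' in a period are excluded as having insufficient data. Zero-variance genes
#' get p = 1 and `zero_variance = TRUE`.
#'
#' @param rel_fitness per-site table from [fitness_per_period()]
#' @param annotation gene data.frame from [read_gff3()]
#' @param min_insertions minimum insertions per gene per period (default 3)
#' @return data.frame with columns gene_id, growth_period, n_insertions,
#'   mean_relative_fitness, ci95_low, ci95_high, p_value, p_adj, zero_variance
#' @export
gene_fitness <- function(rel_fitness, annotation, min_insertions = 3) {
  assign <- map_insertions_to_genes(rel_fitness, annotation)
  merged <- merge(rel_fitness[c("replicon", "position", "growth_period", "w_rel")],
                  assign, by = c("replicon", "position"))
  grp <- factor(paste(merged$gene_id, merged$growth_period, sep = "\r"))
  s <- split(merged$w_rel, grp)
  n <- lengths(s)
  keys <- strsplit(names(s), "\r", fixed = TRUE)
  gene_id <- vapply(keys, `[[`, character(1L), 1L)
  period <- as.integer(vapply(keys, `[[`, character(1L), 2L))

  means <- vapply(s, mean, numeric(1L))
  sds <- vapply(s, stats::sd, numeric(1L))
  ok <- n >= 2L
  half <- rep(NA_real_, length(n))
  p <- rep(NA_real_, length(n))
  half[ok] <- stats::qt(0.975, n[ok] - 1) * sds[ok] / sqrt(n[ok])
  tstat <- (means[ok] - 1) / (sds[ok] / sqrt(n[ok]))
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n[ok] - 1)
  zero_var <- !is.na(sds) & sds == 0
  p[zero_var] <- 1

  out <- data.frame(
    gene_id = gene_id, growth_period = period, n_insertions = n,
    mean_relative_fitness = means,
    ci95_low = means - half, ci95_high = means + half,
    p_value = p, zero_variance = zero_var,
    stringsAsFactors = FALSE, row.names = NULL)
  dropped <- out$n_insertions < min_insertions
  if (any(dropped)) {
    message(sum(dropped),
            " gene/period record(s) excluded for insufficient data (< ",
            min_insertions, " insertions)")
  }
  out <- out[!dropped, , drop = FALSE]
  out$p_adj <- NA_real_
  for (k in unique(out$growth_period)) {
    idx <- out$growth_period == k
    out$p_adj[idx] <- bh_adjust(out$p_value[idx])
  }
  out <- out[order(out$growth_period, out$mean_relative_fitness,
                   out$p_adj, out$gene_id), ]
  rownames(out) <- NULL
  out[c("gene_id", "growth_period", "n_insertions", "mean_relative_fitness",
        "ci95_low", "ci95_high", "p_value", "p_adj", "zero_variance")]
}

#' Select candidate genes from one growth period
#'
#' Restricts a gene table to one growth period and `p_adj < alpha`, sorts
#' ascending by mean relative fitness (ties broken by smaller adjusted p, then
#' lexicographic gene id) and returns the first `top_n` rows (fewer if fewer
#' qualify).
#'
#' @param gene_table output of [gene_fitness()]
#' @param growth_period which period to rank (default 2)
#' @param top_n list length cap (default 200)
#' @param alpha adjusted-p cutoff, strict `<` (default 0.01)
#' @return subset of `gene_table`, ranked
#' @export
select_candidates <- function(gene_table, growth_period = 2, top_n = 200,
                              alpha = 0.01) {
  g <- gene_table[gene_table$growth_period == growth_period &
                    gene_table$p_adj < alpha, , drop = FALSE]
  g <- g[order(g$mean_relative_fitness, g$p_adj, g$gene_id), , drop = FALSE]
  g <- utils::head(g, top_n)
  rownames(g) <- NULL
  g
}
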