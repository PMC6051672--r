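#' Total-count normalization of a spectral-count matrix
#'
#' Scales each sample (column) so its total matches the across-sample mean
#' total — the usual first-pass correction for run-to-run loading differences
#' in spectral counting.
#'
#' @param raw matrix, proteins in rows, samples in columns, counts >= 0
#' @return normalized matrix of the same shape
#' @export
normalize_counts <- function(raw) {
  if (any(raw < 0)) stop("spectral counts must be non-negative")
  totals <- colSums(raw)
  if (any(totals == 0)) stop("all-zero sample column: ",
                             colnames(raw)[which(totals == 0)[1L]])
  sweep(raw, 2L, mean(totals) / totals, `*`)
}

#' Per-protein differential abundance between two groups
#'
#' For each protein: fold change = mean(group B)/mean(group A) and a
#' two-sample t-test p-value (pooled-variance Student by default, Welch
#' optionally). Proteins with a zero group-A mean get an infinite fold change
#' and are retained with a flag. Proteins with no within-group variance get
#' p = 1 when the group means agree (nothing to test) and p = 0 otherwise.
#'
#' @param matrix normalized spectral matrix (see [normalize_counts()])
#' @param group_a,group_b column names or indices of the two groups
#'   (>= 2 replicates each); by convention A = reference (WT), B = mutant
#' @param var_equal pooled-variance t-test (default TRUE)
#' @param alpha significance cutoff used for the summary counts (default 0.05)
#' @return data.frame: protein_id, mean_a, mean_b, fold_change, p_value,
#'   infinite_fold, zero_variance; attribute `summary` holds
#'   `n_significant` (p < alpha) and `n_significant_up` (also fold > 1)
#' @export
differential_abundance <- function(matrix, group_a, group_b,
                                   var_equal = TRUE, alpha = 0.05) {
  a <- matrix[, group_a, drop = FALSE]
  b <- matrix[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("need at least two replicates per group")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (mb - ma) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_var <- se == 0
  p[zero_var & mb == ma] <- 1
  p[zero_var & mb != ma] <- 0
  fold <- ifelse(ma > 0, mb / ma, Inf)
  out <- data.frame(
    protein_id = rownames(matrix) %||% as.character(seq_along(ma)),
    mean_a = ma, mean_b = mb, fold_change = fold, p_value = p,
    infinite_fold = ma == 0, zero_variance = zero_var,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "summary") <- list(
    n_proteins = nrow(out),
    n_significant = sum(out$p_value < alpha),
    n_significant_up = sum(out$p_value < alpha & out$fold_change > 1))
  out
}

#' Proportion of filamentous cells
#'
#' Fraction of cells strictly longer than `threshold` (default 6.75 um,
#' three times a typical 2.25 um cell — the operational definition of a
#' filamenting, division-blocked cell), with the binomial-proportion standard
#' deviation sqrt(p(1-p)/n).
#'
#' @param lengths cell lengths in micrometres (n >= 1, positive)
#' @param threshold length cutoff in micrometres, strict `>` (default 6.75)
#' @return list: `p`, `sd`, `n`
#' @export
proportion_long <- function(lengths, threshold = 6.75) {
  if (length(lengths) == 0L) stop("empty length sample")
  if (any(lengths <= 0)) stop("cell lengths must be positive")
  n <- length(lengths)
  p <- mean(lengths > threshold)
  list(p = p, sd = sqrt(p * (1 - p) / n), n = n)
}

#' One-tailed two-proportion Z-test
#'
#' Tests whether proportion `p2` exceeds `p1` using the pooled-proportion
#' z statistic z = (p2 - p1) / sqrt(pbar (1 - pbar) (1/n1 + 1/n2)), with the
#' upper-tail normal p-value (alternative p2 > p1). `pooled = FALSE` uses the
#' unpooled standard error instead.
#'
#' @param p1,n1 reference proportion and its sample size
#' @param p2,n2 comparison proportion and its sample size
#' @return list: `z`, `p_value`, `degenerate` (TRUE when the pooled
#'   proportion is 0 or 1 with p1 != p2, where the z statistic is undefined)
#' @export
ztest_proportions_onetailed <- function(p1, n1, p2, n2, pooled = TRUE) {
  if (n1 < 1 || n2 < 1) stop("sample sizes must be at least 1")
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  pbar <- (p1 * n1 + p2 * n2) / (n1 + n2)
  se <- if (pooled) {
    sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  } else {
    sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  }
  if (se == 0) {
    if (p1 == p2) return(list(z = 0, p_value = 0.5, degenerate = FALSE))
    return(list(z = NA_real_, p_value = NA_real_, degenerate = TRUE))
  }
  z <- (p2 - p1) / se
  list(z = z, p_value = stats::pnorm(z, lower.tail = FALSE),
       degenerate = FALSE)
}
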