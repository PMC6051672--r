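#' Insertion-coverage profile along the genome
#'
#' Sums reads in fixed-width bins tiling each replicon and reports
#' log10(sum + 1) per bin — the standard whole-genome QC track for a
#' transposon library. Bins whose raw coverage falls below `low_fraction`
#' times the replicon median are flagged; in a saturated library such dips
#' mark clusters of essential genes, where insertions are not recovered.
#'
#' @param sample `sample_counts`
#' @param bin_size bin width in bp (default 10000)
#' @param genome_length named vector of replicon lengths; defaults to the
#'   largest observed position per replicon
#' @param low_fraction flagging threshold as a fraction of the median bin
#'   coverage (default 0.1)
#' @return data.frame: replicon, bin_start, bin_end, reads, log10_coverage,
#'   flagged
#' @export
coverage_profile <- function(sample, bin_size = 10000, genome_length = NULL,
                             low_fraction = 0.1) {
  stopifnot(inherits(sample, "sample_counts"), bin_size >= 1)
  cts <- sample$counts
  reps <- sort(unique(cts$replicon))
  if (is.null(genome_length)) {
    genome_length <- vapply(reps, function(r) {
      max(cts$position[cts$replicon == r])
    }, numeric(1L))
  }
  out <- lapply(names(genome_length), function(r) {
    L <- genome_length[[r]]
    starts <- seq(1L, L, by = bin_size)
    sums <- numeric(length(starts))
    sel <- cts$replicon == r
    if (any(sel)) {
      idx <- pmin((cts$position[sel] - 1L) %/% bin_size + 1L, length(starts))
      agg <- rowsum(cts$count[sel], idx)
      sums[as.integer(rownames(agg))] <- agg[, 1L]
    }
    data.frame(replicon = r, bin_start = starts,
               bin_end = pmin(starts + bin_size - 1, L),
               reads = sums, log10_coverage = log10(sums + 1),
               flagged = sums < low_fraction * stats::median(sums),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Sample skewness (moment estimator m3 / m2^1.5); 0 for degenerate input.
sample_skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

#' Read-count distribution on the log scale
#'
#' Histogram of log10(reads) over sites with reads strictly greater than
#' `min_reads`, plus the skewness of the log counts as a descriptive
#' log-normality diagnostic (sequencing count data over a saturated library
#' should be roughly log-normal, i.e. near-zero skewness on the log scale).
#'
#' @param sample `sample_counts`
#' @param min_reads strict lower read threshold (default 0; 10 reproduces the
#'   control-sample filter)
#' @param bin_width histogram bin width in log10 units (default 0.1)
#' @return list: `histogram` (data.frame bin_low, bin_high, n), `skewness`,
#'   `n_sites`
#' @export
log_count_distribution <- function(sample, min_reads = 0, bin_width = 0.1) {
  stopifnot(inherits(sample, "sample_counts"))
  x <- sample$counts$count[sample$counts$count > min_reads]
  if (length(x) == 0L) stop("no sites above the read threshold")
  lx <- log10(x)
  breaks <- seq(floor(min(lx) / bin_width) * bin_width,
                ceiling(max(lx) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(lx, breaks = breaks, plot = FALSE)
  list(histogram = data.frame(bin_low = utils::head(h$breaks, -1),
                              bin_high = h$breaks[-1], n = h$counts),
       skewness = sample_skewness(lx),
       n_sites = length(x))
}

#' Distribution of per-insertion relative fitness in one growth period
#'
#' Histogram plus mean and SD of w_rel. In a well-behaved screen the
#' distribution is approximately normal with mean close to one (most
#' insertions are neutral to the treatment), which is what licenses the
#' gene-level t-test.
#'
#' @param rel_fitness table from [fitness_per_period()]
#' @param growth_period which period (1..3)
#' @param bin_width histogram bin width (default 0.05)
#' @return list: `histogram`, `mean`, `sd`, `n_sites`
#' @export
relative_fitness_distribution <- function(rel_fitness, growth_period,
                                          bin_width = 0.05) {
  x <- rel_fitness$w_rel[rel_fitness$growth_period == growth_period]
  if (length(x) == 0L) stop("no sites for growth period ", growth_period)
  breaks <- seq(floor(min(x) / bin_width) * bin_width,
                ceiling(max(x) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(histogram = data.frame(bin_low = utils::head(h$breaks, -1),
                              bin_high = h$breaks[-1], n = h$counts),
       mean = mean(x), sd = stats::sd(x), n_sites = length(x))
}
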