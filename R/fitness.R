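#' Population generations and expansion factor from viable counts
#'
#' One growth period expands the culture from `N0` to `Nf` viable cells; the
#' expansion factor is d = Nf/N0 and the number of population generations is
#' G = log2(d).
#'
#' @param N0,Nf positive viable-cell counts at the start and end of the period
#' @return list with numeric vectors `d` and `G`
#' @export
compute_generations <- function(N0, Nf) {
  if (any(N0 <= 0) || any(Nf <= 0)) {
    stop("viable-cell counts must be positive")
  }
  d <- Nf / N0
  list(d = d, G = log2(d))
}

#' Insertion frequency of sites in a sample
#'
#' F = reads at site / total reads in the sample. Sites absent from the sample
#' get frequency 0 (absence is not an error: most sites drop out of deep
#' libraries by chance or by selection).
#'
#' @param sample a [sample_counts()] object
#' @param sites character vector of site keys (see [site_key()]); if `NULL`,
#'   frequencies for all sites present in the sample are returned
#' @return named numeric vector of frequencies
#' @export
insertion_frequency <- function(sample, sites = NULL) {
  stopifnot(inherits(sample, "sample_counts"))
  if (sample$total_reads <= 0) stop("sample has no reads")
  f <- sample$counts$count / sample$total_reads
  names(f) <- site_key(sample$counts$replicon, sample$counts$position,
                       sample$counts$strand)
  if (any(f >= 1)) {
    warning("a site carries all reads of sample ", sample$sample_id,
            "; the rare-mutant assumption does not hold")
  }
  if (is.null(sites)) return(f)
  out <- f[sites]
  out[is.na(out)] <- 0
  names(out) <- sites
  out
}

#' Per-insertion fitness from frequency change over a known expansion
#'
#' For a mutant at frequency `F0` at the start and `Ff` at the end of a growth
#' period in which the whole population expands by factor `d`, fitness is
#'
#'   W = ln(Ff * d / F0) / ln((1 - Ff) * d / (1 - F0))
#'
#' i.e. the mutant's realised doublings relative to the rest of the
#' population. W = 1 means the mutant kept pace (Ff = F0 gives W = 1 exactly);
#' W = 0 means it did not divide at all. Mutants that vanish from the end
#' sample (Ff = 0) are assigned W = 0 and flagged `extinct` rather than given
#' a pseudocount.
#'
#' The estimator measures growth against the complement of the mutant, so it
#' is well behaved (and strictly increasing in Ff) only while the complement
#' itself still expands, i.e. Ff < 1 - (1 - F0)/d; past that point the
#' denominator changes sign. Screens operate in the rare-mutant regime where
#' this bound is immaterial, but a warning is emitted if it is crossed.
#'
#' @param F0 start frequency, strictly inside (0, 1)
#' @param Ff end frequency in \[0, 1)
#' @param d population expansion factor, must exceed 1
#' @return data.frame with columns `W` and `extinct` (vectorised over inputs)
#' @export
insertion_fitness <- function(F0, Ff, d) {
  n <- max(length(F0), length(Ff), length(d))
  F0 <- rep_len(F0, n); Ff <- rep_len(Ff, n); d <- rep_len(d, n)
  if (any(d <= 1)) {
    stop("expansion factor d must exceed 1 (no population expansion, fitness undefined)")
  }
  if (any(F0 <= 0)) stop("F0 must be positive (site absent from start sample)")
  if (any(F0 >= 1) || any(Ff >= 1)) stop("frequencies must be below 1")
  if (any(Ff < 0)) stop("frequencies must be non-negative")
  extinct <- Ff == 0
  W <- numeric(n)
  eq <- !extinct & Ff == F0
  W[eq] <- 1
  rest <- !extinct & !eq
  W[rest] <- log(Ff[rest] * d[rest] / F0[rest]) /
    log((1 - Ff[rest]) * d[rest] / (1 - F0[rest]))
  if (any((1 - Ff) * d <= (1 - F0))) {
    warning("Ff beyond the complement-expansion bound 1 - (1 - F0)/d; ",
            "fitness estimates there are not interpretable")
  }
  data.frame(W = W, extinct = extinct)
}

#' Treatment-to-control relative fitness of an insertion
#'
#' w_rel = W_treatment / W_control isolates the treatment effect from general
#' growth defects. Control-extinct mutants (W_control <= 0) carry no
#' information about the treatment and are returned as NA for the caller to
#' exclude.
#'
#' @param W_treatment,W_control per-insertion fitness values
#' @return numeric vector of ratios, NA where W_control <= 0
#' @export
relative_fitness <- function(W_treatment, W_control) {
  out <- ifelse(W_control > 0, W_treatment / W_control, NA_real_)
  if (anyNA(out)) {
    message(sum(is.na(out)),
            " site(s) excluded: extinct or non-growing in the control")
  }
  out
}

#' Read-count filter on the control start sample
#'
#' Keeps sites with strictly more than `threshold` reads in the (pooled)
#' control sample of a growth period; the default of 10 reads removes sites
#' whose frequency estimates are dominated by counting noise.
#'
#' @param control_sample `sample_counts` (pool replicates first if several)
#' @param threshold minimum read count, exclusive (default 10)
#' @return character vector of retained site keys
#' @export
filter_insertions <- function(control_sample, threshold = 10) {
  stopifnot(inherits(control_sample, "sample_counts"), threshold >= 0)
  keep <- control_sample$counts$count > threshold
  site_key(control_sample$counts$replicon[keep],
           control_sample$counts$position[keep],
           control_sample$counts$strand[keep])
}

# Pool replicate samples of one (condition, growth-period) cell by summing
# counts site-wise. Pooling preserves total_reads (sum of the parts).
pool_samples <- function(samples) {
  stopifnot(length(samples) >= 1L)
  if (length(samples) == 1L) return(samples[[1L]])
  all_counts <- do.call(rbind, lapply(samples, `[[`, "counts"))
  agg <- stats::aggregate(count ~ replicon + position + strand, all_counts, sum)
  sample_counts(agg,
                sample_id = paste0(samples[[1L]]$sample_id, "_pooled"),
                condition = samples[[1L]]$condition,
                growth_period = samples[[1L]]$growth_period,
                replicate = 1L)
}

# Mean of per-replicate frequency vectors over a fixed site set.
mean_frequency <- function(samples, sites) {
  fs <- vapply(samples, function(s) insertion_frequency(s, sites),
               numeric(length(sites)))
  if (length(sites) == 1L) fs <- matrix(fs, nrow = 1L)
  rowMeans(fs)
}

# Select samples of an experiment by metadata.
pick_samples <- function(experiment, condition, growth_period) {
  Filter(function(s) s$condition == condition &&
           s$growth_period == growth_period, experiment$samples)
}

# Geometric-mean expansion factor for (condition, period) from growth records.
expansion_factor <- function(growth, condition, period) {
  g <- growth[growth$condition == condition & growth$growth_period == period, ]
  if (nrow(g) == 0L) return(NA_real_)
  exp(mean(log(g$Nf / g$N0)))
}

#' Per-site relative fitness for each growth period
#'
#' Runs the full per-insertion computation for growth periods 1..3 of a
#' serial-passage screen. For period k the start frequencies come from the
#' sample with growth-period code k (the shared starter for k = 1, the same
#' condition's previous-period sample otherwise) and the end frequencies from
#' code k + 1. Replicates are averaged at the frequency level before fitness
#' is computed (`replicate_mode = "pool"`), or paired replicate-by-replicate
#' and the per-pair ratios averaged (`"pairs"`). Sites must exceed
#' `min_control_reads` reads in the pooled control start sample of the period
#' (strict inequality). Sites absent from the treatment start sample, or
#' extinct/non-growing in the control, are excluded from the ratio.
#'
#' @param experiment a `tnseq_experiment` (from [read_manifest()] or
#'   [simulate_experiment()])
#' @param min_control_reads read filter threshold (default 10, strict `>`)
#' @param replicate_mode `"pool"` (default) or `"pairs"`
#' @param pseudocount reads added to every site of every sample before
#'   frequencies are computed (default 0; sensitivity analysis only)
#' @param periods growth periods to process (default 1:3)
#' @return data.frame with one row per retained (site, period):
#'   replicon, position, strand, growth_period, F0_control, Ff_control,
#'   F0_treatment, Ff_treatment, d_control, d_treatment, W_control,
#'   W_treatment, w_rel, extinct_control, extinct_treatment
#' @export
fitness_per_period <- function(experiment, min_control_reads = 10,
                               replicate_mode = c("pool", "pairs"),
                               pseudocount = 0, periods = 1:3) {
  replicate_mode <- match.arg(replicate_mode)
  growth <- experiment$growth
  if (is.null(growth)) stop("experiment has no viable-count growth records")
  out <- vector("list", length(periods))
  for (i in seq_along(periods)) {
    k <- periods[i]
    start_code <- as.integer(k)       # sample code of the period start
    end_code <- as.integer(k + 1)     # sample code of the period end
    start_cond_ctrl <- if (k == 1L) "shared" else "control"
    start_cond_trt <- if (k == 1L) "shared" else "treatment"
    ctrl0 <- pick_samples(experiment, start_cond_ctrl, start_code)
    trt0 <- pick_samples(experiment, start_cond_trt, start_code)
    ctrlf <- pick_samples(experiment, "control", end_code)
    trtf <- pick_samples(experiment, "treatment", end_code)
    if (!length(ctrl0) || !length(trt0) || !length(ctrlf) || !length(trtf)) {
      warning("growth period ", k, " skipped: missing count sample")
      next
    }
    d_ctrl <- expansion_factor(growth, "control", k)
    d_trt <- expansion_factor(growth, "treatment", k)
    if (is.na(d_ctrl) || is.na(d_trt)) {
      warning("growth period ", k, " skipped: missing growth record")
      next
    }

    if (pseudocount > 0) {
      bump <- function(s) {
        s$counts$count <- s$counts$count + pseudocount
        s$total_reads <- sum(s$counts$count)
        s
      }
      ctrl0 <- lapply(ctrl0, bump); trt0 <- lapply(trt0, bump)
      ctrlf <- lapply(ctrlf, bump); trtf <- lapply(trtf, bump)
    }

    pooled_ctrl0 <- pool_samples(ctrl0)
    sites <- filter_insertions(pooled_ctrl0, min_control_reads)
    if (length(sites) == 0L) next

    if (replicate_mode == "pool") {
      tab <- period_fitness_once(sites, ctrl0, ctrlf, trt0, trtf,
                                 d_ctrl, d_trt)
    } else {
      # per-pair tables share the row set (one row per filtered site, NA where
      # a pair cannot compute the ratio), so they average row-wise
      n_pairs <- min(length(ctrl0), length(ctrlf), length(trt0), length(trtf))
      pair_tabs <- lapply(seq_len(n_pairs), function(r) {
        period_fitness_once(sites, ctrl0[r], ctrlf[r], trt0[r], trtf[r],
                            d_ctrl, d_trt)
      })
      tab <- pair_tabs[[1L]]
      if (n_pairs > 1L) {
        num_cols <- c("F0_control", "Ff_control", "F0_treatment",
                      "Ff_treatment", "W_control", "W_treatment", "w_rel")
        for (cn in num_cols) {
          m <- vapply(pair_tabs, `[[`, numeric(nrow(tab)), cn)
          tab[[cn]] <- rowMeans(m, na.rm = TRUE)
        }
        tab$extinct_control <-
          Reduce(`&`, lapply(pair_tabs, `[[`, "extinct_control"))
        tab$extinct_treatment <-
          Reduce(`&`, lapply(pair_tabs, `[[`, "extinct_treatment"))
      }
    }
    keep <- is.finite(tab$w_rel)
    n_excl <- sum(!keep)
    if (n_excl > 0) {
      message("period ", k, ": ", n_excl,
              " site(s) excluded (absent from a start sample or control-extinct)")
    }
    tab <- tab[keep, , drop = FALSE]
    if (nrow(tab) == 0L) next
    tab$growth_period <- k
    out[[i]] <- tab
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    stop("no growth period could be processed")
  }
  rownames(res) <- NULL
  cols <- c("replicon", "position", "strand", "growth_period",
            "F0_control", "Ff_control", "F0_treatment", "Ff_treatment",
            "d_control", "d_treatment", "W_control", "W_treatment", "w_rel",
            "extinct_control", "extinct_treatment")
  res[cols]
}

# One period's fitness table for a given replicate grouping: one row per site
# in `sites`, w_rel = NA where the ratio cannot be computed (site absent from
# a start sample, or control-extinct). No period column.
period_fitness_once <- function(sites, ctrl0, ctrlf, trt0, trtf,
                                d_ctrl, d_trt) {
  F0c <- mean_frequency(ctrl0, sites)
  Ffc <- mean_frequency(ctrlf, sites)
  F0t <- mean_frequency(trt0, sites)
  Fft <- mean_frequency(trtf, sites)

  n <- length(sites)
  Wc <- rep(NA_real_, n); Wt <- rep(NA_real_, n)
  exc <- rep(NA, n); ext <- rep(NA, n)
  ok <- F0c > 0 & F0t > 0       # must be present in both start samples
  if (any(ok)) {
    wc <- insertion_fitness(F0c[ok], Ffc[ok], d_ctrl)
    wt <- insertion_fitness(F0t[ok], Fft[ok], d_trt)
    Wc[ok] <- wc$W; Wt[ok] <- wt$W
    exc[ok] <- wc$extinct; ext[ok] <- wt$extinct
  }
  w_rel <- ifelse(!is.na(Wc) & Wc > 0, Wt / Wc, NA_real_)
  parts <- do.call(rbind, strsplit(sites, ":", fixed = TRUE))
  data.frame(
    replicon = parts[, 1L], position = as.integer(parts[, 2L]),
    strand = parts[, 3L],
    F0_control = F0c, Ff_control = Ffc,
    F0_treatment = F0t, Ff_treatment = Fft,
    d_control = d_ctrl, d_treatment = d_trt,
    W_control = Wc, W_treatment = Wt,
    w_rel = w_rel,
    extinct_control = exc,
    extinct_treatment = ext,
    stringsAsFactors = FALSE)
}
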