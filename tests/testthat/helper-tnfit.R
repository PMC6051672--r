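# Shared fixtures and independent oracles for the test suite.

# A small hand-built sample: four sites on one replicon.
tiny_sample <- function(counts = c(5, 10, 15, 500), condition = "shared",
                        growth_period = 0L, replicate = 1L) {
  sample_counts(
    data.frame(replicon = "chr",
               position = c(100L, 250L, 400L, 900L)[seq_along(counts)],
               strand = c("+", "-", "+", "-")[seq_along(counts)],
               count = counts),
    sample_id = "tiny", condition = condition,
    growth_period = growth_period, replicate = replicate)
}

# Build a sample_counts directly from a frequency vector over a site table,
# with counts proportional to frequency at a given (noise-free) depth.
exact_sample <- function(sites, freq, depth, condition, growth_period,
                         replicate = 1L, id = "exact") {
  cts <- data.frame(sites, count = freq * depth)
  sample_counts(cts[cts$count > 0, ], sample_id = id, condition = condition,
                growth_period = growth_period, replicate = replicate)
}

# Brute-force Benjamini-Hochberg: adj_i = min over j with p_j >= p_i of
# p_j * m / rank_j, straight from the step-up definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(ranked[i:m] * m / (i:m), 1)
  }, numeric(1))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Noise-free serial-passage fitness estimate for one rare mutant of true
# fitness w in a neutral background: grow, then invert through the estimator.
rare_mutant_west <- function(w_true, f0 = 1e-4, d = 100, n_background = 9) {
  freq <- c(f0, rep((1 - f0) / n_background, n_background))
  w <- c(w_true, rep(1, n_background))
  pass <- simulate_passage(freq, w, d)
  est <- insertion_fitness(f0, pass$frequencies[1L],
                           pass$Nf / pass$N0)
  est$W
}

# Small full experiment used by several files (1-2 s to simulate); any
# sim_config argument can be overridden.
small_experiment <- function(seed = 11, ...) {
  defaults <- list(n_genes = 60, n_insertions = 6000, read_depth = 3e5,
                   n_sensitive_genes = 5, essential_gene_fraction = 0.1)
  args <- utils::modifyList(defaults, list(...))
  simulate_experiment(do.call(sim_config, c(list(seed = seed), args)))
}
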