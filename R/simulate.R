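#' Simulation configuration for a synthetic Tn-seq screen
#'
#' Defaults describe the screen the pipeline is designed for: a saturated
#' transposon library of 120,000 distinct insertion sites over a genome of
#' 1,000 genes with two clustered essential regions, split into control and
#' treatment cultures and passaged for three growth periods of three
#' generations each (d = 8 per period, matching viable counts of the
#' 5e6 -> 4e7 kind), with a minority of genes carrying a condition-specific
#' fitness deficit and multinomial sequencing noise at 5e6 reads per sample.
#'
#' @param seed master seed; per-sample seeds are derived from it by a stable
#'   hash of (condition, growth period, replicate)
#' @param n_genes number of genes
#' @param mean_gene_length,gene_length_sd gene length distribution (bp)
#' @param intergenic_fraction fraction of the genome between genes
#' @param n_insertions distinct insertion sites in the library
#' @param essential_gene_fraction fraction of genes that are essential
#'   (insertions in them are never recovered); placed in
#'   `n_essential_clusters` contiguous blocks
#' @param n_essential_clusters number of essential clusters
#' @param n_sensitive_genes genes with a treatment-specific fitness deficit
#' @param sensitive_genes optional explicit gene ids overriding
#'   `n_sensitive_genes` (used to build screens sharing hits)
#' @param true_w_treatment fitness of sensitive-gene insertions under
#'   treatment
#' @param true_w_control fitness of all (non-essential) insertions in the
#'   control
#' @param n_periods growth periods after the split
#' @param d_per_period population expansion factor per period
#' @param read_depth reads per sequencing sample
#' @param n_replicates replicate cultures (and samples) per condition
#' @param n0_cells viable cells at the start of each period
#' @param bottleneck_size if set, cells are multinomially subsampled to this
#'   number between periods (adds drift; off by default)
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L, n_genes = 1000L, mean_gene_length = 900,
                       gene_length_sd = 180, intergenic_fraction = 0.15,
                       n_insertions = 120000L,
                       essential_gene_fraction = 0.05,
                       n_essential_clusters = 2L,
                       n_sensitive_genes = 20L, sensitive_genes = NULL,
                       true_w_treatment = 0.5, true_w_control = 1,
                       n_periods = 3L, d_per_period = 8,
                       read_depth = 5e6, n_replicates = 2L,
                       n0_cells = 5e6, bottleneck_size = NULL) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              mean_gene_length = mean_gene_length,
              gene_length_sd = gene_length_sd,
              intergenic_fraction = intergenic_fraction,
              n_insertions = as.integer(n_insertions),
              essential_gene_fraction = essential_gene_fraction,
              n_essential_clusters = as.integer(n_essential_clusters),
              n_sensitive_genes = as.integer(n_sensitive_genes),
              sensitive_genes = sensitive_genes,
              true_w_treatment = true_w_treatment,
              true_w_control = true_w_control,
              n_periods = as.integer(n_periods),
              d_per_period = d_per_period,
              read_depth = read_depth,
              n_replicates = as.integer(n_replicates),
              n0_cells = n0_cells, bottleneck_size = bottleneck_size)
  if (cfg$n_genes <= 0) stop("n_genes must be positive")
  if (cfg$n_insertions <= 0) stop("n_insertions must be positive")
  if (cfg$intergenic_fraction < 0 || cfg$intergenic_fraction >= 1) {
    stop("intergenic_fraction must be in [0, 1)")
  }
  if (cfg$essential_gene_fraction < 0 || cfg$essential_gene_fraction > 1) {
    stop("essential_gene_fraction must be in [0, 1]")
  }
  if (cfg$true_w_treatment < 0 || cfg$true_w_control < 0) {
    stop("true fitness values must be non-negative")
  }
  if (cfg$d_per_period <= 1) stop("d_per_period must exceed 1")
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic 31-bit seed from the master seed plus a string tag, so each
# sample's noise is reproducible independently of evaluation order.
derive_seed <- function(master, ...) {
  tag <- paste(..., sep = "/")
  h <- as.numeric(master) %% 2147483647
  for (c in utf8ToInt(tag)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Simulate a genome annotation
#'
#' Packs `n_genes` non-overlapping genes of normally distributed length onto
#' one circular replicon (`chr`) with intergenic gaps sized to hit the
#' configured intergenic fraction. A contiguous block (or blocks) of genes is
#' marked essential. Deterministic under the config seed.
#'
#' @param config `sim_config`
#' @return list: `genes` (data.frame gene_id, name, replicon, start, end,
#'   strand, essential), `genome_length`
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  n <- config$n_genes
  lens <- pmax(150, round(stats::rnorm(n, config$mean_gene_length,
                                       config$gene_length_sd)))
  ig_total <- sum(lens) * config$intergenic_fraction /
    (1 - config$intergenic_fraction)
  gap_mean <- ig_total / (n + 1)
  gaps <- pmax(10, round(stats::rnorm(n + 1, gap_mean, gap_mean * 0.3)))
  starts <- cumsum(gaps[seq_len(n)]) + c(0, cumsum(lens))[seq_len(n)] + 1
  ends <- starts + lens - 1
  genome_length <- ends[n] + gaps[n + 1]

  n_ess <- round(config$essential_gene_fraction * n)
  essential <- rep(FALSE, n)
  if (n_ess > 0) {
    k <- max(1L, config$n_essential_clusters)
    block <- ceiling(n_ess / k)
    anchors <- round(seq(0.25, 0.75, length.out = k) * n)
    for (a in anchors) {
      take <- seq(a, length.out = block)
      take <- take[take <= n]
      essential[take] <- TRUE
    }
    # trim to exactly n_ess if rounding over-assigned
    extra <- sum(essential) - n_ess
    if (extra > 0) essential[rev(which(essential))[seq_len(extra)]] <- FALSE
  }
  genes <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(n)),
    name = sprintf("gene_%04d", seq_len(n)),
    replicon = "chr", start = starts, end = ends,
    strand = sample(c("+", "-"), n, replace = TRUE),
    essential = essential, stringsAsFactors = FALSE)
  list(genes = genes, genome_length = genome_length)
}

#' Write a simulated annotation as GFF3
#'
#' @param genome result of [simulate_genome()]
#' @param path output path
#' @export
write_genome_gff3 <- function(genome, path) {
  g <- genome$genes
  lines <- c("##gff-version 3",
             sprintf("##sequence-region chr 1 %d", genome$genome_length),
             sprintf("chr\ttnfit_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     g$start, g$end, g$strand, g$gene_id, g$name))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a transposon insertion library
#'
#' Insertion positions are uniform over the genome excluding essential gene
#' bodies (so the coverage track dips there, as in a real saturated library);
#' initial abundances are equal across sites. Sites inside sensitive genes
#' carry the configured treatment fitness in the truth table; all sites have
#' the configured control fitness.
#'
#' @param genome result of [simulate_genome()]
#' @param config `sim_config`
#' @return list: `sites` (replicon, position, strand), `truth` (site columns,
#'   gene_id, label in neutral/sensitive, w_control, w_treatment),
#'   `frequencies` (equal), `sensitive_genes`
#' @export
simulate_library <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "library"))
  g <- genome$genes
  allowed <- rep(TRUE, genome$genome_length)
  ess <- g[g$essential, , drop = FALSE]
  for (i in seq_len(nrow(ess))) allowed[ess$start[i]:ess$end[i]] <- FALSE
  pool <- which(allowed)
  if (length(pool) < config$n_insertions) {
    stop("genome too small for ", config$n_insertions, " distinct insertions")
  }
  pos <- sort(sample(pool, config$n_insertions))
  sites <- data.frame(replicon = "chr", position = pos,
                      strand = sample(c("+", "-"), length(pos), replace = TRUE),
                      stringsAsFactors = FALSE)

  sens <- config$sensitive_genes
  if (is.null(sens)) {
    pool_genes <- g$gene_id[!g$essential]
    sens <- sort(sample(pool_genes, config$n_sensitive_genes))
  }
  if (!all(sens %in% g$gene_id)) stop("unknown sensitive gene id")

  # gene of each site (first containing gene; simulated genes never overlap)
  idx <- findInterval(sites$position, g$start)
  gene_id <- ifelse(idx >= 1 & sites$position <= g$end[pmax(idx, 1L)],
                    g$gene_id[pmax(idx, 1L)], NA_character_)
  in_sens <- !is.na(gene_id) & gene_id %in% sens
  truth <- data.frame(
    sites,
    gene_id = gene_id,
    label = ifelse(in_sens, "sensitive", "neutral"),
    w_control = config$true_w_control,
    w_treatment = ifelse(in_sens, config$true_w_treatment, 1),
    stringsAsFactors = FALSE)
  list(sites = sites, truth = truth,
       frequencies = rep(1 / nrow(sites), nrow(sites)),
       sensitive_genes = sens)
}

#' Deterministic growth of the mutant pool over one period
#'
#' Each mutant's cell count is multiplied by d^W over a period in which a
#' fully fit mutant expands d-fold. The realised population expansion
#' Nf/N0 = sum(f_i d^(W_i)) therefore reflects the fitness mixture rather
#' than the nominal d, exactly as viable-cell counts would.
#'
#' @param frequencies current site frequencies (sum to 1)
#' @param w per-site fitness under the growing condition
#' @param d nominal per-period expansion factor (> 1)
#' @param n0_cells viable cells at the period start
#' @return list: `frequencies` (after growth), `N0`, `Nf`, `d_realized`
#' @export
simulate_passage <- function(frequencies, w, d, n0_cells = 5e6) {
  if (d <= 1) stop("expansion factor d must exceed 1")
  stopifnot(length(frequencies) == length(w))
  grown <- frequencies * d^w
  d_real <- sum(grown)
  list(frequencies = grown / d_real, N0 = n0_cells, Nf = n0_cells * d_real,
       d_realized = d_real)
}

#' Multinomial sequencing of the pool
#'
#' Draws `depth` reads over sites proportional to abundance; total reads
#' equal `depth` exactly.
#'
#' @param frequencies site frequencies
#' @param depth total reads
#' @param seed optional seed set before the draw
#' @return integer read counts aligned with `frequencies`
#' @export
sample_reads <- function(frequencies, depth, seed = NULL) {
  if (depth <= 0) stop("depth must be positive")
  if (!is.null(seed)) set.seed(seed)
  as.vector(stats::rmultinom(1L, size = depth, prob = frequencies))
}

#' Simulate a complete serial-passage screen
#'
#' Library -> starter -> split into control and treatment -> `n_periods`
#' growth periods, sequencing every sample with multinomial noise and
#' recording viable-cell counts per period. Replicate cultures share the
#' deterministic growth trajectory and differ in sequencing noise (and in
#' drift if a bottleneck is configured). Byte-deterministic under the config
#' seed. Optionally writes the whole dataset (count tables, viable counts,
#' GFF3, truth table, manifest) to `dir`.
#'
#' @param config `sim_config`
#' @param dir optional output directory
#' @return `tnseq_experiment` list with elements `samples`, `growth`,
#'   `annotation`, plus `truth`, `sensitive_genes`, `genome_length`, `config`
#' @export
simulate_experiment <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genome <- simulate_genome(config)
  lib <- simulate_library(genome, config)
  n_sites <- nrow(lib$sites)

  make_sample <- function(freq, condition, code, rep) {
    counts <- sample_reads(freq, config$read_depth,
                           seed = derive_seed(config$seed, condition, code, rep))
    keep <- counts > 0
    sample_counts(
      data.frame(replicon = lib$sites$replicon[keep],
                 position = lib$sites$position[keep],
                 strand = lib$sites$strand[keep],
                 count = counts[keep], stringsAsFactors = FALSE),
      sample_id = sprintf("%s_p%d_rep%d", condition, code, rep),
      condition = condition, growth_period = code, replicate = rep)
  }

  samples <- list()
  for (r in seq_len(config$n_replicates)) {
    samples[[length(samples) + 1L]] <- make_sample(lib$frequencies, "shared", 0L, r)
  }
  # starter: neutral outgrowth of the library, frequencies unchanged
  for (r in seq_len(config$n_replicates)) {
    samples[[length(samples) + 1L]] <- make_sample(lib$frequencies, "shared", 1L, r)
  }

  growth <- list()
  for (cond in c("control", "treatment")) {
    w <- if (cond == "treatment") lib$truth$w_treatment else lib$truth$w_control
    f <- lib$frequencies
    for (k in seq_len(config$n_periods)) {
      if (!is.null(config$bottleneck_size) && k > 1L) {
        bn <- sample_reads(f, config$bottleneck_size,
                           seed = derive_seed(config$seed, cond, "bottleneck", k))
        f <- bn / sum(bn)
      }
      pass <- simulate_passage(f, w, config$d_per_period, config$n0_cells)
      f <- pass$frequencies
      for (r in seq_len(config$n_replicates)) {
        samples[[length(samples) + 1L]] <- make_sample(f, cond, k + 1L, r)
        growth[[length(growth) + 1L]] <- data.frame(
          condition = cond, growth_period = k, replicate = r,
          N0 = pass$N0, Nf = pass$Nf, stringsAsFactors = FALSE)
      }
    }
  }
  growth <- do.call(rbind, growth)

  annotation <- genome$genes[c("gene_id", "name", "replicon", "start",
                               "end", "strand")]
  exp <- structure(
    list(samples = samples, growth = growth, annotation = annotation,
         truth = lib$truth, sensitive_genes = lib$sensitive_genes,
         essential_genes = genome$genes$gene_id[genome$genes$essential],
         genome_length = genome$genome_length, config = config),
    class = "tnseq_experiment")

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    entries <- lapply(exp$samples, function(s) {
      fn <- paste0(s$sample_id, ".tsv")
      write_count_table(s, file.path(dir, fn))
      list(file = fn, sample_id = s$sample_id, condition = s$condition,
           growth_period = s$growth_period, replicate = s$replicate)
    })
    write_viable_counts(growth, file.path(dir, "viable_counts.tsv"))
    write_genome_gff3(genome, file.path(dir, "genome.gff3"))
    utils::write.table(lib$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    yaml::write_yaml(list(annotation = "genome.gff3",
                          viable_counts = "viable_counts.tsv",
                          samples = entries),
                     file.path(dir, "manifest.yaml"))
  }
  exp
}
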