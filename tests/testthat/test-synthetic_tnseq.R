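test_that("simulated genomes pack genes to the configured density", {
  cfg <- sim_config(seed = 5, n_genes = 100, mean_gene_length = 900,
                    intergenic_fraction = 0.15)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$genes), 100L)
  expect_equal(g$genome_length, 100 * 900 / 0.85, tolerance = 0.1)
  # genes do not overlap and sit inside the genome
  expect_true(all(g$genes$start <= g$genes$end))
  expect_true(all(diff(g$genes$start) > 0))
  expect_true(all(g$genes$end[-100] < g$genes$start[-1]))
  expect_lte(max(g$genes$end), g$genome_length)

  expect_error(sim_config(n_genes = 0), "positive")
})

test_that("the same seed reproduces the annotation byte for byte", {
  cfg <- sim_config(seed = 9, n_genes = 40)
  p1 <- withr::local_tempfile(fileext = ".gff3")
  p2 <- withr::local_tempfile(fileext = ".gff3")
  write_genome_gff3(simulate_genome(cfg), p1)
  write_genome_gff3(simulate_genome(cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
  ann <- read_gff3(p1)
  expect_equal(nrow(ann), 40L)
})

test_that("libraries avoid essential genes and mark sensitive sites", {
  cfg <- sim_config(seed = 6, n_genes = 80, n_insertions = 4000,
                    essential_gene_fraction = 0.25, n_sensitive_genes = 6)
  g <- simulate_genome(cfg)
  lib <- simulate_library(g, cfg)
  ess <- g$genes[g$genes$essential, ]
  expect_gt(nrow(ess), 0L)
  in_ess <- vapply(lib$sites$position, function(p) {
    any(p >= ess$start & p <= ess$end)
  }, logical(1))
  expect_false(any(in_ess))

  sens_sites <- lib$truth$label == "sensitive"
  expect_setequal(unique(lib$truth$gene_id[sens_sites]), lib$sensitive_genes)
  expect_true(all(lib$truth$w_treatment[sens_sites] == cfg$true_w_treatment))
  expect_true(all(lib$truth$w_treatment[!sens_sites] == 1))
  expect_true(all(lib$truth$w_control == 1))

  open_cfg <- sim_config(seed = 6, n_genes = 80, n_insertions = 4000,
                         essential_gene_fraction = 0)
  open_lib <- simulate_library(simulate_genome(open_cfg), open_cfg)
  expect_equal(nrow(open_lib$sites), 4000L)
  expect_true(all(table(cut(open_lib$sites$position, 4)) > 0))
})

test_that("deterministic passage follows d^W growth", {
  f <- rep(0.25, 4)
  neutral <- simulate_passage(f, rep(1, 4), d = 100)
  expect_equal(neutral$frequencies, f)
  expect_equal(neutral$Nf / neutral$N0, 100)

  # rare mutant of half fitness: frequency ratio ~ d^(-1/2)
  f2 <- c(1e-4, 1 - 1e-4)
  p <- simulate_passage(f2, c(0.5, 1), d = 100)
  expect_equal(p$frequencies[1L] / f2[1L], 100^-0.5, tolerance = 1e-3)

  # a W=0 mutant keeps its absolute cells and is diluted ~1/d
  p0 <- simulate_passage(f2, c(0, 1), d = 100)
  expect_equal(p0$frequencies[1L] / f2[1L], 1 / 100, tolerance = 1e-3)

  expect_error(simulate_passage(f, rep(1, 4), d = 1), "exceed 1")
})

test_that("sequencing draws conserve depth and match binomial moments", {
  f <- c(0.01, 0.99)
  r <- sample_reads(f, 1e6, seed = 77)
  expect_equal(sum(r), 1e6)
  expect_lt(abs(r[1L] - 1e4), 5 * sqrt(1e6 * 0.01 * 0.99))

  expect_equal(sample_reads(1, 500, seed = 1), 500)
  expect_error(sample_reads(f, 0), "positive")
})

test_that("simulated experiments have the full layout and are reproducible", {
  cfg <- sim_config(seed = 31, n_genes = 20, n_insertions = 800,
                    read_depth = 5e4, n_replicates = 2,
                    n_sensitive_genes = 2)
  exp <- simulate_experiment(cfg)
  # library + starter (shared) plus 2 conditions x 3 periods, all x 2 reps
  expect_length(exp$samples, (2 + 2 * 3) * 2)
  expect_equal(nrow(exp$growth), 2 * 3 * 2)
  expect_equal(nrow(exp$truth), 800L)
  expect_true(all(vapply(exp$samples, function(s) {
    s$total_reads == 5e4
  }, logical(1))))

  again <- simulate_experiment(cfg)
  expect_identical(lapply(exp$samples, `[[`, "counts"),
                   lapply(again$samples, `[[`, "counts"))
  expect_identical(exp$truth, again$truth)
})

test_that("at saturating depth the pipeline recovers truth within 1%", {
  # ~2% of sites sensitive, as in the default screen conditions; fitness is
  # measured against the population mean, so a larger sensitive fraction
  # would shift all estimates away from nominal truth by construction
  cfg <- sim_config(seed = 32, n_genes = 50, n_insertions = 500,
                    read_depth = 1e9, n_replicates = 1,
                    n_sensitive_genes = 1, essential_gene_fraction = 0)
  exp <- simulate_experiment(cfg)
  rf <- suppressMessages(fitness_per_period(exp, min_control_reads = 10))
  truth <- exp$truth
  sens_pos <- truth$position[truth$label == "sensitive"]
  p1 <- rf[rf$growth_period == 1L, ]
  w_hat_sens <- p1$w_rel[p1$position %in% sens_pos]
  w_hat_neut <- p1$w_rel[!(p1$position %in% sens_pos)]
  expect_gt(length(w_hat_sens), 0L)
  expect_lt(max(abs(w_hat_sens - cfg$true_w_treatment)) /
              cfg$true_w_treatment, 0.01)
  expect_lt(max(abs(w_hat_neut - 1)), 0.01)
})
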