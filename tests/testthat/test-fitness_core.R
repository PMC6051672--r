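test_that("generations follow log2 of the viable-count expansion", {
  g <- compute_generations(5e6, 4e7)
  expect_equal(g$G, 3)
  expect_equal(g$d, 8)
  expect_equal(compute_generations(1e6, 1e6)$G, 0)
  expect_equal(compute_generations(1e6, 1e8)$d, 100)
  expect_equal(compute_generations(1e6, 1e8)$G, log2(100))
  expect_error(compute_generations(0, 1e7), "positive")
})

test_that("insertion frequencies are read fractions with 0 for absent sites", {
  s <- tiny_sample(c(10, 490, 250, 250))
  f <- insertion_frequency(s, c("chr:100:+", "chr:999:+"))
  expect_equal(unname(f), c(0.01, 0))
  one <- tiny_sample(1000)
  expect_warning(insertion_frequency(one), "rare-mutant")
})

test_that("the fitness estimator honours its defining identities", {
  # unchanged frequency means the mutant matched the population exactly
  expect_identical(insertion_fitness(0.001, 0.001, 100)$W, 1)

  # doubling frequency over a 100-fold expansion: closed-form log ratio
  w_expected <- log(0.002 * 100 / 0.001) / log((1 - 0.002) * 100 / (1 - 0.001))
  est <- insertion_fitness(0.001, 0.002, 100)
  expect_equal(est$W, w_expected)
  expect_equal(est$W, 1.1508, tolerance = 1e-4)

  ext <- insertion_fitness(0.001, 0, 100)
  expect_equal(ext$W, 0)
  expect_true(ext$extinct)

  expect_error(insertion_fitness(0.001, 0.001, 1), "expansion")
  expect_error(insertion_fitness(0, 0.001, 100), "F0")
})

test_that("neutral identity and monotonicity hold across random inputs", {
  set.seed(101)
  F0 <- runif(500, 1e-6, 0.5)
  d <- runif(500, 1.01, 1000)
  expect_true(all(insertion_fitness(F0, F0, d)$W == 1))

  # W strictly increases in Ff at fixed (F0, d), on the domain where the
  # complement of the mutant still expands
  for (f0 in c(1e-4, 0.01, 0.3)) {
    bound <- 1 - (1 - f0) / 50
    ff_grid <- seq(1e-6, 0.95 * bound, length.out = 200)
    w <- insertion_fitness(rep(f0, 200), ff_grid, 50)$W
    expect_true(all(diff(w) > 0))
  }
  expect_warning(insertion_fitness(0.01, 0.999, 50), "bound")
})

test_that("the estimator inverts deterministic growth of a rare mutant", {
  for (w_true in c(0.2, 0.5, 0.8, 1.0, 1.2)) {
    w_hat <- rare_mutant_west(w_true, f0 = 1e-4, d = 100)
    expect_lt(abs(w_hat - w_true), 0.01 * w_true)
  }
})

test_that("relative fitness is the treatment/control ratio with exclusions", {
  expect_equal(relative_fitness(0.6, 1.2), 0.5)
  expect_equal(relative_fitness(0.9, 0.9), 1)
  expect_equal(relative_fitness(0, 1), 0)
  expect_message(out <- relative_fitness(1, 0), "excluded")
  expect_true(is.na(out))
})

test_that("the control read filter uses a strict inequality", {
  s <- tiny_sample(c(10, 11, 500))
  expect_setequal(filter_insertions(s, 10), c("chr:250:-", "chr:400:+"))
  expect_setequal(filter_insertions(tiny_sample(c(1, 0, 2)), 0),
                  c("chr:100:+", "chr:400:+"))
  expect_length(filter_insertions(tiny_sample(c(0, 0)), 10), 0L)
})

test_that("noise-free periods recover truth site by site", {
  n <- 1000L
  sites <- data.frame(replicon = "chr", position = seq_len(n) * 10L,
                      strand = "+")
  w_trt <- rep(1, n); w_trt[2L] <- 0.5   # site 2 is treatment-sensitive
  d <- 8
  depth <- 1e7
  f <- rep(1 / n, n)
  samples <- list(exact_sample(sites, f, depth, "shared", 1L))
  growth <- list()
  fc <- f; ft <- f
  for (k in 1:3) {
    pc <- simulate_passage(fc, rep(1, n), d); fc <- pc$frequencies
    pt_ <- simulate_passage(ft, w_trt, d); ft <- pt_$frequencies
    samples <- c(samples,
                 list(exact_sample(sites, fc, depth, "control", k + 1L),
                      exact_sample(sites, ft, depth, "treatment", k + 1L)))
    growth <- c(growth, list(
      data.frame(condition = c("control", "treatment"), growth_period = k,
                 replicate = 1L, N0 = pc$N0, Nf = c(pc$Nf, pt_$Nf))))
  }
  exp <- structure(list(samples = samples, growth = do.call(rbind, growth),
                        annotation = NULL), class = "tnseq_experiment")
  rf <- suppressMessages(fitness_per_period(exp, min_control_reads = 10))
  expect_equal(nrow(rf), 3L * n)
  neutral <- rf$w_rel[rf$position != 20L]
  expect_equal(neutral, rep(1, length(neutral)), tolerance = 0.005)
  sens <- rf[rf$position == 20L, ]
  expect_equal(sens$w_rel, rep(0.5, 3), tolerance = 0.01)
})

test_that("the per-period filter drops a site only in the failing period", {
  sites <- data.frame(replicon = "chr", position = c(10L, 20L), strand = "+")
  # site 2 passes the 10-read filter in the control starts of periods 1 and 3
  # (200 reads) but not of period 2, where the sample was sequenced shallowly
  # (freq 0.03 x depth 300 = 9 reads, still growing: W_control > 0)
  mk <- function(c2, cond, code, depth = 1000) {
    exact_sample(sites, c(1 - c2, c2), depth, cond, code)
  }
  samples <- list(mk(0.2, "shared", 1L),
                  mk(0.03, "control", 2L, depth = 300),
                  mk(0.2, "treatment", 2L),
                  mk(0.2, "control", 3L), mk(0.2, "treatment", 3L),
                  mk(0.2, "control", 4L), mk(0.2, "treatment", 4L))
  growth <- expand.grid(condition = c("control", "treatment"),
                        growth_period = 1:3, replicate = 1L,
                        stringsAsFactors = FALSE)
  growth$N0 <- 1e6; growth$Nf <- 8e6
  exp <- structure(list(samples = samples, growth = growth, annotation = NULL),
                   class = "tnseq_experiment")
  rf <- suppressMessages(fitness_per_period(exp, min_control_reads = 10))
  here <- rf$position == 20L
  expect_setequal(rf$growth_period[here], c(1L, 3L))
})

test_that("replicate pooling conserves total reads", {
  a <- tiny_sample(c(5, 10, 15), "control", 2L, 1L)
  b <- tiny_sample(c(1, 2, 3), "control", 2L, 2L)
  pooled <- tnfit:::pool_samples(list(a, b))
  expect_equal(pooled$total_reads, a$total_reads + b$total_reads)
  expect_equal(sum(pooled$counts$count), 36)
})
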