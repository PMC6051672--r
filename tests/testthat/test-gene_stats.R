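test_that("sites map to genes by inclusive coordinates, strand ignored", {
  ann <- data.frame(gene_id = c("gA", "gB"), name = c("gA", "gB"),
                    replicon = "chr", start = c(100L, 600L),
                    end = c(400L, 900L), strand = c("+", "-"))
  sites <- data.frame(replicon = "chr",
                      position = c(150L, 400L, 401L, 599L, 600L, 950L))
  m <- map_insertions_to_genes(sites, ann)
  got <- setNames(m$gene_id, m$position)
  expect_equal(unname(got[c("150", "400")]), c("gA", "gA"))
  expect_equal(unname(got["600"]), "gB")
  expect_match(got["401"], "^ig_")
  expect_match(got["599"], "^ig_")
  expect_equal(got[["401"]], got[["599"]])      # same intergenic region
  expect_false(got[["401"]] == got[["950"]])    # trailing region is distinct
})

test_that("a site inside two overlapping genes is assigned to both", {
  ann <- data.frame(gene_id = c("gA", "gB"), name = c("gA", "gB"),
                    replicon = "chr", start = c(100L, 300L),
                    end = c(500L, 700L), strand = "+")
  sites <- data.frame(replicon = "chr", position = 350L)
  expect_warning(m <- map_insertions_to_genes(sites, ann), "overlapping")
  expect_setequal(m$gene_id, c("gA", "gB"))
})

test_that("gene mean and CI follow the one-sample t construction", {
  r <- gene_relative_fitness(c(0.8, 0.9, 1.0))
  expect_equal(r$mean, 0.9)
  expect_equal(r$ci95_low, 0.6516, tolerance = 1e-4)
  expect_equal(r$ci95_high, 1.1484, tolerance = 1e-4)
  expect_equal(r$n, 3L)

  flat <- gene_relative_fitness(c(1, 1, 1, 1))
  expect_equal(flat$mean, 1)
  expect_equal(flat$ci95_high - flat$ci95_low, 0)

  expect_error(gene_relative_fitness(0.5, min_insertions = 3), "insufficient")
})

test_that("the neutrality test matches its closed form and conventions", {
  expect_equal(test_vs_neutral(c(0.8, 0.9, 1.0)), 0.2254, tolerance = 1e-4)
  # independent route: stats::t.test with mu = 1
  expect_equal(test_vs_neutral(c(0.8, 0.9, 1.0)),
               t.test(c(0.8, 0.9, 1.0), mu = 1)$p.value)
  expect_equal(test_vs_neutral(c(0.7, 1.3)), 1)       # symmetric about 1
  expect_equal(test_vs_neutral(rep(0.5, 4)), 1)       # zero-variance convention
  expect_error(test_vs_neutral(0.9), "at least two")
})

test_that("BH adjustment equals the exhaustive step-up oracle", {
  expect_equal(bh_adjust(c(0.001, 0.01, 0.03, 0.04)),
               c(0.004, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(202)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("candidate selection ranks, gates and caps correctly", {
  n <- 300L
  tab <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n)), growth_period = 2L,
    n_insertions = 5L,
    mean_relative_fitness = seq(0.1, 0.9, length.out = n),
    ci95_low = 0, ci95_high = 1,
    p_value = 1e-4, p_adj = rep(c(1e-3, 0.5), length.out = n))
  cand <- select_candidates(tab, growth_period = 2, top_n = 200, alpha = 0.01)
  qualifying <- tab[tab$p_adj < 0.01, ]
  expect_equal(nrow(cand), min(200L, nrow(qualifying)))
  expect_equal(cand$mean_relative_fitness,
               sort(qualifying$mean_relative_fitness)[seq_len(nrow(cand))])

  few <- tab[seq_len(100), ]
  expect_equal(nrow(select_candidates(few, 2, 200, 0.01)), 50L)

  # ties at the boundary break by p_adj then gene id
  ties <- data.frame(gene_id = c("gB", "gA", "gC"), growth_period = 2L,
                     n_insertions = 3L, mean_relative_fitness = 0.5,
                     ci95_low = 0, ci95_high = 1, p_value = 1e-4,
                     p_adj = c(1e-3, 1e-3, 1e-4))
  picked <- select_candidates(ties, 2, 2, 0.01)
  expect_equal(picked$gene_id, c("gC", "gA"))
})

test_that("gene aggregation excludes thin genes and flags zero variance", {
  rel <- data.frame(
    replicon = "chr",
    position = c(110L, 120L, 130L, 610L, 620L, 710L),
    strand = "+", growth_period = 1L,
    w_rel = c(0.8, 0.9, 1.0, 1, 1, 0.5))
  ann <- data.frame(gene_id = c("gA", "gB"), name = c("gA", "gB"),
                    replicon = "chr", start = c(100L, 600L),
                    end = c(400L, 650L), strand = "+")
  gt <- suppressMessages(gene_fitness(rel, ann, min_insertions = 3))
  expect_false(any(gt$n_insertions < 3))
  expect_false("ig_2" %in% gt$gene_id)  # single-site intergenic region dropped
  gA <- gt[gt$gene_id == "gA", ]
  expect_equal(gA$mean_relative_fitness, 0.9)
  expect_equal(gA$p_value, 0.2254, tolerance = 1e-4)
  expect_false("gB" %in% gt$gene_id)    # only 2 insertions
  expect_true(all(gt$p_adj >= gt$p_value))
  expect_true(all(gt$ci95_low <= gt$mean_relative_fitness &
                    gt$mean_relative_fitness <= gt$ci95_high))
})

test_that("95% CIs cover the neutral mean at their nominal rate", {
  set.seed(303)
  n_genes <- 10000L
  n_ins <- 8L
  vals <- matrix(rnorm(n_genes * n_ins, mean = 1, sd = 0.15), n_genes)
  covered <- apply(vals, 1L, function(v) {
    ci <- gene_relative_fitness(v)
    ci$ci95_low <= 1 && 1 <= ci$ci95_high
  })
  coverage <- mean(covered)
  expect_gt(coverage, 0.93)
  expect_lt(coverage, 0.97)
})
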