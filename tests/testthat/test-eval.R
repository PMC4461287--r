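test_that("gene splits partition the profile reproducibly", {
  genes <- sprintf("g%d", 1:6)
  set.seed(1)
  sp <- split_genes(genes, 3L)
  expect_length(sp$training, 3L)
  expect_length(sp$validation, 3L)
  expect_setequal(c(sp$training, sp$validation), genes)
  expect_length(intersect(sp$training, sp$validation), 0L)

  set.seed(1)
  expect_identical(split_genes(genes, 3L), sp)

  full <- split_genes(genes, 6L)
  expect_length(full$validation, 0L)
  expect_error(split_genes(genes, 0L), "train_size")
  expect_error(split_genes(genes, 7L), "train_size")
})

test_that("full-profile cross-validation reproduces the plain optimization pathway", {
  inst <- generate_planted(seed = 41)
  genes <- intersect(ph_genes(inst$phenotypes), inst$pkn$nodes)
  cfg <- optimization_config(max_iterations = 10L, seed = 5L)
  runs <- cross_validate(inst$pkn, inst$phenotypes, train_sizes = length(genes),
                         n_splits = 1L, config = cfg)
  expect_length(runs, 1L)
  run <- runs[[1]]
  expect_length(run$validation_genes, 0L)
  # same derived seed, full gene set: identical to a direct optimization
  cfg2 <- cfg; cfg2$seed <- run$seed
  direct <- contextualize(inst$pkn, inst$phenotypes, config = cfg2)
  expect_identical(run$training_scores, direct$final_scores)
  # with nothing held out, the prediction score equals the training score
  expect_equal(run$scores, run$training_scores)
})

test_that("cross-validation pools population_size x n_splits prediction scores", {
  inst <- generate_planted(seed = 42)
  cfg <- optimization_config(max_iterations = 5L, population_size = 8L,
                             selection_number = 4L, elitism_number = 2L, seed = 3L)
  runs <- cross_validate(inst$pkn, inst$phenotypes, train_sizes = 4L,
                         n_splits = 3L, config = cfg)
  expect_length(runs, 3L)
  pooled <- pooled_scores(runs, train_size = 4L)
  expect_length(pooled, 8L * 3L)
  expect_true(all(pooled >= 0 & pooled <= 1))
  for (run in runs) {
    expect_length(run$training_genes, 4L)
    expect_setequal(c(run$training_genes, run$validation_genes),
                    intersect(ph_genes(inst$phenotypes), inst$pkn$nodes))
  }
})

test_that("cumulative frequency curves are valid ECDFs", {
  set.seed(7)
  cdf <- score_cdf(round(runif(50), 2))
  expect_true(all(diff(cdf$cumfreq) > 0))
  expect_equal(cdf$cumfreq[nrow(cdf)], 1)
  expect_true(all(cdf$cumfreq > 0 & cdf$cumfreq <= 1))
})

test_that("the Welch comparison matches the closed form and its limits", {
  set.seed(8)
  x <- rnorm(300, 0.6, 0.05)
  y <- rnorm(300, 0.4, 0.05)
  w <- compare_to_baseline(x, y)
  ref <- welch_oracle(x, y)
  expect_equal(w$t, ref$t, tolerance = 1e-10)
  expect_equal(w$df, ref$df, tolerance = 1e-10)
  expect_equal(w$p, ref$p, tolerance = 1e-10)
  expect_lt(w$p, 0.01)

  # symmetry and the identical-sample limit
  expect_equal(compare_to_baseline(y, x)$p, w$p)
  same <- compare_to_baseline(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # degenerate variances map to the limits of the statistic
  expect_equal(compare_to_baseline(rep(1, 5), rep(1, 5))$p, 1)
  expect_equal(compare_to_baseline(rep(1, 5), rep(0, 5))$p, 0)
  expect_error(compare_to_baseline(1, c(1, 2)), ">= 2")
})

test_that("withholding no gene reproduces the standard run", {
  inst <- generate_planted(seed = 43)
  cfg <- optimization_config(max_iterations = 8L, seed = 4L)
  dist0 <- sensitivity_missing(inst$pkn, inst$phenotypes, character(), config = cfg)
  direct <- contextualize(inst$pkn, inst$phenotypes, config = cfg)
  expect_equal(dist0, direct$final_scores)
  expect_length(dist0, cfg$population_size)
  expect_error(sensitivity_missing(inst$pkn, inst$phenotypes,
                                   ph_genes(inst$phenotypes), config = cfg),
               "remove all")
})

test_that("withholding a gene cannot raise the mean full-profile score", {
  inst <- generate_planted(seed = 44)
  cfg <- optimization_config(max_iterations = 20L, seed = 10L)
  full <- mean(sensitivity_missing(inst$pkn, inst$phenotypes, character(), cfg))
  gene <- setdiff(ph_genes(inst$phenotypes), inst$inputs)[1]
  miss <- mean(sensitivity_missing(inst$pkn, inst$phenotypes, gene, cfg))
  expect_lte(miss, full + 1e-9)
})

test_that("wrong information: no flips is the identity, flipping all swaps phenotypes", {
  inst <- generate_planted(seed = 45)   # complement phenotypes by design
  cfg <- optimization_config(max_iterations = 8L, seed = 6L)
  base <- sensitivity_wrong(inst$pkn, inst$phenotypes, character(), cfg)
  direct <- contextualize(inst$pkn, inst$phenotypes, config = cfg)
  expect_equal(base, direct$final_scores)

  # flipping every gene of two complementary phenotypes merely swaps their
  # roles; the optimization and its evaluation against the originals coincide
  flipped_all <- sensitivity_wrong(inst$pkn, inst$phenotypes,
                                   ph_genes(inst$phenotypes), cfg)
  expect_equal(flipped_all, base)

  expect_error(sensitivity_wrong(inst$pkn, inst$phenotypes, "NOPE", cfg), "NOPE")
})

test_that("corrupting a training gene cannot raise the mean score", {
  inst <- generate_planted(seed = 46)
  cfg <- optimization_config(max_iterations = 20L, seed = 11L)
  base <- mean(sensitivity_wrong(inst$pkn, inst$phenotypes, character(), cfg))
  gene <- setdiff(ph_genes(inst$phenotypes), inst$inputs)[1]
  bad <- mean(sensitivity_wrong(inst$pkn, inst$phenotypes, gene, cfg))
  expect_lte(bad, base + 1e-9)
})
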