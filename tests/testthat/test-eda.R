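test_that("random subnetworks respect the PKN and the inclusion probability", {
  inst <- generate_planted(seed = 21)
  pkn <- inst$pkn

  set.seed(1)
  expect_identical(net_hash(random_subnetwork(pkn, p = 1)), net_hash(pkn))

  set.seed(2)
  for (i in 1:20) {
    sub <- random_subnetwork(pkn, 0.5)
    expect_true(all(edge_keys(sub) %in% edge_keys(pkn)))
    expect_identical(sub$nodes, pkn$nodes)
  }

  # per-edge inclusion frequency converges to p (3-sigma binomial band)
  set.seed(3)
  n_draws <- 10000L
  counts <- numeric(n_edges(pkn))
  for (i in seq_len(n_draws))
    counts <- counts + (edge_keys(pkn) %in% edge_keys(random_subnetwork(pkn, 0.5)))
  tol <- 3 * sqrt(0.5 * 0.5 / n_draws)
  expect_true(all(abs(counts / n_draws - 0.5) <= tol))
})

test_that("edge frequencies count occurrences in the selected group", {
  pkn <- make_net(c("A", "B", "C"), c(1L, -1L, 1L), c("B", "C", "A"))
  keys <- edge_keys(pkn)
  # edge 1 in all 10, edge 2 in 8 of 10, edge 3 in none
  selected <- lapply(1:10, function(i) {
    keep <- c(TRUE, i <= 8, FALSE)
    signed_digraph(pkn$edges[keep, ], nodes = pkn$nodes)
  })
  fr <- edge_frequencies(selected, pkn)
  expect_identical(names(fr), keys)
  expect_equal(unname(fr), c(1.0, 0.8, 0.0))
  expect_error(edge_frequencies(list(), pkn), "empty")
})

test_that("frequency sampling keeps an edge iff the draw is at most its frequency", {
  inst <- generate_planted(seed = 22)
  pkn <- inst$pkn
  ones <- setNames(rep(1, n_edges(pkn)), edge_keys(pkn))
  zeros <- setNames(rep(0, n_edges(pkn)), edge_keys(pkn))
  set.seed(4)
  expect_identical(net_hash(sample_from_frequencies(ones, pkn)), net_hash(pkn))
  expect_equal(n_edges(sample_from_frequencies(zeros, pkn)), 0L)

  set.seed(5)
  fr <- setNames(rep(0.8, n_edges(pkn)), edge_keys(pkn))
  kept <- replicate(4000, n_edges(sample_from_frequencies(fr, pkn)))
  rate <- sum(kept) / (4000 * n_edges(pkn))
  expect_true(abs(rate - 0.8) <= 3 * sqrt(0.8 * 0.2 / (4000 * n_edges(pkn))))
})

test_that("the EDA loop is seeded-deterministic and keeps every invariant", {
  inst <- generate_planted(seed = 23)
  cfg <- optimization_config(max_iterations = 15L, seed = 9L)
  r1 <- contextualize(inst$pkn, inst$phenotypes, config = cfg)
  r2 <- contextualize(inst$pkn, inst$phenotypes, config = cfg)
  expect_identical(vapply(r1$final_population, net_hash, character(1)),
                   vapply(r2$final_population, net_hash, character(1)))
  expect_identical(r1$final_scores, r2$final_scores)
  expect_identical(r1$trace, r2$trace)

  # population bookkeeping
  expect_length(r1$final_population, cfg$population_size)
  expect_equal(r1$n_evaluations, cfg$population_size * (cfg$max_iterations + 1L))
  for (net in r1$final_population) {
    expect_true(all(edge_keys(net) %in% edge_keys(inst$pkn)))
    expect_identical(net$nodes, inst$pkn$nodes)
  }

  # elitism makes the best-so-far trace non-decreasing
  expect_true(all(diff(r1$trace$best_f) >= 0))
  archive_f <- vapply(r1$best_networks, `[[`, numeric(1), "f")
  expect_true(all(diff(archive_f) <= 0))  # archive sorted best-first
  expect_equal(max(r1$trace$best_f), archive_f[1])
})

test_that("zero iterations return the scored initial population unchanged", {
  inst <- generate_planted(seed = 24)
  cfg <- optimization_config(max_iterations = 0L, seed = 2L)
  res <- contextualize(inst$pkn, inst$phenotypes, config = cfg)
  expect_length(res$final_population, cfg$population_size)
  expect_equal(nrow(res$trace), 1L)
  expect_equal(res$n_evaluations, cfg$population_size)

  # the initial population is exactly the seeded p = 0.5 draw
  set.seed(2L)
  expected <- replicate(cfg$population_size,
                        net_hash(random_subnetwork(inst$pkn, 0.5)))
  expect_identical(vapply(res$final_population, net_hash, character(1)), expected)
})

test_that("the random-search baseline evaluates exactly as many subnetworks", {
  inst <- generate_planted(seed = 25)
  cfg <- optimization_config(max_iterations = 10L, seed = 6L)
  opt <- contextualize(inst$pkn, inst$phenotypes, config = cfg)
  bas <- random_search_baseline(inst$pkn, inst$phenotypes, config = cfg)
  expect_identical(opt$n_evaluations, bas$n_evaluations)
  expect_identical(bas$method, "random")
  expect_true(all(diff(bas$trace$best_f) >= 0))  # elitism retained
})

test_that("full elitism degenerates to retaining the best-ever networks", {
  inst <- generate_planted(seed = 26)
  cfg <- optimization_config(max_iterations = 5L, population_size = 6L,
                             selection_number = 6L, elitism_number = 6L,
                             seed = 8L)
  res <- random_search_baseline(inst$pkn, inst$phenotypes, config = cfg)
  pop_keys <- sort(vapply(res$final_population, net_hash, character(1)))
  elite_keys <- sort(vapply(res$best_networks, function(b) net_hash(b$network),
                            character(1)))
  # distinct elites fill the population; any remainder is fresh samples
  expect_true(all(elite_keys %in% pop_keys))
})

test_that("configuration invariants are enforced", {
  expect_error(optimization_config(selection_number = 40L), "selection_number")
  expect_error(optimization_config(elitism_number = 11L), "elitism_number")
  expect_error(optimization_config(initial_edge_probability = 0), "probability")
})
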