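test_that("rules derived from a subnetwork read regulators from its edges only", {
  pkn <- toy_boolean_network()
  rules <- build_rules(pkn)
  expect_identical(rules$activators$a, c("b", "c"))
  expect_identical(rules$inhibitors$b, "b")
  expect_identical(rules$activators$c, c("a", "b"))
  expect_false(any(rules$is_input))  # every toy node is regulated

  sub <- make_net("b", 1L, "a", nodes = pkn$nodes)
  sr <- build_rules(pkn, sub)
  expect_identical(sr$activators$a, "b")
  expect_length(sr$activators$c, 0L)
  expect_identical(sr$is_input, rules$is_input)  # inputs come from the PKN

  chain <- make_net("A", 1L, "B")
  expect_true(build_rules(chain)$is_input[["A"]])
  expect_false(build_rules(chain)$is_input[["B"]])

  expect_error(build_rules(sub, pkn), "absent from the PKN")
  expect_error(build_rules(pkn, make_net("b", 1L, "a")), "node set")
})

test_that("synchronous update follows the polynomial encoding", {
  toy <- toy_boolean_system()
  x1 <- update_state(toy, c(a = 0L, b = 0L, c = 1L))
  expect_identical(x1, c(a = 0L, b = 1L, c = 0L))

  # an active inhibitor vetoes an active activator
  net <- make_net(c("A", "B"), c(1L, -1L), c("V", "V"))
  rules <- build_rules(net)
  nx <- update_state(rules, c(A = 1L, B = 1L, V = 1L))
  expect_identical(nx[["V"]], 0L)

  # input nodes hold their state regardless of the rest of the network
  expect_identical(nx[["A"]], 1L)
  nx0 <- update_state(rules, c(A = 0L, B = 1L, V = 1L))
  expect_identical(nx0[["A"]], 0L)

  # with the strict rule everywhere, unregulated nodes decay to 0
  strict <- build_rules(net, inputs_hold_state = FALSE)
  expect_identical(update_state(strict, c(A = 1L, B = 1L, V = 0L))[["A"]], 0L)

  expect_error(update_state(rules, c(A = 1L, B = 0L)), "missing gene")
})

test_that("matrix update equals direct logical evaluation on all states", {
  # planted PKNs and random subnetworks, exhaustively over the state space
  for (seed in 1:3) {
    inst <- generate_planted(seed = seed)
    set.seed(seed)
    nets <- c(list(inst$pkn, inst$true_subnetwork),
              lapply(1:3, function(i) random_subnetwork(inst$pkn, 0.5)))
    states <- all_states(sort(inst$pkn$nodes))
    for (net in nets) {
      rules <- build_rules(inst$pkn, net)
      for (r in seq_len(nrow(states))) {
        x <- states[r, ]
        expect_identical(update_state(rules, x),
                         oracle_next_state(net, inst$pkn, x))
      }
    }
  }
})

test_that("trajectories classify as fixed point, cycle or truncated", {
  # the three-node demo system has no fixed point: all 8 states cycle
  toy <- toy_boolean_system()
  for (r in seq_len(8)) {
    x0 <- all_states(c("a", "b", "c"))[r, ]
    expect_identical(run_to_attractor(toy, x0)$outcome, "cycle")
  }

  # activation chain relaxes in one step
  solo <- build_rules(make_net("A", 1L, "B"))
  x0 <- c(A = 1L, B = 0L)
  tr <- run_to_attractor(solo, x0)
  expect_identical(tr$outcome, "fixed_point")
  expect_identical(tr$attractor_state, c(A = 1L, B = 1L))
  expect_identical(tr$steps_taken, 1L)

  inputs_only <- build_rules(make_net(character(), integer(), character(),
                                      nodes = c("A", "B")))
  tr0 <- run_to_attractor(inputs_only, c(A = 1L, B = 0L))
  expect_identical(tr0$outcome, "fixed_point")
  expect_identical(tr0$steps_taken, 0L)
  expect_identical(tr0$attractor_state, c(A = 1L, B = 0L))

  # a driven self-inhibition oscillates while its activator input is on;
  # the cycle is invisible when max_steps stops the walk first
  osc <- build_rules(make_net(c("A", "b"), c(1L, -1L), c("b", "b")))
  x0 <- c(A = 1L, b = 0L)
  trunc <- run_to_attractor(osc, x0, max_steps = 1L)
  expect_identical(trunc$outcome, "truncated")
  expect_identical(trunc$steps_taken, 1L)
  expect_identical(run_to_attractor(osc, x0)$outcome, "cycle")
  expect_identical(run_to_attractor(osc, x0)$cycle_length, 2L)
})

test_that("fixed points are certified and classification matches the oracle", {
  for (seed in 4:6) {
    inst <- generate_planted(seed = seed)
    set.seed(seed)
    states <- all_states(sort(inst$pkn$nodes))
    for (i in 1:4) {
      net <- random_subnetwork(inst$pkn, 0.5)
      rules <- build_rules(inst$pkn, net)
      x0 <- states[sample(nrow(states), 1L), ]
      tr <- run_to_attractor(rules, x0, max_steps = 300L)
      ref <- oracle_classify(net, inst$pkn, x0, max_steps = 300L)
      expect_identical(tr$outcome, ref$outcome)
      expect_true(tr$steps_taken <= 300L)
      if (tr$outcome == "fixed_point") {
        expect_identical(update_state(rules, tr$attractor_state),
                         tr$attractor_state)
        expect_identical(unname(tr$attractor_state), unname(ref$state))
      }
      if (tr$outcome == "cycle")
        expect_identical(tr$cycle_length, ref$cycle_length)
    }
  }
})

test_that("rules export as readable formulas", {
  pkn <- make_net(c("A", "B", "A"), c(1L, -1L, 1L), c("V", "V", "B"))
  lines <- format_rules(build_rules(pkn))
  expect_match(lines[grepl("^V", lines)], "\\(A\\) & !\\(B\\)")
  expect_match(lines[grepl("^A", lines)], "INPUT")
  path <- withr::local_tempfile()
  write_rules(build_rules(pkn), path)
  expect_identical(readLines(path), lines)
})
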