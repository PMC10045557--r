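test_that("fitness-energy conversion matches the closed form and round-trips", {
  expect_identical(fitness_to_energy(1, beta = 5), 0)
  expect_equal(fitness_to_energy(exp(-1), beta = 1), 1)
  expect_equal(fitness_to_energy(0.5, beta = 2), log(2) / 2)
  expect_true(all(diff(fitness_to_energy(c(0.1, 0.5, 0.9), beta = 2)) < 0))

  expect_identical(energy_to_fitness(0, beta = 3), 1)
  expect_equal(energy_to_fitness(1, beta = 1), exp(-1))
  for (eta in c(0.37, 1e-6, 5)) {
    expect_equal(energy_to_fitness(fitness_to_energy(eta, 2.5), 2.5), eta,
                 tolerance = 1e-12)
  }

  expect_error(fitness_to_energy(0, 1), "zero-fitness")
  expect_error(fitness_to_energy(1, -1), "beta")
  expect_error(energy_to_fitness(1, 0), "beta")
})

test_that("fitness_from_payoff is |p * P| and rejects invalid probabilities", {
  expect_equal(fitness_from_payoff(0.5, -2), 1)
  expect_equal(fitness_from_payoff(0.3, 2), 0.6)
  expect_identical(fitness_from_payoff(0, 100), 0)
  expect_error(fitness_from_payoff(1.2, 1), "\\[0, 1\\]")
  expect_error(fitness_from_payoff(-0.1, 1), "\\[0, 1\\]")
})

test_that("expected_degree follows m (t/t_i)^f", {
  expect_equal(expected_degree(3, 10, 10, 0.7), 3)
  expect_equal(expected_degree(1, 4, 1, 1), 4)
  expect_equal(expected_degree(2, 4, 1, 0.5), 4)
  expect_error(expected_degree(2, 3, 5, 0.5), "birth step")
})

test_that("attachment probabilities are fitness-weighted and normalized", {
  g <- igraph::make_graph(c(1, 2), directed = FALSE)
  net <- as_grown_network(g, eta = c(1, 1), beta = 1)
  expect_equal(attachment_probabilities(net)$prob, c(0.5, 0.5))

  # eta = (2, 1) against degree = (1, 2): products equal, probabilities equal
  g2 <- igraph::make_graph(c(1, 2, 2, 3), directed = FALSE)
  net2 <- as_grown_network(g2, eta = c(2, 1, 4), beta = 1)
  p <- attachment_probabilities(net2)$prob
  expect_equal(p[1], p[2])
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # zero eta * degree nodes get exactly zero probability
  net3 <- as_grown_network(g2, eta = c(2, 1, 0), beta = 1)
  expect_identical(attachment_probabilities(net3)$prob[3], 0)

  net4 <- as_grown_network(igraph::make_empty_graph(2, directed = FALSE),
                           eta = c(1, 1), beta = 1)
  expect_error(attachment_probabilities(net4), "Degenerate")
})

test_that("attachment probability is monotone in fitness at fixed degree", {
  g <- igraph::make_ring(6) # all degrees equal
  etas <- c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2)
  net <- as_grown_network(g, eta = etas, beta = 1)
  expect_true(all(diff(attachment_probabilities(net)$prob) > 0))
})

test_that("growth conserves degree and adds exactly m edges per step", {
  net <- small_net(n = 80, m = 2, seed = 11)
  expect_identical(sum(net$nodes$degree), as.integer(2 * igraph::gsize(net$graph)))
  # complete seed on m + 1 = 3 nodes, then m per step
  steps <- 80 - 3
  expect_identical(igraph::gsize(net$graph), 3 + 2 * steps)
  expect_false(igraph::any_multiple(net$graph))
  expect_equal(igraph::count_components(net$graph), 1)

  # per-step invariant along the recorded history
  h <- net$degree_history
  totals <- rowSums(h, na.rm = TRUE)
  expect_equal(unname(diff(totals)), rep(2 * 2, steps))
  # attachment probabilities along history are distributions
  expect_equal(rowSums(net$prob_history), rep(1, steps + 1), tolerance = 1e-12)
  expect_true(all(net$prob_history >= 0))
})

test_that("simulate_growth is reproducible under a fixed seed", {
  a <- small_net(n = 100, seed = 42, history = FALSE)
  b <- small_net(n = 100, seed = 42, history = FALSE)
  expect_identical(igraph::as_edgelist(a$graph), igraph::as_edgelist(b$graph))
  expect_identical(a$nodes, b$nodes)
  c <- small_net(n = 100, seed = 43, history = FALSE)
  expect_false(identical(igraph::as_edgelist(a$graph),
                         igraph::as_edgelist(c$graph)))
})

test_that("grow_step adds one node with m new edges; forced choice on a seed pair", {
  net <- small_net(n = 20, m = 2, seed = 3)
  set.seed(1)
  net2 <- grow_step(net)
  expect_identical(nrow(net2$nodes), 21L)
  expect_identical(igraph::gsize(net2$graph), igraph::gsize(net$graph) + 2)
  expect_identical(sum(net2$nodes$degree), as.integer(2 * igraph::gsize(net2$graph)))

  # m = 1 with a single attachable node: the entrant must link to it
  cfg <- growth_config(3, m = 1, beta = 1, seed = 5)
  tiny <- simulate_growth(cfg)
  expect_true(all(igraph::degree(tiny$graph) >= 1))
})

test_that("node energies satisfy eps = -(1/beta) log(eta) for any beta", {
  net <- small_net(n = 50, beta = 3.7, seed = 2)
  expect_equal(net$nodes$eps, -log(net$nodes$eta) / 3.7, tolerance = 1e-12)
})

test_that("growth_config validates its arguments", {
  expect_error(growth_config(10, m = 0, beta = 1), "m")
  expect_error(growth_config(2, m = 2, beta = 1), "n_nodes")
  expect_error(growth_config(10, m = 2), "beta")
  expect_error(growth_config(10, m = 2, beta = 1, gamma = 1), "only one")
  expect_error(growth_config(10, m = 2, beta = -1), "positive")
  # gamma parameterization: beta = 1/gamma
  cfg <- growth_config(10, m = 2, gamma = 4)
  expect_equal(cfg$beta, 0.25)
})

test_that("degree_history long format matches the recorded matrix", {
  net <- small_net(n = 30, seed = 9)
  dh <- degree_history(net)
  expect_named(dh, c("step", "node_id", "degree"))
  last <- dplyr::filter(dh, step == max(step))
  expect_identical(last$degree, net$nodes$degree)
})
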