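test_that("Betti numbers and Euler characteristic on canonical graphs", {
  tree <- make_graph_fixture("tree", n = 10)
  expect_identical(betti_numbers(tree), c(b0 = 1L, b1 = 0L))
  expect_identical(euler_characteristic(tree), 1L)

  cyc <- make_graph_fixture("cycle", n = 7)
  expect_identical(betti_numbers(cyc), c(b0 = 1L, b1 = 1L))
  expect_identical(euler_characteristic(cyc), 0L)

  tt <- make_graph_fixture("two-triangles")
  expect_identical(betti_numbers(tt), c(b0 = 2L, b1 = 2L))
  expect_identical(euler_characteristic(tt), 0L)

  expect_error(betti_numbers(igraph::make_empty_graph(0)), "Empty")
})

test_that("chi equals V - E on random graphs and is relabeling-invariant", {
  for (s in 1:20) {
    g <- igraph::sample_gnp(12, 0.25)
    net <- as_grown_network(g, eta = rep(1, 12))
    expect_equal(euler_characteristic(net),
                 igraph::gorder(g) - igraph::gsize(g))
    perm <- igraph::permute(g, sample(12))
    expect_identical(euler_characteristic(as_grown_network(perm, eta = rep(1, 12))),
                 euler_characteristic(net))
  }
})

test_that("winding numbers recover generating frequency ratios", {
  traj <- make_trajectory("periodic") # 2, 3, 5 Hz sinusoids
  w <- winding_numbers(traj)
  expect_true(w$rational)
  expect_identical(w$triple, c(2L, 3L, 5L))
  expect_equal(unname(w$frequencies), c(2, 3, 5), tolerance = 1e-3)

  # identical sinusoids: 1 : 1 : 1
  tt <- seq_len(1000) / 100
  s <- sin(2 * pi * 4 * tt)
  same <- as_trajectory(tibble::tibble(x = s, y = s, z = s), fs = 100)
  w2 <- winding_numbers(same)
  expect_true(w2$rational)
  expect_identical(w2$triple, c(1L, 1L, 1L))

  # golden-ratio frequencies: no rational triple within tolerance
  w3 <- winding_numbers(make_trajectory("quasiperiodic"))
  expect_false(w3$rational)

  flat <- tibble::tibble(x = rep(1, 100), y = rep(1, 100), z = rep(2, 100))
  expect_error(winding_numbers(as_trajectory(flat, fs = 10)), "degenerate")
})

test_that("small-denominator ratios survive 20 dB of observation noise", {
  for (s in 1:3) {
    traj <- make_trajectory("periodic", seed = s, snr_db = 20)
    w <- winding_numbers(traj)
    expect_true(w$rational)
    expect_identical(w$triple, c(2L, 3L, 5L))
  }
})

test_that("coherence hits its endpoints: identical -> 1, independent -> ~0", {
  tt <- seq_len(2000) / 100
  s <- sin(2 * pi * 5 * tt)
  same <- as_trajectory(tibble::tibble(x = s, y = s, z = s), fs = 100)
  expect_equal(as.numeric(coherence(same)), 1, tolerance = 1e-6)

  set.seed(31)
  noise <- as_trajectory(tibble::tibble(x = rnorm(1e4), y = rnorm(1e4),
                                        z = rnorm(1e4)), fs = 100)
  expect_lt(as.numeric(coherence(noise)), 0.05)

  short <- as_trajectory(tibble::tibble(x = rnorm(70), y = rnorm(70),
                                        z = rnorm(70)), fs = 10)
  expect_error(coherence(short), "8 Welch segments")
})

test_that("coherence stays within [0, 1] across random trajectories", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(c(600, 1200, 2500), 1)
    base <- rnorm(n)
    mix <- runif(1)
    df <- tibble::tibble(
      x = mix * base + (1 - mix) * rnorm(n),
      y = mix * base + (1 - mix) * rnorm(n),
      z = rnorm(n) + runif(1, 0, 2) * sin(2 * pi * 3 * seq_len(n) / 100))
    k <- as.numeric(coherence(as_trajectory(df, fs = 100)))
    expect_gte(k, 0)
    expect_lte(k, 1)
  }
})

test_that("the dynamics decision table is honored", {
  expect_identical(classify_dynamics(rational = TRUE, k = 0.9), "periodic")
  expect_identical(classify_dynamics(rational = FALSE, k = 0.1), "quasiperiodic")
  expect_identical(classify_dynamics(rational = FALSE, k = 0.6), "chaotic")
  expect_identical(classify_dynamics(FALSE, 0.25), "quasiperiodic") # boundary
  expect_identical(classify_dynamics(TRUE, 0, zero_variance = TRUE),
                   "fixed-point")
})

test_that("Wolfram classes map from dynamics classes", {
  expect_identical(wolfram_class("fixed-point"), "I")
  expect_identical(wolfram_class("periodic"), "II")
  expect_identical(wolfram_class("quasiperiodic"), "IV")
  expect_identical(wolfram_class("chaotic"), "III")
})

test_that("each fixture class lands in its own decision-table branch", {
  expect_identical(classify_trajectory(make_trajectory("fixed-point"))$wolfram_class,
                   "I")
  rep_p <- classify_trajectory(make_trajectory("periodic"))
  expect_identical(rep_p$dynamics_class, "periodic")
  expect_identical(rep_p$wolfram_class, "II")
  rep_q <- classify_trajectory(make_trajectory("quasiperiodic"))
  expect_identical(rep_q$dynamics_class, "quasiperiodic")
  expect_identical(rep_q$wolfram_class, "IV")
  expect_lte(rep_q$coherence, 0.25)
})

test_that("delay embedding has the right shape and preserves values", {
  s <- sin(2 * pi * seq_len(100) / 25)
  expect_equal(delay_embed(s, dim = 1)[, 1], s)
  emb <- delay_embed(seq_len(100), dim = 3, lag = 10)
  expect_identical(dim(emb), c(80L, 3L))
  expect_equal(emb[1, ], c(1, 11, 21))
  expect_lte(max(abs(delay_embed(s, 3, 5))), 1)
  expect_error(delay_embed(seq_len(10), dim = 3, lag = 10), "too short")
})
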