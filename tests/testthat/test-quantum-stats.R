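test_that("dynamic exponent pivots at the chemical potential", {
  expect_identical(dynamic_exponent(2, beta = 3, mu = 2), 1)
  expect_equal(dynamic_exponent(log(2), 1, 0), 0.5)
  expect_equal(dynamic_exponent(-log(2), 1, 0), 2)
})

test_that("occupation numbers match their closed forms", {
  # beta (eps - mu) = ln 2
  expect_equal(occupation_be(log(2), 1, 0), 1)
  expect_equal(occupation_mb(log(2), 1, 0), 0.5)
  expect_equal(occupation_fd(log(2), 1, 0), 1 / 3)
  # beta (eps - mu) = 1
  expect_equal(occupation_be(1, 1, 0), 1 / (exp(1) - 1))
  expect_equal(occupation_mb(1, 1, 0), exp(-1))
  # boundary behaviour
  expect_equal(occupation_mb(0, 2, 0), 1)
  expect_equal(occupation_fd(0, 2, 0), 0.5)
  expect_lt(occupation_be(40, 1, 0), 1e-15)
  expect_error(occupation_be(0, 1, 0), "condensation")
  expect_error(occupation_be(-1, 1, 2), "condensation")
})

test_that("occupations order FD < MB < BE and converge in the dilute limit", {
  for (x in c(0.1, 0.5, 1, 3, 10)) {
    expect_lt(occupation_fd(x, 1, 0), occupation_mb(x, 1, 0))
    expect_lt(occupation_mb(x, 1, 0), occupation_be(x, 1, 0))
  }
  # Maxwell-Boltzmann limit at beta (eps - mu) = 20
  mb <- occupation_mb(20, 1, 0)
  expect_lt(abs(occupation_be(20, 1, 0) - mb) / mb, 1e-8)
  expect_lt(abs(occupation_fd(20, 1, 0) - mb) / mb, 1e-8)
})

test_that("chemical potential solver inverts the single-level MB closed form", {
  for (n_target in c(0.2, 1, 7)) {
    sol <- solve_chemical_potential(2, beta = 3, total_occupation = n_target,
                                    statistics = "mb")
    expect_equal(sol$mu, 2 + log(n_target) / 3, tolerance = 1e-8)
  }
})

test_that("solver round-trips occupations to the target for all statistics", {
  set.seed(1)
  eps <- sort(runif(40, 0, 5))
  cap <- sum(1 / expm1(2 * (eps[eps > min(eps)] - min(eps))))
  for (st in c("be", "mb", "fd")) {
    # FD is capped at one endpoint per level; BE must stay below the
    # excited-level capacity to admit a genuine (uncondensed) root
    target <- switch(st, fd = 10, be = 0.8 * cap, mb = 60)
    sol <- solve_chemical_potential(eps, beta = 2, total_occupation = target,
                                    statistics = st)
    expect_false(sol$condensed)
    expect_equal(sum(sol$occupations), target, tolerance = 1e-8)
    expect_true(all(sol$occupations >= 0))
  }
})

test_that("occupation sums increase monotonically in mu", {
  eps <- c(0.5, 1, 2.5)
  mus <- seq(-3, 0.4, length.out = 15)
  for (fn in list(occupation_be, occupation_mb, occupation_fd)) {
    sums <- vapply(mus, function(m) sum(fn(eps, 1.3, m)), numeric(1))
    expect_true(all(diff(sums) > 0))
  }
})

test_that("BE solver flags condensation when excited levels cannot hold the load", {
  eps <- c(0, 1, 2)
  cap <- sum(1 / expm1(1 * (eps[-1] - 0)))
  sol <- solve_chemical_potential(eps, beta = 1, total_occupation = cap * 3,
                                  statistics = "be")
  expect_true(sol$condensed)
  expect_equal(sol$mu, 0)
  expect_equal(sol$excess, cap * 3 - cap)
  expect_equal(sol$occupations[1], sol$excess)
  expect_equal(sum(sol$occupations), cap * 3, tolerance = 1e-10)

  # comfortably below capacity: a genuine root exists
  sol2 <- solve_chemical_potential(eps, beta = 1, total_occupation = cap / 2,
                                   statistics = "be")
  expect_false(sol2$condensed)
  expect_lt(sol2$mu, 0)
  expect_error(solve_chemical_potential(c(0, Inf), 1, 1), "finite")
})

test_that("phase classification follows the exponent thresholds", {
  expect_identical(classify_phase(1), "bose-einstein")
  expect_identical(classify_phase(1e-3), "maxwell-boltzmann")
  expect_identical(classify_phase(1e3), "fermi-dirac")
  expect_identical(classify_phase(0.5), "crossover")
  expect_identical(classify_phase(c(0.98, 1.0, 1.02)), "bose-einstein")
  expect_error(classify_phase(numeric(0)), "non-empty")
})

test_that("critical gamma follows the zeta(3/2) scaling law", {
  # unit-density cancellation
  z32 <- pracma::zeta(1.5)
  expect_equal(critical_gamma(2, n_density = z32), 2)
  # (2/3)-power scaling: 8x density -> gamma_c / 4
  expect_equal(critical_gamma(1, 8), critical_gamma(1, 1) / 4)
  # frozen high-precision value of zeta(3/2)^(2/3)
  expect_equal(critical_gamma(1, 1), 1.8968095081, tolerance = 1e-9)
  expect_error(critical_gamma(-1, 1), "positive")
})

test_that("condensate fraction counts the minimum-energy node's endpoint share", {
  star <- star_min_hub(6)
  expect_equal(condensate_fraction(star), 0.5)
  # invariance under relabeling
  g <- igraph::make_star(7, mode = "undirected", center = 4)
  net2 <- as_grown_network(g, eps = c(rep(1, 3), -1, rep(1, 3)), beta = 1)
  expect_equal(condensate_fraction(net2), 0.5)
  empty <- as_grown_network(igraph::make_empty_graph(3, directed = FALSE),
                            eta = rep(1, 3))
  expect_error(condensate_fraction(empty), "edge")
})

test_that("condensate fraction of equal-fitness networks decays with size", {
  frac <- function(n) {
    mean(vapply(1:8, function(s) {
      condensate_fraction(small_net(n, beta = 1,
                                    dist = fitness_dist("dirac", value = 0.5),
                                    seed = s, history = FALSE))
    }, numeric(1)))
  }
  expect_lt(frac(400), frac(60))
})

test_that("phase_report assembles a coherent summary", {
  net <- small_net(n = 80, beta = 2, seed = 5)
  rep <- phase_report(net)
  expect_s3_class(rep, "phase_report")
  expect_true(all(rep$occupations >= 0))
  expect_equal(sum(rep$occupations), sum(net$nodes$degree), tolerance = 1e-6)
  expect_true(rep$phase_label %in%
    c("bose-einstein", "maxwell-boltzmann", "fermi-dirac", "crossover",
      "condensate"))
  expect_named(glance(rep),
               c("mu", "phase_label", "condensate_fraction", "gamma_c",
                 "normalization", "beta", "statistics"))
  expect_identical(nrow(tidy(rep)), 80L)
})
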