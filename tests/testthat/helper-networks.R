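# Shared builders for small deterministic networks.

small_net <- function(n = 60, m = 2, beta = 1, seed = 7,
                      dist = fitness_dist("uniform"), history = TRUE) {
  simulate_growth(growth_config(n, m = m, beta = beta, fitness_dist = dist,
                                seed = seed),
                  record_history = history)
}

# A star whose hub (node 1) carries the minimum energy.
star_min_hub <- function(leaves = 6) {
  g <- igraph::make_star(leaves + 1, mode = "undirected", center = 1)
  as_grown_network(g, eps = c(-1, rep(1, leaves)), beta = 1)
}
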