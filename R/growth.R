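#' Convert fitness to an energy level
#'
#' A node's fitness \eqn{\eta > 0} maps to a fixed energy level
#' \eqn{\varepsilon = -(1/\beta)\log\eta}, where \eqn{\beta = 1/T} is the
#' inverse temperature. Fitter nodes sit at lower energies; \eqn{\eta = 1}
#' sits at \eqn{\varepsilon = 0}.
#'
#' @param eta Positive fitness value(s).
#' @param beta Positive inverse temperature.
#' @return Energy level(s), same length as `eta`.
#' @seealso [energy_to_fitness()] for the inverse map.
#' @export
#' @examples
#' fitness_to_energy(0.5, beta = 2) # log(2)/2
fitness_to_energy <- function(eta, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    abort("`beta` must be a single positive number.")
  }
  if (any(!is.finite(eta)) || any(eta <= 0)) {
    abort("`eta` must be positive: a zero-fitness node has no finite energy.")
  }
  -log(eta) / beta
}

#' Convert an energy level back to fitness
#'
#' Inverse of [fitness_to_energy()]: \eqn{\eta = e^{-\beta\varepsilon}}.
#'
#' @param eps Energy level(s).
#' @param beta Positive inverse temperature.
#' @return Fitness value(s) in \eqn{(0, \infty)}.
#' @export
energy_to_fitness <- function(eps, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    abort("`beta` must be a single positive number.")
  }
  if (any(!is.finite(eps))) abort("`eps` must be finite.")
  exp(-beta * eps)
}

#' Fitness from selection probability and perceived payoff
#'
#' Allocates a node's fitness as \eqn{\eta = |p \cdot P|}: the Bayesian
#' probability `p` that the node is selected into the network, times the
#' perceived net payoff `P` of doing so (signed; costs give negative `P`).
#'
#' @param p Selection probability in \[0, 1\].
#' @param payoff Perceived net payoff, any sign.
#' @return Non-negative fitness, vectorized over the inputs.
#' @export
fitness_from_payoff <- function(p, payoff) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("`p` must lie in [0, 1].")
  }
  abs(p * payoff)
}

#' Expected degree under power-law growth
#'
#' The mean number of links a node born at step `t_i` holds at step `t`
#' follows \eqn{k(t) = m (t/t_i)^{f(\varepsilon)}}, where the dynamic
#' exponent \eqn{f(\varepsilon)} is set by the node's energy level (see
#' [dynamic_exponent()]).
#'
#' @param m Links added per entrant node.
#' @param t Current growth step, `t >= t_i`.
#' @param t_i Birth step of the node, `>= 1`.
#' @param f_eps Dynamic exponent, `>= 0`.
#' @return Expected link count.
#' @export
expected_degree <- function(m, t, t_i, f_eps) {
  if (any(t_i < 1) || any(m < 1) || any(f_eps < 0)) {
    abort("Require m >= 1, t_i >= 1, f_eps >= 0.")
  }
  if (any(t < t_i)) abort("`t` must be at least the birth step `t_i`.")
  m * (t / t_i)^f_eps
}

#' Growth configuration
#'
#' Bundles the parameters of a fitness-driven growth run. The temperature can
#' be given either as the inverse temperature `beta` or as the annealing
#' parameter `gamma` (in which case `beta = 1/gamma`).
#'
#' @param n_nodes Total number of nodes to grow (including the seed clique).
#' @param m Links added per entrant node.
#' @param beta Inverse temperature (> 0). Exactly one of `beta`/`gamma`.
#' @param gamma Annealing parameter (> 0), an alternative to `beta`.
#' @param fitness_dist A distribution spec from [fitness_dist()].
#' @param seed Integer RNG seed.
#' @return A `growth_config` list.
#' @export
growth_config <- function(n_nodes, m = 2, beta = NULL, gamma = NULL,
                          fitness_dist = neurofield::fitness_dist("uniform"),
                          seed = 1L) {
  if (is.null(beta) && is.null(gamma)) abort("Supply `beta` or `gamma`.")
  if (!is.null(beta) && !is.null(gamma)) abort("Supply only one of `beta`, `gamma`.")
  if (!is.null(gamma)) {
    if (gamma <= 0) abort("`gamma` must be positive.")
    beta <- 1 / gamma
  }
  if (beta <= 0) abort("`beta` must be positive.")
  m <- as.integer(m); n_nodes <- as.integer(n_nodes)
  if (m < 1) abort("`m` must be at least 1.")
  if (n_nodes <= m) abort("`n_nodes` must exceed `m`.")
  structure(
    list(n_nodes = n_nodes, m = m, beta = beta, gamma = gamma,
         fitness_dist = fitness_dist, seed = as.integer(seed)),
    class = "growth_config"
  )
}

#' @export
print.growth_config <- function(x, ...) {
  cat("<growth_config> n_nodes =", x$n_nodes, " m =", x$m,
      " beta =", format(x$beta), " fitness:", x$fitness_dist$family, "\n")
  invisible(x)
}

new_grown_network <- function(edges, eta, eps, birth_time, config,
                              degree_history = NULL, prob_history = NULL) {
  n <- length(eta)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  igraph::V(g)$name <- as.character(seq_len(n))
  igraph::V(g)$eta <- eta
  igraph::V(g)$eps <- eps
  igraph::V(g)$birth_time <- birth_time
  structure(
    list(graph = g,
         nodes = tibble(id = seq_len(n), eta = eta, eps = eps,
                        degree = as.integer(igraph::degree(g)),
                        birth_time = as.integer(birth_time)),
         degree_history = degree_history,
         prob_history = prob_history,
         config = config),
    class = "grown_network"
  )
}

#' @export
print.grown_network <- function(x, ...) {
  cat("<grown_network>", nrow(x$nodes), "nodes,",
      igraph::gsize(x$graph), "edges\n")
  if (!is.null(x$config)) print(x$config)
  invisible(x)
}

#' @rdname grown_network-accessors
#' @export
as_tibble.grown_network <- function(x, ...) x$nodes

#' Tidy and summarize grown networks
#'
#' `tidy()` returns the per-node table (id, fitness, energy, degree, birth
#' time); `glance()` returns a one-row summary with node/edge counts, the
#' condensate fraction and the configuration's temperature parameters.
#'
#' @param x A `grown_network`.
#' @param ... Unused.
#' @name grown_network-accessors
#' @export
tidy.grown_network <- function(x, ...) x$nodes

#' @rdname grown_network-accessors
#' @export
glance.grown_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = igraph::gsize(x$graph),
    total_degree = sum(x$nodes$degree),
    condensate_fraction = condensate_fraction(x),
    beta = if (is.null(x$config)) NA_real_ else x$config$beta,
    m = if (is.null(x$config)) NA_integer_ else x$config$m
  )
}

#' Degree history of a grown network in long format
#'
#' @param network A `grown_network` grown with `record_history = TRUE`.
#' @return A tibble with columns `step`, `node_id`, `degree`, one row per
#'   alive node per step.
#' @export
degree_history <- function(network) {
  h <- network$degree_history
  if (is.null(h)) abort("Network was grown without `record_history = TRUE`.")
  steps <- nrow(h)
  out <- tibble(
    step = rep(seq_len(steps), each = ncol(h)),
    node_id = rep(seq_len(ncol(h)), times = steps),
    degree = as.integer(t(h))
  )
  dplyr::filter(out, !is.na(.data$degree))
}

eta_k_weights <- function(network) {
  network$nodes$eta * network$nodes$degree
}

#' Link-attachment probabilities
#'
#' The probability that node *i* receives the next link endpoint is
#' \eqn{\Pi_i = \eta_i k_i / \sum_\ell \eta_\ell k_\ell}: preferential
#' attachment weighted by fitness. Nodes with \eqn{\eta_i k_i = 0} have
#' probability zero and are never selected.
#'
#' @param network A `grown_network`.
#' @return The node tibble with an added `prob` column summing to 1.
#' @export
attachment_probabilities <- function(network) {
  w <- eta_k_weights(network)
  s <- sum(w)
  if (s <= 0) abort("Degenerate network: all nodes have eta * degree = 0.")
  dplyr::mutate(network$nodes, prob = w / s)
}

#' Grow the network by one node
#'
#' Adds a single entrant with fitness drawn from the configured distribution
#' and links it to `m` distinct existing nodes sampled (without replacement)
#' by the attachment probabilities. Uses R's global random stream; seed it
#' for reproducibility.
#'
#' @param network A `grown_network`.
#' @return The grown `grown_network` with one extra node and `m` extra edges.
#' @export
grow_step <- function(network) {
  cfg <- network$config
  if (is.null(cfg)) abort("`network` carries no growth configuration.")
  m <- cfg$m
  n <- nrow(network$nodes)
  w <- eta_k_weights(network)
  if (sum(w > 0) < m) abort("Fewer than `m` attachable target nodes.")
  targets <- sample.int(n, m, prob = w)

  eta0 <- make_fitness_samples(1L, cfg$fitness_dist)
  eps_new <- -log(eta0)
  eta_new <- exp(-cfg$beta * eps_new)

  g <- igraph::add_vertices(network$graph, 1,
                            name = as.character(n + 1L),
                            eta = eta_new, eps = eps_new,
                            birth_time = max(network$nodes$birth_time) + 1L)
  g <- igraph::add_edges(g, as.vector(rbind(n + 1L, targets)))

  nodes <- dplyr::bind_rows(
    network$nodes,
    tibble(id = n + 1L, eta = eta_new, eps = eps_new, degree = 0L,
           birth_time = max(network$nodes$birth_time) + 1L)
  )
  nodes$degree <- as.integer(igraph::degree(g))

  out <- network
  out$graph <- g
  out$nodes <- nodes
  if (!is.null(network$degree_history)) {
    h <- cbind(network$degree_history,
               matrix(NA_integer_, nrow(network$degree_history), 1))
    out$degree_history <- rbind(h, nodes$degree)
  }
  if (!is.null(network$prob_history)) {
    p <- numeric(n + 1L)
    p[seq_len(n)] <- w / sum(w)
    out$prob_history <- rbind(cbind(network$prob_history, 0), p)[, seq_len(n + 1L)]
  }
  out
}

#' Simulate fitness-driven network growth
#'
#' Starts from a complete seed graph on `m + 1` nodes (all with birth time 1)
#' and adds nodes one at a time until `n_nodes` is reached. Each entrant draws
#' a base fitness \eqn{\eta_0} from the configured distribution; its energy is
#' fixed once as \eqn{\varepsilon = -\log\eta_0} and its operative fitness at
#' inverse temperature \eqn{\beta} is \eqn{\eta = e^{-\beta\varepsilon} =
#' \eta_0^\beta}, so that temperature genuinely controls the transition
#' between the fit-get-rich regime and Bose-Einstein condensation. Entrants
#' link to `m` distinct targets sampled without replacement with probability
#' \eqn{\Pi_i \propto \eta_i k_i}; repeat selections of an already-linked
#' target are re-drawn, so no multi-edges or self-loops arise.
#'
#' @param config A [growth_config()].
#' @param record_history Record per-step degree snapshots and attachment
#'   probabilities? Costs O(n^2) memory; disable for large ensembles.
#' @return A `grown_network`: igraph graph plus node tibble, optional degree
#'   and probability history, and the generating config.
#' @export
#' @examples
#' net <- simulate_growth(growth_config(100, m = 2, beta = 1, seed = 42))
#' glance(net)
simulate_growth <- function(config, record_history = TRUE) {
  if (!inherits(config, "growth_config")) abort("`config` must be a growth_config.")
  set.seed(config$seed)
  n <- config$n_nodes
  m <- config$m
  n0 <- m + 1L

  eta0 <- make_fitness_samples(n, config$fitness_dist)
  eps <- -log(eta0)
  eta <- exp(-config$beta * eps)

  deg <- integer(n)
  deg[seq_len(n0)] <- m
  birth <- c(rep(1L, n0), seq(2L, length.out = n - n0))

  seed_pairs <- utils::combn(n0, 2L)
  edges <- matrix(0L, ncol(seed_pairs) + (n - n0) * m, 2L)
  edges[seq_len(ncol(seed_pairs)), ] <- t(seed_pairs)
  e <- ncol(seed_pairs)

  steps <- n - n0
  deg_hist <- if (record_history) matrix(NA_integer_, steps + 1L, n) else NULL
  prob_hist <- if (record_history) matrix(0, steps + 1L, n) else NULL
  if (record_history) {
    deg_hist[1L, seq_len(n0)] <- deg[seq_len(n0)]
    prob_hist[1L, seq_len(n0)] <- 1 / n0
  }

  for (v in seq(n0 + 1L, length.out = steps)) {
    prev <- seq_len(v - 1L)
    w <- eta[prev] * deg[prev]
    if (sum(w > 0) < m) abort("Fewer than `m` attachable target nodes.")
    targets <- sample.int(v - 1L, m, prob = w)
    deg[targets] <- deg[targets] + 1L
    deg[v] <- m
    edges[e + seq_len(m), ] <- cbind(v, targets)
    e <- e + m
    if (record_history) {
      row <- v - n0 + 1L
      deg_hist[row, seq_len(v)] <- deg[seq_len(v)]
      prob_hist[row, prev] <- w / sum(w)
    }
  }

  new_grown_network(edges, eta, eps, birth, config,
                    degree_history = deg_hist, prob_history = prob_hist)
}

#' Degree-distribution plot for a grown network
#'
#' Log-log plot of the empirical degree survival function, the standard
#' diagnostic for power-law tails in preferential-attachment models.
#'
#' @param object A `grown_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grown_network <- function(object, ...) {
  d <- sort(object$nodes$degree, decreasing = TRUE)
  df <- tibble(degree = d, survival = seq_along(d) / length(d))
  ggplot2::ggplot(df, ggplot2::aes(.data$degree, .data$survival)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "P(K ≥ k)",
                  title = "Degree distribution") +
    ggplot2::theme_minimal()
}
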