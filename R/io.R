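#' Wrap an igraph graph as a grown network
#'
#' Attaches fitness/energy attributes and builds the node tibble. At least
#' one of `eta` / `eps` must be available (as arguments or vertex
#' attributes); the missing one is derived through the fitness-energy map
#' at the given `beta`.
#'
#' @param g An igraph graph (undirected).
#' @param eta,eps Optional per-node fitness / energy vectors (fall back to
#'   vertex attributes of the same names).
#' @param beta Inverse temperature used to derive the missing attribute.
#' @param birth_time Optional per-node birth steps (default 1).
#' @return A `grown_network` (no growth history, no config).
#' @export
as_grown_network <- function(g, eta = NULL, eps = NULL, beta = 1,
                             birth_time = NULL) {
  n <- igraph::gorder(g)
  eta <- eta %||% igraph::vertex_attr(g, "eta")
  eps <- eps %||% igraph::vertex_attr(g, "eps")
  if (is.null(eta) && is.null(eps)) {
    abort("Need node attribute `eta` or `eps` (schema error).")
  }
  if (is.null(eps)) {
    # zero-fitness nodes are tolerated in the graph (infinite energy);
    # fitness_to_energy itself rejects them
    eps <- ifelse(eta > 0, -log(eta) / beta, Inf)
  }
  if (is.null(eta)) eta <- energy_to_fitness(eps, beta)
  birth_time <- birth_time %||% igraph::vertex_attr(g, "birth_time") %||%
    rep(1L, n)
  igraph::V(g)$eta <- eta
  igraph::V(g)$eps <- eps
  igraph::V(g)$birth_time <- as.integer(birth_time)
  if (is.null(igraph::V(g)$name)) igraph::V(g)$name <- as.character(seq_len(n))
  structure(
    list(graph = g,
         nodes = tibble(id = seq_len(n), eta = as.numeric(eta),
                        eps = as.numeric(eps),
                        degree = as.integer(igraph::degree(g)),
                        birth_time = as.integer(birth_time)),
         degree_history = NULL, prob_history = NULL, config = NULL),
    class = "grown_network"
  )
}

provenance_line <- function(seed = NA) {
  paste0("# neurofield ", as.character(utils::packageVersion("neurofield")),
         " seed=", seed, " date=", format(Sys.Date()))
}

#' Write a network to disk
#'
#' GraphML keeps all node attributes in one file. The edge-list dialect
#' writes a two-column CSV of node ids plus a companion
#' `<stem>_nodes.csv` with the node attributes.
#'
#' @param network A `grown_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  g <- network$graph
  seed <- if (!is.null(network$config)) network$config$seed else NA
  if (format == "graphml") {
    g <- igraph::set_graph_attr(g, "generator",
                                sub("^# ", "", provenance_line(seed)))
    if (!is.null(network$config)) {
      g <- igraph::set_graph_attr(g, "beta", network$config$beta)
      g <- igraph::set_graph_attr(g, "m", network$config$m)
    }
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g, names = FALSE)
    con <- file(path, "w")
    writeLines(provenance_line(seed), con)
    utils::write.csv(data.frame(from = el[, 1], to = el[, 2]), con,
                     row.names = FALSE)
    close(con)
    npath <- paste0(tools::file_path_sans_ext(path), "_nodes.csv")
    con <- file(npath, "w")
    writeLines(provenance_line(seed), con)
    utils::write.csv(as.data.frame(network$nodes), con, row.names = FALSE)
    close(con)
  }
  invisible(path)
}

#' Read a network from disk
#'
#' Inverse of [write_network()]. Duplicate edges are removed with a
#' warning; when only one of `eta`/`eps` is present the other is derived
#' through the fitness-energy map at `beta`.
#'
#' @param path File path (for `"edgelist"`, the edge CSV; the node CSV is
#'   looked up at `<stem>_nodes.csv`).
#' @param format `"graphml"` or `"edgelist"`.
#' @param beta Inverse temperature for attribute derivation (default: the
#'   file's recorded beta, else 1).
#' @return A `grown_network`.
#' @export
read_network <- function(path, format = c("graphml", "edgelist"), beta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    beta <- beta %||% igraph::graph_attr(g, "beta") %||% 1
  } else {
    edges <- utils::read.csv(path, comment.char = "#")
    npath <- paste0(tools::file_path_sans_ext(path), "_nodes.csv")
    if (!file.exists(npath)) abort(paste0("Node attribute file not found: ", npath))
    nodes <- utils::read.csv(npath, comment.char = "#")
    n <- max(max(edges$from, edges$to), nrow(nodes))
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(as.matrix(edges[, c("from", "to")])))
    if ("eta" %in% names(nodes)) igraph::V(g)$eta <- nodes$eta
    if ("eps" %in% names(nodes)) igraph::V(g)$eps <- nodes$eps
    if ("birth_time" %in% names(nodes)) igraph::V(g)$birth_time <- nodes$birth_time
    beta <- beta %||% 1
  }
  if (igraph::any_multiple(g)) {
    warning("Duplicate edges found; removing multi-edges.", call. = FALSE)
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
  }
  as_grown_network(g, beta = beta)
}

#' Write / read a trajectory as CSV
#'
#' Columns `t, x, y, z`; the sampling rate is recoverable from `t`.
#'
#' @param traj An `nf_trajectory`.
#' @param path CSV path.
#' @return `path` (write) / an `nf_trajectory` (read).
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  writeLines(provenance_line(), con)
  utils::write.csv(as.data.frame(as_tibble(traj)[, c("t", "x", "y", "z")]),
                   con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  as_trajectory(utils::read.csv(path, comment.char = "#"))
}

#' Write / read an Arrhenius rate series as CSV
#'
#' Two columns: `temp`, `rate`.
#'
#' @param series Tibble with `temp` and `rate` columns.
#' @param path CSV path.
#' @return `path` (write) / a tibble (read).
#' @export
write_rate_series <- function(series, path) {
  con <- file(path, "w")
  writeLines(provenance_line(), con)
  utils::write.csv(as.data.frame(series[, c("temp", "rate")]), con,
                   row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_rate_series
#' @export
read_rate_series <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' Write a degree history in long format
#'
#' @param network A `grown_network` grown with `record_history = TRUE`.
#' @param path CSV path (columns step, node_id, degree).
#' @return `path`, invisibly.
#' @export
write_degree_history <- function(network, path) {
  con <- file(path, "w")
  writeLines(provenance_line(
    if (!is.null(network$config)) network$config$seed else NA), con)
  utils::write.csv(as.data.frame(degree_history(network)), con,
                   row.names = FALSE)
  close(con)
  invisible(path)
}

#' Write a landscape grid as CSV
#'
#' Long-format grid: columns `x`, `y`, `v`.
#'
#' @param ls An `nf_landscape`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(ls, path) {
  con <- file(path, "w")
  writeLines(provenance_line(ls$seed), con)
  utils::write.csv(as.data.frame(ls$grid), con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Write an eigenmode set as CSV
#'
#' One row per mode: `eigenvalue` followed by the mode vector entries.
#'
#' @param em An `eigenmode_set`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_eigenmodes <- function(em, path) {
  df <- data.frame(eigenvalue = em$eigenvalues)
  modes <- t(em$modes)
  colnames(modes) <- paste0("u", seq_len(ncol(modes)))
  con <- file(path, "w")
  writeLines(provenance_line(), con)
  utils::write.csv(cbind(df, modes), con, row.names = FALSE)
  close(con)
  invisible(path)
}
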