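#' Potential landscape of a network
#'
#' Maps the network onto a planar potential surface \eqn{V(x, y)} whose
#' value at each node's coordinate equals that node's energy level
#' \eqn{\varepsilon}: wells mark fit (low-energy, strongly connected)
#' nodes. Between anchors the potential is a normalized singular-Gaussian
#' (Shepard-type) kernel average,
#' \eqn{V(p) = \sum_i w_i(p)\varepsilon_i / \sum_i w_i(p)} with
#' \eqn{w_i(p) = e^{-d_i^2/(2h^2)}/d_i^2}: exact at every anchor and a
#' convex combination elsewhere, so \eqn{\min\varepsilon \le V \le
#' \max\varepsilon} everywhere.
#'
#' @param network A `grown_network` (or igraph with `eps` vertex attribute).
#' @param layout Optional n-by-2 matrix / data frame of node coordinates;
#'   when absent a deterministic seeded Fruchterman-Reingold embedding is
#'   used.
#' @param bandwidth Kernel width `h`; defaults to half the median
#'   nearest-neighbor distance of the layout.
#' @param grid_n Grid resolution per axis.
#' @param seed Seed for the force-directed layout.
#' @return An `nf_landscape` list: `grid` (tibble x, y, v), `node_layout`
#'   (tibble id, x, y, eps), `bandwidth`, `seed`.
#' @export
landscape <- function(network, layout = NULL, bandwidth = NULL, grid_n = 64,
                      seed = 1L) {
  g <- as_igraph(network)
  eps <- igraph::V(g)$eps
  if (is.null(eps) || any(!is.finite(eps))) {
    abort("Every node needs a finite energy level `eps`.")
  }
  if (is.null(layout)) {
    set.seed(seed)
    layout <- igraph::layout_with_fr(g)
  }
  layout <- as.matrix(layout)[, 1:2, drop = FALSE]
  n <- nrow(layout)
  if (is.null(bandwidth)) {
    if (n > 1) {
      d <- as.matrix(stats::dist(layout))
      diag(d) <- Inf
      bandwidth <- median(apply(d, 1, min)) / 2
    } else bandwidth <- 1
  }
  pad <- max(bandwidth, 1e-6) * 2
  gx <- seq(min(layout[, 1]) - pad, max(layout[, 1]) + pad, length.out = grid_n)
  gy <- seq(min(layout[, 2]) - pad, max(layout[, 2]) + pad, length.out = grid_n)
  pts <- as.matrix(expand.grid(x = gx, y = gy))
  v <- shepard_gauss(pts, layout, eps, bandwidth)
  structure(
    list(grid = tibble(x = pts[, 1], y = pts[, 2], v = v),
         node_layout = tibble(id = seq_len(n), x = layout[, 1],
                              y = layout[, 2], eps = eps),
         bandwidth = bandwidth, seed = seed),
    class = "nf_landscape"
  )
}

# Normalized singular-Gaussian kernel interpolation: exact at anchors,
# convex combination of anchor values elsewhere.
shepard_gauss <- function(points, anchors, values, h) {
  apply(points, 1, function(p) {
    d2 <- (anchors[, 1] - p[1])^2 + (anchors[, 2] - p[2])^2
    hit <- which(d2 < .Machine$double.eps)
    if (length(hit)) return(values[hit[1]])
    w <- exp(-d2 / (2 * h^2)) / d2
    if (!any(w > 0)) { # far field: fall back to inverse-square weights
      w <- 1 / d2
    }
    sum(w * values) / sum(w)
  })
}

#' Evaluate a landscape's potential at arbitrary points
#'
#' @param ls An `nf_landscape`.
#' @param points Matrix or data frame of (x, y) coordinates.
#' @return Potential values, exact \eqn{\varepsilon} at node coordinates.
#' @export
landscape_potential <- function(ls, points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  shepard_gauss(pts, as.matrix(ls$node_layout[, c("x", "y")]),
                ls$node_layout$eps, ls$bandwidth)
}

#' @export
print.nf_landscape <- function(x, ...) {
  cat("<nf_landscape>", nrow(x$node_layout), "nodes on a",
      length(unique(x$grid$x)), "x", length(unique(x$grid$y)), "grid; V in [",
      format(signif(min(x$grid$v), 4)), ",", format(signif(max(x$grid$v), 4)),
      "]\n")
  invisible(x)
}

#' Landscape heat map
#'
#' @param object An `nf_landscape`.
#' @param ... Unused.
#' @return A ggplot object (filled potential raster with node positions).
#' @export
autoplot.nf_landscape <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$v)) +
    ggplot2::geom_point(data = object$node_layout, shape = 21,
                        fill = "white", size = 1.5) +
    ggplot2::scale_fill_viridis_c(name = "V(x, y)") +
    ggplot2::labs(title = "Potential landscape") +
    ggplot2::theme_minimal()
}

#' Geodesic length of a path under a metric field
#'
#' Discrete path length \eqn{\sum_{\mathrm{segments}}
#' \sqrt{\sum_{ij} g_{ij}\,dx_i\,dx_j}}. The metric may be `NULL`
#' (identity: Euclidean polyline length), a single symmetric
#' positive-definite matrix, a function `point -> matrix`, or an array of
#' per-point matrices (evaluated at segment midpoints by averaging the two
#' endpoint tensors).
#'
#' @param path An ordered point sequence (matrix or data frame, >= 2 rows).
#' @param metric `NULL`, a d-by-d matrix, a `function(point)`, or an
#'   n-by-d-by-d array.
#' @return Path length (scalar).
#' @export
geodesic_length <- function(path, metric = NULL) {
  p <- as.matrix(path)
  if (nrow(p) < 2) abort("Path needs at least 2 points.")
  d <- ncol(p)
  seg <- diff(p)
  get_metric <- function(i) {
    gm <- if (is.null(metric)) {
      diag(d)
    } else if (is.function(metric)) {
      metric((p[i, ] + p[i + 1, ]) / 2)
    } else if (is.matrix(metric)) {
      metric
    } else if (is.array(metric) && length(dim(metric)) == 3) {
      (metric[i, , ] + metric[i + 1, , ]) / 2
    } else {
      abort("Unsupported metric specification.")
    }
    if (!isTRUE(all.equal(gm, t(gm)))) abort("Metric must be symmetric.")
    ev <- eigen(gm, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) abort("Metric must be positive-definite along the path.")
    gm
  }
  if (is.null(metric)) {
    return(sum(sqrt(rowSums(seg^2))))
  }
  if (is.matrix(metric)) {
    gm <- get_metric(1)
    return(sum(sqrt(rowSums((seg %*% gm) * seg))))
  }
  total <- 0
  for (i in seq_len(nrow(seg))) {
    gm <- get_metric(i)
    total <- total + sqrt(drop(seg[i, ] %*% gm %*% seg[i, ]))
  }
  total
}

#' Laplacian eigenmodes of a network or grid
#'
#' Eigen-decomposition of the combinatorial graph Laplacian (or of the
#' 5-point Laplacian of a regular planar grid), the discrete analogue of
#' the Laplace-Beltrami operator: solutions of the Helmholtz equation
#' \eqn{\nabla^2 u = -k^2 u}. Eigenvalues come back sorted ascending; the
#' number of (numerically) zero eigenvalues equals the number of connected
#' components, and low eigenvalues correspond to spatially smooth modes
#' while high ones capture locally discrete structure.
#'
#' @param x A `grown_network`, an igraph graph, or `c(nx, ny)` grid
#'   dimensions.
#' @param n_modes Number of eigenpairs to return (default: all).
#' @return An `eigenmode_set` list: `eigenvalues`, `modes` (columns are
#'   eigenvectors), `operator_kind`.
#' @export
laplacian_eigenmodes <- function(x, n_modes = NULL) {
  if (is.numeric(x) && length(x) == 2) {
    nx <- as.integer(x[1]); ny <- as.integer(x[2])
    g <- igraph::make_lattice(c(nx, ny))
    kind <- "grid-laplacian"
  } else {
    g <- as_igraph(x)
    kind <- "graph-laplacian"
  }
  nv <- igraph::gorder(g)
  if (nv == 0) abort("Empty graph.")
  n_modes <- n_modes %||% nv
  if (n_modes > nv) abort("`n_modes` exceeds the node count.")
  lap <- as.matrix(igraph::laplacian_matrix(g))
  e <- eigen(lap, symmetric = TRUE)
  ord <- order(e$values)
  vals <- pmax(e$values[ord], 0)
  structure(
    list(eigenvalues = vals[seq_len(n_modes)],
         modes = e$vectors[, ord, drop = FALSE][, seq_len(n_modes), drop = FALSE],
         operator_kind = kind),
    class = "eigenmode_set"
  )
}

#' @export
print.eigenmode_set <- function(x, ...) {
  cat("<eigenmode_set>", length(x$eigenvalues), "modes (", x$operator_kind,
      "); eigenvalues", paste(signif(head(x$eigenvalues, 5), 4),
                              collapse = ", "),
      if (length(x$eigenvalues) > 5) "..." else "", "\n")
  invisible(x)
}

#' @rdname laplacian_eigenmodes
#' @param ... Unused.
#' @export
tidy.eigenmode_set <- function(x, ...) {
  tibble(mode = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues)
}
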