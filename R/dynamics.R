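#' Winding numbers of a trajectory
#'
#' Extracts each dimension's dominant oscillation frequency (full-length
#' Hann periodogram peak with sub-bin quadratic refinement) and reports the
#' winding-number ratio \eqn{W = f_X : f_Y : f_Z}, reduced by the smallest
#' member. `W` is declared rational when a simultaneous integer-triple
#' approximation with entries at most `max_int` matches the reduced ratios
#' within absolute tolerance `tol`; rational `W` marks periodic dynamics,
#' irrational `W` quasiperiodic or chaotic dynamics.
#'
#' @param traj An `nf_trajectory`.
#' @param max_int Largest integer allowed in the rational triple.
#' @param tol Absolute tolerance on the reduced ratios.
#' @param spline_smooth Apply cubic-spline pre-smoothing before the
#'   periodogram (off by default; see Details in the package vignette).
#' @return A `winding` list: `frequencies` (named f_x, f_y, f_z), `ratio`
#'   (reduced by the smallest member), `rational`, `triple` (integer triple
#'   when rational), `max_int`, `tol`.
#' @export
winding_numbers <- function(traj, max_int = 32, tol = 1e-3,
                            spline_smooth = FALSE) {
  fs <- sampling_rate(traj)
  m <- as.matrix(as_tibble(traj)[, c("x", "y", "z")])
  if (any(apply(m, 2, var) == 0)) {
    abort("Constant dimension: degenerate trajectory.")
  }
  f <- apply(m, 2, dominant_frequency, fs = fs, spline_smooth = spline_smooth)
  names(f) <- c("f_x", "f_y", "f_z")
  ra <- rational_approximation(f, max_int = max_int, tol = tol)
  structure(list(frequencies = f, ratio = f / min(f),
                 rational = ra$rational, triple = ra$triple,
                 max_int = max_int, tol = tol),
            class = "winding")
}

#' @export
print.winding <- function(x, ...) {
  cat("<winding>", paste(signif(x$frequencies, 5), collapse = " : "),
      if (x$rational) paste0("= ", paste(x$triple, collapse = ":"),
                             " (rational)") else "(irrational)", "\n")
  invisible(x)
}

#' Nonlinear coherence of a trajectory
#'
#' Coupling strength \eqn{K \in [0, 1]} among the three state-space
#' dimensions: 0 at maximal desynchronization, 1 at maximal
#' synchronization, with \eqn{K > 0.25} (default threshold) marking chaos
#' for irrationally wound trajectories.
#'
#' The normalized estimator (default) computes Welch-averaged
#' (Hann-windowed, 50% overlap) magnitude-squared coherences for the three
#' dimension pairs and takes their geometric mean at the shared dominant
#' frequency band. Candidate bands are each dimension's spectral peak plus
#' the joint (summed normalized spectra) peak; the band of strongest joint
#' coupling is reported. The `"literal"` estimator returns the un-normalized
#' frequency-domain triple product ratio
#' \eqn{|C_{XYZ}|/(|A_X||A_Y||A_Z|)} at the joint peak and carries no
#' \[0, 1\] guarantee.
#'
#' @param traj An `nf_trajectory` long enough for >= 8 Welch segments.
#' @param estimator `"normalized"` (default) or `"literal"`.
#' @return Coherence `K` (scalar), with attributes `frequency` (center of
#'   the selected band) and `n_segments`.
#' @export
coherence <- function(traj, estimator = c("normalized", "literal")) {
  estimator <- match.arg(estimator)
  fs <- sampling_rate(traj)
  m <- as.matrix(as_tibble(traj)[, c("x", "y", "z")])
  n <- nrow(m)
  L <- welch_segment_length(n)
  if (floor((n - L) / (L %/% 2)) + 1 < 8) {
    abort("Trajectory too short: fewer than 8 Welch segments.")
  }
  pxy <- welch_cross(m[, 1], m[, 2], L)
  pxz <- welch_cross(m[, 1], m[, 3], L)
  pyz <- welch_cross(m[, 2], m[, 3], L)
  ax <- pxy$sxx / sum(pxy$sxx)
  ay <- pxy$syy / sum(pxy$syy)
  az <- pyz$syy / sum(pyz$syy)
  nb <- length(ax)

  if (estimator == "literal") {
    k0 <- which.max(ax + ay + az)
    bin <- k0 + 1L  # welch_cross dropped the DC bin
    w <- hann(L)
    starts <- seq(1, n - L + 1, by = L %/% 2)
    cxyz <- 0 + 0i; axx <- ayy <- azz <- 0
    for (s in starts) {
      i <- s:(s + L - 1)
      fx <- fft((m[i, 1] - mean(m[i, 1])) * w)[bin]
      fy <- fft((m[i, 2] - mean(m[i, 2])) * w)[bin]
      fz <- fft((m[i, 3] - mean(m[i, 3])) * w)[bin]
      cxyz <- cxyz + fx * fy * fz
      axx <- axx + Mod(fx); ayy <- ayy + Mod(fy); azz <- azz + Mod(fz)
    }
    ns <- length(starts)
    k <- Mod(cxyz / ns) / ((axx / ns) * (ayy / ns) * (azz / ns))
    return(structure(k, frequency = pxy$freq[k0] * fs,
                     n_segments = ns, estimator = estimator))
  }

  candidates <- unique(c(which.max(ax), which.max(ay), which.max(az),
                         which.max(ax + ay + az)))
  msc_band <- function(p, band) {
    min(1, sum(Mod(p$sxy[band])^2) / sum(p$sxx[band] * p$syy[band]))
  }
  best <- -Inf; best_k <- candidates[1]
  for (k0 in candidates) {
    band <- intersect((k0 - 1):(k0 + 1), seq_len(nb))
    g <- (msc_band(pxy, band) * msc_band(pxz, band) * msc_band(pyz, band))^(1 / 3)
    if (g > best) { best <- g; best_k <- k0 }
  }
  structure(min(1, max(0, best)), frequency = pxy$freq[best_k] * fs,
            n_segments = pxy$n_segments, estimator = estimator)
}

#' Classify trajectory dynamics
#'
#' Decision table: zero-variance trajectory is a fixed point; rational
#' winding is periodic; irrational winding is quasiperiodic when the
#' coherence stays at or below the chaos threshold and chaotic above it.
#'
#' @param rational Logical: is the winding ratio rational? (Or a `winding`
#'   object.)
#' @param k Coherence from [coherence()].
#' @param zero_variance Is the trajectory constant?
#' @param chaos_threshold Coherence bound above which chaos is declared.
#' @return One of `"fixed-point"`, `"periodic"`, `"quasiperiodic"`,
#'   `"chaotic"`.
#' @export
classify_dynamics <- function(rational, k, zero_variance = FALSE,
                              chaos_threshold = 0.25) {
  if (inherits(rational, "winding")) rational <- rational$rational
  if (isTRUE(zero_variance)) return("fixed-point")
  if (isTRUE(rational)) return("periodic")
  if (k > chaos_threshold) "chaotic" else "quasiperiodic"
}

#' Wolfram class of a dynamics label
#'
#' Fixed points map to Class I (homogeneous), periodic dynamics to Class II,
#' chaotic dynamics to Class III (indeterminable), and quasiperiodic
#' dynamics to Class IV (complex, capable of universal computation).
#'
#' @param dynamics_class A label from [classify_dynamics()].
#' @return `"I"`, `"II"`, `"III"` or `"IV"`.
#' @export
wolfram_class <- function(dynamics_class) {
  switch(match.arg(dynamics_class,
                   c("fixed-point", "periodic", "quasiperiodic", "chaotic")),
         "fixed-point" = "I", periodic = "II", quasiperiodic = "IV",
         chaotic = "III")
}

#' Full dynamics report for a trajectory
#'
#' Runs winding-number extraction, coherence estimation and the dynamics and
#' Wolfram classifications in one pass.
#'
#' @inheritParams winding_numbers
#' @param chaos_threshold Coherence bound above which chaos is declared.
#' @return A `dynamics_report` list: `winding`, `coherence`,
#'   `dynamics_class`, `wolfram_class`.
#' @export
#' @examples
#' traj <- make_trajectory("periodic")
#' classify_trajectory(traj)
classify_trajectory <- function(traj, max_int = 32, tol = 1e-3,
                                chaos_threshold = 0.25) {
  m <- as.matrix(as_tibble(traj)[, c("x", "y", "z")])
  if (all(apply(m, 2, var) == 0)) {
    return(structure(list(winding = NULL, coherence = NA_real_,
                          dynamics_class = "fixed-point",
                          wolfram_class = "I"),
                     class = "dynamics_report"))
  }
  w <- winding_numbers(traj, max_int = max_int, tol = tol)
  k <- coherence(traj)
  cls <- classify_dynamics(w$rational, k, chaos_threshold = chaos_threshold)
  structure(list(winding = w, coherence = as.numeric(k),
                 coherence_frequency = attr(k, "frequency"),
                 dynamics_class = cls, wolfram_class = wolfram_class(cls)),
            class = "dynamics_report")
}

#' @export
print.dynamics_report <- function(x, ...) {
  cat("<dynamics_report>", x$dynamics_class,
      paste0("(Wolfram ", x$wolfram_class, ")"),
      "| K =", format(signif(x$coherence, 4)), "\n")
  invisible(x)
}

#' @rdname classify_trajectory
#' @param x A `dynamics_report`.
#' @param ... Unused.
#' @export
glance.dynamics_report <- function(x, ...) {
  tibble(dynamics_class = x$dynamics_class, wolfram_class = x$wolfram_class,
         coherence = x$coherence,
         rational = if (is.null(x$winding)) NA else x$winding$rational,
         f_x = if (is.null(x$winding)) NA_real_ else x$winding$frequencies[["f_x"]],
         f_y = if (is.null(x$winding)) NA_real_ else x$winding$frequencies[["f_y"]],
         f_z = if (is.null(x$winding)) NA_real_ else x$winding$frequencies[["f_z"]])
}

#' Betti numbers of a network
#'
#' Treats the graph as a 1-complex: \eqn{B_0} is the number of connected
#' components and \eqn{B_1 = E - V + B_0} the cycle rank (independent
#' loops).
#'
#' @param network A `grown_network` or igraph graph with at least one node.
#' @return Named integer vector `c(b0, b1)`.
#' @export
betti_numbers <- function(network) {
  g <- as_igraph(network)
  if (igraph::gorder(g) == 0) abort("Empty graph.")
  b0 <- igraph::count_components(g)
  b1 <- igraph::gsize(g) - igraph::gorder(g) + b0
  c(b0 = as.integer(b0), b1 = as.integer(b1))
}

#' Euler characteristic of a network
#'
#' \eqn{\chi = \sum_i (-1)^i B_i = B_0 - B_1} for a 1-complex, which equals
#' \eqn{V - E}. Two networks of equal \eqn{\chi} are algebraically
#' invariant in the homological sense.
#'
#' @inheritParams betti_numbers
#' @return Integer \eqn{\chi}.
#' @export
euler_characteristic <- function(network) {
  b <- betti_numbers(network)
  as.integer(b[["b0"]] - b[["b1"]])
}

as_igraph <- function(x) {
  if (inherits(x, "grown_network")) return(x$graph)
  if (inherits(x, "igraph")) return(x)
  abort("Expected a grown_network or igraph object.")
}
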