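#' Fitness distribution specification
#'
#' Names a family for the base fitness draw \eqn{\rho(\eta)}:
#'
#' * `"uniform"` — uniform on (0, 1\].
#' * `"exponential"` — exponential with the given `rate`.
#' * `"dirac"` — every node has fitness `value` (the uniform-fitness limit;
#'   growth then reduces to classical preferential attachment).
#' * `"truncated_power"` — \eqn{\rho(\eta) = (\theta+1)(1-\eta)^\theta} on
#'   \[0, 1\), `exponent` \eqn{= \theta \ge 0}. Mass accumulates just below
#'   the maximal fitness while the very fittest values stay rare, which is
#'   the regime that provokes Bose-Einstein condensation of links on the
#'   minimum-energy node at low temperature.
#'
#' @param family One of `"uniform"`, `"exponential"`, `"dirac"`,
#'   `"truncated_power"`.
#' @param rate Rate of the exponential family.
#' @param value Atom of the dirac family.
#' @param exponent Exponent \eqn{\theta} of the truncated-power family.
#' @return A `fitness_dist` spec usable in [growth_config()] and
#'   [make_fitness_samples()].
#' @export
fitness_dist <- function(family = c("uniform", "exponential", "dirac",
                                    "truncated_power"),
                         rate = 1, value = 1, exponent = 1) {
  family <- tryCatch(match.arg(family),
                     error = function(e) abort(paste0("Unknown fitness family: ",
                                                      family[1])))
  if (family == "exponential" && rate <= 0) abort("`rate` must be positive.")
  if (family == "dirac" && (value < 0 || !is.finite(value))) {
    abort("`value` must be finite and non-negative.")
  }
  if (family == "truncated_power" && exponent < 0) abort("`exponent` must be >= 0.")
  structure(list(family = family, rate = rate, value = value,
                 exponent = exponent), class = "fitness_dist")
}

#' Draw fitness samples
#'
#' Samples `n` base fitness values from a [fitness_dist()] spec, using R's
#' global random stream (pass `seed` to make the draw self-contained).
#'
#' @param n Number of samples.
#' @param dist A `fitness_dist` spec.
#' @param seed Optional integer seed applied before sampling.
#' @return Numeric vector of length `n`.
#' @export
make_fitness_samples <- function(n, dist = fitness_dist("uniform"), seed = NULL) {
  if (!inherits(dist, "fitness_dist")) abort("`dist` must come from fitness_dist().")
  if (!is.null(seed)) set.seed(seed)
  switch(dist$family,
    uniform = 1 - runif(n) * (1 - .Machine$double.eps), # support (0, 1]
    exponential = stats::rexp(n, rate = dist$rate),
    dirac = rep(dist$value, n),
    truncated_power = 1 - runif(n)^(1 / (dist$exponent + 1))
  )
}

#' Synthetic state-space trajectories
#'
#' Deterministic generators for each dynamics class:
#'
#' * `"fixed-point"` — constant coordinates (zero variance).
#' * `"periodic"` — sinusoids at 2, 3 and 5 Hz (a small-integer frequency
#'   ratio, hence rational winding).
#' * `"quasiperiodic"` — sinusoids at 1, \eqn{\varphi} and \eqn{\varphi^2} Hz
#'   (\eqn{\varphi} the golden ratio): mutually incommensurate, hence
#'   irrational winding with near-zero cross-dimension coherence.
#' * `"chaotic-coupled"` — three identical Rössler oscillators in the funnel
#'   regime (a = 0.28, b = 0.2, c = 5.7, time scale 15) with all-to-all
#'   diffusive coupling in x of strength 2, above the synchronization
#'   threshold; integrated by fixed-step RK4 from pinned initial conditions
#'   after an 80-time-unit transient. The trajectory records (x of oscillator
#'   1, y of oscillator 2, z of oscillator 3): once synchronized these are the
#'   three coordinates of a single funnel Rössler system, so the dimensions
#'   are strongly coherent while their dominant frequencies are
#'   incommensurate.
#'
#' The chaotic fixture is fully deterministic; `seed` only affects the
#' (noiseless by default) periodic and quasiperiodic classes when `snr_db`
#' is finite.
#'
#' @param class Trajectory class.
#' @param fs Sampling rate (samples per second). Defaults: 100, except 200
#'   for `"chaotic-coupled"`.
#' @param duration Length in seconds. Defaults: 10 (fixed-point, periodic),
#'   40 (quasiperiodic), 60 (chaotic-coupled).
#' @param seed RNG seed for optional observation noise.
#' @param snr_db Per-dimension signal-to-noise ratio in dB; `Inf` (default)
#'   adds no noise.
#' @return An `nf_trajectory` tibble with columns `t`, `x`, `y`, `z`.
#' @export
make_trajectory <- function(class = c("fixed-point", "periodic",
                                      "quasiperiodic", "chaotic-coupled"),
                            fs = NULL, duration = NULL, seed = 1L,
                            snr_db = Inf) {
  class <- match.arg(class)
  fs <- fs %||% if (class == "chaotic-coupled") 200 else 100
  duration <- duration %||% switch(class,
    "fixed-point" = 10, "periodic" = 10, "quasiperiodic" = 40,
    "chaotic-coupled" = 60)
  if (fs * duration < 512) abort("Require fs * duration >= 512.")
  tt <- seq_len(fs * duration) / fs
  phi <- (1 + sqrt(5)) / 2
  X <- switch(class,
    "fixed-point" = cbind(x = rep(1.5, length(tt)),
                          y = rep(-0.5, length(tt)),
                          z = rep(2.0, length(tt))),
    "periodic" = cbind(x = sin(2 * pi * 2 * tt),
                       y = sin(2 * pi * 3 * tt),
                       z = sin(2 * pi * 5 * tt)),
    "quasiperiodic" = cbind(x = sin(2 * pi * 1 * tt),
                            y = sin(2 * pi * phi * tt),
                            z = sin(2 * pi * phi^2 * tt)),
    "chaotic-coupled" = rossler_triple(fs, duration)
  )
  if (is.finite(snr_db) && class != "fixed-point") {
    set.seed(seed)
    sdn <- apply(X, 2, sd) / 10^(snr_db / 20)
    X <- X + cbind(rnorm(nrow(X), 0, sdn[1]), rnorm(nrow(X), 0, sdn[2]),
                   rnorm(nrow(X), 0, sdn[3]))
  }
  as_trajectory(tibble(t = tt, x = X[, 1], y = X[, 2], z = X[, 3]), fs = fs)
}

# Three diffusively x-coupled identical funnel Rössler oscillators, RK4.
# Returns cbind(x1, y2, z3). Deterministic: fixed ICs, fixed step 1/(4 fs).
rossler_triple <- function(fs, duration, coupling = 2, tau = 15,
                           a = 0.28, b = 0.2, cc = 5.7, transient = 80) {
  sub <- 4L
  h <- 1 / (fs * sub)
  deriv <- function(s) {
    x <- s[c(1L, 4L, 7L)]; y <- s[c(2L, 5L, 8L)]; z <- s[c(3L, 6L, 9L)]
    mx <- mean(x)
    tau * as.vector(rbind(-y - z + coupling * (mx - x),
                          x + a * y,
                          b + z * (x - cc)))
  }
  rk4 <- function(s) {
    k1 <- deriv(s); k2 <- deriv(s + h / 2 * k1)
    k3 <- deriv(s + h / 2 * k2); k4 <- deriv(s + h * k3)
    s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s <- c(1, 5, 0.2, -3, 2, 0.1, 5, -4, 0.3)
  for (i in seq_len(round(transient * fs * sub / tau))) s <- rk4(s)
  n <- round(fs * duration)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (j in seq_len(sub)) s <- rk4(s)
    out[i, ] <- c(s[1L], s[5L], s[9L])
  }
  colnames(out) <- c("x", "y", "z")
  out
}

#' Synthetic Arrhenius rate series
#'
#' Generates \eqn{k(T) = A e^{-E_a/(R T)} + \mathrm{floor}}. A zero
#' tunneling floor gives exactly classical Arrhenius data (linear
#' \eqn{\ln k} vs \eqn{1/T}); a temperature-independent floor emulates a
#' quantum tunneling channel that dominates at low temperature and bends the
#' Arrhenius plot.
#'
#' @param e_a Activation energy.
#' @param a_prefactor Pre-exponential rate constant A.
#' @param temps Positive, sorted temperatures.
#' @param tunneling_floor Temperature-independent additive rate.
#' @param r_gas Gas constant in working units (1 in natural units).
#' @return Tibble with columns `temp`, `rate`.
#' @export
make_rate_series <- function(e_a, a_prefactor, temps, tunneling_floor = 0,
                             r_gas = 1) {
  if (any(temps <= 0)) abort("Temperatures must be positive.")
  tibble(temp = temps,
         rate = a_prefactor * exp(-e_a / (r_gas * temps)) + tunneling_floor)
}

#' Small deterministic graph fixtures
#'
#' Toy graphs with fitness/energy attributes for topology and eigenmode
#' tests: a balanced tree, a cycle, a star (hub first), two disjoint
#' triangles, or an Erdős–Rényi graph.
#'
#' @param kind One of `"tree"`, `"cycle"`, `"star"`, `"two-triangles"`,
#'   `"random"`.
#' @param n Number of nodes (ignored for `"two-triangles"`).
#' @param seed Seed for fitness draws (and edges of `"random"`).
#' @param p Edge probability for `"random"`.
#' @return A `grown_network` (without growth history or config).
#' @export
make_graph_fixture <- function(kind = c("tree", "cycle", "star",
                                        "two-triangles", "random"),
                               n = 8, seed = 1L, p = 0.3) {
  kind <- match.arg(kind)
  set.seed(seed)
  g <- switch(kind,
    tree = igraph::make_tree(n, children = 2, mode = "undirected"),
    cycle = igraph::make_ring(n),
    star = igraph::make_star(n, mode = "undirected", center = 1),
    "two-triangles" = igraph::make_graph(c(1,2, 2,3, 3,1, 4,5, 5,6, 6,4),
                                         directed = FALSE),
    random = igraph::sample_gnp(n, p)
  )
  nv <- igraph::gorder(g)
  eta <- make_fitness_samples(nv, fitness_dist("uniform"))
  as_grown_network(g, eta = eta, beta = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
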