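#' Dynamic exponent of link acquisition
#'
#' \eqn{f(\varepsilon) = e^{-\beta(\varepsilon - \mu)}}: the power-law
#' exponent with which a node at energy \eqn{\varepsilon} accrues links
#' (see [expected_degree()]). \eqn{f = 1} at \eqn{\varepsilon = \mu} marks
#' the Bose-Einstein point; \eqn{f \ll 1} the classical Maxwell-Boltzmann
#' regime; \eqn{f \gg 1} the Fermi-Dirac regime.
#'
#' @param eps Energy level(s).
#' @param beta Positive inverse temperature.
#' @param mu Chemical potential.
#' @return Dynamic exponent(s), positive.
#' @export
dynamic_exponent <- function(eps, beta, mu) {
  if (beta <= 0) abort("`beta` must be positive.")
  exp(-beta * (eps - mu))
}

#' Occupation numbers under the three statistics
#'
#' Expected number of link endpoints at a node of energy \eqn{\varepsilon}:
#' Bose-Einstein \eqn{n = 1/(e^{\beta(\varepsilon-\mu)} - 1)} (requires
#' \eqn{\varepsilon > \mu}), Maxwell-Boltzmann
#' \eqn{n = e^{-\beta(\varepsilon-\mu)}}, Fermi-Dirac
#' \eqn{n = 1/(e^{\beta(\varepsilon-\mu)} + 1)}. For any common argument
#' with \eqn{\beta(\varepsilon-\mu) > 0} they order
#' \eqn{n_{FD} < n_{MB} < n_{BE}} and agree in the dilute limit.
#'
#' @param eps Energy level(s).
#' @param beta Positive inverse temperature.
#' @param mu Chemical potential.
#' @return Occupation number(s).
#' @name occupation
NULL

#' @rdname occupation
#' @export
occupation_be <- function(eps, beta, mu) {
  if (beta <= 0) abort("`beta` must be positive.")
  if (any(eps <= mu)) {
    abort(paste("Bose-Einstein occupation diverges for eps <= mu:",
                "the chemical potential has reached the band bottom",
                "(condensation)."))
  }
  1 / expm1(beta * (eps - mu))
}

#' @rdname occupation
#' @export
occupation_mb <- function(eps, beta, mu) {
  if (beta <= 0) abort("`beta` must be positive.")
  exp(-beta * (eps - mu))
}

#' @rdname occupation
#' @export
occupation_fd <- function(eps, beta, mu) {
  if (beta <= 0) abort("`beta` must be positive.")
  1 / (exp(beta * (eps - mu)) + 1)
}

#' Solve for the chemical potential
#'
#' Finds \eqn{\mu} such that the occupation numbers over the given energy
#' levels sum to `total_occupation` (for a grown network: twice the edge
#' count). The occupation sum is strictly increasing in \eqn{\mu}, so a
#' bracketed bisection is used. Under Bose-Einstein statistics \eqn{\mu}
#' must stay below the band bottom \eqn{\min\varepsilon}; when even
#' \eqn{\mu \to \min\varepsilon} cannot place the required occupation on the
#' excited levels, the solver reports condensation: \eqn{\mu} pinned at the
#' band bottom and the excess occupation assigned to the minimum-energy
#' level.
#'
#' @param energies Finite energy levels, one per node.
#' @param beta Positive inverse temperature.
#' @param total_occupation Target total occupation (> 0).
#' @param statistics `"be"`, `"mb"` or `"fd"`.
#' @param tol Relative tolerance on the occupation sum.
#' @return A `chem_potential` list: `mu`, `condensed`, `occupations`
#'   (per level), `excess` (condensate occupation, 0 if not condensed),
#'   `normalization` (the partition-style sum \eqn{\sum_i
#'   e^{-\beta(\varepsilon_i - \mu)}}).
#' @export
solve_chemical_potential <- function(energies, beta,
                                     total_occupation,
                                     statistics = c("be", "mb", "fd"),
                                     tol = 1e-10) {
  statistics <- match.arg(statistics)
  if (length(energies) == 0) abort("`energies` must be non-empty.")
  if (any(!is.finite(energies))) abort("`energies` must all be finite.")
  if (total_occupation <= 0) abort("`total_occupation` must be positive.")
  if (beta <= 0) abort("`beta` must be positive.")

  occ_fun <- switch(statistics, be = occupation_be, mb = occupation_mb,
                    fd = occupation_fd)
  e_min <- min(energies)

  if (statistics == "be") {
    excited <- energies[energies > e_min]
    capacity <- if (length(excited)) sum(1 / expm1(beta * (excited - e_min))) else 0
    if (total_occupation >= capacity) {
      mu <- e_min
      occ <- numeric(length(energies))
      occ[energies > e_min] <- 1 / expm1(beta * (energies[energies > e_min] - e_min))
      excess <- total_occupation - capacity
      ground <- which(energies == e_min)
      occ[ground] <- excess / length(ground)
      return(structure(list(mu = mu, condensed = TRUE, occupations = occ,
                            excess = excess,
                            normalization = sum(exp(-beta * (energies - mu)))),
                       class = "chem_potential"))
    }
    lo <- e_min - 50 / beta
    hi <- e_min - 1e-12
    while (sum(occ_fun(energies, beta, lo)) > total_occupation) lo <- lo - 50 / beta
  } else {
    lo <- e_min - 50 / beta
    hi <- max(energies) + 50 / beta
    while (sum(occ_fun(energies, beta, lo)) > total_occupation) lo <- lo - 50 / beta
    while (sum(occ_fun(energies, beta, hi)) < total_occupation) hi <- hi + 50 / beta
  }
  f <- function(mu) sum(occ_fun(energies, beta, mu)) - total_occupation
  mu <- (lo + hi) / 2
  for (i in seq_len(200)) {
    mu <- (lo + hi) / 2
    fm <- f(mu)
    if (abs(fm) <= tol * total_occupation) break
    if (fm > 0) hi <- mu else lo <- mu
  }
  structure(list(mu = mu, condensed = FALSE,
                 occupations = occ_fun(energies, beta, mu), excess = 0,
                 normalization = sum(exp(-beta * (energies - mu)))),
            class = "chem_potential")
}

#' @export
print.chem_potential <- function(x, ...) {
  cat("<chem_potential> mu =", format(x$mu),
      if (x$condensed) " [condensed]" else "", "\n")
  invisible(x)
}

#' Classify the computational phase from dynamic exponents
#'
#' Maps the representative (median) dynamic exponent to a phase label:
#' within `delta` of 1 is Bose-Einstein; at or below `f_lo` is
#' Maxwell-Boltzmann (the "much less than 1" regime); at or above `f_hi` is
#' Fermi-Dirac (the "much greater than 1" regime); anything else is a
#' crossover.
#'
#' @param f_values Non-empty, non-negative dynamic exponents.
#' @param thresholds Named numeric vector `c(f_lo, delta, f_hi)`.
#' @return One of `"bose-einstein"`, `"maxwell-boltzmann"`, `"fermi-dirac"`,
#'   `"crossover"`.
#' @export
classify_phase <- function(f_values,
                           thresholds = c(f_lo = 0.1, delta = 0.05, f_hi = 10)) {
  if (length(f_values) == 0 || any(f_values < 0)) {
    abort("`f_values` must be non-empty and non-negative.")
  }
  f <- median(f_values)
  if (abs(f - 1) <= thresholds[["delta"]]) return("bose-einstein")
  if (f <= thresholds[["f_lo"]]) return("maxwell-boltzmann")
  if (f >= thresholds[["f_hi"]]) return("fermi-dirac")
  "crossover"
}

#' Critical annealing parameter
#'
#' The annealing parameter \eqn{\Gamma} stands in for absolute temperature;
#' its critical value relates to the condensation temperature \eqn{T_C} by
#' \eqn{\Gamma_C = T_C k_B / (n/\zeta(3/2))^{2/3}} with \eqn{n} the particle
#' density and \eqn{\zeta} the Riemann zeta function.
#'
#' @param t_c Condensation temperature (> 0).
#' @param n_density Particle density (> 0).
#' @param k_b Boltzmann constant in working units (1 in natural units).
#' @return \eqn{\Gamma_C}.
#' @export
critical_gamma <- function(t_c, n_density, k_b = 1) {
  if (any(t_c <= 0) || any(n_density <= 0) || k_b <= 0) {
    abort("`t_c`, `n_density` and `k_b` must be positive.")
  }
  (t_c * k_b) / (n_density / pracma::zeta(1.5))^(2 / 3)
}

#' Condensate fraction of a grown network
#'
#' Share of all link endpoints held by the minimum-energy (fittest) node.
#' Near 0 in the fit-get-rich phase; order one when the network has
#' Bose-Einstein condensed onto its fittest node.
#'
#' @param network A `grown_network` with at least one edge.
#' @return Fraction in \[0, 1\].
#' @export
condensate_fraction <- function(network) {
  nodes <- network$nodes
  if (nrow(nodes) == 0 || sum(nodes$degree) == 0) {
    abort("Network must have at least one edge.")
  }
  nodes$degree[which.min(nodes$eps)] / sum(nodes$degree)
}

#' Phase report for a grown network
#'
#' Solves the chemical potential for the network's energy levels and total
#' link-endpoint count, computes per-node dynamic exponents and occupation
#' numbers, labels the computational phase, and reports the condensate
#' fraction and the critical annealing parameter. Conventions: the target
#' occupation is \eqn{2E} (each edge contributes two endpoints);
#' \eqn{\Gamma_C} is evaluated at \eqn{T_C = 1/\beta} with particle density
#' \eqn{2E/N} in natural units (\eqn{k_B = 1}).
#'
#' @param network A `grown_network`.
#' @param beta Inverse temperature; defaults to the growth config's.
#' @param statistics `"be"` (default), `"mb"` or `"fd"`.
#' @param thresholds Phase thresholds, see [classify_phase()].
#' @return A `phase_report` list: `mu`, `f_values`, `occupations`,
#'   `normalization`, `phase_label`, `condensate_fraction`, `gamma_c`.
#' @export
phase_report <- function(network, beta = NULL,
                         statistics = c("be", "mb", "fd"),
                         thresholds = c(f_lo = 0.1, delta = 0.05, f_hi = 10)) {
  statistics <- match.arg(statistics)
  beta <- beta %||% network$config$beta
  if (is.null(beta)) abort("Supply `beta` (network has no config).")
  nodes <- network$nodes
  total <- sum(nodes$degree)
  sol <- solve_chemical_potential(nodes$eps, beta, total, statistics)
  f_vals <- dynamic_exponent(nodes$eps, beta, sol$mu)
  label <- if (sol$condensed) "condensate" else classify_phase(f_vals, thresholds)
  structure(
    list(mu = sol$mu, f_values = f_vals, occupations = sol$occupations,
         normalization = sol$normalization, phase_label = label,
         condensate_fraction = condensate_fraction(network),
         gamma_c = critical_gamma(1 / beta, total / nrow(nodes)),
         beta = beta, statistics = statistics),
    class = "phase_report"
  )
}

#' @export
print.phase_report <- function(x, ...) {
  cat("<phase_report>", x$phase_label,
      "| mu =", format(x$mu),
      "| condensate fraction =", format(round(x$condensate_fraction, 4)), "\n")
  invisible(x)
}

#' @rdname phase_report
#' @param x A `phase_report`.
#' @param ... Unused.
#' @export
tidy.phase_report <- function(x, ...) {
  tibble(node = seq_along(x$f_values), f = x$f_values,
         occupation = x$occupations)
}

#' @rdname phase_report
#' @export
glance.phase_report <- function(x, ...) {
  tibble(mu = x$mu, phase_label = x$phase_label,
         condensate_fraction = x$condensate_fraction,
         gamma_c = x$gamma_c, normalization = x$normalization,
         beta = x$beta, statistics = x$statistics)
}

#' Occupation-vs-energy plot of a phase report
#'
#' @param object A `phase_report`.
#' @param network The `grown_network` the report was computed from (supplies
#'   the energy axis); if omitted, nodes are indexed by rank.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_report <- function(object, network = NULL, ...) {
  df <- tidy(object)
  if (!is.null(network)) df$energy <- network$nodes$eps else df$energy <- df$node
  ggplot2::ggplot(df, ggplot2::aes(.data$energy, .data$occupation)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = if (is.null(network)) "node" else "energy level",
                  y = "occupation n", title = paste("Phase:", object$phase_label)) +
    ggplot2::theme_minimal()
}
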