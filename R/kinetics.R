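#' Classical Arrhenius rate
#'
#' First-order rate constant \eqn{k = A e^{-E_a/(RT)}}.
#'
#' @param a_prefactor Proportionality constant A (> 0), rate units.
#' @param e_a Activation energy.
#' @param temp Absolute temperature (> 0).
#' @param r_gas Gas constant in working units (1 in natural units).
#' @return Rate constant.
#' @export
arrhenius_rate <- function(a_prefactor, e_a, temp, r_gas = 1) {
  if (any(temp <= 0) || r_gas <= 0) abort("`temp` and `r_gas` must be positive.")
  if (any(a_prefactor <= 0)) abort("`a_prefactor` must be positive.")
  a_prefactor * exp(-e_a / (r_gas * temp))
}

#' Quantum (annealing) transition rate
#'
#' \eqn{k = (k_B \Gamma / h) f(\varepsilon)}: the tunneling-field form of
#' the rate, linear in both the annealing parameter \eqn{\Gamma} and the
#' dynamic exponent \eqn{f(\varepsilon)}.
#'
#' @param gamma Annealing parameter (> 0).
#' @param f_eps Dynamic exponent (>= 0), see [dynamic_exponent()].
#' @param k_b Boltzmann constant in working units.
#' @param h_planck Planck constant in working units.
#' @return Rate constant.
#' @export
quantum_rate <- function(gamma, f_eps, k_b = 1, h_planck = 1) {
  if (any(gamma <= 0)) abort("`gamma` must be positive.")
  if (any(f_eps < 0)) abort("`f_eps` must be non-negative.")
  (k_b * gamma / h_planck) * f_eps
}

#' Activation energy from an observed rate
#'
#' Inverts the Arrhenius law: \eqn{E_a = -RT \ln(k/A)}. In the quantum
#' regime the rate is first formed from the annealing parameters via
#' [quantum_rate()] and then inverted the same way (with `temp`, or with
#' `gamma` substituted for the temperature when `use_gamma = TRUE`).
#'
#' @param rate Observed rate (> 0); ignored in the quantum regime.
#' @param a_prefactor Prefactor A (> 0).
#' @param temp Absolute temperature.
#' @param r_gas Gas constant in working units.
#' @param regime `"classical"` or `"quantum"`.
#' @param gamma,f_eps,k_b,h_planck Quantum-regime rate inputs.
#' @param use_gamma Use \eqn{\Gamma} in place of T in the inversion?
#' @return Activation energy.
#' @export
activation_energy <- function(rate = NULL, a_prefactor, temp, r_gas = 1,
                              regime = c("classical", "quantum"),
                              gamma = NULL, f_eps = NULL,
                              k_b = 1, h_planck = 1, use_gamma = FALSE) {
  regime <- match.arg(regime)
  if (regime == "quantum") {
    rate <- quantum_rate(gamma, f_eps, k_b, h_planck)
    if (use_gamma) temp <- gamma
  }
  if (any(rate <= 0)) abort("`rate` must be positive.")
  if (any(a_prefactor <= 0)) abort("`a_prefactor` must be positive.")
  -r_gas * temp * log(rate / a_prefactor)
}

#' Arrhenius-plot linearity diagnostic
#'
#' Regresses \eqn{\ln k} on \eqn{1/T}. A classical (thermally activated)
#' process gives a straight line with slope \eqn{-E_a/R}; quantum tunneling
#' contributes a temperature-independent channel that bends the plot at low
#' temperature. The series is labeled classical when the fit's \eqn{R^2}
#' reaches `r2_threshold`, quantum otherwise.
#'
#' @param rates Positive rate series (or a tibble from [make_rate_series()]).
#' @param temps Positive temperatures, same length; ignored when `rates` is
#'   a tibble with `temp`/`rate` columns.
#' @param r2_threshold Coefficient-of-determination threshold.
#' @param r_gas Gas constant used to convert the slope into \eqn{E_a}.
#' @return An `arrhenius_fit` list: `regime`, `slope`, `intercept`,
#'   `r_squared`, `e_a`, `ln_a`.
#' @export
arrhenius_linearity <- function(rates, temps = NULL, r2_threshold = 0.995,
                                r_gas = 1) {
  if (is.data.frame(rates)) {
    temps <- rates$temp
    rates <- rates$rate
  }
  if (length(rates) < 4) abort("Need at least 4 rate/temperature points.")
  if (length(rates) != length(temps)) abort("`rates` and `temps` lengths differ.")
  if (any(rates <= 0) || any(temps <= 0)) abort("Rates and temperatures must be positive.")
  y <- log(rates)
  fit <- lm(y ~ I(1 / temps))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  structure(
    list(regime = if (r2 >= r2_threshold) "classical" else "quantum",
         slope = slope, intercept = intercept, r_squared = r2,
         e_a = -slope * r_gas, ln_a = intercept,
         r2_threshold = r2_threshold),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat("<arrhenius_fit>", x$regime, "| R^2 =", format(round(x$r_squared, 6)),
      "| E_a =", format(x$e_a), "\n")
  invisible(x)
}

#' @rdname arrhenius_linearity
#' @param x An `arrhenius_fit`.
#' @param ... Unused.
#' @export
tidy.arrhenius_fit <- function(x, ...) {
  tibble(term = c("intercept (ln A)", "slope (-E_a/R)"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname arrhenius_linearity
#' @export
glance.arrhenius_fit <- function(x, ...) {
  tibble(regime = x$regime, r_squared = x$r_squared, e_a = x$e_a,
         ln_a = x$ln_a)
}

#' Landauer reset energy of a node state
#'
#' Minimum energy to reset/erase the stored state of a node of fitness
#' \eqn{\eta}: under the default parse,
#' \eqn{\varepsilon = -(1/\beta)\ln(2\eta)}, which differs from the plain
#' fitness-energy map by the Landauer \eqn{\ln 2} bit quantum (at
#' \eqn{\eta = 1}, \eqn{\varepsilon = -\ln 2/\beta}, one bit's worth below
#' zero). The alternative parse \eqn{-(1/\beta)\log_2\eta} is selectable.
#'
#' @param eta Positive fitness.
#' @param beta Positive inverse temperature (\eqn{1/(k_B T)}).
#' @param parse `"ln2eta"` (default) or `"log2"`.
#' @return Reset energy.
#' @export
landauer_energy <- function(eta, beta, parse = c("ln2eta", "log2")) {
  parse <- match.arg(parse)
  if (any(eta <= 0)) abort("`eta` must be positive.")
  if (beta <= 0) abort("`beta` must be positive.")
  switch(parse,
         ln2eta = -log(2 * eta) / beta,
         log2 = -log2(eta) / beta)
}

#' Work from the free-energy balance
#'
#' Work-energy theorem for a state switch: classical
#' \eqn{W = \Delta H - T\Delta S}; hybrid \eqn{W = \Delta H - \Gamma\Delta S}
#' with the annealing parameter substituting temperature. The chain of
#' equalities \eqn{W = \Delta E = \Delta E_{free}} is recorded verbatim in
#' the returned row.
#'
#' @param delta_h Enthalpy/heat change.
#' @param delta_s Entropy change.
#' @param control Temperature T (classical mode) or annealing parameter
#'   \eqn{\Gamma} (hybrid mode).
#' @param mode `"classical"` or `"hybrid"`.
#' @return One-row tibble: `work`, `delta_e`, `e_free`, `delta_h`,
#'   `delta_s`, `control`, `mode`.
#' @export
work_free_energy <- function(delta_h, delta_s, control,
                             mode = c("classical", "hybrid")) {
  mode <- match.arg(mode)
  if (any(!is.finite(c(delta_h, delta_s, control)))) abort("Inputs must be finite.")
  w <- delta_h - control * delta_s
  tibble(work = w, delta_e = w, e_free = w, delta_h = delta_h,
         delta_s = delta_s, control = control, mode = mode)
}

#' Engine metrics of a computational stroke
#'
#' Power \eqn{P = \Delta W/\Delta t}, heat-engine efficiency
#' \eqn{\Phi = W/E_{input}}, and refrigeration coefficient of performance
#' \eqn{COP = E_{output}/W}.
#'
#' @param delta_w Work performed (nonzero for COP).
#' @param delta_t Duration (> 0).
#' @param e_input Input energy (> 0).
#' @param e_output Output energy.
#' @return One-row tibble: `power`, `efficiency`, `cop`.
#' @export
engine_metrics <- function(delta_w, delta_t, e_input, e_output) {
  if (any(delta_t <= 0)) abort("`delta_t` must be positive.")
  if (any(e_input <= 0)) abort("`e_input` must be positive.")
  if (any(delta_w == 0)) abort("`delta_w` must be nonzero for the COP.")
  tibble(power = delta_w / delta_t, efficiency = delta_w / e_input,
         cop = e_output / delta_w)
}

#' Classify a state transition as endo- or exothermic
#'
#' Switching from a fitter (lower-energy) state to a less fit
#' (higher-energy) one absorbs energy, like an endothermic reaction;
#' the reverse dissipates energy, like an exothermic one.
#'
#' @param eps_from,eps_to Finite node energies, vectorized.
#' @return Tibble: `eps_from`, `eps_to`, `delta_e`, `direction`
#'   (endothermic / exothermic / neutral).
#' @export
transition_classify <- function(eps_from, eps_to) {
  if (any(!is.finite(c(eps_from, eps_to)))) abort("Energies must be finite.")
  d <- eps_to - eps_from
  tibble(eps_from = eps_from, eps_to = eps_to, delta_e = d,
         direction = dplyr::case_when(d > 0 ~ "endothermic",
                                      d < 0 ~ "exothermic",
                                      TRUE ~ "neutral"))
}
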