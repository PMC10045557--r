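---
title: "A hybrid classical-quantum model of cognitive-emotional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid classical-quantum model of cognitive-emotional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofield)
```

`neurofield` simulates and analyzes a statistical-mechanics model of
cognitive-emotional brain networks. Nodes stand for cognitive-emotional
states; links stand for an agent's transitions between them. The package
covers the model end to end: fitness-driven network growth, occupation
statistics and condensation detection, plasticity rules, transition
kinetics with work-energy accounting, trajectory classification, and
potential-landscape / eigenmode geometry. This vignette explains the model,
the tunable parameters, the numerical choices, and what the synthetic test
surface does and does not establish.

## The growth model

Each node $i$ carries a fitness $\eta_i \ge 0$ and a fixed energy level

$$\varepsilon_i = -\tfrac{1}{\beta}\log \eta_i, \qquad \beta = 1/T,$$

where the "temperature" $T$ is a control parameter, not a physical
temperature. A new node joins the network at every step and connects to $m$
distinct existing nodes, chosen without replacement with probability

$$\Pi_i = \frac{\eta_i k_i}{\sum_\ell \eta_\ell k_\ell},$$

fitness-weighted preferential attachment. Node fitness can also be assigned
from decision-level quantities as $\eta = |p \cdot P|$ (selection
probability times perceived net payoff, `fitness_from_payoff()`).

**How $\beta$ enters the dynamics.** Written literally, $\Pi_i$ depends
only on the drawn fitness values, and the temperature would be decorative.
The model's whole point, however, is that temperature drives transitions
between a fit-get-rich phase and a Bose-Einstein condensate. The package
therefore uses the canonical fitness-model construction: the base draw
$\eta_0 \sim \rho(\eta)$ fixes the node's energy once,
$\varepsilon = -\log\eta_0$, and the *operative* fitness at inverse
temperature $\beta$ is $\eta = e^{-\beta\varepsilon} = \eta_0^{\beta}$. At
$\beta = 1$ this is exactly the literal reading; at large $\beta$ small
energy differences translate into large fitness ratios and the fittest node
can capture a finite share of all links. The stored pair always satisfies
$\varepsilon = -(1/\beta)\log\eta$, so the two formulations agree node by
node.

Other growth choices, made once:

* **Seed graph**: a complete graph on $m + 1$ nodes (birth time 1), which
  guarantees $m$ attachable targets from the first step.
* **No multi-edges, no self-loops**: the $m$ targets are sampled without
  replacement. Revisits of an existing pair are a no-op on the edge set,
  consistent with the degree law counting distinct links.
* **Zero-fitness nodes** may sit in a graph (they are never selected,
  $\Pi_i = 0$, and carry infinite energy); only the explicit conversion
  `fitness_to_energy()` treats $\eta = 0$ as an error.
* **$\Gamma$ vs $T$**: configurations accept either `beta` or the annealing
  parameter `gamma`, with $\beta = 1/\Gamma$, since the model treats
  $\Gamma$ as a drop-in substitute for temperature.

A node born at step $t_i$ accumulates links as
$k(t) = m\,(t/t_i)^{f(\varepsilon)}$ with dynamic exponent
$f(\varepsilon) = e^{-\beta(\varepsilon - \mu)}$. In the equal-fitness
limit the model reduces to classical preferential attachment: $f = 1/2$
and a degree-distribution tail exponent of 3, which the test suite
verifies on a 20-run ensemble of 3000-node networks (maximum-likelihood
tail fit above degree 10), and the degree law itself on a 50-replicate
ensemble of 600-node networks for a node born at step 30. Those sizes were
chosen as the smallest at which the asymptotic results are expected to
hold to the tested tolerances; for nodes born very early ($t_i \lesssim
10$) the continuum degree law is biased upward by more than 10% near
$t/t_i = 4$, so the test pins a mid-history node.

## Fitness distributions

`fitness_dist()` names the base draw $\rho(\eta)$: `uniform` on (0, 1],
`exponential(rate)`, `dirac(value)` (the equal-fitness limit), and
`truncated_power(exponent)` with density
$\rho(\eta) = (\theta + 1)(1 - \eta)^{\theta}$ on [0, 1). The last family
is the condensation-prone one: its energy density behaves as
$g(\varepsilon) \propto \varepsilon^{\theta}$ near the band bottom, so the
very fittest nodes are rare outliers and, at low temperature, the single
minimum-energy node can win a finite fraction of all link endpoints. A
family with mass *accumulating at* $\eta = 1$ (e.g. $\rho \propto
\eta^{\theta}$) cannot condense: its top fitness values are nearly
degenerate, and the winner is decided by birth order just as in the
equal-fitness model. This is why the package defines the truncated-power
family with density vanishing at the maximum.

Empirically (20-run ensembles of 1000-node networks, $\theta = 2$), the
condensate fraction — the minimum-energy node's share of all link
endpoints — rises monotonically with $\beta$ across
$\beta \in \{0.5, 4, 32\}$, and at small $\beta$ it decays with network
size as $O(1/N)$. At large $\beta$ the fraction stays an order-one
quantity but does *not* systematically increase with $N$ in finite
simulations: the minimum-energy node of a larger network is born at a
uniformly random time and must still overtake entrenched hubs, which takes
a time that grows with $N$ for any fixed, stationary energy distribution.
The tests therefore assert the $\beta$-trend and the small-$\beta$ decay,
the two behaviours the model actually produces.

## Occupation statistics, chemical potential, condensation

Link endpoints behave as non-interacting particles occupying node energy
levels. At the Bose-Einstein point $f(\varepsilon) = 1$ (i.e.
$\varepsilon = \mu$) the occupation number is
$n = 1/(e^{\beta(\varepsilon-\mu)} - 1)$; for $f \ll 1$ statistics become
Maxwell-Boltzmann, $n = e^{-\beta(\varepsilon-\mu)}$; for $f \gg 1$
Fermi-Dirac, $n = 1/(e^{\beta(\varepsilon-\mu)} + 1)$. The "much less/much
greater" thresholds are made operational as $f \le 0.1$ and $f \ge 10$,
with a $\pm 0.05$ band around 1 for the Bose-Einstein label; all three are
configurable, and the representative $f$ is the median over nodes.

`solve_chemical_potential()` finds $\mu$ so that occupations sum to the
network's total endpoint count $2E$. All three occupation sums are
strictly increasing in $\mu$, so a plain bracketed bisection is used (200
iterations, relative tolerance $10^{-10}$; the bracket extends downward in
steps of $50/\beta$ until it straddles the root). Under Bose-Einstein
statistics $\mu$ must stay below the band bottom; when even
$\mu \to \min\varepsilon$ leaves the excited levels short of the target —
their capacity being $\sum_{\varepsilon_i > \min\varepsilon}
1/(e^{\beta(\varepsilon_i - \min\varepsilon)} - 1)$ — the solver reports
condensation and assigns the excess occupation to the minimum-energy
level. The partition-style normalization reported alongside is
$\sum_i e^{-\beta(\varepsilon_i - \mu)}$; the model invokes the partition
function only as the normalizer behind the degree law, so no literal
microstate sum is computed.

The critical annealing parameter uses the standard condensation-temperature
relation $\Gamma_C = T_C k_B / (n/\zeta(3/2))^{2/3}$, with $\zeta(3/2)$
from `pracma::zeta` (accurate to well beyond 10 significant digits).
Because the model never defines the particle density $n$ for a growing
network, `critical_gamma()` takes it as an explicit argument;
`phase_report()` adopts the convention $T_C = 1/\beta$, $n = 2E/N$,
$k_B = 1$ (natural units throughout; SI values can be passed wherever a
constant appears).

## Plasticity rules

`hebbian_weights()` is the classical outer-product average
$w_{ij} = (1/p)\sum_a x_i^a x_j^a$ over $p$ training patterns. The
summation is over patterns (the standard Hebbian reading); the diagonal
$w_{ii}$ (mean squared activity) is retained by default and can be zeroed
by flag. `activation()` is the linear unit $\pm(\sum w_i x_i + b)$ with
the sign convention exposed as a polarity flag; `quantum_activation()` is
the state-overlap form $(w \cdot x + b)/(N+1)$, implemented as the printed
closed form rather than an amplitude-encoded state preparation, and its
$|z| \le 1$ overlap guarantee is stated only under the $\pm 1$ encoding
with $|b| \le 1$ — the normalization that would make it a true inner
product of unit states is otherwise unspecified.

`attachment_covariance()` computes the sample covariance of per-step
attachment probabilities for every node pair across the recorded growth
history: persistent positive covariance marks Hebbian-like strengthening
of the pair's coupling, negative covariance anti-Hebbian weakening, with a
$10^{-9}$ neutrality band for floating-point zeros.

## Transition kinetics and energetics

State switches are treated as chemical reactions: switching toward higher
$\varepsilon$ (lower fitness) absorbs energy (endothermic), toward lower
$\varepsilon$ dissipates it (exothermic). The classical rate is Arrhenius,
$k = A e^{-E_a/RT}$; the quantum (annealing) form is
$k = (k_B \Gamma / h) f(\varepsilon)$. `activation_energy()` inverts the
rate law as $E_a = -RT\ln(k/A)$ — in the quantum regime the rate is first
assembled from the annealing form and then inverted, with $T$ by default
and $\Gamma$ substituted on request, since the model prints both symbols
in that context. `arrhenius_linearity()` operationalizes the
classical/quantum diagnostic: regress $\ln k$ on $1/T$ and call the series
classical when $R^2 \ge 0.995$ (configurable). A temperature-independent
tunneling floor of at least a tenth of the prefactor, over a temperature
range that reaches low enough for the floor to dominate, reliably bends
the plot below that threshold.

The Landauer reset energy of a node state is
$\varepsilon = -(1/\beta)\ln(2\eta)$ under the default parse: the inserted
factor of 2 is what distinguishes the reset cost from the plain
fitness-energy map and yields the $\ln 2$ bit quantum at $\eta = 1$. The
alternative reading $-(1/\beta)\log_2\eta$ is available behind a flag; both
are documented because the printed expression is ambiguous.
`work_free_energy()` implements $W = \Delta H - T\Delta S$ (classical) and
$W = \Delta H - \Gamma\Delta S$ (hybrid), recording the chain
$W = \Delta E = \Delta E_{free}$ verbatim; work is computed per switch,
with aggregation over an episode left to the caller.
`engine_metrics()` reports $P = \Delta W/\Delta t$, $\Phi = W/E_{input}$
and $COP = E_{output}/W$.

## Trajectory dynamics: winding, coherence, Wolfram class

A 3-D state-space trajectory (uniformly sampled, at least 64 points) is
classified through two statistics.

**Winding numbers.** Each dimension's dominant frequency is the peak of a
full-length Hann periodogram, refined to sub-bin precision by quadratic
interpolation of log power. Cubic-spline pre-smoothing of the series is
available (`spline_smooth = TRUE`) but off by default: generalized
cross-validated smoothing measurably attenuates and displaces
high-frequency peaks (in development, the 2.618 Hz component of the
quasiperiodic fixture was detected at 2.43 Hz with smoothing on), and peak
detection on a clean periodogram needs no variance reduction. Ties break
toward the lower frequency. The ratio $W = f_X : f_Y : f_Z$, reduced by
its smallest member, is declared *rational* when some integer triple
$(a, b, c)$ with entries at most 32 reproduces the reduced ratios within
an absolute tolerance of $10^{-3}$. This simultaneous integer-triple
reading, rather than independent continued-fraction approximation of each
ratio, is deliberate: the golden-ratio pair $(\varphi, \varphi^2)$ is
approximated by $34/21$ to within $6\times10^{-4}$ *relative* error, so
any per-ratio test with denominators to 32 and a relative tolerance would
misclassify the canonical quasiperiodic frequencies as rational. Bounding
all three integers by 32 leaves the best admissible triple at 13:21:34 —
excluded — and the next at 13:21, which errs by $2.6\times10^{-3}$,
comfortably outside tolerance, while 2:3:5 is recovered exactly. Exact
rationality is undecidable on floats; both the bound and the tolerance are
configurable.

**Nonlinear coherence.** $K \in [0, 1]$ measures coupling strength among
the three dimensions: the geometric mean of the three pairwise
magnitude-squared coherences, Welch-averaged over Hann windows with 50%
overlap, evaluated on the shared dominant frequency band (the peak bin
$\pm 1$). Candidate bands are each dimension's spectral peak plus the
joint peak of the summed unit-power spectra; the band of strongest joint
coupling is reported. Segment length is $2^{\lfloor\log_2(N/16)\rfloor}$,
clamped to [64, 1024], which guarantees at least 8 segments (shorter
records are an error) and gives roughly 40 segments at $N = 10^4$. The
segment count matters for the estimator's floor: magnitude-squared
coherence of *independent* signals is biased upward by about the
reciprocal of the number of averaged segments, so averaging only 8
segments would leave a floor of ~0.125 — indistinguishable from weak
coupling — while ~40 segments put the floor near 0.03, clearly below the
0.25 chaos threshold. Identical signals give exactly $K = 1$ at any
segmentation. The un-normalized triple-product ratio
$|C_{XYZ}|/(|A_X||A_Y||A_Z|)$ is available as `estimator = "literal"`,
without the [0, 1] guarantee.

**Decision table.** Zero variance → fixed point; rational $W$ → periodic;
irrational $W$ with $K \le 0.25$ → quasiperiodic; irrational $W$ with
$K > 0.25$ → chaotic. The 0.25 bound is a named, configurable constant.
Wolfram classes map fixed-point → I, periodic → II, chaotic → III,
quasiperiodic → IV. `delay_embed()` provides the standard Takens
delay-coordinate matrix for building 3-D trajectories from scalar
observables.

## Topology and geometry

Graphs are treated as 1-complexes: $B_0$ is the component count, $B_1 =
E - V + B_0$ the cycle rank, and $\chi = B_0 - B_1 = V - E$. Higher Betti
numbers would require a filled-simplex (clique-complex) convention the
model never states, so they are out of scope; two networks are
"algebraically invariant" when their $\chi$ agree.

`landscape()` realizes the potential-surface picture: a planar layout
(supplied, or a seeded deterministic Fruchterman-Reingold embedding) with
$V(x, y)$ interpolated from the node energies. The kernel is a normalized
singular-Gaussian (Shepard-type) weight
$w_i(p) = e^{-d_i^2/(2h^2)}/d_i^2$: it is exact at every anchor
($V(\text{node}) = \varepsilon$ in the limit, returned exactly at
coincident points) and a convex combination of the $\varepsilon_i$
everywhere else, so the surface can never undershoot the band bottom. An
exact-solve Gaussian radial-basis interpolant was considered and rejected:
RBF coefficients routinely over- and undershoot the anchor range, which
breaks the requirement that the global minimum of the landscape sit at the
minimum-energy node. The default bandwidth is half the median
nearest-neighbor distance of the layout.

`geodesic_length()` evaluates discrete path lengths
$\sum \sqrt{\sum_{ij} g_{ij} dx_i dx_j}$ under a supplied metric —
identity, constant matrix, per-point array, or a function — with per-point
metrics averaged at segment midpoints (second-order accurate; the
quarter-circle test converges at that order). The model never ties
$g_{ij}$ to a network quantity, so the package accepts any
positive-definite field and makes no claim about which one is intended.
Only path-length evaluation is provided; solving geodesic equations is out
of scope.

`laplacian_eigenmodes()` solves the discrete Helmholtz problem
$\nabla^2 u = -k^2 u$ on the combinatorial graph Laplacian (or the 5-point
Laplacian of a regular planar grid, via lattice graphs). Eigenvalues are
returned ascending; the kernel dimension equals the number of connected
components, and on path graphs the $j$-th eigenvector has exactly $j - 1$
sign changes (the Sturm property, exercised in tests up to $n = 12$), the
discrete expression of "low spatial frequencies are globally uniform, high
ones locally discrete". Dense symmetric eigendecomposition is used, which
is exact and fast at the package's intended network sizes (up to a few
thousand nodes); cortical-surface meshes are explicitly out of scope.

## Synthetic fixtures: what they emulate, and what they do not

All test inputs are generated in code, deterministically under a seed:

* **Fitness samples** for each named family.
* **Trajectories**: constant (fixed point); sinusoids at 2, 3, 5 Hz
  (periodic, small-integer winding); sinusoids at 1, $\varphi$,
  $\varphi^2$ Hz (quasiperiodic, provably outside the rational tolerance);
  and the chaotic-coupled fixture — three *identical* Rössler oscillators
  in the funnel regime ($a = 0.28$, $b = 0.2$, $c = 5.7$, time scale 15)
  with all-to-all diffusive coupling of strength 2 in $x$, integrated by
  fixed-step RK4 from pinned initial conditions after an 80-time-unit
  transient, recording ($x_1$, $y_2$, $z_3$). The coupling is far above
  the synchronization threshold, so the three oscillators collapse onto a
  common chaotic orbit and the recorded columns are effectively the three
  coordinates of a single funnel Rössler system: mutually coherent
  (high $K$) yet with incommensurate dominant frequencies (irrational
  $W$), landing the fixture in the chaotic branch of the decision table.
  The funnel regime matters: symmetric attractors pair an even coordinate
  with odd ones, forcing near-zero cross-coherence, and were rejected for
  that reason. Optional observation noise at a chosen SNR is available for
  robustness tests (winding recovery is exercised at 20 dB).
* **Rate series** $k(T) = A e^{-E_a/RT} + \text{floor}$, the floor
  emulating a temperature-independent tunneling channel.
* **Toy graphs** (tree, cycle, star, two disjoint triangles, random) for
  the topology and eigenmode surface.

Passing tests on these fixtures establish that the implementation realizes
the model's stated limiting behaviours and invariants. They do not
establish anything about empirical brain networks: the fixtures contain no
measurement noise models beyond additive white noise, no non-stationarity,
no empirical degree correlations, and the growth model itself excludes
directed or weighted links, node deletion, and rewiring.

## Numerical choices, collected

* Chemical potential: bisection (monotone occupation sums), relative
  tolerance $10^{-10}$, bracket steps $50/\beta$.
* Welch coherence: Hann windows, 50% overlap, segment length
  $2^{\lfloor\log_2(N/16)\rfloor} \in [64, 1024]$, minimum 8 segments,
  band = peak bin $\pm 1$; results clamped to [0, 1].
* Dominant frequency: full-length Hann periodogram, quadratic log-power
  interpolation, ties to the lower frequency, spline pre-smoothing off by
  default.
* Rationality: simultaneous integer-triple approximation, entries
  $\le 32$, absolute tolerance $10^{-3}$.
* Phase thresholds: $f_{lo} = 0.1$, $\delta = 0.05$, $f_{hi} = 10$;
  chaos bound $K = 0.25$; Arrhenius linearity $R^2 = 0.995$. All
  configurable; defaults are order-of-magnitude readings of the model's
  asymptotic statements and its printed constants.
* Degenerate inputs: zero-fitness nodes carry $\Pi = 0$ and infinite
  energy; constant trajectory dimensions are rejected by the spectral
  operations and routed to the fixed-point class by the classifier;
  empty graphs and too-short series raise informative errors.
* Test problem sizes: growth ensembles of 20 × 3000 nodes (tail
  exponent), 50 × 600 (degree law), 3 × 20 × 1000 (condensation trend);
  trajectory fixtures of 1000–12000 samples. Chosen as the smallest sizes
  at which the asymptotics under test are expected to hold at the stated
  tolerances.

## Serialization

Networks round-trip through GraphML (attribute-rich, the canonical format
here) or a two-column edge-list CSV with a companion node-attribute CSV;
trajectories, rate series, degree histories, landscapes and eigenmodes
through plain CSV. Landscape grids are written as long-format CSV
(`x, y, v`), a deliberately dependency-free choice. Every file embeds a
provenance comment line (package version, seed, date), and a file carrying
only fitness or only energy has the other attribute derived on read at a
stated $\beta$. The `exec/neurofield` script exposes the `grow`, `phase`,
`kinetics`, `dynamics`, `landscape`, `eigenmodes` and `fixtures`
subcommands over these formats.

## Known limitations

* The growth model is undirected, unweighted, and additive-only; no
  deletion or rewiring.
* $B_i$ beyond $i = 1$, fundamental/Poincaré groups, torsion, knot
  invariants and Lyapunov exponents are not computed.
* The condensate-fraction size trend at large $\beta$ is flat in finite
  simulations (see above); only the $\beta$-trend and small-$\beta$ decay
  are asserted.
* $\Gamma_C$ is a formula evaluation; no mapping to an empirical
  observable is claimed.
* The coherence estimator's independence floor (~1/segments) means short
  records cannot certify $K \approx 0$; the package refuses records with
  fewer than 8 segments rather than report an inflated floor.
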