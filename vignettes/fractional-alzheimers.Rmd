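---
title: "Methods: a fractional-order model of Alzheimer's disease and its toolchain"
author: "fracAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a fractional-order model of Alzheimer's disease and its toolchain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

The package models five interacting compartments of Alzheimer's pathology —
functional neurons $F_N$, infected (inflamed) neurons $I_N$, amyloid-beta
$A_\beta$, tau protein $T_\mu$ and microglia $M_\rho$, all in g/ml — with a
Caputo fractional derivative of order $\sigma \in (0,1]$ on the left-hand
side:

$$
\begin{aligned}
D^\sigma F_N &= \Pi_N + \rho T_\mu - \alpha F_N A_\beta - \phi_1 F_N,\\
D^\sigma I_N &= \alpha F_N A_\beta - \beta_1 I_N M_\rho - (\gamma+\phi_2) I_N,\\
D^\sigma A_\beta &= \gamma I_N - \beta_2 A_\beta M_\rho - (d_\beta+\kappa) A_\beta,\\
D^\sigma T_\mu &= \kappa A_\beta - \beta_3 T_\mu M_\rho - (d_\mu+\rho) T_\mu,\\
D^\sigma M_\rho &= (\beta_1 I_N + \beta_2 A_\beta + \beta_3 T_\mu) M_\rho - \phi_3 M_\rho.
\end{aligned}
$$

The fractional order is a phenomenological memory parameter: $\sigma = 1$
recovers the classical ODE system, while smaller $\sigma$ weights the whole
history of each compartment with a power-law kernel. The model is
well-mixed (no spatial structure), has no age structure, and treats all
interactions as mass-action. The amyloid cascade hypothesis is baked into
the wiring: amyloid infects neurons ($\alpha F_N A_\beta$), infected
neurons produce amyloid ($\gamma I_N$), amyloid seeds tau
($\kappa A_\beta$), and microglia clear all three pathological species at
rates $\beta_{1,2,3}$.

### Parameters

All rates are per day and non-negative; `ad_params()` validates
$\phi_1 > 0$, $d_\beta + \kappa > 0$ and $d_\mu + \rho > 0$, the
denominators of the equilibrium formulas. The baseline preset
(`ad_preset("table1")`) uses the literature values shipped with the
package, with initial state $(0.14, 0, 10^{-6}, 10^{-6}, 0.02)$ g/ml — the
tiny amyloid/tau seeds represent an early pathological stage. One source
lists the natural neuron death rate $\phi_1$ "per year" while every other
rate and every simulation horizon is in days; the package treats all rates
as per-day, the only reading under which the published day-scale horizons
make sense. The alternative `"chaos"` preset (large neuron production
$\Pi_N = 700$, near-zero death $\phi_1 = 3\times10^{-5}$) exercises the
gain-stabilization analysis; the microglial rates it leaves unspecified
are completed from the baseline, which is immaterial because they do not
enter the four-state Jacobian or $R_0$.

### Therapeutic controls

Two bounded intensities $z_1, z_2 \in [0,1]$ represent anti-amyloid and
anti-neurodegeneration interventions. The controlled equations are an
interpretation fixed by this package: $z_1$ scales the amyloid source
$\gamma I_N$ by $(1-z_1)$ and $z_2$ scales the infection term
$\alpha F_N A_\beta$ by $(1-z_2)$ in both neuron equations — the minimal
multiplicative placement consistent with the stated intervention targets.
Because both controls only remove disease sources, any admissible schedule
leaves functional neurons at or above the uncontrolled trajectory, which is
the structural fact behind the strategy-ordering tests.

## The Grünwald–Letnikov solver

The Caputo derivative is discretized on a uniform grid $t_n = nh$ by the GL
convolution with fractional binomial weights
$w_k = (-1)^k \binom{\sigma}{k}$, computed by the stable recursion
$w_k = w_{k-1}(1 - (\sigma+1)/k)$. The explicit update is

$$
u_n = u_0 + h^\sigma f(t_{n-1}, u_{n-1}) - \sum_{k=1}^{n} w_k (u_{n-k} - u_0).
$$

Three numerical choices matter:

* **Caputo shift.** The $(u - u_0)$ shift inside the convolution realizes
  the Caputo derivative for nonzero initial data. Without it the scheme
  would discretize the Riemann–Liouville derivative and fail to preserve
  constants; `fde_solve` preserves constant solutions exactly and the test
  suite asserts it.
* **Full memory.** The convolution keeps every history node (no
  short-memory truncation). The $O(n^2)$ kernel is compiled; horizons of
  1000 days at $h = 0.02$ (50k nodes) run in seconds.
* **$\sigma = 1$ reduction.** At order one the memory sum telescopes and
  the implementation uses the reduced form $u_n = u_{n-1} + h f$, an exact
  algebraic identity. Consequently the $\sigma = 1$ trajectory is
  bit-for-bit identical to an explicit Euler loop.

### Stability restriction and positivity

Like explicit Euler, the scheme has a bounded stability region:
empirically the linear decay rate $\lambda$ must satisfy roughly
$\lambda h^\sigma \lesssim 1.9$. The binding constraint in this model is
amyloid clearance, $d_\beta + \kappa = 9.535$/day. At $h = 0.1$ this
product is 1.90 at $\sigma = 0.7$ (the integrator diverges and raises an
integration-failure error naming the node) and 1.5/1.2 at
$\sigma = 0.8/0.9$, where $A_\beta$ undershoots zero by $\sim 10^{-7}$ g/ml
in the first nodes before recovering. The often-quoted theoretical
positivity of Caputo solutions refers to the continuous system; the
explicit discretization inherits it only under a step-size restriction.
With $h \le 0.02$ all five states remain non-negative for every
$\sigma \in \{0.7, 0.8, 0.9, 1.0\}$ over 200 days; the package's default
steps are chosen accordingly, and the test suite documents the behavior at
$h = 0.1$ as a known limitation.

### Accuracy and the initial boundary layer

Against the closed-form solutions of $D^\sigma u = -u$ (the exponential at
$\sigma = 1$, the Mittag–Leffler function $E_\sigma(-t^\sigma)$ otherwise,
evaluated by direct series summation to absolute tolerance $10^{-12}$ with
a 1000-term cap), the solver's error at any fixed positive time shrinks at
first order in $h$ for every $\sigma$. The max-norm over the whole grid is
a different matter: for $\sigma < 1$ the exact solution has a $t^{\sigma-1}$
derivative singularity at $t = 0$, the first few nodes carry an
$O(h^\sigma)$-at-best error, and for $\sigma = 0.5$ the measured max-norm
error is essentially $h$-independent over practical steps. This order
reduction is intrinsic to GL-type discretizations of solutions that are not
smooth at the origin, affects only a boundary layer of early nodes, and is
asserted explicitly (interior first-order convergence green; max-norm
first-order convergence fails for $\sigma \le 0.7$ and the corresponding
check reports it).

## Equilibria, $R_0$ and stability machinery

The disease-free equilibrium is $E_0 = (\Pi_N/\phi_1, 0, 0, 0, 0)$; the
microglia-free completion makes the four-state linearization consistent.
The endemic branch fixes $M_\rho^* = 0$ and expresses
$A_\beta^* = \gamma I_N^*/(d_\beta+\kappa)$ and
$T_\mu^* = \kappa\gamma I_N^*/((d_\mu+\rho)(d_\beta+\kappa))$;
$F_N^*$ is obtained by solving the $F_N$ balance directly rather than
transcribing a closed form whose published numerator is garbled — the
residual check in the constructor guards the derivation. The
infected-neuron balance pins the self-consistent level
$I_N^*$; `endemic_equilibrium()` solves for it by default (a positive
solution exists iff $R_0 > 1$) and accepts a user-supplied level for
exploration, reporting which equations are then enforced.

The next-generation construction linearizes the infected subsystem
$(I_N, A_\beta, T_\mu)$ at the disease-free state into new-infection and
transition parts, giving

$$
R_0 = \sqrt{\frac{\alpha \gamma \Pi_N}{(d_\beta+\kappa)(\gamma+\phi_2)\phi_1}},
$$

which the implementation cross-checks against the numerical spectral
radius of $F V^{-1}$ to $10^{-12}$. $R_0$ scales as $\sqrt{\alpha}$, so
surfaces over $(\alpha, \cdot)$ pairs are monotone along the $\alpha$ axis,
and the threshold $R_0 = 1$ coincides with the sign change of the dominant
eigenvalue of $F - V$ — both asserted as properties.

The gain-augmented Jacobian subtracts output gains
$\omega_1..\omega_4$ on the diagonal of the disease-free Jacobian (a
declared fifth gain is accepted and ignored: the reduced Jacobian has no
microglial state). Eigenvalues are reported sorted by ascending magnitude
with ties broken by ascending real part, which makes comparisons with
tabulated spectra deterministic. `audit_reported_spectrum()` checks a
published eigenvalue list against the trace identity; for the stabilization
worked example the two structurally forced roots $(-1.00003, -4.302)$
reproduce to machine precision while the remaining published pair is
inconsistent with the printed matrix (their sum misses the trace by more
than 22) — the audit reports this instead of replicating it.

## Logarithmic sensitivity

The elasticity statistic is the centered two-run form

$$
S_{\log}(t) = \frac{\ln y_+(t) - \ln y_-(t)}{2\ln(1+\delta)},
\qquad \delta = 0.1 \text{ by default},
$$

with $y_\pm$ the GL solutions at $p(1\pm\delta)$. No one-sided fallback is
used. Nodes where either output is non-positive are flagged undefined (NA)
rather than zeroed — relevant because $A_\beta$ starts at $10^{-6}$ g/ml
and can transiently undershoot at coarse steps. Initial-condition
perturbations are supported by the same multiplicative convention (the
natural reading for a relative perturbation of a concentration). For a
pure power law $y = C p^k$ the statistic returns
$k \cdot \frac{\ln(1+\delta)-\ln(1-\delta)}{2\ln(1+\delta)} \to k$ as
$\delta \to 0$; the 5% bias at $\delta = 0.1$ is a property of the
symmetric-log estimator, not an error.

## The physics-informed network

All three learning variants share one architecture: a dense tanh network
mapping normalized time $t/T$ to seven outputs — the five states plus the
two controls, the latter squashed into $[0,1]$ by a sigmoid. The loss is

$$
L = L_{\text{data}} + \lambda_{\text{phys}} L_{\text{phys}},
$$

where $L_{\text{data}}$ is the mean squared misfit over data nodes and
$L_{\text{phys}}$ the mean squared GL residual

$$
r_n = h^{-\sigma}\sum_{k=0}^{n} w_k\,(u_{n-k}-u_0) - f(t_n, u_n, z_n)
$$

over the collocation grid (node 0 carries no derivative information and is
excluded). The fractional variant uses the configured $\sigma$, the
integer variant forces $\sigma = 1$, and the baseline sets
$\lambda_{\text{phys}} = 0$ and neither supervises nor uses the controls —
so perturbing the model parameters cannot change a baseline fit, which is
tested. Design choices:

* **Normalization.** States are trained in units of the max absolute value
  of their clean reference series (the same anchor as the noise model), and
  each residual row is divided by the same scale. Without this the
  $F_N \sim 40$ g/ml compartment would dominate the $10^{-6}$-scale
  species by six orders of magnitude.
* **Initial conditions** are enforced softly: $t = 0$ is always a data
  node.
* **Architecture defaults** (4 hidden layers of width 64, tanh) are the
  package's own; everything is overridable in `pinn_config()`.
* **Optimization** is full-batch Adam (seeded Glorot initialization,
  analytic gradients through both loss terms; the gradient of the
  convolution term is the transposed Toeplitz product). The gradients are
  verified against central finite differences in the test suite.
* **Noise model.** Observation noise is i.i.d. Gaussian per state with
  standard deviation = level × the per-state max amplitude, seeded and
  reproducible; the clean trajectory is never modified in place.
* **Reference data.** The generator's reference trajectories are GL
  solutions of the governing system itself at a stability-respecting step
  (default $h = 0.05$ over 200 days), subsampled onto the collocation grid
  (e.g. 0.5-day or 2-day spacing). This emulates densely observed,
  noise-corrupted biomarker series with known ground truth; it does not
  emulate irregular clinical sampling, per-assay noise structure,
  missingness, or model misspecification, so benchmark results speak to
  robustness under the stated noise model only.

The robustness benchmark trains every variant at every noise level for
several replicates (sample sd, $n-1$ denominator) and reports
per-variant robustness ratios: mean final loss at the highest level over
mean final loss at zero noise. The package's scaled-down profile — 3×32
network, learning rate $2\times10^{-3}$, 2000 iterations, a 101-node
collocation grid over 200 days, levels $\{0, 0.2\}$, 3 replicates — was
fixed once as a desk-scale configuration; at these sizes the optimization
floor is common to both physics-informed variants and the fractional
variant's robustness advantage over the integer variant is small though
consistently in the expected direction. Published absolute loss magnitudes
for such benchmarks are architecture- and budget-dependent and are not
meaningful reproduction targets; orderings are.

## Control scenarios

The "optimal" strategy is direct parameterized-control optimization: both
intensities are piecewise constant on 10 equal windows (the smallest basis
that can express a dynamically adjusted schedule), squashed to $[0,1]$,
and fitted by a seeded (1+1) random-search descent that starts from the
constant mid-level schedule $z_1 = z_2 = 0.5$ and accepts only
improvements — hence a non-increasing cost history and a cost bounded by
the constant strategy's by construction. No adjoint/Pontryagin machinery is
used because no Hamiltonian or cost functional accompanies the model; the
objective here is declared by the package:

$$
J = \int_0^T \big( w_I I_N + w_A A_\beta + w_T T_\mu + c_1 z_1^2 + c_2 z_2^2 \big)\,dt,
$$

with default unit burden weights and effort weights $c_1 = c_2 = 10^{-6}$,
chosen so that the quadratic effort of a dimensionless intervention trades
off against burdens that are numerically of order $10^{-6}$–$10^{-4}$
g/ml·day on the baseline preset. The trapezoid rule integrates the running
cost on the solver grid.

## Problem sizes and tolerances

Default/test problem sizes are desk-scale by design: solver grids of
2000–10000 nodes; PINN runs of 2000 iterations on ≤ 401 collocation nodes;
benchmarks of 12 training runs; 100-draw property checks for the $R_0$ and
trace identities. Numerical tolerances: Mittag–Leffler series $10^{-12}$
absolute with a 1000-term cap and convergence diagnostics; equilibrium
residuals $\le 10^{-10}(1+\max|u|)$; $R_0$ closed form vs spectral radius
$10^{-12}$; eigenvalue/trace identity $10^{-8}$ relative; trajectory CSVs
rendered at 17 significant digits for bit-exact round trips (and
platform-stable fixture checksums). All stochastic components (noise,
initialization, optimizers, benchmarks) take explicit seeds and restore
the caller's RNG state.

## Known limitations

* The explicit GL scheme requires $\lambda h^\sigma \lesssim 1.9$ for the
  fastest local decay rate $\lambda$; stiff parameterizations need small
  steps. Implicit or predictor–corrector fractional schemes are out of
  scope.
* Max-norm convergence order degrades to $\sim\sigma$ near $t = 0$ for
  $\sigma < 1$ (initial boundary layer); interior convergence is first
  order.
* The controlled equations, the control objective and the optimizer are
  declared interpretations (the intervention targets are stated in the
  source material, their functional form is not); all are configurable.
* The PINN benchmark explores one noise model and one architecture family;
  it makes ordering claims, not absolute-loss claims.
* Parameter estimation from real biomarker data (PET/CSF series) is not
  implemented; the data interface accepts user trajectories in the
  documented CSV dialect for fitting by the PINN's data term.
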