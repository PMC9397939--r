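---
title: "Seizure spread on Epileptor networks: model, stability method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure spread on Epileptor networks: model, stability method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epileptornet)
```

## The model

`epileptornet` simulates and analyses the spread of focal seizures on a
structural brain network in which every node is an Epileptor — a
phenomenological fast–slow neural-mass model that transitions spontaneously
in and out of seizure-like events. Per node $i$ the full model carries six
state variables,

$$
\begin{aligned}
\dot x_{1,i} &= y_{1,i} - f_1(x_{1,i}, x_{2,i}, z_i) - z_i + I_1,\\
\dot y_{1,i} &= \tfrac{1}{\tau_1}\,(1 - 5x_{1,i}^2 - y_{1,i}),\\
\dot z_i &= \tfrac{1}{\tau_0}\Big(4(x_{1,i} - x_{0,i}) - z_i
  - w \sum_j W_{ij}\,[x_{1,j}(t - \tau_{ij}) - x_{1,i}]\Big),\\
\dot x_{2,i} &= -y_{2,i} + x_{2,i} - x_{2,i}^3 + I_2 + 0.002\,g_i
  - 0.3\,(z_i - 3.5) + \xi_i(t),\\
\dot y_{2,i} &= \tfrac{1}{\tau_2}\,(-y_{2,i} + f_2(x_{2,i})) + \eta_i(t),\\
\dot g_i &= x_{1,i} - \gamma\, g_i,
\end{aligned}
$$

with piecewise nonlinearities $f_1 = x_1^3 - 3x_1^2$ for $x_1 < 0$ and
$f_1 = (x_2 - 0.6(z-4)^2)\,x_1$ for $x_1 \ge 0$, and $f_2 = 0$ for
$x_2 < -0.25$, $f_2 = 6(x_2 + 0.25)$ otherwise. Both are continuous at the
switch, and the switch points themselves take the $\ge$ branch. The low-pass
variable $g$ is the exponentially filtered history of $x_1$ integrated as an
ordinary differential equation, which makes the node a 6-dimensional system.
The constants are $I_1 = 3.1$, $I_2 = 0.45$, $\gamma = 0.01$,
$\tau_0 = 6667$, $\tau_1 = 1$, $\tau_2 = 10$, giving the characteristic
time-scale separation $\tau_0 \gg \tau_2 \gg \tau_1$ between the slow
permittivity variable $z$, the spike–wave subsystem and the fast
oscillations.

A two-variable reduction with one fast variable per node,
$\dot x_i = -x_i^3 - 2x_i^2 + 1 - z_i + I_1 + \xi_i$, and the same $z$
equation, is available everywhere (`model = "reduced"`); at a resting state
($x_1 < 0$) its fixed points coincide exactly with the $(x_1, z)$ components
of the full model's, which is why it reproduces the full model's phase
predictions so closely.

The coupling is diffusive and runs exclusively through the slow variable:
node $j$ perturbs node $i$'s ionic/metabolic balance in proportion to
$W_{ij}[x_{1,j}(t-\tau_{ij}) - x_{1,i}]$. It vanishes for identical states,
and can restrain as well as promote seizures — the source of the
`no_seizure` phase in which a strongly coupled surround suppresses seizure
initiation in the epileptogenic zone itself.

**Excitability.** The node parameter $x_0$ measures distance to the seizure
threshold. An isolated node with the constants above loses its stable
resting state at $x_0^c \approx -2.061$ (recomputed by
`critical_excitability_single()`); a node is epileptogenic when
$x_0 > x_0^c$. The epileptogenic-zone (EZ) node is activated at
$x_0 = -1.6$; surround nodes stay in the non-epileptic band
$[-2.3, -2.09]$.

## Seizure protocol and coarse-graining

One simulated seizure (`simulate_seizure_protocol()`) consists of

1. integration for `settle_steps` (default 20,000) steps of size
   $\Delta t = 0.05$ with all nodes at the surround excitability, started
   exactly at the single-node stable fixed point tiled across nodes;
2. activation: the selected EZ node's $x_0$ switches to $-1.6$;
3. up to `max_steps` (default 200,000) further steps. When a node's seizure
   terminates, the node is uncoupled from the network for the rest of the
   run (postictal refractory state) and, if it is the active EZ, its $x_0$
   reverts to the surround value. One seizure per run is analysed.

With the model time unit mapped to 0.02 s this corresponds to a 1000-Hz
sampling rate. Tract lengths (mm) convert to interaction delays via a
conduction speed of 60 mm per time unit (3000 mm/s), i.e. at most
$\approx 0.067$ s for the longest 200-mm fibers; delays are rounded to the
nearest integer step and served from a ring buffer whose history is
pre-filled with the initial state.

**Integration.** The stochastic system is interpreted in the Itô sense and
integrated with the predictor–corrector Heun scheme; the noise is additive
(state-independent), injected only into $\dot x_2$ and $\dot y_2$ (the $\dot
x$ equation of the reduced model) as i.i.d. Gaussian increments of variance
$\sigma^2 \Delta t$, so the scheme is unbiased for the Itô system. The same
increment is used in predictor and corrector. Deterministic runs draw no
random numbers, and equal seeds give bit-identical trajectories (the
integrator draws from R's RNG). The scheme's stationary variance on the
effectively linear $y_2$ equation (when the resting $x_2$ sits on the
$f_2 = 0$ branch) matches the Ornstein–Uhlenbeck value
$\sigma^2 \tau_2 / 2$, which the test suite verifies by simulation.

**Seizure detection.** A node counts as recruited when its $g$ variable —
much smoother than $x_1$ or $z$ — crosses an onset threshold upward after EZ
activation; its seizure terminates at the subsequent downward crossing of a
lower hysteresis threshold, which also triggers the postictal uncoupling.
No threshold value is canonical, so the package auto-calibrates per
parameter set from a deterministic isolated-EZ reference run: the onset
threshold is baseline $+ 0.5\times$(ictal plateau $-$ baseline). The
termination threshold sits at 90 % of the *rise* above baseline (i.e.
baseline $+0.45\times$ the span). Defining the hysteresis relative to
baseline matters because $g \approx x_1/\gamma$ is around $-150$ at rest:
scaling the threshold value itself by 0.9 would move it the wrong way.
Calibrated values are attached to every trajectory and can be overridden in
the protocol.

**Order parameter.** `extract_spread()` reduces a run to binary recruitment
states, onset/offset times, the spread size (recruited nodes, EZ included)
and a phase label: `no_seizure` (nothing seized), `no_spread` (only the
active EZ seized), `spread`.

## The two-Jacobian stability method

`classify_phase()` predicts the phase of a parameter setting without
simulation, from local linear stability of the deterministic network with
delays set to zero (interactions run through the slow variable, so delays do
not move equilibria or their stability).

Two linearizations are combined:

* **EZ included** ($6N \times 6N$): the network fixed point is tracked with
  $x_0 = -1.6$ at the active EZ and the homogeneous surround value
  elsewhere; $\lambda_R$ is the largest real part of the Jacobian's
  eigenvalues. $\lambda_R < 0$ means the coupled resting state is stable —
  the surround suppresses the EZ and *no seizure* occurs.
* **EZ replaced by its mean ictal drive** ($6(N-1) \times 6(N-1)$): the EZ
  node's rows and columns are deleted and its coupling terms are frozen at
  the constant $\bar x_{1,EZ}$, the time average of the EZ's $x_1$ over one
  isolated deterministic seizure (`ez_mean_drive()`; the isolated-node
  convention is adopted and configurable). The constant drive does not
  appear in the Jacobian but shifts the fixed point at which it is
  evaluated. $\tilde\lambda_R < 0$ means the surround withstands an ictal
  EZ: *no spread*.

The phase is `no_seizure` if $\lambda_R < 0$ (dominating whatever
$\tilde\lambda_R$ says), `no_spread` if $\lambda_R > 0 >
\tilde\lambda_R$, and `spread` if both exceed zero. Because the relevant
eigenvalues scale with $1/\tau_0$, the numeric zero threshold is tight
($10^{-9}$).

All Jacobian blocks are analytic and certified in the test suite against
central finite differences of the drift ($<10^{-6}$ max-abs on 3- and
10-node networks, both variants, both models). One printed-source subtlety:
differentiating the $\dot y_2$ equation gives $+f_2'(x_2)/\tau_2$ for the
$J_{y_2,x_2}$ block; the finite-difference oracle confirms the positive
sign, and the package derives every block from the equations rather than
from any transcribed table.

**Recruitment order.** When spread is predicted, the leading eigenvector of
the with-EZ Jacobian (unit 2-norm; complex modulus per component) indicates
the directions along which the instability grows. The magnitudes
$|v_{z,i}|$ of its permittivity components, EZ excluded, rank the surround:
larger magnitude, earlier predicted recruitment (`recruitment_ranks()`,
ties broken by ascending node index). On hub-like fixtures $\log |v_{z,i}|$
tracks $\log W_{i,EZ}$ approximately linearly, so the direct EZ coupling
weight is a cheap proxy for the predicted order.

### Numerical design of the fixed-point search

On the resting branch ($x_1 < 0$) the $(x_1, y_1, z, g)$ subsystem closes on
itself and the network fixed point reduces to a smooth $m$-dimensional
problem in $x_1$ plus a per-node piecewise-cubic solve for $(x_2, y_2)$
(solved by `polyroot` with branch-validity checks). The solver exploits
this: a damped Newton iteration on the $x_1$ system, then the slaved pair,
tracked by natural continuation in $w$ from the exact decoupled ($w = 0$)
solution in steps of at most 0.25, halving on failure. Convergence to a
different root family is rejected by a continuity guard (no O(1) state
component may jump by more than 0.25 between continuation steps; $g$ is
excluded since it scales as $x_1/\gamma$). A generic semismooth damped
Newton on the stacked system (with a few non-monotone full steps to cross
the $f_2$ switch plane, and `pracma::fsolve` as a last-resort polisher)
backs up the structured path. Fixed points are accepted at drift residual
$<10^{-9}$.

If the step underflows before reaching the target $w$, the tracked resting
equilibrium has ended in a fold: the corresponding resting state no longer
exists. `classify_phase()` treats a fold as maximal instability (the
eigenvalue is reported as $+\infty$): losing the surround's resting state
under the EZ drive *is* the onset of spread. This case arises in small
fixtures under strong constant drive.

**Fixed-point multiplicity.** Because the $(x_2, y_2)$ pair is slaved, an
isolated node's resting-branch equilibria share one $x_1$ and differ only in
the fast pair: three roots, exactly one stable at non-epileptic $x_0$. An
exhaustive search (`branch = "all"`) finds one further, strongly unstable
equilibrium on the ictal branch $x_1 \ge 0$; the default `"resting"`
convention seeds near the resting state, which is the convention under
which "three fixed points" is the right count and which the bisection for
$x_0^c$ relies on.

## Synthetic connectomes

Patient tractography matrices are not shipped; `synth_connectome()`
generates stand-ins with their invariants: symmetric, non-negative,
zero-diagonal weights, truncated at the 95th percentile (computed over all
$n^2$ entries including the zero diagonal, linear-interpolation convention)
and normalized to $[0,1]$; tract lengths are Euclidean distances of random
positions in a 150-mm box, capped at 200 mm, so delay structure correlates
with topology as in real tractography. Raw weights are log-normal
(`meanlog = 0`, `sdlog = 1` by default), emulating the right-skew of
streamline counts.

Two kinds of synthetic study nets are used in the tests:

* a *sparse heavy-tailed* net (density 0.3–0.5, `sdlog = 1`) exercising
  structure-sensitive behaviour — graded recruitment, hub effects,
  staircase-like partial spreads;
* a *dense, weight-homogeneous* net (density 1, `sdlog = 0.25`) for the
  phase-diagram study. A 10-node sparse graph is a poor stand-in for an
  84-area connectome, where every area couples to dozens of others and
  spread is a collective, near all-or-none event; compressing that into ten
  nodes requires full density and moderate weight dispersion, otherwise a
  single strong edge dominates and the transition breaks into per-edge
  steps rather than the collective one whose near-critical bimodality the
  pipeline quantifies.

Deterministic fixtures (`synth_fixtures()`): `two_node` (the minimal
spread problem), `chain` (propagation order along a path), `star_hub` (EZ
hub with strictly decreasing leaf weights — the canonical rank-prediction
fixture, since the predicted recruitment order is the weight order).

What passing tests on these fixtures do *not* show: fidelity to any real
patient's connectome statistics, parcellation effects, asymmetric or
directed connectivity, and network sizes beyond tens of nodes.

## Phase diagrams and near-criticality

`sweep_phase_diagram()` runs the protocol over an $(x_0, w)$ grid
(realization seeds = `base_seed` + counter, all recorded for exact replay)
and labels each cell from its realizations. Fluctuating cells — non-zero
spread-size standard deviation across realizations — concentrate in a
narrow band along the no-spread/spread transition; `near_criticality_stats()`
pools their outcomes and reports the fraction of mass in the two extreme
bins (width `k_small`, default 10 % of $n$ rounded up). Two conventions
coexist for the spread size: the order parameter counts recruited nodes
*including* the active EZ (that is what phase labels and diagram colours
use), while the near-criticality histogram counts recruited *surrounding*
nodes, EZ excluded — so "no spread" contributes 0, and "EZ plus its
strongest neighbour" contributes 1, inside the small-spread mode. Away from
the fluctuation band the dynamics are effectively deterministic at these
noise levels.

The test suite's phase-diagram study uses a 10-node dense homogeneous net, a
10-value $x_0$ grid spanning the non-epileptic band and a 10-value $w$ grid
chosen to straddle the *predicted* transition curve (seven values along the
`classify_phase` boundary, three spanning the deep-spread and
surround-suppression regimes), 10 stochastic realizations per cell at
$\sigma = 0.05$ with the default run lengths (20,000 settle + 200,000
post-activation steps). Concordance between predicted and empirical labels
is assessed outside the fluctuation mask; the stability method is expected
to overestimate the spread region slightly near the boundary, which the
80 % concordance bar absorbs.

## Known limitations

* The seizure-detection thresholds are calibration choices, not model
  constants; pathological parameter sets (e.g. a non-epileptic EZ) have no
  reference seizure and require explicit thresholds.
* The fold convention (resting state lost $\Rightarrow$ maximally unstable)
  conflates "no equilibrium" with "unstable equilibrium"; both imply
  departure from rest, but the eigenvector-based rank prediction is
  unavailable in the fold case.
* Recruitment ranks compare against first onsets only; re-entrant or
  secondary seizures after postictal uncoupling are out of scope (one
  seizure per run).
* Near the phase boundary, empirical labels at 10–30 realizations are
  themselves stochastic; rare-event cells can be mislabelled, which is why
  concordance is only evaluated outside the fluctuation mask.
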