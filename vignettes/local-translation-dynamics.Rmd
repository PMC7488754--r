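---
title: "Dynamical regimes of FMRP-dependent local translation with receptor recycling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical regimes of FMRP-dependent local translation with receptor recycling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptodyn)
```

## The model

At an activated glutamatergic synapse, the density of active receptors on
the postsynaptic membrane is maintained by two routes: de novo synthesis of
receptor proteins under the control of FMRP (the dendritic mRNA-binding
translational repressor), and the return of internalized receptors from the
recycling endosome. `synaptodyn` implements the three-pool delay model of
this circuit:

$$
\begin{aligned}
\frac{dx}{dt} &= f_x\!\big(y(t-\tau_e)\big) + k_{rz}\, z(t-\tau_r)
                 - (k_{rx}+k_{dx})\, x,\\
\frac{dy}{dt} &= f_a\!\big(x(t-\tau_a)\big)\,(y_0-y)
                 - f_b\!\big(x(t-\tau_b)\big)\, y,\\
\frac{dz}{dt} &= k_{rx}\, x - (k_{rz}+k_{dz})\, z,
\end{aligned}
\qquad
f_\delta(u) = k_{\delta,0} + k_\delta\,
  \frac{(u/K_\delta)^{h_\delta}}{1+(u/K_\delta)^{h_\delta}},
$$

where $x$ is the pool of active membrane receptors (mGluR), $y$ the pool of
active (dephosphorylated) FMRP bounded by the capacity $y_0$, and $z$ the
endosomal pool. The generalized Hill controls $f_a$, $f_b$, $f_x$ describe
translation activation (direct dephosphorylation by PP2A, hence $h_a = 1$
by default), suppression through the multi-step mTOR/S6K phosphorylation
cascade (steep: $h_b$ of order 5–20), and the synthesis/incorporation of
new receptors ($h_x$ between 1 and 3). Four delays carry the circuit's
characteristic times, in minutes: signal-to-dephosphorylation $\tau_a$
(about 1), signal-to-phosphorylation via mTOR $\tau_b$ (1–5), translation
elongation plus membrane incorporation $\tau_e$ (3–20), and endosomal
residence $\tau_r$ (3–15).

Because activation and suppression act with different lags and opposite
signs, the circuit is a delayed mixed-feedback oscillator: depending on the
parameters it settles to an equilibrium (possibly the origin), a limit
cycle, a torus-like quasi-periodic motion, or a chaotic attractor. The
package's purpose is to map these regimes.

`model_params()` returns the reference parameter set used throughout
(`k_a0 = 0, k_a = 1, K_a = 1, h_a = 1, y0 = 1, k_b0 = 1, k_b = 200,
K_b = 3, h_b = 15, h_x = 3, k_x = 40, k_dx = 0.1, k_rx = 0.9, k_dz = 0.8,
k_rz = 0.2`), and `delay_params()` the reference delays
(`tau_a = 1, tau_b = 1, tau_r = 10, tau_e = 15`); the regime studies
mostly override the delays to `(1, 2, 3, 3–5)`. Two synthesis constants are
not experimentally constrained and are package choices: the constitutive
synthesis rate `k_x0 = 0` (so that the origin is an exact equilibrium,
matching the observed collapse to a zero state under strong suppression)
and the synthesis half-saturation `K_x = 1`, which puts the Hill argument
$y/K_x$ on the FMRP-capacity scale ($K_x = y_0$). Regime boundaries along
$k_{rz}$ shift by a few hundredths when `K_x` moves within a factor of two,
and the oscillatory regime of the low-nonlinearity parameter corner
disappears entirely for `K_x` of 2 or more; this sensitivity should be kept
in mind when comparing absolute threshold values across studies
(see "Limitations").

In the recycling scans the endosomal outflow is held fixed by the coupling
$k_{dz} = 1 - k_{rz}$ (`with_recycling()`), so $k_{rz}$ moves the *share*
of outflow that is recycled rather than the total rate; `k_rz = 0` is no
recycling, `k_rz = 1` full recycling.

## Integrating the delayed Cauchy problem

A delay system needs the state on a whole pre-interval. All studies here
use constant initial functions; the reference history is
$x \equiv 2.5,\; y \equiv 0.5,\; z \equiv 5$ (`standard_history()`).

`integrate_dde()` advances the system with a fixed-step classical
Runge–Kutta scheme of order 4. Lagged values are read from the stored
solution record by local cubic (4-point Lagrange) interpolation, and from
the constant history before $t = 0$; a zero delay falls back to the current
stage state, so the delay-free limit is plain RK4 on the reduced ODE. The
default step is $h = \min(0.01, \tau_{\min}/20)$ minutes and the default
span `t_end = 4000` minutes; both are settings, not constants. Two
numerical points matter:

* **Stability, not accuracy, binds the step.** The suppression control can
  reach rates of order $k_{b0}+k_b \approx 200$/min, so the fastest local
  relaxation time is about 0.005 min; an explicit scheme needs
  $h \lesssim 2.8/200 \approx 0.014$. The default $h = 0.01$ sits inside
  the stability region with margin; $h = 0.02$ visibly diverges on the
  reference set, which the integrator reports as a non-finite state rather
  than silently returning garbage.
* **Derivative kinks from the constant history.** A constant initial
  function joins the solution with a jump in the first derivative at
  $t = 0$, which propagates (with increasing smoothness) at delay
  multiples. The integrator does not track these breakpoints explicitly;
  with the small fixed step the observed convergence order on delayed
  problems is between 3 and 4, while on smooth (delay-free) problems the
  scheme shows its clean fourth order. All regime diagnostics used here are
  statistical properties of long windows, not pointwise values, and are
  step-robust (halving $h$ does not change any reported label).

The integrator refuses to continue when the state leaves the nonnegative
orthant beyond a tolerance and names the violation time; with admissible
parameters the orthant and the FMRP capacity bound $y \le y_0$ are
invariant, which the test suite checks as a property.

`integrate_twin()` runs the same problem twice with the initial `x` shifted
by $\varepsilon$ ($10^{-6}$ by default), for the sensitivity criterion
below.

## Classifying a long-term regime

`classify_setting()` combines two diagnostics, applied to the second half
of the integration span (the first half is discarded as transient):

1. **Poincaré crossing structure.** The trajectory's crossings of a plane
   (default $x = 2$, increasing direction) are located by sign change and
   linear refinement; the crossing ordinates ($y$ at crossing) are
   clustered in one dimension with an absolute gap tolerance of $10^{-2}$.
   A cycle yields a stable, finite cluster count revisited in a fixed
   cyclic order (the count is the reported multiplicity); growing or
   unordered cluster structure indicates quasi-periodic or chaotic motion.
   When an attractor never reaches the chosen plane, a fallback section
   through the middle of the observed $x$-range is used and flagged.
2. **Sensitivity to initial data.** When the crossing structure is
   aperiodic, the twin-trajectory divergence decides: the motion counts as
   sensitive when $\max |x_1 - x_2|$ over the post-transient window reaches
   10% of the peak-to-peak amplitude — an order-of-magnitude criterion, as
   chaotic divergence saturates at the attractor diameter while
   quasi-periodic phase drift stays small. Sensitive aperiodic motion is
   labeled `CHAOTIC`, insensitive `QUASIPERIODIC`.

Solutions whose post-transient $x$-amplitude falls below $10^{-4}$ are
`STATIONARY`, and additionally `ZERO` when the final state's max-norm is
below $10^{-6}$ (the zero label is cross-checked against the equilibrium
solver `find_equilibria()`, which reduces the fixed-point system to a
scalar residual in $x^*$ — delays drop out at equilibrium). Anything the
criteria cannot decide — too few crossings, or a missing sensitivity
verdict — is reported `UNRESOLVED`, never guessed. Near a regime boundary
a slowly decaying oscillation can legitimately come out `UNRESOLVED` at a
short span and `STATIONARY` at the full default span; threshold work should
use `t_end = 4000` or more.

## Censuses, scans, tables

The model is multistable in large parts of its parameter space, so a single
trajectory understates the dynamics. `attractor_census()` integrates from
the standard history plus `n_starts - 1` constant histories drawn uniformly
from a start box (default $x \in [0,5]$, $y \in [0,1]$, $z \in [0,10]$,
seed 0), classifies each, and merges signatures that describe the same
attractor (periodic ones by their crossing-ordinate clusters, stationary
ones by their fixed point, irregular ones by the extent and mean of their
crossing band). The default census size is 12; the census outcome is
seed-invariant on the reference settings at sizes of 20 and up.

A uniform census resolves basins down to a few percent of the start box and
no further. Two known consequences, verified by direct integration: under
strong suppression with full recycling ($K_a = 3$, $h_b = 20$,
$k_{rz} = 1$) a second small cycle coexists with the main one, reachable
from a thin shell of histories near $z \approx 2$ (e.g.
`c(4.5, 0.05, 1.8)`) that a 12–20 start census virtually never samples;
and on the $\tau_e$ axis at 25% recycling the simple-cycle branch's basin
shrinks below census resolution around $\tau_e \approx 4.3$ although the
cycle itself persists to about 4.5. Census-based attractor counts are
therefore lower bounds, exact only when basins are generous.

`scan_parameter()` runs a census per grid value of any model or delay
parameter (applying the $k_{dz} = 1-k_{rz}$ coupling when requested),
records every crossing ordinate per attractor, and threads branch
identities across adjacent grid values by nearest-signature matching.
`locate_transition()` takes such a diagram, finds the bracketing grid
interval of a regime change and refines it by bisection with fresh
censuses; the refined threshold always lies inside the reported bracket.
`regime_table()` renders censuses over an $(h_b, k_x) \times (K_a, k_rz)$
grid in the compact symbol alphabet `S` (stationary), `0` (zero), `P`,
`2P`, … (that many coexisting cycles), `QP`, `C`, `P+C`; `UNRESOLVED`
cells stay marked rather than being coerced.

## Reference regimes

Three settings anchor the qualitative picture (all with delays
$(1, 2, 3, \tau_e)$ and the coupling $k_{dz} = 1 - k_{rz}$):

* $k_{rz} = 0.25$, $\tau_e = 5$: sustained irregular oscillation; the twin
  divergence grows from $10^{-6}$ to the attractor scale — chaotic.
* $k_{rz} = 1$, $\tau_e = 5$: a single limit cycle (the census finds one
  attractor from every start).
* Minimum varying-parameter corner ($h_x = 1, h_b = 5, k_x = 10,
  k_b = 100, K_a = 1$), $\tau_e = 3$: periodic at low $k_{rz}$, stationary
  at high $k_{rz}$; the maximum corner ($h_x = 3, h_b = 15, k_x = 40,
  k_b = 200, K_a = 3$) inverts this, with *zero* stationary states at low
  recycling giving way to cycles at high recycling.

Increasing the recycling share thus simplifies the dynamics at low
synthesis nonlinearity but is the only route to sustained oscillation under
strong suppression — the regime tables produced by `regime_table()` show
both patterns cell by cell.

## Problem sizes and reproducibility

The shipped analyses use deliberately desk-scale sizes: single trajectories
at $h = 0.01$, `t_end = 4000`; threshold scans on $k_{rz}$ grids of step
0.01 with one (standard-history) start per point; the $\tau_e$ scan on a
0.02 grid with 12-start censuses; table spot-checks at `t_end = 2000` with
6–12 starts. `scripts/acceptance.R` re-runs the threshold scans, the zero
state and the $\tau_e$ branch extent from scratch and writes the resulting
numbers as JSON; every run is reproducible from its seed, and
`run_experiment()` bundles any configuration with a manifest naming every
resolved parameter.

## Limitations

* `K_x` and `k_x0` are not constrained by data; the defaults are a scale
  choice. Absolute positions of regime boundaries along $k_{rz}$ (and the
  zero-vs-stationary character of individual table cells) move with them,
  while the qualitative structure — which parameters simplify the dynamics
  and which complicate it — is robust.
* Census-based multiplicity is a lower bound (small basins escape uniform
  sampling; see above).
* The integrator is explicit and fixed-step: parameter sets far outside
  the studied ranges (rates of order $10^3$/min and up) would need a
  smaller step or a stiff method, which is out of scope.
* Chaos labels rest on the sensitivity-plus-Poincaré criteria, not on
  Lyapunov spectra or rigorous enclosures; they are stable under step
  halving and span doubling on every labeled setting in the test suite.
* Constant initial histories only; the recorded-trajectory interpolation
  contract would support piecewise histories, but no study here needs them.
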