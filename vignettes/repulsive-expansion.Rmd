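---
title: "Repulsive expansion: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repulsive expansion: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyflow)
```

## The model and its assumptions

`colonyflow` treats a growing colony as a radially symmetric, close-packed,
z-homogeneous disc. Cell division in the interior pushes outer material
outward; because the packing is incompressible, the radial velocity at
radius $x$ is fully determined by the division activity inside it:

$$u(x,t) = \frac{v}{x}\int_0^x s\,\sigma(s,t)\,ds,$$

with $\sigma(x,t) = \sigma_0\,\frac{n}{n+n^*}\,
\frac{K_\sigma^{n_\sigma}}{K_\sigma^{n_\sigma}+(R-x)^{n_\sigma}}$ the local
division rate. The assumptions this encodes:

* **Uniform nutrient.** The nutrient diffusion length exceeds the colony
  size, so $n(t)$ is a single pool shared by all cells. Consequently the
  quantity $n + \frac{\tilde\sigma_n}{2v}R^2$ is exactly conserved, and the
  final colony radius is set by the nutrient budget, not by the initial
  radius.
* **Edge-biased division.** Division decays with distance from the edge
  over a length $K_\sigma$ with sharpness $n_\sigma$ (nutrient and oxygen
  access at the rim).
* **Lagrangian decoupling.** A tracked radius obeys an ODE that involves
  only its own position and $(R, n)$, so marker trajectories are
  independent of the rest of the ensemble — discretization refinement
  changes resolution, never the answer.

All quantities are dimensionless model units: lengths relative to a unit
habitat radius, times relative to $1/\sigma_0$ of the fast regimes; $v$ and
$\tilde\sigma_n$ are lumped constants absorbing per-cell volume, packing
density and colony height.

The patterning layer runs a synthetic gene circuit along every trajectory:
self-activating T7 RNAP ($T$), a global well-mixed quorum signal AHL ($A$),
AHL-induced lysozyme ($L$), and a T7–lysozyme complex ($P$) that sequesters
T7 and represses its transcription. Synthesis is scaled by the
gene-expression capacity $\phi(d) = K_\phi^{n_\phi}/(K_\phi^{n_\phi} +
d^{n_\phi})$ (maximal at the edge) and taxed back onto growth as metabolic
burden $\beta = 1/(1+(b(T+L))^{h_b})$. Growth dilutes every intracellular
species at the local volumetric rate $\lambda = v\,\sigma\,\beta$, the
dilution a close-packed incompressible colony imposes.

Two rate-law choices are this package's own:

* **Nutrient gating of synthesis.** All synthesis terms (T7, lysozyme,
  AHL) carry the same saturation factor $n/(n+n^*)$ as division. Without
  it, edge cells at the stalled late-time front would keep synthesizing at
  full capacity with near-zero dilution, so the "pattern at nutrient
  exhaustion" would depend on the exhaustion floor rather than freeze.
* **Habitat-area nutrient scaling.** In coupled runs the nutrient is the
  concentration in a well-mixed habitat disc of radius $R_{domain}$:
  consumption is $\tilde\sigma_n/R_{domain}^2$ times the division integral,
  and AHL synthesis is diluted over the same area. Larger habitats hold
  proportionally more nutrient and sustain proportionally larger colonies —
  this, together with threshold-triggered lysozyme deposition, is what
  makes ring width and colony radius scale with habitat size. Growth-only
  runs use the lumped $\tilde\sigma_n$ directly.

## Parameters and regimes

The growth defaults ($\sigma_0 = 1$, $n^* = 0.5$, $v = 1$) set the time and
concentration scales. The packaged regimes encode the patterning
phenomenologies the model is known for:

| preset | capacity | burden | growth | A(0) | outcome |
|---|---|---|---|---|---|
| `fig3_high_burden_sharp` | $K_\phi=0.06$, $n_\phi=6$ (sharp) | $b=0.1$ | $K_\sigma=0.15$, $n_\sigma=6$ | 0 | single ring |
| `fig3c_ahl03` | same | same | same | 0.3 | earlier ring onset |
| `fig3d_ahl08` | same | same | same | 0.8 | double ring |
| `fig3_domain2x` | same | same | same, $R_{domain}=2$ | 0 | ring in a 2x colony |
| `fig4_low_burden` | $K_\phi=0.1$, $n_\phi=2$ (gradual) | $b=0$ | $K_\sigma=0.1$, $n_\sigma=2$ | 0.3 | core–ring, core first |
| `fig4F_low_division` | $K_\phi=0.1$, $n_\phi=2$ | $b=0.1$ | same + $\sigma_0=0.4$ | 0 | ring before core |

The shared circuit constants ($\alpha_T=8$, $K_T=0.1$, $h_T=2$, $K_P=0.5$,
$\alpha_L=6$, $K_A=0.3$, $h_A=10$, $k_{on}=3$, $k_{off}=1$, $d_T=0.5$,
$d_L=0.05$, $d_P=0.3$, $\alpha_A=2$, $d_A=0.2$) are the package's
calibration, chosen once so that the mechanisms behind each regime operate
cleanly, and then frozen:

* T7 autoactivation must escape from the seed $T(0)=0.1$ even under an
  early lysozyme assault (small $K_T$, moderate binding), or a high initial
  AHL kills the circuit and no second ring can form.
* The AHL switch must be sharp ($h_A = 10$) and synthesis strong enough
  that $A$ crosses $K_A$ decisively; a shallow switch lets the
  lysozyme–T7 negative feedback clamp $A$ just below threshold
  indefinitely.
* Lysozyme must decay slowly ($d_L = 0.05$) so rings laid down mid-run
  survive to nutrient exhaustion; the troughs between features are carved
  by growth dilution and by T7 binding, not by decay.
* In the slow-division regime the central core exists because T7
  autoactivation is bistable: deep-interior cells fall below the escape
  threshold and lose T7 entirely, so lysozyme accumulates there unbound,
  while mid-colony cells retain T7 and keep sequestering it.

Two caveats from this calibration are worth stating plainly. First, with an
initial AHL of 0.3 the lysozyme onset happens earlier and the interior
lysozyme tail reaches deeper, but the final ring *peak* shifts only
marginally (and slightly outward, not inward): the peak position is
dominated by the deposition window the base case shares. Second, the
low-division regime is realized with a reduced $\sigma_0$ on top of the
shallow division profile, and it keeps the gradual capacity of the
core–ring analysis — with the sharp edge-confined capacity a central core
can never form, because no synthesis reaches the interior at all.

## Numerics

* **Growth-only runs** integrate with `deSolve::lsodar` at
  rtol = 1e-10/atol = 1e-12 and evaluate the division integral by adaptive
  quadrature (`stats::integrate`, rel. tol 1e-9) segment-wise over the
  sorted markers, re-evaluated at every right-hand-side call. This keeps
  the conservation drift near machine precision.
* **Coupled runs** default to rtol = atol = 1e-8. The division integral
  now contains the burden profile, known only at marker positions
  (piecewise-linear in between), so the right-hand side uses a composite
  trapezoid rule on a dense grid whose nodes include every marker
  (`n_quad = 201` plus markers). Agreement with the adaptive path in the
  burden-free limit is at the 1e-4 relative level, which bounds the
  quadrature error of patterning runs.
* **Nutrient floor.** Integration stops at the event $n \le 10^{-4}
  n(0)$ — "nutrient exhaustion", the pattern read-out time. The floor
  avoids chasing an asymptotically decaying tail, and the nutrient gating
  of synthesis makes the read-out insensitive to its exact value.
* **Marker spawning.** New markers are inserted whenever the widest
  relative coverage gap (between adjacent markers, or between the
  outermost marker and the front) exceeds 2% of the colony radius: at
  $R(1-10^{-3})$ if the front gap is widest, else at the midpoint of the
  widest interior gap, with circuit state linearly interpolated. A
  front-only trigger fails in the high-burden regime, where burden slows
  the edge and coverage holes open in the interior instead. Spawning
  changes existing trajectories only through the quadrature node set
  (≤ 5e-4 relative).
* **A marker at $r = 0$** has $\dot r = 0$ by the analytic limit (the
  integral vanishes like $r^2$).
* **Ring/core detection** operationalizes visual scoring: features are
  local maxima with topographic prominence at least 10% of the profile
  maximum and height above 1% of the global species maximum; widths are
  full width at half prominence (robust on the elevated baselines of
  core–ring profiles); a feature whose half-prominence support reaches the
  colony center is a core, not a ring. Emergence ordering scores
  kymograph rows only once $R(t)$ exceeds 20% of its final value — in a
  newborn colony a few cells wide, "ring" and "core" are not yet
  meaningful.
* **The Eulerian reference** is a deliberately simple first-order upwind
  finite-volume scheme in conservative radial form (dilution enters as the
  flux divergence), explicit Euler with CFL 0.5 and a reaction-limited
  step cap. It converges first order to the Lagrangian solution in the
  interior; comparisons exclude a 5% front margin, where the cut cell at
  the moving boundary carries a local error of finite physical width.
* **Moderate sub-range.** Scale-invariance fits use the central 60% of
  the swept habitat radii by default; the extremes (nutrient excess,
  confinement) are excluded from the linear regime.

## What the simulations do and do not show

All runs are self-contained simulations of the model itself; there is no
external data. Passing tests demonstrate internal consistency (conservation,
discretization independence, solver-vs-solver agreement) and that the
calibrated regimes reproduce the qualitative patterning phenomenology —
they do not validate the model against experimental colonies. Known
limitations: AHL has no spatial gradient (well-mixed by assumption), there
is no cell-level stochasticity or lineage structure, the circuit rate laws
are a minimal realization of the stated regulatory logic, and wall-clock
performance claims are out of scope. Typical problem sizes used throughout
the tests: 10–130 markers, output grids of ~160–200 points, Eulerian grids
of 100–400 cells — each coupled run takes a few seconds on one CPU.
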