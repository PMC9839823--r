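---
title: "Reaction-diffusion patterning on concentration-dependent evolving domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-diffusion patterning on concentration-dependent evolving domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdgrow)
```

## The model

`rdgrow` simulates $m \in \{1,2\}$ morphogen concentrations
$\boldsymbol{u}$ on a compact evolving domain $\Omega(t)$ whose growth and
contraction are driven by the concentrations themselves. In a Lagrangian
frame attached to the tissue, conservation of mass gives

$$\frac{\partial \boldsymbol u}{\partial t}
  = \boldsymbol D \nabla^2_{\Omega(t)} \boldsymbol u
  - \boldsymbol u \,(\nabla \cdot \boldsymbol a)
  + \boldsymbol f(\boldsymbol u),$$

where $\boldsymbol a$ is the material flow and $-\boldsymbol u
(\nabla\cdot\boldsymbol a)$ is the dilution (or concentration, under
shrinkage) caused by local volume change. The closure is a *local
isotropic dilation law*: the volume-form coefficient
$\mu = \sqrt{|\det G|}$ of the Lagrangian metric evolves as

$$\frac{\partial}{\partial t} \log \mu = S(t, \boldsymbol u),$$

with $\mu(0,\cdot) = 1$. The dilation rate $S$ (units: inverse time) is
the single modelling knob coupling chemistry to geometry; built-in forms
are listed under `?growth_law`.

**One dimension.** On $X \in [0, L]$ the system closes completely:

$$\frac{\partial \boldsymbol u}{\partial t}
   = \frac{\boldsymbol D}{\mu}\frac{\partial}{\partial X}
     \Bigl(\frac{1}{\mu}\frac{\partial \boldsymbol u}{\partial X}\Bigr)
   - \boldsymbol u\, S + \boldsymbol f(\boldsymbol u),
 \qquad
 \frac{\partial}{\partial t}\log\mu = S,$$

with Neumann data, and the Eulerian image of a material point is
$x(t, X) = \int_0^X \mu(t, y)\,dy$ anchored at $x(t,0) = 0$
(`eulerian_positions()`). Pattern figures conventionally recentre the
domain midpoint; `render_outputs(anchor = "midpoint")` does this at
output time only — the dynamics never depend on the anchor.

**Two dimensions.** Knowing $\mu$ alone no longer determines the domain:
a constitutive choice is needed. The package adopts the simplest
kinematic closure: the flow is irrotational
($\boldsymbol a = \nabla\phi$) and purely normal at the boundary, which
together force

$$\nabla^2 \phi = S(t, \boldsymbol u), \qquad \phi = 0 \text{ on }
\partial\Omega(t),$$

a Poisson problem solved on the current geometry each step
(`solve_potential()`). A consequence worth internalizing: *uniform* $S$
does **not** dilate a 2D domain uniformly — boundary curvature is
progressively evened out (the star-domain demo below), which is also the
obstruction to extending the 1D linear stability theory to 2D.

## Kinetics

Five classical kinetics ship with analytic Jacobians and
companion-matrix equilibrium solvers: Schnakenberg, Gierer–Meinhardt,
FitzHugh–Nagumo, logistic and bistable (`?kinetics_spec`). One
correction deserves emphasis: the Gierer–Meinhardt activator equation is
implemented in its classical form $f = a + u^2/v - bu$. The variant with
$-u^2/v$ that sometimes appears in print has equilibrium
$u^* = (a-c)/b$, which is negative (hence unphysical for an activator)
for the parameter set $a = 0.01$, $b = 0.5$, $c = 5.5$ used throughout;
the classical sign gives $u^* = (a+c)/b = 11.02$, matching the reference
value used by the concentration-dependent growth laws:

```{r}
gm <- kinetics_spec("gierer_meinhardt", list(a = 0.01, b = 0.5, c = 5.5))
find_equilibria(gm)[[1]]
```

Custom kinetics and growth laws are plain R functions (optionally
vectorized over grid nodes); without an analytic Jacobian or gradient a
central finite difference is substituted with a one-time warning.

## The 1D solver

The diffusion operator is discretized with the metric-weighted
three-point stencil

$$\frac{1}{2\mu_i}\Bigl[\frac{u_{i+1}+u_{i-1}-2u_i}{\mu_i}
 + \frac{u_{i+1}-u_i}{\mu_{i+1}} + \frac{u_{i-1}-u_i}{\mu_{i-1}}\Bigr]
 \Big/ \Delta X^2,$$

with ghost-node reflection at Neumann boundaries. Two properties drive
this choice: it reduces to the standard second difference for
$\mu \equiv 1$ (the $1/\Delta X^2$ divisor is required for the continuum
limit and is verified against heat-kernel decay in the tests), and it is
in flux form, so the semi-discrete system conserves the trapezoidal mass
$\int u\,\mu\,dX$ *exactly* whenever $\boldsymbol f \equiv 0$, for any
growth law. The suite asserts conservation to $10^{-8}$ over $t = 100$
at the default tolerances (the measured drift is $\sim 10^{-12}$), and
pins the stencil's $1/\Delta X^2$ scale with a heat-kernel decay test.

Time stepping is a purpose-built adaptive, L-stable, stiffly accurate
3-stage SDIRK method of order 3 (diagonal coefficient
$\gamma \approx 0.4359$) with an embedded second-order error estimate,
modified Newton iterations, and a banded finite-difference Jacobian
factorized by LAPACK's banded LU — the state interleaves
$(u_1, \dots, u_m, \mu)$ per node, giving half-bandwidth $2(m+1)-1$.
Default tolerances are `rtol = atol = 1e-11`; per-step error control.
Scaled-down pattern runs in the tests use `1e-8`, which changes final
domain lengths by well under the asserted tolerances.

**Epochs and remeshing.** Material points separate exponentially, so a
run is split into epochs: at an epoch boundary (fixed length and/or the
mesh-quality trigger $\max\mu/\min\mu > 2$) the current Eulerian domain
becomes the new uniformly spaced computational grid, $\mu$ resets to 1,
and fields are transferred by monotone piecewise-cubic interpolation
(default; monotone to avoid overshoot at spike profiles — cubic and
linear are options). Domain length is preserved exactly; mass to
interpolation error. A remesh-invariance test checks that adding epochs
changes the final length of a growing Schnakenberg run by $<0.1\%$.

**Initial conditions.** Noisy equilibria follow
$u(0,x) = u^*(1+\eta(x))$ with i.i.d. zero-mean normal $\eta$ of
variance $10^{-2}$ (the default). Noise is drawn from a counter-based
generator keyed by `(seed, species, node index)`, so runs are
bit-reproducible and node $i$'s draw does not depend on the grid size.

## Linear stability about evolving base states

The homogeneous base state solves
$\dot{\boldsymbol u}^* = -S \boldsymbol u^* + \boldsymbol f$,
$\mu^*(t) = \exp\int_0^t S\,ds$, starting from an equilibrium of
$\boldsymbol f$ (`integrate_base_state()`; $\mu^*$ by per-interval
Simpson quadrature along the trajectory, verified to $10^{-8}$ against
an independent fine quadrature). Linearizing, mode $k$ with Lagrangian
eigenvalue $\rho_k = (k\pi/L)^2$ obeys

$$\dot{\boldsymbol V}_k = -\rho_k\,\mu^*(t)^{-2} \boldsymbol D
  \boldsymbol V_k + \boldsymbol M(t) \boldsymbol V_k,
 \qquad \boldsymbol M = \boldsymbol J - \boldsymbol K - S \boldsymbol I,$$

where $K_{ij} = (\partial S/\partial u_j)\,u_i^*$ is the new, rank-one
term contributed by concentration dependence. `theorem1_flag()`
evaluates a local-in-time sufficient condition for exponential mode
growth: writing $\tilde\rho = \rho_k/\mu^{*2}$,

$$\det \boldsymbol M - (D_2 M_{11} + D_1 M_{22})\,\tilde\rho
  + D_1 D_2 \tilde\rho^2
  < \max\Bigl\{ M_{12}\tfrac{d}{dt}\Bigl[\tfrac{M_{11}-D_1\tilde\rho}{M_{12}}\Bigr],\;
               M_{21}\tfrac{d}{dt}\Bigl[\tfrac{M_{22}-D_2\tilde\rho}{M_{21}}\Bigr]\Bigr\}.$$

Two numerical policies follow the criterion's hypotheses: if both
off-diagonal entries of $\boldsymbol M$ vanish (to `1e-12`) the result
is `NA` ("criterion inapplicable"), and a single vanishing denominator
drops that branch with a note. The printed source of this criterion
pairs $D_1$ with $M_{11}$ on the *left* side; that pairing is
inconsistent with its own right-hand brackets and with the
constant-coefficient dispersion relation
$\det(\boldsymbol M - \tilde\rho \boldsymbol D) < 0$, so the standard
pairing $(D_2 M_{11} + D_1 M_{22})$ is implemented. With frozen
coefficients the flag then reduces exactly to brute-force eigenvalue
classification — the suite verifies this for 200 random stable
matrices, all modes $k \le 50$, and checks the Schnakenberg band
endpoints ($\rho \approx 0.033568$, $0.917611$ for $a=0.01$, $b=1.1$,
$\boldsymbol D = (1,40)$) to $10^{-6}$ against a root-finding oracle.

Time derivatives on the right-hand side are centred differences on the
(spline-interpolated) base-state grid with half-step `1e-3`
(configurable); for the constant-coefficient and quasi-static cases this
is exact to rounding. Instability intervals $\mathcal I_k$ are reported
raw (`unstable_modes()`, `intervals_frame()`): the theory does not say
how long a mode must stay flagged to pattern visibly, so interpretation
is left to the user.

## The 2D solver

P1 triangles throughout (the original computations used second-order
elements; P1 keeps remeshing and interpolation robust, and the analytic
acceptance tolerances are set accordingly). Meshes are built from a
boundary polyline plus a hexagonal interior lattice via an in-package
Bowyer–Watson Delaunay triangulation with outside-centroid filtering for
non-convex shapes. The dumbbell domain is the region
$|y| \le (x^8 + 0.01)\sqrt{1-x^8}$, $|x| \le 0.995$ — the printed
parametric curve makes $x(s)$ and $y(s)$ proportional (a degenerate
segment), so the package reinterprets it as the described two-lobe shape
with a channel of half-width exactly $0.01$ at $x = 0$; boundary
sampling follows the local half-width so the channel stays resolved.

Each macro step of `advance_2d()` splits:

1. Poisson solve for $\phi$ on the current geometry; nodal
   $\boldsymbol a = \nabla\phi$ by area-weighted gradient recovery.
2. Mesh advection $x \leftarrow x + \Delta t\,\boldsymbol a$, with
   boundary velocities projected onto the outward normal (the continuous
   flow is normal there; projection suppresses discrete tangential
   drift). $\Delta t$ is capped at $0.2\,h/\max|\boldsymbol a|$ and
   halved if an element would invert.
3. Conservative dilution: nodal values are rescaled by the lumped-mass
   ratio, making $\int u\,dA$ exactly invariant when
   $\boldsymbol f \equiv 0$.
4. A Strang sandwich: pointwise RK4 reaction ($\Delta t/2$),
   $\theta$-method diffusion ($\Delta t$), reaction ($\Delta t/2$).

The diffusion $\theta$ defaults to 1 (backward Euler): monotone damping
in the spirit of the stiff BDF integrator the problem calls for, robust
for sharp fronts such as the bistable dumbbell's initial data.
$\theta = 0.5$ (Crank–Nicolson) makes the static-domain scheme second
order in $\Delta t$ and is used (a) in the $S \equiv 0$ equivalence
study, which matches an independent method-of-lines solve to $10^{-4}$
at $t = 10$, and (b) by the Gierer–Meinhardt disk presets: with
$D_2 = 1000$, backward Euler at the practical $\Delta t = 0.05$
overdamps the inhibitor and suppresses spot formation entirely — a
useful cautionary example of splitting artefacts. The macro step for
those presets must satisfy $D_2 \rho\, \Delta t = O(1)$ for the
patterning modes, hence $\Delta t = 0.05$.

Remeshing re-triangulates the current boundary at the target edge
length. The boundary polyline is resampled by arc length with a
local-feature-size-aware spacing (near-touching walls keep spacing tied
to their separation), with new vertices placed on the old polyline so
the enclosed area changes only by corner-cut terms of order
$h^2 \times$ turning angle. Triggers: minimum element quality
$2 r_{in}/r_{circ} < 0.3$ (0.12 for the dumbbell presets, whose channel
unavoidably contains thinner elements) or mean boundary-edge drift
beyond $2h$. A self-intersecting boundary — expected only under strong
contraction, where the physical domain is approaching self-contact —
is reported as an error, never repaired.

`boundary_curvature_stats()` measures discrete curvature as turning
angle over arc length, after resampling the polyline to uniform
arc-length spacing (same vertex count): between remeshes the Lagrangian
boundary vertices cluster tangentially at concave necks, and the raw
vertex-wise spread would sawtooth with the remesh cycle rather than
track the geometry. Pass `resample = FALSE` for the raw estimator.

## What the generator emulates, and what a green test establishes

Synthetic inputs are exactly the stated scenarios: seeded
$u^*(1+\eta)$ noise at variance $10^{-2}$, the tanh front for the
logistic waves, $u(0,x,y) = x$ on the dumbbell, and the printed growth
laws. Where a rate constant was never printed (the logistic-wave rates,
the thresholded/proportional Schnakenberg rates, the Gierer–Meinhardt
$r$, the FitzHugh–Nagumo linear-$S$ slope), presets carry documented
plausible defaults and are flagged `paper_approximate`; `paper_exact`
presets use only printed parameters. The FitzHugh–Nagumo linear law
defaults to $S(u) = 0.01 + \sigma u$: the intercept is forced by
requiring the base state to sit at $(u^*, v^*) = (0, 1)$, since
$g(0, 1) = (a - b)/c = 0.01$ must be cancelled by $S v^*$.

Green tests establish: the analytic structure (equilibria, Jacobians,
metric identities, Poisson solution, conservation laws, the
frozen-coefficient equivalence of the instability flag), the qualitative
regime phenomenology at scaled-down resolution (spike counts that only
insert, the two-point growth/shrinkage proxy, curvature uniformization,
front persistence and contraction slow-down), and bit-reproducibility.
They do not establish quantitative agreement with any specific published
trajectory at full resolution ($N_s = 10^4$, long horizons, $r$-grids at
$10^{-3}$ spacing): those remain overnight-scale computations that the
presets can drive but the suite does not run.

Three model-level observations the tests encode deliberately:

* On the unit-scale dumbbell with $D = 1$ the diffusion length exceeds
  the lobe size, so the stable heterogeneous state equilibrates with
  lobe values just above $\pm 0.9$, not $\pm 1$ (refinement-stable:
  max $|u|$ 0.9028/0.9059/0.9062 at $h$ = 0.06/0.04/0.03). This is why
  the 0.9 growth threshold is an interesting choice: the state straddles
  it.
* The long-time classifier gives a clear log-slope trend precedence over
  oscillation detection (thresholds $10^{-4}$ per unit time and 1%
  residual amplitude, both configurable): patterned growth carries
  pattern-scale wiggles that would otherwise mask every "growing"
  verdict. "Oscillating" therefore means sustained oscillation about a
  flat trend; windows that disagree return "undetermined". Regime
  boundaries in $r$ are treated as seed-averaged quantities.
* The spike-count diagnostic excludes boundary maxima by default (a
  Neumann boundary pins half-spikes) and uses topographic prominence at
  10% of the field range, so insertion events never transiently lower
  the count on the tested runs.

## Known limitations

No gene-expression delays, no more than two species, no Stefan-type
boundary-localized growth, no curved manifolds or multiple charts, no
contact handling (self-intersection is detected and reported only), and
no wave-speed estimation. The 2D mesh motion couples to transport at
first order in $\Delta t$; quantitative 2D work should check
$\Delta t$- and $h$-convergence for the specific scenario, as the
original computations did. Configs serialize to JSON (not YAML) and
results to CSV/JSON (not HDF5/VTU): the environment provides no R
bindings for the latter formats, and the layouts are versioned,
fixed-format text so re-rendering is byte-identical.

## A worked example

```{r, eval = FALSE}
cfg <- make_preset("fig7")        # star domain, uniform S = 0.001
res <- run_simulation_2d(cfg)
sapply(res$snapshots,
       function(s) boundary_curvature_stats(s$boundary)$sd_curvature)
# 3.064 2.486 1.319 0.563 0.215 0.112  -- curvature is uniformized
render_outputs(res, "star-out")   # boundary.csv, area.csv
```
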