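---
title: "Multiscale modelling of non-local cell-cell adhesion with adhesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale modelling of non-local cell-cell adhesion with adhesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhesim)
```

## The model

Cell-cell adhesion (CCA) — cells binding to neighbours through
cadherin-mediated junctions — regulates migration during embryogenesis,
wound healing and cancer invasion. `adhesim` simulates a self-adhesive
cell population on three levels that are connected by a mean-field /
kinetic upscaling argument.

**Microscale.** `N` cells are points $(x_i, v_i)$ obeying Newtonian
dynamics with Stokes friction and a pairwise adhesion force,

$$\frac{dx_i}{dt} = v_i, \qquad
  \frac{dv_i}{dt} = -a v_i + \chi(t, x_i)\,\frac{1}{N}
  \sum_{j \ne i} \nabla H_r(x_i - x_j),$$

where the adhesion potential
$H_r(x) = \tfrac{1}{r|B_r|}\int_{\min(|x|,r)}^{r} F(s)\,ds$ is supported
on the sensing ball of radius $r$ and $F \ge 0$ profiles the force with
distance. Speeds are rescaled so that 1 is an unattainable cap; this is
guaranteed whenever $\tfrac{1}{r|B_r|}\sup\chi\,\sup F \le a$
(`velocity_bound_ok()`), and `simulate_micro()` refuses configurations
that violate it. Stochastic reorientation along tissue fibers with
orientational distribution $q$ ($\bar q = 1/d$) enters through the
turning operator $c \mapsto d\,q\,\bar c - c$.

**CAM binding.** Each cell carries a fraction $y_i \in [0,1]$ of bound
cell adhesion molecules. Pairs within reach bind and unbind by mass
action,

$$\frac{dy_i}{dt} = \frac{1}{N}\sum_{j\ne i}
  G^+_r (1-y_i)(1-y_j) - G^-_r\, y_i y_j, \qquad
  G^\pm_r = \frac{k^\pm\!\big(S(t,\tfrac{x_i+x_j}{2}),\,|x_i-x_j|\big)}{|B_r|},$$

with rates that vanish for separations $\ge r$ and depend on a chemical
field $S$ (calcium in the cadherin picture) at the pair midpoint. In CAM
mode the adhesion force on cell $i$ is weighted by $y_i$: more bonds,
stronger pull.

**Macroscale.** The parabolic scaling limit of the associated kinetic
transport equation gives, for the density $u$,

$$(a+1)\,\partial_t u
  = c_1\, \partial_x\big(D(x)\,\partial_x u\big)
  + \partial_x\Big(u\big(\theta\, c_1\, \partial_x D
  - \chi_0\, \mathcal{A}_r u\big)\Big), \qquad
  c_1 = \frac{1}{2a+1}\frac{d}{d+2},$$

where $\mathcal{A}_r u(x) = \tfrac{1}{r|B_r|}\int_{B_r} u(x+\xi)
\tfrac{\xi}{|\xi|} F(|\xi|)\,d\xi \equiv \nabla H_r \star u$ is the
non-local adhesion operator and the $\theta$-drift is the extra
advection produced by writing the *myopic* diffusion
$\partial_x^2(D u)$ in divergence form ($\theta = 0$ switches to
ordinary, non-myopic diffusion with the same coefficient). With CAM
binding the advective flux becomes $\chi\,\mu_1\,\mathcal{A}_r u$,
where the bound-CAM moment $\mu_1 = \overline{y u}$ closes the system
through a non-linear integral equation,

$$\mu_1 = \mu_0\, \mathcal{Y}_r[S](\mu_0, \mu_1), \qquad
  \mathcal{Y}_r[S](\mu_0,\mu_1)
  = \frac{\mathcal{G}^+_r(\mu_0-\mu_1)}
         {\mathcal{G}^+_r(\mu_0-\mu_1) + \mathcal{G}^-_r \mu_1},$$

with $\mathcal{G}^\pm_r$ the spatial integral operators built from
$G^\pm_r$. For rates concentrated at zero separation this collapses to
the closed form $\mu_1 = \sqrt{K^+}/(\sqrt{K^+}+\sqrt{K^-})\,\mu_0$
(`bound_fraction_local()`); remarkably, for *identical* binding and
unbinding kernels linearity of $\mathcal{G}_r$ makes $\mu_1 = \mu_0/2$
exact at any kernel width. The equilibrium mesoscopic velocity profile
is the factorised $c^0 = \mu_0\, q(v)\, \xi_1(v)$ with the speed factor
`xi1()`; its velocity integral returns $\mu_0$ exactly.

## Parameters that matter

| parameter | meaning | default | units |
|---|---|---|---|
| `r` | sensing radius | 1 | space |
| `a` | deceleration (viscous) rate | 1 | 1/time |
| `F` | force-with-distance profile | constant 1 | — |
| `chi0` | adhesion sensitivity | 0.5 | — |
| `D0`, `delta` | diffusion moment $D(x) = D_0 + \delta x$ | 0.15, 0 | — |
| `theta` | myopic-drift switch | 1 | — |
| `L`, `T` | domain length, final time | 6, 25 | space, time |
| `h`, `dt_outer` | space step, splitting window | 0.01, 0.01 | space, time |
| `inner_substeps` | inner time mesh per window | 41 | — |
| `u0` | initial density | uniform 5 | cells/length |

The defaults are the conditions of the package's reference simulation
study: a homogeneous epithelial sheet ($u_0 \equiv 5$) that has
undergone a partial epithelial-mesenchymal transition — weakened but
present adhesion ($\chi_0 \in \{0.5, 1\}$) and enhanced motility in a
mildly heterogeneous matrix ($D_0 \in \{0.15, 3, 5, 8\}$,
$\delta \in \{0, 1\}$). With $a = d = 1$ the diffusion prefactor is
$c_1 = 1/9$ and the equation carries the overall factor $a + 1 = 2$.
An affine $D(x)$ is accepted as a free coefficient field: in $d = 1$
the normalisation $\bar q = 1/d$ would force $D[q] \equiv 1$, so the
solver deliberately decouples the coefficient fields from an explicit
fiber distribution.

## Numerical choices

**Outer splitting.** The non-local flux makes an implicit solve of the
full equation awkward, so `solve_ibvp()` splits time into windows of
length `dt_outer`. Within a window the adhesion velocity
$\chi_0 \mathcal{A}_r u$ is frozen at the window's initial density; the
remaining *local* advection-diffusion problem is advanced by a stiff
method-of-lines integrator (`deSolve::lsoda` with a banded Jacobian) on
an inner mesh of `dt_outer / inner_substeps`. Explicit stepping is
rejected: the diffusion CFL at $h = 0.01$ would require far smaller
steps.

**Spatial discretisation.** A conservative finite-volume scheme on
nodes $x_m = m h$ (both endpoints included; boundary cells of width
$h/2$). Fluxes live on cell faces; the diffusive part uses exact face
values of the affine $D$; the advective face density is a centred
average by default (`advection = "upwind"` is available for very steep
aggregates). No-flux means the total flux vanishes at $x = 0, L$, so
the trapezoid-weighted mass derivative is identically zero and mass is
conserved to integrator tolerance (measured: $10^{-13}$ relative over
the full reference run).

**The non-local stencil.** `adhesion_grid_1d()` evaluates
$\mathcal{A}_r u$ by the right-endpoint Riemann sum
$s_m = h \sum_{l=a(m)}^{b(m)} u(x_{m+l})\,\mathrm{sign}(l h)\,F(|l h|)$
with $a(m) = \max(-(\ell_r - 1), -m)$, $b(m) = \min(\ell_r, M - m)$,
$\ell_r = \mathrm{round}(r/h)$, zero-extending the density outside the
domain; face values are obtained by linear interpolation. The
conventions at the measure-zero sets are $\mathrm{sign}(0) = 0$ and the
one-sided value $F(r)$ at $|\xi| = r$. Beware that the right-endpoint
rule is *not* antisymmetric: on a constant field the interior stencil
leaves an $O(h)$ remainder $h\,u$, a small directional bias. It is
first-order consistent (verified against adaptive quadrature under mesh
halving), but it breaks exact mirror symmetry of symmetric initial
data: aggregate *positions* remain mirrored to within one node while
amplitudes differ at the percent level. The $\chi_0 = 0$ core is
exactly symmetric.

**Bound-CAM fixed point.** `solve_bound_fraction()` uses damped Picard
iteration $\mu_1 \leftarrow (1-\omega)\mu_1 + \omega\,\mu_0
\mathcal{Y}_r(\mu_0,\mu_1)$ with $\omega = 0.5$, starting from
$\mu_0/2$, residual tolerance $10^{-10}$, at most $10^4$ iterations,
clipping to $[0, \mu_0]$. Uniqueness for general non-local kernels is
not established; the solver reports its residual and iteration count so
damping-dependent answers would be visible, and an independent
pointwise quadratic-root oracle covers the constant-kernel case in the
tests. A vanishing denominator of $\mathcal{Y}_r$ where $\mu_0 > 0$ is
a hard error (degenerate binding state), not a silent regularisation.
The unbinding blow-up of the separable example family as
$\rho \to r$ is capped (default $10^6$).

**Micro integrator.** Fixed-step classical RK4 (reproducibility over
adaptive stepping; the dynamics are smooth and non-stiff for
$a\,dt \le 0.1$), with the $O(N^2)$ pairwise force in compiled code.
In CAM mode the binding term adds its own stiffness scale: with the
separable rate family the capped unbinding blow-up near pair
separation $r$ gives net rates of order `cap`$/|B_r|$, so choose `cap`
and `dt` with `cap * dt` well below 1 — otherwise mid-stage excursions
of $y$ outside $[0,1]$ can destabilise the explicit step.
The compiled kernel interpolates a 4097-point tabulation of $F$,
exact for the constant default and otherwise negligible against the
integrator error; the direct R sum is kept as a bit-comparison
reference. The turning operator is realised as a jump process:
unit-rate exponential waiting times (per-step turning probability
$1 - e^{-dt}$) and post-turn velocities drawn from the density
$d\,q$ on the unit ball — in 1D, direction $+1$ with probability
$q_+(x)$ and speed uniform on $(0,1)$, the unique density matching a
direction-only $q$. Coincident particles exert no force
($\mathrm{sign}(0) = 0$).

**Hyperbolic modes.** The conservative transport equation
$(a+1)\partial_t u + \tfrac{d}{d+1}\partial_x(E u) = 0$ is solved with
first-order upwinding and explicit Euler steps under an enforced CFL
bound; `mode = "hyperbolic"` adds the $O(\varepsilon)$ corrections
(myopic diffusion, adhesion, and the $E$-cross term with prefactor
$\tfrac{1}{(a+1)^2}\tfrac{d^2}{(d+1)^2}$). These modes are
first-order accurate and intended for qualitative exploration; the
parabolic solver is the production path.

## What the generators emulate — and what they do not

All inputs are synthetic and generated in code (`make_ic()`,
`make_fiber_field()`, `make_particle_cloud()`, `kinetics_example()`);
there is no external data. The generators reproduce the *study
conditions*: uniform or Gaussian initial densities, affine diffusion
fields, uniformly seeded particle clouds, separable binding rates. They
do not emulate measured cell tracks, realistic cadherin kinetics, cell
size exclusion, proliferation, or 2D/3D tissue geometry — so passing
tests demonstrate internal consistency of the multiscale framework and
faithful reproduction of its idealised dynamics, not agreement with any
experiment.

## Problem sizes used by the test suite

The suite runs four full reference-mesh runs to $T = 25$ (about 30-40 s
each), one mesh-halved run for the refinement check, micro consistency
at $N = 5000$ particles to $t = 1$ with a tenfold step refinement as
its own oracle, and CAM equilibration with 60-120 particles. Aggregate
statistics are computed at threshold 5 — the initial uniform level —
and the measured counts are threshold-stable across $[1, 10]$.

## Known limitations

* The grid PDE solver is 1D; pointwise kernel operations
  (`adhesion_point()`, `ring_operator()`) are generic in dimension but
  there is no 2D/3D grid solver.
* The velocity-jump simulation is 1D and assumes a unit turning rate.
* Only zero-extension of the density inside the non-local integral plus
  no-flux differential boundary conditions are implemented; other
  boundary treatments change aggregate behaviour near walls.
* The $O(h)$ directional bias of the right-endpoint stencil (above) is
  part of the adopted discrete convention; halve `h` to halve it.
* The macroscopic CAM coupling equilibrates the bound fraction
  instantaneously each splitting window (fast-kinetics limit); no
  finite-rate relaxation is modelled on the macro clock.
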