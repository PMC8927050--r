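---
title: "A two-phase mechanochemical model of cell-seeded gel swelling and contraction"
author: "gelmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-phase mechanochemical model of cell-seeded gel swelling and contraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelmech)
```

## The model

`gelmech` simulates a one-dimensional gel — a polymer network saturated with
solvent and (optionally) seeded with cells — sitting in a bath of pure
solvent. The gel occupies $0 \le x \le L(t)$, is symmetric about $x = 0$,
and exchanges solvent with the bath across the moving interface at
$x = L(t)$. Both phases are treated as viscous fluids; elastic stresses are
neglected because the Deborah number of collagen-like gels over
contraction timescales is small. Two force systems compete:

* **Osmotic forces.** The Flory–Huggins free energy density
  $f(\theta_p) = \tfrac{\theta_p}{N}\log\theta_p + \theta_s\log\theta_s +
  \chi\theta_p\theta_s + \mu_p^0\theta_p + \mu_s^0\theta_s$
  (with $\theta_s = 1-\theta_p$ by the no-voids condition) defines
  chemical potentials $\mu_p = f + \theta_s f'$, $\mu_s = f - \theta_p f'$.
  Solvent crosses the interface toward lower solvent potential: a gel with
  $\mu_s(\theta_p) < \mu_s^e$ imbibes solvent and swells; the reverse
  drives syneresis. The standard free energies $\mu_p^0,\mu_s^0$ cancel
  from every term the dynamics uses (only $\mu_s - \mu_s^e$, $f''$ and
  $\theta_p G$ appear) and are kept for generality only.
* **Cell traction.** Cells adhere to the network and pull on it with a
  body force $\nabla(\theta_p G)$ derived from the Hill potential
  $G(n) = \tau_0 n^2 / (1 + \lambda n^2)$: monotone in the cell density
  $n$, so the force always points up cell-density gradients, and
  saturating at $\tau_0/\lambda$ (contact inhibition). Cells advect with
  the network and diffuse with coefficient $D$; proliferation and death
  are excluded, so total cell mass is conserved.

Everything is dimensionless: lengths on the initial gel size, time on the
ratio of polymer viscosity to the free-energy density scale, cell density
on its initial mean (`nondimensionalise()` documents the conversion from
laboratory constants). Mapping $X = x/L(t)$ fixes the domain to $[0,1]$ at
the price of an extra advection term $-X\dot L/L\,\partial_X$.

The model integrated by `simulate_gel()` is, on $0 \le X \le 1$:
a quasi-static two-point boundary-value problem for the network velocity
$v_p$ (network and solvent viscous stresses, interphase drag $\xi$,
osmotic forcing $-\theta_p\theta_s f''\partial_X\theta_p / L$ and traction
forcing $\theta_s\partial_X(\theta_p G)/L$), conservative transport of
$\theta_p$ and $n$, and boundary motion $\dot L = v_p(1)$. At $X=0$
symmetry gives $v_p = 0$ and zero slopes; at $X=1$ the viscous/osmotic
stress balance carries the interface resistance $\mathcal{R}$, which
throttles solvent exchange with the bath. The solvent velocity is slaved
to $v_p$ by the zero-volume-flux identity
$\theta_p v_p + \theta_s v_s = 0$. The pressure field is deliberately not
recovered: the mechanics that move the gel do not require it.

## Steady states, stability, bifurcation

A spatially uniform state is an equilibrium iff
$\theta_p G(n) + \mu_s(\theta_p) - \mu_s^e = 0$. Mass conservation pins the
rest: a uniform start $(\theta_i, \bar n_i)$ reaching a uniform equilibrium
$\theta^*$ must have $L^* = \theta_i/\theta^*$ and
$n^* = \bar n_i\theta^*/\theta_i$. `solve_uniform_steady_states()` scans
2001 grid points on $(10^{-6}, 1-10^{-6})$ for sign changes of the
residual and refines each bracket to $|\Delta\theta| < 10^{-12}$; scanning
is deliberate, because the residual can have zero, one or two roots (the
balance $G = \theta_p f''$ is a quadratic in $\theta_p$ — see
`marginal_roots()`), and an empty result is itself the prediction that the
gel dissolves.

Stability is labelled by the short-time growth factor
$z = \theta^* f''(\theta^*) - \tau_0/(1+\lambda) -
2\theta^*\tau_0 N_{01}/(1+\lambda)^2$ of a cosine perturbation (cell
amplitude $N_{01}$ times the polymer amplitude): perturbations decay iff
$z > 0$. Cell-free, this is just the sign of $f''$; traction only ever
lowers $z$. Two documented choices here:

* $N_{01} = 1$ is the default amplitude ratio for labelling (perturb cells
  and polymer equally, in relative terms). The criterion genuinely depends
  on $N_{01}$ and no canonical value exists; it is an argument everywhere.
* The criterion is derived in the zero-drag limit ($\xi = 0$) but applied
  as a label to all equilibria; the package's simulations support the
  labels away from that limit.

`chi_for_theta()`/`tau0_for_theta()` invert the equilibrium condition
explicitly, tracing bifurcation branches; `cell_free_existence_threshold()`
locates the fold ($\chi_{\min} \approx 0.62$ at $N = 100$) below which a
cell-free gel has no uniform steady state for any initial composition.

## Short-time solutions

Two closed-form expansions serve both as user-facing analysis and as the
solver's independent oracle.

From a uniform non-equilibrium start, the early velocity field is
$A_0\sinh(\alpha X)$ with
$\alpha = \sqrt{\theta_i\xi / [(2{+}\kappa_p)\theta_i\theta_s +
(2\eta_s{+}\kappa_s)\theta_i^2]}$, and
$L = 1 + T A_0\sinh\alpha$, with $\theta_p$ and $n$ decreasing fastest at
the interface (`short_time_uniform()`). $A_0$ is proportional to the net
force $\theta_i G + \mu_s - \mu_s^e$, so it vanishes identically at
equilibrium and its sign decides swelling versus contraction. As
$\xi \to 0$ the response becomes spatially uniform; the implementation
takes that limit explicitly rather than evaluating $0/0$.

About an equilibrium, `short_time_perturbed()` evaluates the cosine-mode
expansion (wavenumber $\gamma = Z\pi$, integer $Z$, which keeps the
perturbation mass-free): with drag, a $\cosh(\alpha X)$ boundary mode
changes the gel length at rate $A_{01}\sinh\alpha$, while the cosine
amplitudes evolve at rate set by $z$; without drag the length is frozen at
this order. Known caveat, reported as a machine-readable
`boundary_layer_warning`: with drag the cell field of the printed
expansion violates the no-flux condition at $X = 1$ in a thin layer (a
singular-perturbation effect); no boundary-layer correction is attempted
since the error is confined near the interface. Hyperbolic functions are
evaluated as scaled exponentials so large $\alpha$ cannot overflow.

## Numerical scheme

The reference resolution is $dX = 0.002$ (501 nodes) and $dT = 0.0005$.
Choices the governing equations do not dictate, and why:

* **Time coupling** (operator splitting): $v_p$ is solved quasi-statically
  from the current state; $\dot L = v_p(1)$; $\theta_p$ then $n$ advance
  by Crank–Nicolson with $v_p$, $L$, $\dot L$ frozen; $L$ advances by
  forward Euler. The splitting error is first order but premultiplied by
  $\dot L$, and at $dT = 5\times10^{-4}$ it is far below the spatial
  error. The update order ($\theta_p$ before $n$) is immaterial at
  $O(dT)$ and fixed for reproducibility.
* **Velocity discretization**: nested derivatives expanded by the product
  rule to $P v_p'' + Q v_p' + S v_p = \mathrm{RHS}$; central second-order
  stencils; $v_p(0)=0$ imposed strongly; at $X=1$ a ghost value of $v_p$
  is eliminated through the interface stress condition and derivatives of
  $\theta_p$ use one-sided second-order stencils. One tridiagonal solve
  per step.
* **Transport in conservative form**: writing the mapped advection as
  $\partial_X(\theta_p u)/L + \dot L\theta_p/L$ with
  $u = v_p - X\dot L$ (which vanishes at both ends) and differencing the
  flux at half-nodes makes the spatial operator telescoping: the
  trapezoidal masses $L\int\theta_p\,dX$ and $L\int n\,dX$ are conserved
  exactly by the spatial scheme, and drift comes only from the
  $O(dT^2)$-per-step time coupling. Advection is centrally differenced
  with no upwinding — the flows are slow and the fields smooth.
* **Guards**: $\theta_p$ is clamped to $[10^{-10}, 1-10^{-10}]$ (the
  logarithms diverge at the endpoints; activations are counted and
  reported), dissolution is declared when $\max\theta_p < 10^{-3}$ (the
  continuum model has no intrinsic stopping rule), and steady state when
  $\max|v_p| < 10^{-8}$ for 10 consecutive steps. Initial polymer
  profiles must have zero slope at $X=0$ (checked with a second-order
  one-sided estimate, tolerance $\max(10^{-8}, 10\,dX^2)$ so that
  analytically symmetric profiles pass at any resolution).

The inner loop is compiled (Rcpp); a full reference-resolution run to
$T = 250$ takes roughly 20 s on one core.

## What the reference scenarios emulate

`scenario_registry()` holds the study conditions: fixed constants
$N = 100$, $\lambda = 1$, $\mu_p^0 = \mu_s^0 = 0$,
$\kappa_p = \kappa_s = 0$, with $\theta_i \in [0.2, 0.7]$,
$\chi \in [-0.1, 1.5]$, $\tau_0 \in [0.1, 1]$ and mechanical ratios of
order one. They cover: osmotic swelling versus contraction of cell-free
gels, the traction-induced switch from swelling to contraction, the
negative correlation between initial polymer fraction and final gel
length, drag/resistance/viscosity effects on equilibration lag,
non-uniform steady states reachable only with $D = 0$ and non-uniform
initial data, and a narrow parameter window
($\chi = -0.1$, $\tau_0 = 0.8$, $\xi = \mathcal{R} = 1.5$) in which parts
of the gel cycle between swelling and contraction while the total length
grows monotonically, before eventual dissolution. In the `fig11`
scenario the cell-perturbation amplitude is 0.025 (the value stated with
the scenario's figure; a variant value 0.05 also circulates in prose).

The generator is an idealisation: initial profiles are smooth and
symmetric, cells are a continuum with no proliferation or death, the
traction law is a single Hill form, and the geometry is 1D Cartesian.
Passing tests therefore demonstrate internal consistency of the model and
scheme — equilibria, stability verdicts, conservation, asymptotic
agreement — not agreement with any particular laboratory gel.

## Worked example

```{r example, eval = FALSE}
p <- gel_params(chi = 0.75, tau0 = 1, eta_s = 0.25, xi = 0.5, R = 0.5,
                D = 0.01)
solve_uniform_steady_states(0.6, 1, p)
#   theta_star    n_star     L_star   stable     residual
# 1 0.03078876 0.0513146 19.4876298 unstable 4.062234e-16
# 2 0.86476208 1.4412701  0.6938325   stable 0.000000e+00

traj <- run_scenario("fig4b")   # same physics, full PDE, ~4 s
steady_state(traj)              # converges to the stable root above
mass_audit(traj)                # drift ~6e-4 %
```

The problem sizes used throughout the test-suite are chosen for the
property under test: reference resolution ($dX = 0.002$) wherever a
reported number or the scheme audit is at stake, and coarser grids
($dX = 0.005$–$0.01$) for structural properties — fixed points, regime
classification, stability-verdict agreement — that do not depend on
resolution.

## Limitations

* Uniform-equilibrium analysis only; spatially non-uniform equilibria
  (possible when $D = 0$) are reachable by simulation but not by the
  algebraic solver.
* The stability label inherits the zero-drag derivation and the
  $N_{01}$ convention above.
* No pressure recovery, no spherical or thin-film geometry, no
  composition-dependent $\chi$, no cell proliferation.
* Near dissolution the polymer fraction approaches the clamp floor and
  the continuum description itself degrades; results past the first
  clamp activation should be read qualitatively.
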