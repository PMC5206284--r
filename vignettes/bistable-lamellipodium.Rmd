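---
title: "A planar actin-myosin lamellipodium model and the bistability of cell fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A planar actin-myosin lamellipodium model and the bistability of cell fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamellipod)
```

## The biological question

Lamellipodial fragments of fish keratocytes — pieces of the thin actin sheet
that drives crawling, detached from the cell body — are bistable: the same
fragment can sit still in a circular shape or crawl steadily in a
crescent-moon shape, and a transient mechanical push can switch it from one
to the other. The working hypothesis encoded here is that myosin-II is the
switch. Myosin filaments connect pairs of crossing actin filaments, slide
them and turn them towards antiparallel, but they can only engage when the
two filaments are already antiparallel *enough*. That angle dependence makes
the local network geometry self-reinforcing: a sufficiently collapsed region
recruits myosin and collapses further, while a well-spread region stays
myosin-free.

## The reduced model

The actin sheet is described by two transversal families of locally parallel
filaments. In a translationally invariant strip of lamellipodium, with rigid
filaments of length $L$, all geometry is captured by a single angle
$\omega \in (0, \pi/2]$ between the filaments and the leading edge; crossing
filaments of opposite families meet at $\varphi = \pi - 2\omega$. The strip
state $(x, y, \omega)$ (lateral position, edge position, angle) obeys three
ODEs obtained by balancing, along each filament, substrate friction from
adhesions ($\mu^A$), friction and turning torques from transient cross-links
($\mu^S$, $\mu^T$, equilibrium crossing angle $\varphi_0$), the analogous
myosin terms ($\mu^{SM}(\varphi)$, $\mu^{TM}(\varphi)$, equilibrium angle
$\pi$, walking speed $v^M$), polymerization at speed $v$, and the external
line forces: membrane tension $f_{mem}$ on the barbed ends and a
stress-fibre pull $f_{stress}$ on the pointed ends, both normal to the edge.

The angle dynamics decouple and take the factored form

$$\dot\omega \, g(\omega) = \cos\omega\left(\frac{f_{stress}-f_{mem}}{4}
  + h(\omega)\right),
\qquad
h(\omega) = \mu^T(\pi-2\omega-\varphi_0)
  - 2\omega\,\overline{\mu^{TM}}\,(\pi-2\omega-\bar\varphi)_+ ,$$

with the strictly positive drag $g(\omega)$ of `g_drag()`. Everything about
bistability is contained in the torque balance $h$: the cross-link term is
linear and vanishes at $\omega_{10} = (\pi-\varphi_0)/2$; the myosin term
switches on only below the cutoff angle $\omega < (\pi-\bar\varphi)/2$
(equivalently $\varphi > \bar\varphi$) and is quadratic there.

### Myosin kinetics behind the cutoff law

The effective stiffnesses $\mu^{SM}, \mu^{TM}$ arise from an age-structured
population of transient myosin connections, created at rate $\beta(\varphi)$
on unconnected crossings and breaking at rate $\zeta$. In the fast-turnover
limit the age density equilibrates to
$\rho^M_0(a) = \frac{\beta\zeta}{\beta+\zeta}e^{-\zeta a}$
(`age_density()`), connections never accumulate stretch (only the
zero-stretch breakage rate matters, and the initial time layer is ignored),
and integrating the elastic energies over age gives
$\mu^{SM} = \beta\kappa^{SM}/(\zeta(\beta+\zeta))$ and
$\mu^{TM} = \beta\kappa^{TM}/(\beta+\zeta)$ (`effective_stiffness()`). The
package does not integrate the finite-turnover population equation: the
reduced analyses use only the limit. The working closure for all analyses is
the hinge law
$\mu^{SM}(\varphi) = \overline{\mu^{SM}}(\varphi-\bar\varphi)_+$,
$\mu^{TM}(\varphi) = \overline{\mu^{TM}}(\varphi-\bar\varphi)_+$
(`cutoff_stiffness()`), a limiting description of the observation that
myosin acts efficiently only on sufficiently antiparallel networks. Any
smooth kinetics $(\beta,\zeta)$ reproducing this law is admissible; the
kinetics module exists to make that connection concrete and testable.

## Parameters

`default_parameters()` returns the reference table (units pN, µm, min;
angles stored in radians, configuration files may declare degrees):
$L = 8$ µm, $\mu^A = 0.14$ pN min µm⁻², $v = 3$ µm min⁻¹, $v^M = 1$ µm
min⁻¹, $\varphi_0 = 70°$ (the branching angle), $\bar\varphi = 100°$,
$\mu^S = \mu^T = 4.2\times10^{-3}$, $\overline{\mu^{SM}} =
4.2\times10^{-3}$, and $\overline{\mu^{TM}} = 1.8\times10^{-2}$ pN µm
(preset `"simulation2"`; preset `"simulation1"` uses $1.4\times10^{-2}$).
The bending stiffness $\mu^B$, filament count $N$ and equilibrium area
$A_0$ are carried for documentation; the rigid-filament reduction does not
use the first two, and $A_0$ only sets the default reference size
$Y_0 = 2\sqrt{A_0/\pi} \approx 19.5$ µm of the stress-fibre closure — the
diameter of the equilibrium disc, our own identification since a strip
caricature has no literal area.

## The dominance condition and the single strip

`bistability_threshold()` evaluates the closed-form threshold that
$\overline{\mu^{TM}}/\mu^T$ must exceed for $h$ to have three simple zeroes

```{r}
p <- default_parameters()
bistability_condition(p)[c("ratio", "threshold", "holds")]
h_zeros(p)
```

Both presets exceed the threshold (ratios 3.33 and 4.29 against 2.28). The
zeroes are found per smooth branch in closed form — the linear branch root
$(\pi-\varphi_0)/2$ and the two roots of the quadratic myosin branch — never
by blind global search, so no root can be missed and each is verified to
annihilate $h$ to $10^{-12}$. With a small force difference the strip then
has four equilibria (`planar_steady_states()`): the degenerate parallel
state $\pi/2$ (unstable), the cross-link-dominated state $\omega_1 =
(\pi-\varphi_0)/2 + (f_{stress}-f_{mem})/(8\mu^T)$ (stable; the formula is
*exact* here because the branch is linear), a separatrix (unstable) and the
myosin-influenced collapsed state (stable). Stability is judged by the sign
of the numerical derivative of the full right-hand side, which for simple
roots agrees with the sign of $h'$ since drag and $\cos\omega$ are positive.
"Small" is made concrete by `delta_f_bound()`, which bisects for the widest
force window keeping four equilibria (about $[-8.8\times10^{-3},
1.6\times10^{-2}]$ pN µm⁻¹ at reference parameters) and reports it rather
than asserting any particular value.

## The rigid-filament quadrature oracle

The closed-form right-hand sides above involve several exact integrals and
one delicate reduction (the boundary-torque lever arms contributing the
$6/L^2$ term). `rhs_by_quadrature()` re-derives the dynamics without any of
those manipulations: it substitutes the rigid-filament ansatz of both
families into the raw integral force and torque balances, evaluates the
arclength integrals by Gauss–Legendre quadrature (the integrands are
quadratic polynomials in $s$, so three nodes are already exact), and solves
the resulting linear system for the velocities. The sign convention of the
per-family twist torques — written ambiguously as $\pm$ in the general
two-family formulation — is fixed by requiring that the cross-link torque
restores the crossing angle towards $\varphi_0$, and validated by the sign
of $\dot\omega$ on either side of the cross-link equilibrium. Closed form
and oracle agree to better than $10^{-10}$ relative on randomized
parameter/angle grids; this agreement is the package's strongest internal
correctness guarantee and also settles that the differing friction brackets
of the lateral and angular equations are both correct as printed.

## The coupled fragment

A fragment is caricatured as two back-to-back strips sharing the same
membrane and stress-fibre forces, one of which regulates the fragment size
$Y = y + \hat y$. With the Case A closure ($f_{mem}$ constant,
$f_{stress}(Y)$ nondecreasing) the system closes in $(Y, \omega,
\hat\omega)$ (`fragment_rhs()`). Steady states satisfy
$f_{stress}(Y) = -f_{mem} + \tfrac{\mu^A L v}{2}(\sin\omega+\sin\hat\omega)$
(`stationary_size()`, solved by monotone bracketing) and $h(\omega) =
h(\hat\omega) = -(f_{stress}-f_{mem})/4$, so each angle sits near one of the
two stable torque zeroes: four stable combinations — symmetric cross-link
(spread, stationary), symmetric myosin (collapsed, stationary), and the two
polarized states (one spread front, one collapsed rear) that move at

$$\dot y = -\dot{\hat y} = \frac{v}{2}(\sin\omega - \sin\hat\omega).$$

`fragment_steady_states()` finds them by damped Newton iteration seeded at
all pairs of torque zeroes (combinations involving the separatrix are
returned too, flagged unstable), labels them, and attaches the analytic
Jacobian eigenvalues.

### The smallness regime is real, and the package makes it explicit

The perturbation argument behind the four-state structure requires
$f_{mem}$ and the product $\mu^A v L$ small. This is not a technicality: the
angle shift away from the torque zeroes is of order $\mu^A v L /|h'|$, and
at the full reference adhesion ($\mu^A v L = 3.36$ pN µm min⁻¹ against
$|h| \lesssim 5\times10^{-3}$) the coupled size equation is inconsistent
with any admissible angle — the reduced fragment has *no* steady state and
every trajectory drifts to the degenerate parallel configuration.
`fragment_defaults()` therefore works at $\mu^A = 10^{-4}$ pN min µm⁻²
(everything else as in the reference table), a choice made once on two
grounds: it sits about a factor ten inside the four-state existence edge
located empirically by `coupling_bound()` (bisection on the adhesion scale;
edge near $9\times10^{-4}$), and it yields polarized-fragment speeds of
about 1 µm min⁻¹, the observed scale for keratocyte fragments. The
stress-fibre slope defaults to the hinge law with $\kappa = 5\times10^{-2}$
pN µm⁻² around $Y_0$; because stability work needs a continuously
differentiable force, the hinge is C¹-smoothed over a 0.1 µm width by a
quadratic blend (the exact hinge remains available with `width = 0`).

```{r}
fd <- fragment_defaults()
ss <- fragment_steady_states(fd$params, fd$sfm)
ss[ss$stable, c("Y", "omega", "omega_hat", "label", "speed", "max_re_lambda")]
```

### Eigenvalue structure of the size-angle coupling

The Jacobian has an arrow structure: two fast angle modes
$\lambda_{1,2} \approx \frac{\cos\omega}{g(\omega)}h'(\omega)$ and one slow
size mode proportional to the force slope $\kappa = f_{stress}'(Y)$.
First-order eigenvalue perturbation of the implemented linearization gives

$$\lambda_3 = \kappa\left(-\frac{2}{\mu^A L}
  - \frac{v\cos\omega}{4h'(\omega)}
  - \frac{v\cos\hat\omega}{4h'(\hat\omega)}\right) + O(\kappa^2).$$

Since $h' < 0$ at both stable angles, the two angle terms are *positive*:
size growth raises the stress-fibre pull, which steepens the angles, which
raises protrusion and feeds back into size growth. The steady states are
stable because the direct size relaxation $-2/(\mu^A L)$ dominates whenever
$\mu^A v L$ is small — the same smallness hypothesis again, now with a
mechanistic reading: strong treadmilling can destabilize the stationary
fragment through the size-angle loop. `slow_eigenvalue_estimate()`
implements this expression; against the numeric eigenvalues its error
contracts by a factor $\approx 4$ under $\kappa$-halving, confirming the
$O(\kappa^2)$ remainder. (For the perturbation ordering to be visible the
slope must satisfy $2\kappa/(\mu^A L) \ll |\lambda_{1,2}|$, which is why the
convergence tests use the linear closure with $\kappa \le 10^{-5}$ rather
than the simulation-scale hinge slope.)

## Trajectories and basins

`integrate_fragment()` integrates the full five-variable dynamics (size,
two angles, and the passive individual edge and lateral positions) with
`deSolve::lsoda`, raises a collapse event if an angle reaches the floor
`omega_floor` ($10^{-6}$ rad by default — the continuum model cannot
represent full network collapse, so we stop rather than pretend), and
classifies the terminal state. The standard experiments
(`make_fixture()`) mirror the bistability protocol: a symmetric start at
the cross-link angle stays stationary; a start whose rear angle is pushed
below the separatrix (default 0.05 rad below it) polarizes and moves; and
with $\overline{\mu^{TM}}$ lowered below the dominance threshold the myosin
state does not exist and every fixture reverts to the symmetric cross-link
state:

```{r}
run <- integrate_fragment(make_fixture("asymmetric", fd$params, fd$sfm)[[1]],
                          fd$params, fd$sfm, t_end = 120)
c(outcome = run$outcome, speed = round(run$terminal_speed, 4))
```

The slowest relaxation rate at the reference setup is
$|\lambda| \approx 0.25$ min⁻¹ (e-folding ≈ 4 min), so runs of 120–150
model minutes reach the steady-state classification tolerance
($|\dot{\text{state}}| < 10^{-8}$); the 15-minute horizon of the original
bistability experiments shows the qualitative outcome but not yet that
tolerance.

## Parameter dependencies

`sensitivity_report()` takes central finite differences of the polarized
state through the full steady-state computation. At the reference setup the
fragment speed increases with adhesion ($+$; the model lives in the
small-adhesion regime, where experiment also finds a positive correlation)
and with the myosin twisting constant ($+$, stronger myosin collapses the
rear further), while the myosin stretching constant leaves the equilibrium
angles and the speed unchanged (it enters only the drag, hence only
transients). One intermediate quantity deserves a remark: because $h' < 0$
at *both* stable angles, the two equilibrium angles co-vary with the common
torque level, with slope $d\omega_{MY}/d\omega_{CL} =
h'(\omega_{CL})/h'(\omega_{MY}) \approx +0.25$ at reference parameters; the
speed still rises with adhesion because
$\cos\omega_{CL} - (h'_{CL}/h'_{MY})\cos\omega_{MY} > 0$ there.

## What the fixtures do and do not show

All tests run on the reduced strip/fragment geometry with the reference
parameter table, programmatically generated initial conditions, and the
problem sizes quoted above (1000-point oracle grids, 120–150 min
trajectories, $\kappa$-halving pairs). Passing them establishes the internal
mathematics of the reduced model — root structure, stability, asymptotics,
and the equivalence of two independent derivations of the dynamics. It does
not establish fidelity to real fragments: the reduction has no leading-edge
curvature, no transition zone between front and rear lamellipodium, no rear
bundle, no membrane shape mechanics, constant polymerization speed, and
fixed filament density $\eta = 1$. The bistability mechanism itself, not
quantitative speeds of any particular cell, is the claim under test.

## Numerical choices

* **Roots**: per-branch closed forms everywhere (quadratics via the
  numerically stable $q$-formula); simplicity asserted via $|h'| >
  10^{-10}$.
* **Newton**: analytic Jacobian, step damping by residual decrease, domain
  guards at the angle floor and $\pi/2$; convergence at residual
  $10^{-11}$, per-seed failures reported without aborting other seeds.
* **Integration**: `lsoda` with `rtol = 10^{-10}`, `atol = 10^{-12}`; the
  size mode is much faster than the angle modes at simulation-scale slopes
  (stiffness ratio ≈ 500), which `lsoda` handles by switching to BDF.
* **Kink handling**: $h$ is only C⁰ at the cutoff angle; derivative-based
  quantities use the branch containing the evaluation point, and the
  convention at the kink itself is the above-cutoff branch.
* **Degenerate inputs**: $\omega = \pi/2$ is an admissible fixed point but a
  degenerate crossing geometry (the coordinate-change map warns);
  $\zeta = 0$ (immortal linkers) and $\varphi_0 \ge \bar\varphi$ are
  rejected at construction.
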