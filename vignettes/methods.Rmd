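---
title: "Coupled vascular–interstitial fluid transport: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled vascular–interstitial fluid transport: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumourflow)
```

This vignette is the package's own account of the science it implements:
the two-compartment fluid-transport model, its assumptions, the parameters
that matter and their defaults, the numerical choices, and the places where
the design was genuinely open and a decision had to be made. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

## The two-compartment model

### Vascular blood flow

A segmented microvascular network is a graph of nodes (3-D positions,
micron) and vessel segments (diameter $d_j$, centreline length $l_j$).
Degree-1 nodes are *boundary* nodes — terminals at which flow enters,
leaves, or dead-ends. Each segment carries Poiseuille flow,

$$Q_j = \frac{\pi d_j^4}{128\,\mu_j l_j}\,(p_{a} - p_{b}),$$

and flux is conserved at every interior junction, giving the nodal system
$\sum_k K_{ik} p_k = -Q_{0i}$ with $K = LM$ assembled from the signed
incidence and conductance matrices. The effective viscosity
$\mu_j(d_j, H)$ follows the empirical in vivo law for blood in
microvessels — apparent viscosity rising steeply below ~10 µm diameter
(the Fåhræus–Lindqvist regime) and with haematocrit. Discharge haematocrit
is uniform at $H = 0.45$: a haematocrit-splitting model would need data no
whole-tumour dataset provides, and the viscosity law accepts heterogeneous
$H$ later without structural change. Plasma viscosity defaults to 1.05 cP
and is configurable.

Assumptions worth keeping in view: steady laminar flow, rigid vessels
(no compliance or compression), Newtonian plasma with all non-Newtonian
behaviour absorbed into $\mu(d, H)$, and no pulsatility.

### Estimating unknown boundary conditions

Pressures or flows can realistically be assigned at only a handful of the
hundreds-to-thousands of boundary nodes. The remaining degrees of freedom
are fixed by a constrained least-squares principle: minimise

$$\tfrac{1}{2} k_p \sum_k w_k (p_k - p_0)^2 +
  \tfrac{1}{2} k_\tau \sum_j l_j (\tau_j - \tau_{0j})^2$$

subject to exact flux conservation, where $\tau_j = d_j\,\Delta p_j/(4 l_j)$
is the wall shear stress, $w_k$ is half the summed length of segments
incident to node $k$, and $p_0$, $\tau_0$ encode typical network
haemodynamics. Stationarity yields a sparse symmetric saddle system in
pressures and Lagrange multipliers. Because the target shear must have the
sign of the (unknown) flow direction, the solve sits in a fixed-point loop
over direction signs; zero-flow segments keep their previous direction, and
a segment that reverses five times has no stable preferred direction and
has its shear target zeroed so the loop can settle. The iteration cap is
100; the objective value is recorded each pass and is non-increasing.

Defaults: $p_0 = 31$ mmHg, $\tau_0 = 15$ dyn/cm², $k_p = 0.1$, and
$k_\tau$ auto-scaled on the first solve so both penalty terms are
comparable. All four are exposed; none is hard-coded. The constraint rows
are rescaled by the median segment conductance before factorisation — the
saddle system otherwise mixes $O(10^{-2})$ objective entries with
$O(10^{-8})$ conductances and becomes numerically singular for networks
with strongly heterogeneous diameters.

### Interstitial Darcy flow by Green's superposition

The interstitium is a porous medium with volume-averaged velocity
$\mathbf{u} = -\kappa \nabla p$ and far-field pressure
$p \to p_\infty$. The vasculature appears as $N_s$ point sources of
transvascular flux, one per sub-segment of length at most $\delta$
(default 50 µm), each regularized over a sphere whose radius equals the
local vessel radius. The kernel

$$G(r) = \begin{cases}
\dfrac{3 - (r/r_0)^2}{8\pi\kappa r_0}, & r \le r_0,\\[6pt]
\dfrac{1}{4\pi\kappa r}, & r > r_0,
\end{cases}$$

is continuous with continuous gradient at $r = r_0$ and corresponds to a
uniform volumetric source in the sphere. Pressure and velocity fields are
sums over sources; no volumetric mesh exists anywhere in the method, which
is what makes whole-network computations tractable and keeps artificial
outer boundary conditions out of the tissue domain.

Starling's law $J_v = L_p S (\Delta p - \sigma \Delta\Pi)$, integrated over
each source's vessel surface and combined with the superposed field,
closes a dense $N_s \times N_s$ linear system

$$\sum_j \Big(G_{ij} - \frac{\kappa_i}{L_{p,i}} \nabla G_{ij}\Big) q_j
  = p_{b,i} - p_\infty - \sigma_i (\Pi_b - \Pi_v).$$

The $\kappa_i/L_{p,i}$ coefficient follows from eliminating the wall
pressure: the vessel surface area cancels between the wall resistance
$1/(L_p S_i)$ and the integrated flux $-2\pi\kappa r_v l \sum_j \nabla
G_{ij} q_j$. The oncotic pressure difference is held fixed
($\Pi_b - \Pi_v = 5$ mmHg, $\sigma = 0.82$): protein transport is not
modelled.

Baseline parameters: $\kappa = 1.7\times10^{-7}$ cm²/mmHg/s,
$L_p = 2.8\times10^{-7}$ cm/mmHg/s, $p_\infty = 0$ mmHg (isolated
subcutaneous tissue without lymphatics). All may be per-source, which is
how the normalization scenarios install radially varying properties; for
heterogeneous $\kappa$ the kernel uses the conductivity of the evaluating
source — an approximation, since the variable-coefficient problem has no
closed-form kernel, implemented exactly as the equations are written.

### The self-interaction term

The diagonal of the source system is the one place the continuum equations
do not dictate the discretisation. Evaluated literally at $r = 0$ the
regularized kernel's gradient vanishes, so the self term contributes only
$G(0) = 3/(8\pi\kappa r_0)$; alternatives are to evaluate the self gradient
at the vessel wall, or to identify each source's wall flux with its own
strength. All three closures are implemented
(`interstitial_params(self_term = "drop" | "wall" | "identify")`), and the
default is `"drop"` — the equations as written. The reasons are physical,
not cosmetic. Under the wall and identify closures the wall resistance
enters each diagonal directly and the resulting wall pressure drop
$K_i J_{v,i}$ absorbs essentially the whole driving pressure
$p_b - p_\infty - \sigma\Delta\Pi$; any scheme that then feeds the wall
pressure back into the vascular boundary condition contracts the system
towards zero filtration and a uniform far-field interstitium, which is not
what whole-network simulations of leaky tumour vasculature report. Under
`"drop"` the wall permeability acts collectively through the
neighbour-interaction terms $(\kappa/L_p)\nabla G_{ij}$; the two physical
limits survive for multi-source networks ($L_p \to 0$ forces all strengths,
hence the IFP deviation from $p_\infty$, to zero; $L_p \to \infty$ recovers
the pure Green's system), and the feedback onto the vasculature is the
small correction the coupled iteration expects. The cost of `"drop"` is
that a *single isolated* source loses its $L_p$ sensitivity — the
single-source configurations in this package are used for closed-form
kernel checks, not permeability studies. Both alternative closures are
exercised in the test suite and validated against the finite-difference
oracle, which checks the field given the strengths and is satisfied by all
three.

### Coupling the compartments

The solved strengths drain fluid from (or return it to) the vessels, which
perturbs the intravascular pressures, which changes the Starling driving
terms. The fixed-point loop re-solves the Poiseuille network each iteration
with the per-source transvascular fluxes deposited on the segment endpoints
as nodal sinks, holding the boundary pressures of the reference solution
fixed, then re-interpolates the vascular pressure at each source and
re-solves the source system (the matrix inverse is computed once; only the
right-hand side moves). Because the transvascular losses are orders of
magnitude below the intravascular flows, the update is a contraction and
converges in two or three iterations on every shipped fixture, to a
tolerance of $10^{-6}$ µl/min on the largest strength update (cap 50).

A literal alternative — updating only the source pressures by
$p_b \leftarrow p_b - K_i J_{v,i}$ without re-solving the network — is
retained behind `resolve_vascular = FALSE` for sensitivity studies, with a
warning in its documentation: that map's only fixed point is zero
filtration, and depending on the self-term closure it either collapses to
the far-field solution or diverges. It is not the default for that reason.

## Boundary assignment and perfusion

Surface boundary nodes (within a depth tolerance — default twice the mean
vessel diameter — of the convex hull) are assumed to connect to the
peritumoural circulation. A seeded shuffle assigns the top
$\lfloor 0.05 n \rfloor$ (at least 2) of them a high or low pressure with
equal probability; an axis-aligned exclusion ellipsoid with principal
diameters 5% of the tissue dimensions prevents opposite extremes from
landing adjacent to each other (steep local gradients otherwise produce
unphysiological flows); conflicting draws are redrawn up to 100 per
assignment before a clear error. Of the remaining boundary nodes 33%
become zero-flux blind ends and the rest stay unknown for the estimator.
Default pressure extremes are 45/15 mmHg, with 30/20 mmHg the other
canonical pair; `calibrate_to_perfusion()` grid-searches pairs and seeds
until simulated perfusion matches a measured target within a relative
tolerance (default 20%).

Total tissue perfusion sums (i) vascular inflow at surface boundary nodes
and (ii) interstitial inflow through the hull surface, per 100 g of tissue
(hull volume × 1 g/cm³). The interstitial term uses a paired surface:
every hull vertex gets a partner 10 µm outward along its normal, the
pressure difference gives the normal Darcy velocity, and non-overlapping
spheres packed on the vertices turn vertex velocities into fluxes. Only
inflowing contributions count by default (`mode = "net"` subtracts
outflow). One numerical point deserves emphasis: a non-overlapping disc
packing covers only 72–83% of the surface *at every refinement level* —
porosity is scale-invariant — so the raw $\sum v_n \pi R^2$ sum is a
biased quadrature. The disc areas are therefore normalised to the true
hull area, which makes the estimator consistent under refinement; on the
central-source sphere fixture the hull outflow then recovers the enclosed
source strength to within a few percent, where the raw sum misses by the
porosity.

## Synthetic networks

Real whole-tumour vessel graphs are large and not generally available, so
the package ships seeded generators. `single_vessel`, `y_junction` and
`lattice3d` are deterministic test topologies. `tumour_like` grows
bifurcating trees inward from roots on an ellipsoid surface: branch
lengths are drawn around the target mean, child diameters follow a
Murray-type $2^{-1/3}$ taper with log-normal noise, tips terminate
stochastically (blind ends), are clipped onto the surface when they cross
it (becoming surface boundary nodes), and growth stops at the target
vascular density, with new tips budding from existing nodes if a cohort
exhausts early. Two amendments keep the fixture usable where a pure
multi-tree forest would not be: the roots are joined by a peritumoural
ring of segments, guaranteeing a single connected component, and all
diameters are rescaled multiplicatively to the target mean. A single
recalibration pass re-targets the branch-length draw and the stopping
volume so the realised statistics (measured against the convex hull, as
the summary statistics report them) land on the targets.

Default targets are the low-density colorectal-xenograft-like morphology —
mean diameter 8.9 ± 2.8 µm, mean branching length 88.8 µm, vascular
density 0.37% — in a ~2.2 mm ellipsoidal domain. The default domain is a
desk-scale fixture, two to three times smaller in radius than a real
tumour; since the interstitial screening length at baseline parameters is
millimetric, absolute IFP magnitudes on fixtures sit well below in vivo
values. What the fixture does reproduce — and what the tests assert — is
structure: core-elevated, radially decreasing IFP; mixed sources and
sinks; perfusion dominated by the surface vasculature; and the directions
of all parameter sensitivities. Passing tests on synthetic fixtures show
the machinery is correct at desk scale, not that any particular tumour's
absolute numbers are reproduced; the generator is test scaffolding, not a
mechanistic angiogenesis model (no flow-coupled remodelling, no real
tortuosity, i.i.d. rather than spatially correlated diameters).

## Validation oracles

Two independent reference paths guard the Green's-function machinery. The
closed-form single-source field checks the evaluators to machine
precision. A brute-force finite-difference solver discretises
$-\kappa\nabla^2 p = f$ on a uniform grid (7-point Laplacian, matrix-free
conjugate gradients) with each source deposited as a uniform density over
its sphere, discretely renormalised so the deposited total equals $q$
exactly. Its Dirichlet data defaults to the closed-form outer-kernel sum
on the box faces ("superposition"), exact whenever the faces lie outside
all source spheres: with plain far-field Dirichlet the monopole tail
$\sum q/(4\pi\kappa R)$ induces a near-constant truncation error of order
10% at any affordable box size, which would swamp the comparison the
oracle exists to make. The uniform-$p_\infty$ option remains available.
The oracle verifies the PDE, the kernel derivation, the source deposition
and interior superposition; second-order convergence is asserted against
the analytic single source, and the ten-source fixture agrees with the
superposed field to well under the 5% gate used in the acceptance suite.

## Numerical choices, degenerate inputs, determinism

* Internal units are {cm, s, mmHg}; geometry is stored in micron and flows
  reported in nl/min (vascular), µl/min (transvascular), velocities in
  µm/s, perfusion in ml/min/100g. One conversion table (`tf_units`) owns
  every factor.
* Linear solves: sparse LU for the nodal and saddle systems; one dense
  inverse for the source system (re-used across coupling iterations), with
  an unpreconditioned BiCGSTAB fallback above 20,000 sources.
* Coincident distinct sources fall on the regularized inner branch and
  warn; sources with $L_p = 0$ are excluded from the system with
  identically zero strength; networks with a disconnected component
  lacking a pressure condition error by name.
* Duplicate-node merging uses a 10⁻³ µm tolerance — below imaging
  resolution, above float noise. Segment lengths are trusted as centreline
  (tortuous) lengths and validated to be at least the endpoint chord.
* Every stochastic element — generation, boundary assignment, probe
  sampling, calibration — derives from explicit integer seeds; identical
  configuration and seed reproduce every number bit-exactly, and the run
  manifest records the configuration hash.
* Problem sizes in the shipped tests and acceptance script: fixtures of
  roughly 1,000–3,000 segments and 1,500–3,500 sources, oracle grids up to
  81³, chosen as the smallest sizes at which the qualitative tumour
  configuration (core-elevated IFP, mixed source/sink structure) is stable
  across seeds.

## Known limitations

Static vasculature (no compliance, compression, growth or pruning);
uniform haematocrit; fixed oncotic gradient; no lymphatics; no transient
dynamics; heterogeneous-$\kappa$ fields handled by a per-source kernel
approximation; single-source configurations lose $L_p$ sensitivity under
the default self-term closure (use `"wall"` for isolated-vessel studies);
and absolute field magnitudes on desk-scale synthetic fixtures are not
those of centimetre-scale tumours.
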