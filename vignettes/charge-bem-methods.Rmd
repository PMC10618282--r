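---
title: "Charge-based BEM for TMS electric fields: model, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge-based BEM for TMS electric fields: model, numerics, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical model

A TMS coil driven with a current slew rate $dI/dt$ produces a primary
(free-space, inductive) electric field.  Approximating the winding by
elementary current elements with positions $p_j$ and oriented length
vectors $m_j$,

$$E^p(r) = -\frac{\mu_0}{4\pi}\,\frac{dI}{dt}\sum_j \frac{m_j}{|r-p_j|},
\qquad \frac{\mu_0}{4\pi} = 10^{-7}\ \mathrm{exactly}.$$

In the quasistatic regime the head responds by accumulating surface charge
on every tissue conductivity interface.  Writing $c = \rho/\varepsilon_0$
for the scaled surface charge density (units V/m; $\varepsilon_0$ is a pure
normalization and never enters the solver), the total field off the
interfaces is the primary field plus the Coulomb field of the charges.
Approaching an interface with unit normal $n$ (pointing from the "in"
medium to the "out" medium), the two one-sided limits are the continuous
(principal-value) part plus the local planar charge sheet,
$E_{in/out} = E_{cont} \mp n\,c/2$, so the normal field jumps by exactly
$c$ across the sheet.

Current conservation, $\sigma_{in}\, n\cdot E_{in} =
\sigma_{out}\, n\cdot E_{out}$, turns this into a second-kind Fredholm
equation for $c$ with the conductivity contrast
$K = (\sigma_{in}-\sigma_{out})/(\sigma_{in}+\sigma_{out})$, $|K|\le 1$ for
non-negative conductivities.  With piecewise-constant charge per triangular
facet the discrete system is

$$A x = b,\qquad
A_{mn} = \tfrac12\delta_{mn} - \frac{K_m}{A_m}\, n_m\cdot
  \iint_{t_m t_n}\frac{1}{4\pi}\frac{r-r'}{|r-r'|^3}\,dr'\,dr,\qquad
b_m = K_m\, n_m\cdot \langle E^p\rangle_{t_m}.$$

The operator is identity-plus-compact and well conditioned, which is why
unpreconditioned, unrestarted GMRES converges in a few tens of iterations
regardless of mesh size.

Two solution paths expose the same system:

* **Iterative**: GMRES on a matrix-free operator whose far field is a fast
  point-charge summation (exact pairwise or treecode).
* **Direct**: assemble and factorize $A$ once, then solve for many
  right-hand sides — one per coil placement — at negligible per-solve cost.
  This is the work-flow for coil-position scans: the matrix depends only on
  the head model, the right-hand side only on the coil.

## Discretization and the near/far split

The inner (source) integral over a flat facet is evaluated in closed form:
the solid-angle term (van Oosterom–Strackee) carries the normal component
and the three edge-potential terms
$\ln\big((R^++s^+)/(R^-+s^-)\big)$ carry the in-plane components.  Each
edge term has two algebraically equal forms; the code picks the one with
the larger denominator, which keeps the formula stable arbitrarily close to
an edge.  On the facet's own plane the normal term is the principal value
(zero), so the flat-facet self entry is $A_{mm}=\tfrac12$ to machine
precision, and the two one-sided limits differ by exactly $\pm n/2$ per
unit $c$ — both properties are asserted in the tests rather than assumed.

The outer integral over the observation facet uses a symmetric barycentric
quadrature rule of order 1 (centroid collocation, the default), 3
(degree 2) or 7 (degree 5).  Centroid collocation keeps the classical
collocation reading of the system and is the cheapest; the degree-5 rule
roughly halves-to-thirds the field error on sphere benchmarks and is what
the sphere-validation workflow uses.  Interface-field audits evaluate the
continuous part with the same rule the solver used.  At centroid
collocation the continuity residual is then algebraically the collocated
equation residual and tracks the solver tolerance (RMS ~1e-8 at GMRES
tolerance 1e-6); at higher quadrature orders the operator still collocates
its far point-charge field at centroids, so the audit floors near 1e-4 of
the field scale rather than at the solver tolerance.

Facet pairs with centroid distance below $\eta(\rho_m+\rho_n)$ ($\rho$ =
facet circumradius) are integrated analytically; all other interactions
treat the source facet as a centroid point charge $q_n = x_n A_n$.  The
precision knob takes the values $10^{-1}\dots10^{-6}$ and controls both the
summation backend and $\eta$:

| precision | 1e-1 | 1e-2 | 1e-3 | 1e-4 | 1e-5 | 1e-6 |
|-----------|------|------|------|------|------|------|
| $\eta$    | 2    | 3    | 4    | 5    | 14   | 40   |

$\eta = 5$ at the default precision 1e-4.  Tighter precisions must enlarge
the analytic zone because beyond it the panel-to-point-charge substitution,
not the summation backend, limits the accuracy; at 1e-5/1e-6 on small
meshes the operator effectively becomes all-analytic and agrees with the
dense matrix to machine precision.  The near-field corrections are
precomputed once into a sparse matrix (about 250 pairs per facet on a
single level-4 icosphere at $\eta=5$, about 950 on the four-layer model
whose inter-surface gaps are small).

## Fast summation backend

The optional treecode is a Barnes–Hut octree with Cartesian moments up to
octupole order, stored in symmetric-reduced form.  A cluster is accepted
when (cluster radius)/(distance) $\le\theta$, with $\theta$ chosen per
precision level separately for the Coulomb-gradient kernel (charges) and
the slower-converging $1/R$ kernel (coil current elements).  The tables
were calibrated on random clouds, nested-sphere centroid sets and placed
coils so that the measured relative error sits a factor 2–10 below each
precision level; exact pairwise summation remains the default and is
always available.  We make no $O(N\log N)$ claims for the direct
factorization path — the compressed method's contract is accuracy, not
asymptotics.

## Direct factorization

The `"dense"` method is LU with partial pivoting on the analytically
assembled matrix (facet cap 20,000 by default, ~3.2 GB).  The
`"compressed"` method orders facets along a Morton space-filling curve
(octree-leaf order), partitions the matrix into blocks (256 by default),
replaces every off-diagonal block with an adaptive-rank truncated SVD whose
discarded Frobenius tail is below the requested precision, and then
performs the block elimination on the compressed operator.  On a 5120-facet
four-layer model at precision 1e-4 the mean off-diagonal rank is ~34 of
256 and the solution differs from the dense solve by ~3e-5.  Factorizations
serialize to a versioned binary container so one subject's decomposition
can be reused across sessions; multi-right-hand-side solves always iterate
column by column, which makes them bitwise identical to single solves by
construction.

## The analytic sphere reference

For a spherically symmetric conductor of outer radius $R$ and any radial
conductivity profile, the interior total field is $E = E^p - \nabla\varphi$
with $\varphi$ harmonic inside and $\partial\varphi/\partial r =
\hat r\cdot E^p$ on $r=R$.  Because $r\cdot E^p$ is itself harmonic
(divergence-free field with a harmonic vector potential), matching the
radial derivative on the surface cancels the radial component at every
interior point: the induced field is purely tangential and independent of
the layering.  The implementation expands the surface Neumann data in real
spherical harmonics (Gauss–Legendre $\times$ uniform-azimuth quadrature,
degree cap `lmax = 60` with a tail check at the outermost observation
radius) and evaluates $\nabla\varphi$ with analytic angular derivatives of
the normalized associated Legendre recursion.  Points on the $z$-axis sit
on a removable coordinate singularity and are nudged $10^{-7}$ off the
pole.  The gradient algebra is cross-checked in the tests by
finite-difference curl/divergence of $E^p - E$, and the whole construction
is validated against dense BEM solves: a coaxial loop (purely azimuthal
$E^p$) induces nothing, and homogeneous vs four-layer BEM models agree
with the same analytic field to a fraction of a percent at level-4 meshes.

## Synthetic study conditions

No external data is required.  The generator produces:

* **Head models**: nested icospheres, default radii 92/86/80/78 mm with
  SimNIBS-style conductivities 0.465 (scalp), 0.010 (skull), 1.654 (CSF),
  0.275 (brain) S/m; outside is air (0 S/m).  These values are
  configuration, not ground truth.  Icospheres have every vertex exactly on
  the sphere and `20 * 4^level` facets; level 4 gives 5120 facets per
  interface, edge length ~7 mm at scalp radius.
* **Coils**: a parametric figure-of-eight coil, two coplanar 35 mm wings
  of opposite winding sense, 64 segments per turn, driven at
  $dI/dt = 9.4\times10^7$ A/s, placed 10 mm above the scalp.  Arbitrary
  element tables (e.g. multi-layer or deformable windings) are accepted
  through a documented CSV format; no interpolation cache is ever used, so
  per-solve coil geometry changes are free.

What this emulates — and what it does not: the spheres reproduce the
multi-compartment, high-contrast structure of segmented head models
(including an insulating-skull layer with $K\approx-0.96$ and thin gaps
between interfaces) but not their anatomical curvature, handedness of
sulci, or meshing irregularity.  Passing the sphere benchmarks therefore
validates the formulation, the quadrature/near-field machinery and the
solvers, not segmentation quality or conductivity choices on real heads.
Tissue anisotropy is out of scope: the formulation is restricted to
piecewise-homogeneous compartments.

## Numerical choices and degenerate inputs

* Units are meters and S/m throughout; STL carries no units, so the loader
  takes a unit-scale factor (1e-3 for millimeter files).
* Vertex welding on STL load uses a grid of 1e-8 of the bounding-box
  diagonal; zero-area facets are reported by index.  A closed mesh wound
  inward (negative signed volume) is flipped with a warning — the sign
  conventions only require consistency.
* Indices are 1-based everywhere, following R convention.
* GMRES: no restart, no preconditioner, left residual relative to
  $\|b\|$, happy-breakdown handled (a zero-contrast model converges in one
  iteration with the exact solution $x = 2b$).
* Observation points closer to a facet than 0.1 of its circumradius are
  rejected by name; limiting values on the surfaces come from the jump
  relation instead.
* Error metrics are unweighted 2-norms over the supplied points by
  default; area weights and an outlier-trim fraction (default off) are
  options.
* The head-model manifest and run configurations are YAML; every closed
  surface is treated independently through its own
  $(\sigma_{in},\sigma_{out})$ pair, which also covers disjoint
  same-level compartments (eyes, ventricles).

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated
geometry, sized to validate each claim at the smallest scale where it is
meaningful: four-layer models at 20,480 facets for the GMRES iteration
bound, homogeneous spheres at 5,120/20,480 facets (one 1:4 refinement) for
the analytic-reference comparison, 5,120 facets for the
iterative-vs-direct and compressed-vs-dense comparisons, and 1,280 facets
for the matrix-free-vs-dense operator identity.  The radial-field bound of
1% (max norm) is met at the 20,480-facet refinement; at 5,120 facets the
maximum radial fraction is ~1.4% (RMS ~0.4%), dropping by ~2.5x per
refinement level, consistent with the first-order convergence of
flat-facet centroid collocation observed throughout.

## Known limitations

* Flat facets and piecewise-constant charges: field errors converge at
  roughly first order in edge length on curved anatomy; uniform 1:4
  refinement (`subdivide_1to4`, optionally with spherical reprojection for
  synthetic models) is the intended accuracy control.
* The compressed factorization performs its block elimination at dense
  cost; it demonstrates the accuracy contract of hierarchical low-rank
  direct solvers at desk scale rather than their asymptotic complexity.
* The analytic reference applies to spherically symmetric conductors
  only; no ellipsoidal or realistic-geometry closed forms are provided.
* Mesh repair is out of scope: badly broken surfaces are reported, not
  fixed.
* At `K = 1` (a conductor in air — every outermost interface) the
  continuum operator annihilates the constant charge mode, so the net
  induced charge, zero in the continuum, is only weakly determined by the
  discrete system: it stays a small bounded fraction (~1e-3 of the total
  absolute charge) instead of decreasing monotonically under refinement.
  For interfaces with `|K| < 1` the fraction sits at the far-field
  precision floor (~1e-5).
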