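# tmsbem

Charge-based boundary element modelling of the electric fields that
transcranial magnetic stimulation (TMS) coils induce in multi-compartment
surface head models.

## The problem and who this is for

Dosing and targeting TMS requires knowing the induced E-field inside the
head, and workflows such as motor mapping or stimulation planning need that
field for hundreds or thousands of candidate coil placements.  `tmsbem` is
for researchers who want a self-contained, testable implementation of the
surface-charge formulation of this problem: head anatomy enters only
through triangulated tissue interfaces (STL), coils only through tables of
elementary current elements, and everything — head models, coils, analytic
references — can also be generated synthetically, so the package runs and
validates itself without any external data.

## The model

A coil driven with slew rate dI/dt produces the primary inductive field

    E_p(r) = -(mu0/4pi) * dI/dt * sum_j m_j / |r - p_j|

from elements with positions `p_j` and oriented lengths `m_j`.  The head
responds with a surface charge density on every conductivity interface;
writing `c = rho/eps0` (V/m) and
`K = (sigma_in - sigma_out)/(sigma_in + sigma_out)` for the conductivity
contrast, current continuity across the interfaces gives a well-conditioned
second-kind Fredholm equation, discretized with one constant charge per
triangular facet:

    A x = b,   A_mn = 1/2 delta_mn - (K_m/A_m) n_m . Int_{t_m} Int_{t_n} (1/4pi) (r-r')/|r-r'|^3 dr' dr
               b_m  = K_m n_m . <E_p>_{t_m}

Near-facet interactions are integrated in closed form (solid angle plus
edge potentials); far interactions use centroid point charges summed
exactly or by a Barnes-Hut treecode.  The system is solved either

* **iteratively** — unrestarted GMRES on the matrix-free operator
  (converges in a few tens of iterations), or
* **directly** — factorize `A` once per head model (dense LU, or a
  block-low-rank compressed variant), then solve one right-hand side per
  coil placement at negligible cost, bitwise reproducibly.

The total field is `E = E_p + E_secondary`; one-sided interface limits
follow the jump relation `E_in/out = E_cont -/+ n c/2`.  An analytic
spherically-symmetric-conductor solution (spherical-harmonic Neumann
problem; the interior field is tangential and independent of the layering)
serves as ground truth for validation.

## Worked example

A four-layer sphere head (scalp/skull/CSF/brain, radii 92/86/80/78 mm,
SimNIBS-style conductivities) under a 35 mm figure-of-eight coil placed
10 mm above the scalp apex:

```r
library(tmsbem)
head <- nested_sphere_model(subdiv_level = 3)
head
#> head_model: 4 interfaces, 5120 facets
#>   1. scalp          1280 facets  sigma_in=0.465 sigma_out=0  K=+1.000
#>   2. skull          1280 facets  sigma_in=0.01 sigma_out=0.465  K=-0.958
#>   3. csf            1280 facets  sigma_in=1.65 sigma_out=0.01  K=+0.988
#>   4. brain          1280 facets  sigma_in=0.275 sigma_out=1.65  K=-0.715

coil <- place_coil(build_figure8_coil(didt = 9.4e7),
                   target = c(0, 0, 0.092), axis_dir = c(0, 0, -1),
                   handle_dir = c(1, 0, 0), standoff = 0.01)

op  <- bem_operator(head, precision = 1e-4)
rhs <- build_rhs(head, coil)
fit <- solve_iterative(op, rhs, tol = 1e-6, coil = coil)
fit
#> GMRES: 35 iterations, final relative residual 8.885e-07 (converged)

pts    <- sphere_points(0.064, level = 2)   # observation sphere in the brain
fields <- total_field(fit$solution, pts)
fields
#> field_samples: 162 points, |E| max 8.641, mean 1.359 V/m

roi <- roi_select(pts, target = c(0, 0, 0.064), radius = 0.02)
round(range(sqrt(rowSums(fields$E_total[roi, ]^2))), 2)
#> [1] 7.37 8.64
```

The 35 GMRES iterations and the ~8.6 V/m peak under the coil are what the
physics predicts: the skull layer (K = -0.96) shields the interior, the
field is strongest in the ROI beneath the coil center, and doubling dI/dt
would exactly double every field value.

For many placements, factorize once and reuse:

```r
fact <- factorize_direct(head, "dense")        # once per head model
x    <- solve_factored(fact, build_rhs(head, coil))   # per placement
```

Command-line wrappers (`solve`, `validate-sphere`, `scan`, `make-spheres`,
`make-coil`) live in `inst/cli/tmsbem`; configs are YAML, STL meshes and
coil CSV tables are the on-disk interfaces.

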