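# edgeom

Diffraction-geometry modelling, refinement and diagnostics for
continuous-rotation **electron diffraction** (ED).

Protein nanocrystals can be solved by the standard rotation method with
electrons instead of X-rays, but the geometry is extreme: at 200 kV the
electron wavelength is λ = 0.02508 Å — roughly 40 times shorter than a
12 keV X-ray's 1.0332 Å — so the Ewald sphere is almost flat (2θ ≈ 1.44°
at 1 Å resolution instead of 62.2°). That flatness makes the usual joint
least-squares refinement of beam, crystal and detector parameters
ill-conditioned: the unit-cell scale becomes nearly indistinguishable from
the effective detector distance, the handedness of rotation is hard to
determine, and the beam may drift during the scan. `edgeom` provides, for
users processing or studying rotation-method ED data:

* **Experiment models** — beam, multi-panel detector, goniometer, scan and
  crystal (reciprocal metrical matrix `g* = B Bᵀ` with lattice
  constraints), with a versioned JSON serialisation;
* **Ewald prediction** — closed-form rotation-method crossing angles
  `|R(φ) U B h + s0| = 1/λ`, centroid prediction onto panels, mapping of
  observations back to reciprocal space, nearest-integer index assignment;
* **Image preparation** — Timepix quad expansion (512×512 → 516×516 with
  a six-pixel cross and ×3 gain normalisation), gain estimation
  (variance/mean), dispersion-threshold spot finding, elliptical
  distortion-map generation and lookup-table pixel↔mm transforms, and a
  rotation-axis azimuth heuristic;
* **Refinement** — restraint-stabilised Levenberg–Marquardt refinement of
  the standard 13-parameter static model (6 detector + 1 beam + 3
  orientation + 3 cell for orthorhombic), parameter fixing, Tukey outlier
  rejection, and scan-varying crystal/beam models interpolated by a
  Gaussian smoother;
* **Diagnostics** — per-block corrgrams (pairwise correlations of Jacobian
  columns for the X, Y and φ residual blocks), the Jacobian condition
  number κ(J) = σ_max/σ_min, and a rotation-handedness comparison test;
* **A simulator** — fully synthetic ED and X-ray data sets sharing one
  crystal and scan (an orthorhombic lysozyme-like cell, 32 × 68 × 105 Å),
  with seeded centroid noise, smooth beam drift, lens distortion and
  rendered frames, so every claim can be checked against known ground
  truth.

## Worked example

Simulate a narrow-wedge ED data set (10° in 50 images, 0.3 px / 0.02°
centroid noise), perturb the model, refine with the stabilised protocol
(distance and the detector tilts fixed), and diagnose the conditioning:

```r
library(edgeom)

spec <- simulation_spec("ED", seed = 42)   # lambda 0.02508 A, 2000 mm
sim  <- simulate_reflections(spec)
sim$experiment
#> Experiment model
#>   beam:    lambda = 0.02508 A, direction = (0.0000, 0.0000, 1.0000)
#>   crystal: orthorhombic, cell = 32.000 68.000 105.000 A, 90.00 90.00 90.00 deg
#>   scan:    images 1..50, phi 0.000..10.000 deg
#>   detector: 1 panel(s)
nrow(sim$reflections)
#> [1] 1953

# start from a perturbed model: cell scaled by 1.003, orientation off by 0.15 deg
ex0 <- sim$experiment
cell <- cell_from_metrical(ex0$crystal$g_star); cell[1:3] <- cell[1:3] * 1.003
ex0$crystal <- crystal_model(rotation_about_axis(c(0, 0, 1), 0.15) %*% ex0$crystal$U,
                             metrical_from_cell(cell), "orthorhombic")

res <- refine_geometry(ex0, sim$reflections, fix = c("dist", "tau2", "tau3"))
res$rmsd
#>      x_px      y_px   phi_deg
#> 0.299     0.304     0.0204
cell_from_metrical(res$experiment$crystal$g_star)
#> [1]  32.0009  67.9973 105.0135  90.0000  90.0000  90.0000
```

The r.m.s.d.s sit at the simulated noise floor and the cell is recovered
to ~0.01 Å. The conditioning diagnostics show why the protocol fixes the
distance and tilts:

```r
b13 <- residuals_and_jacobian(build_parameterisation(res$experiment), res$obs)
condition_number(b13)
#> [1] 716400                      # 13-parameter ED problem
b10 <- residuals_and_jacobian(
  build_parameterisation(res$experiment, fix = c("dist", "tau2", "tau3")), res$obs)
condition_number(b10)
#> [1] 36930                       # ~19x better posed
```

Repeating the same refinement with the matched X-ray geometry (same
crystal, scan and reflections; only λ and distance change) gives
κ(J) ≈ 4.2 × 10³ — the ED problem is two to three orders of magnitude
worse posed purely because of its geometry. `corrgram_blocks(b13)` shows
the same story parameter-by-parameter, and
`handedness_test(experiment, reflections)` compares the φ residuals under
both rotation-axis hypotheses.

A command-line interface wrapping these functions is installed as
`exec/edgeom` (subcommands `simulate`, `timepix-expand`,
`make-distortion-maps`, `find-spots`, `predict`, `refine`, `diagnose`).

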