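---
title: "Diffraction geometry for continuous-rotation electron diffraction: models, refinement and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffraction geometry for continuous-rotation electron diffraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgeom)
```

## The problem

In the rotation method a crystal turns at constant velocity about a single
axis while diffraction images are recorded as contiguous angular wedges. A
reciprocal-lattice point \(\mathbf r = R(\varphi)\,U B\,\mathbf h\)
diffracts when it lies on the Ewald sphere,

\[
\bigl\lVert \mathbf r(\varphi) + \mathbf s_0 \bigr\rVert = 1/\lambda,
\qquad \mathbf s_0 = \hat{\mathbf d}/\lambda ,
\]

and the diffracted ray \(\mathbf s_1 = \mathbf s_0 + \mathbf r\) is recorded
on a detector panel. For 200 kV electrons \(\lambda = 0.02508\) Å, some 40
times shorter than a typical 12 keV X-ray wavelength (1.0332 Å), so the
Ewald sphere is nearly flat: the scattering angle at 1 Å resolution is
\(2\theta \approx 1.44^\circ\) instead of \(62.2^\circ\). Almost everything
that makes electron-diffraction (ED) geometry refinement hard follows from
this one number:

* a large *effective* detector distance (set by the projector lenses, not
  mechanically measurable) is needed to separate peaks;
* the sphere is locally almost invariant under a uniform change of scale,
  so the unit-cell volume and the detector distance become nearly
  indistinguishable;
* inverting the assumed sense of rotation still produces a regular
  reconstructed lattice, so the handedness of the scan is not obvious from
  indexing alone;
* the beam direction may drift during the scan because of charging and
  alignment instability.

This package models that geometry, simulates it with known ground truth,
refines it by restrained nonlinear least squares, and quantifies *why* the
refinement is ill-conditioned.

## Conventions

The lab frame is right-handed with the nominal beam along \(+z\) and the
nominal rotation axis along \(+x\); positive rotation is right-handed about
the axis, and an inverted-axis hypothesis is the negated axis vector.
Continuous pixel coordinates are 0-based with pixel centres at half-integer
coordinates; `origin + X*px_fast*fast_axis + Y*px_slow*slow_axis` is the
lab position of pixel coordinate (X, Y). Angles are degrees at every user
interface and radians internally. Physical constants are CODATA 2018
values frozen in one place.

The unit cell is carried as the reciprocal metrical matrix
\(g^* = B B^{\mathsf T}\); its independent elements (six for triclinic,
three diagonal elements for orthorhombic, one for cubic) are the cell
parameters seen by refinement, and `metrical_from_cell()` /
`cell_from_metrical()` convert to and from the familiar
\((a, b, c, \alpha, \beta, \gamma)\).

## Reflection prediction

Crossing angles are solved in closed form: decomposing
\(\mathbf r_0 = U B \mathbf h\) into components along and perpendicular to
the axis turns the Ewald condition into
\(A\cos\varphi + B\sin\varphi = C\), with zero, one or two solutions in
\([0^\circ, 360^\circ)\). Points near the rotation axis never satisfy the
condition (the blind region). A brute-force sign-change scan over
\(0.001^\circ\) steps exists in the tests as an independent oracle; the
closed form is the implementation.

Absolute crossing angles depend on the arbitrary crystal orientation at
\(\varphi = 0\); only differences are orientation-free. `calibrate_crossing()`
pre-rotates the crystal about the axis so a named reflection crosses at a
named angle, which is how the package reproduces printed crossing-angle
pairs (15.0° to 27.0° for the X-ray row, 12.1° to 12.4° for ED) from a
stated reference.

## Image preparation

A 512x512 Timepix quad is four abutting 256x256 ASICs whose boundary
pixels have roughly three times the ordinary pitch. `timepix_expand()`
splits each boundary row/column into three ordinary-width copies, each
**replicating** the full original count, and multiplies everything outside
the resulting six-pixel cross by three. The choice to replicate rather
than divide is deliberate: the cross then shows ~3x gain, which the global
x3 of the other pixels equalises, and the corrected frame is documented as
a Poisson detector with multiplicative gain 3.0.

Distortion is handled as in look-up-table correction schemes: a pair of
per-panel maps stores, for every pixel, the offset `corrected - raw` in
pixels for the fast and slow directions. Pixel-to-mm transforms apply the
*reverse* correction first and then scale; mm-to-pixel computes the raw
coordinate and then applies the correction. Look-ups are
nearest-neighbour with no interpolation; the reverse direction uses a
fixed-point iteration (at most 5 steps, tolerance 0.01 px), which
converges for the slowly varying maps produced by lens aberration. The
elliptical generator models anisotropic magnification — a circular powder
ring recorded as an ellipse — parameterised by a centre, a major/minor
scale pair and the major-axis angle; the stored offset takes each pixel to
its position under the *inverse* scaling so that applying the correction
restores circular symmetry.

The spot finder classifies a pixel as strong when its local window is
overdispersed relative to Poisson background
(\(\mathrm{var}/\mathrm{mean} > g\,(1 + \sigma_b\sqrt{2/(n-1)})\)), the
pixel stands above the local mean by \(\sigma_{\text{strong}}\) background
standard deviations, and it exceeds a global threshold. The default window
is 7x7 (kernel half-width 3): the window must be larger than a spot's core
for the local mean to represent background. Strong pixels merge by
8-connectivity; components smaller than `min_spot_size` (default 2) are
dropped; centroids are intensity-weighted. The rotation-axis azimuth
estimator exploits the depletion of spots along the axis through the beam
centre: a 36-bin azimuthal histogram (mod 180°), smoothed with a 3-bin
circular moving average, whose minimum marks the axis; results from fewer
than 50 spots, or without a clear minimum, carry a low-confidence flag.

## Refinement

The static model has the standard 13 free parameters for a single-panel
orthorhombic experiment: six detector (distance `dist`, in-plane
translations `shift1`/`shift2`, rotations `tau1`/`tau2`/`tau3`), one beam
orientation angle (`mu2`; `mu1`, the rotation about the spindle axis, is
fixed by default and only enters scan-varying beam refinement), three
crystal orientation angles `phi1`/`phi2`/`phi3`, and the three free
metrical elements. Angles are refined in mrad, distances in mm, and the
metrical elements in units of \(10^{-5}\,\text{Å}^{-2}\) — the conventional
scaling that brings their Jacobian columns to the same magnitude as the
geometric parameters; without it the condition-number diagnostic measures
the unit disparity instead of the geometry.

Residuals are ordered as the X block, then Y, then \(\varphi\) (pixels,
pixels, degrees), weighted by inverse centroid standard deviation (unit
weights when variances are absent). Derivatives are central finite
differences with steps of \(10^{-4}\) of a per-parameter characteristic
scale (1 mrad, \(10^{-6}\,\text{Å}^{-2}\), 0.01 mm); an independent
five-point stencil at a different step verifies them to \(10^{-5}\)
relative in the tests, which keeps the machinery self-validating without
analytic gradient code. The Levenberg–Marquardt driver starts its damping
at \(10^{-3}\max(\operatorname{diag}J^{\mathsf T}J)\), multiplies by 10 on
a rejected step and divides by 10 on acceptance, and stops when every
residual dimension's r.m.s.d. improves by less than 0.01% (or after 100
iterations — ED problems genuinely need far more than the historical cap
of 20).

Unit-cell restraints are pseudo-observations \(\sqrt{w}(a - a_t)\) with
\(w = 1/\sigma^2\), specified on the real-space cell for convenience;
restraints on parameters already fixed by the lattice symmetry are dropped
automatically (an orthorhombic cell keeps only a, b, c). As a guide,
\(\sigma \simeq 0.001\) is a strong restraint and \(\sigma \simeq 0.1\) a
weak one; even weak restraints stop the cell and the detector distance
drifting jointly when both are refined. Restraints apply to static cell
models only. Outliers are flagged (never deleted) by per-dimension Tukey
fences at 3 interquartile ranges — a deliberately blunt, distribution-free
stand-in for more elaborate schemes.

Scan-varying refinement replaces a parameter's single value by \(n\)
sample values evenly spaced across the scan, interpolated by a Gaussian
smoother (\(w_i = e^{-\Delta_i^2/\sigma_s^2}\), nearest three samples,
\(\sigma_s = 0.65\) sample spacings) — the defaults are 3 samples per
crystal orientation angle and 2 per beam angle, the simplest smoothed
model, which in practice tracks gradual beam drift remarkably well. All
detector parameters stay at their statically refined values during
scan-varying refinement. Scan-varying values are evaluated at the centre
of the image containing each observation's rotation centroid; within-image
parameter variation is far below the centroid noise for any smooth model.

Two degeneracies of the ED geometry deserve explicit mention because the
tests exercise them:

* **cell scale vs distance** — jointly scaling the detector distance and
  all cell lengths by 1.01 moves ED predictions by well under 0.05 px,
  while the same joint scaling moves high-angle X-ray predictions by more
  than a pixel. Refining with an accurately calibrated, *fixed* distance
  (and fixed `tau2`/`tau3`) is the stabilised protocol.
* **mean beam tilt vs detector shift** — a constant tilt of the beam about
  the spindle axis is almost exactly a detector translation; a static pass
  with free detector shifts therefore absorbs the *mean* of any beam
  drift, and scan-varying refinement recovers the drift *shape* about that
  mean. Recovering an absolute drift track requires trusting (fixing) the
  detector translations, which is how the drift-recovery test is run.

## Diagnostics

Each linearised step solves \(J\,\Delta p \approx \Delta r\). Two
diagnostics are computed from the final-step Jacobian, always excluding
restraint pseudo-observation rows so they describe the geometry alone, and
always on the *unweighted* Jacobian with residuals in physical units (mm,
mm, rad): centroid-variance weights belong to the estimator, not to the
geometry, and the physical-unit convention is the one under which the
characteristic ED-vs-X-ray conditioning contrast appears at its reported
size.

*Corrgrams* are the pairwise Pearson correlations between Jacobian
columns, computed per residual block (X, Y, \(\varphi\)) because
derivatives of different centroid dimensions come from different
distributions; columns with no effect in a block (all detector parameters
in the \(\varphi\) block) are omitted. The *condition number*
\(\kappa(J) = \sigma_{\max}/\sigma_{\min}\) summarises how well posed the
subproblem is; \(\kappa = \infty\) (smallest singular value below
\(10^{-14}\) of the largest) means a singular Jacobian.

On the package's matched simulated pair — identical crystal, scan,
reflection list and noise; only wavelength and distance differ —
refinement of the 13-parameter model gives \(\kappa(J_{\mathrm{ED}})\) of
order \(10^{5{-}6}\) against \(\kappa(J_{\mathrm{MX}})\) of order
\(10^{3}\), and fixing `dist`, `tau2` and `tau3` improves the ED
conditioning by more than an order of magnitude. These are the quantities
`scripts/acceptance.R` recomputes; the acceptance tests assert the orders
of magnitude and the ratios, not exact values, because they depend on the
details of the simulated data set.

The *handedness test* emulates how a pipeline would test the rotation
sense: under the inverted-axis hypothesis the reconstructed lattice is, in
the flat-sphere limit, the mirror image of the true one through the plane
perpendicular to the beam, so the compensating model is the mirrored
setting matrix with one basis vector negated (a pure re-indexing that
restores a proper rotation). Observations are re-indexed by
nearest-integer assignment under each hypothesis, the orientation angles
are refined with everything else fixed, and the \(\varphi\) r.m.s.d.s are
compared. For X-ray curvature the wrong hypothesis misfits by degrees; for
ED both fit well and only a small second-order curvature residual
separates them, so verdicts within 10% of each other — and any
single-image scan, which carries no rotation sense — are reported as
ambiguous.

## The simulator and what passing tests mean

`simulation_spec()` defaults define the study conditions: an orthorhombic
lysozyme-like cell (32, 68, 105 Å) with its short axis nearest the
rotation axis, a single 1024x1024 panel of 55 µm pixels, a narrow 10°
wedge of 50 images at 0.2°/image, centroid noise of 0.3 px / 0.02°, and a
3 Å resolution limit giving on the order of \(2\times10^3\) reflections —
values chosen to match the printed instrument parameters (λ = 0.02508 Å,
~2000 mm effective distance for ED; λ = 1.0332 Å with the distance set so
the same resolution limit meets the panel edge for X-rays) and kept
deliberately modest so the full closed loop (simulate, perturb, refine,
diagnose) runs in seconds. Beam drift is a half-cosine ramp (smooth, zero
slope at the ends) about the rotation axis; each Ewald crossing yields one
observation (no mosaicity, bandpass or partiality); spots on rendered
frames are Poisson-sampled Gaussian blobs on flat Poisson background. A
single seed threads every stochastic step, so identical specs reproduce
bitwise.

Passing tests therefore demonstrate internal consistency and correct
mathematics under idealised conditions — Gaussian centroid errors with
known variances, a rigid single panel, kinematic point-like reflections.
They do not demonstrate robustness to dynamical scattering, inelastic
background, mosaic spread, wide or uneven oscillation widths, or detector
defects beyond the smooth distortion model; those effects are outside the
geometric scope of the package.

## Numerical choices and known limitations

* Cross-validation of every derivative by finite differences trades some
  speed for self-validation; refinement of a 2000-reflection static model
  still converges in a few seconds.
* The statistical test for "constant" scan-varying tracks on static data
  compares the track spread with the scan-varying sample standard errors
  (from the final weighted normal matrix), because the scan-varying
  estimator is intrinsically noisier than the static one — by an order of
  magnitude for the sloppy ED directions — and that sloppiness is a real
  property of the model, not a defect of the fit.
* Crossings that leave the sphere's reach under a finite-difference probe
  are continued smoothly through the tangency point, keeping the Jacobian
  finite near blind-region boundaries.
* Restraint targets interact with the distance degeneracy exactly as
  intended: with the distance free, a weak restraint to the true cell
  pulls the refined cell to within 0.01 Å of it on noise-free data, but on
  real data a restraint to a *wrong* cell volume would be absorbed with
  little r.m.s.d. penalty — the diagnostics, not the residuals, reveal
  this.
* The CLI (`exec/edgeom`, or `edgeom_cli()` in-process) is a thin wrapper
  over the functions documented here: `simulate`, `timepix-expand`,
  `make-distortion-maps`, `find-spots`, `predict`, `refine`, `diagnose`,
  with flag > config-file > default precedence and a single `--seed`
  feeding all randomness.
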