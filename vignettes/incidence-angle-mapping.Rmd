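---
title: "Cranial mapping and the incidence-angle / attenuation relationship: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cranial mapping and the incidence-angle / attenuation relationship}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fusmap)
```

# The problem

A single-element therapeutic bowl (here 250 kHz, outer diameter 110 mm,
inner diameter 44 mm, radius of curvature 110 mm) focuses through the
skull. Two quantities drive planning:

* the **incidence angle** of the beam on the skull — defined as
  90° − α, where α is the angle between the propagation direction and
  the normal of a plane fitted to the sonicated patch of the outer skull
  surface. 90° is normal incidence; smaller values mean a more oblique
  hit;
* the **transcranial attenuation**
  a<sub>skull</sub>(%) = 100 (p<sub>FF</sub> − p<sub>skull</sub>)/p<sub>FF</sub>,
  the focal-pressure deficit relative to the free field.

The package's purpose is to compute the first from 3D skull maps (CT-like
volumes or stacked harmonic B-mode slices), to predict the second with a
wave solver on CT-derived acoustic maps, and to quantify their (negative,
approximately linear) relationship.

# Models

## HU to acoustic properties

CT intensity in Hounsfield units is mapped per voxel to density and sound
speed by linear interpolation between the nodes of a plain-text table
(`inst/extdata/hu_nodes.tsv`). The published coefficients behind such
mappings are not reproduced in the source experiments, so the table is a
documented, user-replaceable default spanning water (0 HU → 1000 kg/m³,
1482 m/s) to dense bone (2000 HU → 1900 kg/m³, 3942 m/s). The top speed
is chosen to make the maximum sound speed exactly 2.66× water, the ratio
that fixes the skull-side grid resolution. Values outside the node range
clamp to the end nodes; the map is monotone.

## Absorption and the y′ = 2 refit

Absorption follows α = α₀ f^y (dB/cm, f in MHz). A k-space solver cannot
vary the exponent spatially (and rejects y = 1), so literature values
quoted at other exponents are re-expressed at the working frequency:
α₀,new = α / f^y′ with y′ = 2. At 0.25 MHz, a bone value of
2.7 dB/cm/MHz (y = 1) gives α = 0.675 dB/cm and refits to
α₀,new = 10.8 dB/cm/MHz². With y = 2 the loss operator needs no
fractional Laplacian: it reduces to the thermoviscous closure
p = c₀²(ρ + τ ∂ρ/∂t), τ = 2 α c₀ (in Np·(rad/s)⁻²·m⁻¹ units), which the
solver implements locally in time via the already-available ∇·u. The
absorption *map* is heterogeneous: per voxel, α₀ interpolates linearly in
the normalized bone fraction (ρ − ρ_water)/(ρ_max − ρ_water), an interior
rule of this package (the sources state only the maximum value).

## Wave propagation

`run_pstd()` integrates the first-order linear acoustic equations with
spectral spatial derivatives on staggered grids, a k-space dispersion
correction sinc(c_ref k Δt/2) with c_ref = max sound speed, split-field
PML boundaries (default 10 cells, quartic profile), and the loss term
above. The time step is set by the Courant–Friedrichs–Lewy relation
Δt = CFL·Δx/c_max with CFL = 0.2 (0.4 mm in water → 54 ns). 1D, 2D and
3D run through the same code path; 2D is a first-class mode used for
desk-scale experiments, with a matched 2D oracle (below) rather than the
3D one.

Sources: the bowl is voxelized as the set of grid points within half a
grid step of the sphere of radius = focal distance about the geometric
focus, restricted to the annular aperture; all voxels are driven in
phase, so focusing is purely geometric. Drives are sine bursts with a
half-Hann ramp (default 2 cycles; 15-cycle bursts for the therapeutic
pulse). Per-voxel maximum |p| is recorded after a 2-cycle start-up
window.

## Free-field oracle

`oneil_reference()` integrates exp(ikR)/R over the spherical-cap annulus
(midpoint quadrature; the on-axis case has a closed form used to verify
the quadrature to 0.1%). On these profiles the axial and lateral
half-maximum widths of the default bowl in water are ≈ 59.6 mm and
7.2 mm. The 2D solver mode is checked against `oneil_reference_2d()`,
the focused-arc integral with the H₀ Hankel Green's function — measured
agreement of the lateral width is ~0.2% at 10 points per wavelength
(ppw). A full-3D solver run of this bowl at ≥10 ppw is beyond desk scale
in pure R, which is why the cross-validation runs in 2D and the absolute
free-field numbers come from the Rayleigh integral.

## Incidence angle

From a binary skull volume seen from the transducer: (1) the first
bone-entry crossing per beam-parallel voxel column (half-voxel midpoint
interpolation) gives the outer surface; (2) points outside the focusing
cone are dropped — at axial depth z the cone radius is
r(z) = (OD/2)(F − z)/F; the central-hole shadow is *not* carved out
(the sonicated patch is the full cone cross-section, a documented
reading); (3) a total-least-squares plane fit (smallest principal
component of the centred points) gives the normal, oriented toward the
transducer; (4) the angle uses |n·axis|, making the result independent of
normal orientation. On tilted-slab phantoms the full pipeline recovers
the constructed angle to well under 1° for tilts 0–45°.

# The synthetic-data generator

There are no deposited skulls or acquisitions, so the phantom module is
the data source for every test:

* **Slabs** — a plane of bone of stated thickness rotated by the tilt
  pair; truth (normal, incidence angle, surface points, thickness) is
  analytic. Partial-volume voxels get linearly interpolated HU so that
  surface positions are meaningful at subvoxel scale. A consequence
  worth stating: the half-amplitude surface is the geometric surface, so
  binarizing at 400 HU is exact for 800-HU bone and dilates by
  (0.5 − 400/HU_bone) voxels per face for brighter bone — the package's
  tests assert exactly that, rather than pretending thresholding is
  bias-free.
* **Shells** — spherical caps with sinusoidal thickness ripple, straight
  suture grooves carved into the inner table, and cylindrical orbit
  holes; the constructed thickness and local obliquity are recorded per
  beam column.
* **B-mode stacks** — slices show the truth mask at amplitude 1 over a
  0.05 background, degraded by multiplicative unit-mean Rayleigh speckle
  (blend fraction 0.5) and additive Gaussian noise at a stated SNR, then
  normalized to [0, 1] per slice so the 0.19 threshold applies. The noise
  model is a stand-in chosen once — the source images' speckle statistics
  are not characterized anywhere — so a green segmentation test
  establishes correctness of the chain, not scanner realism. With SNR =
  ∞ the model is off and thresholding recovers truth exactly.
* **Channel data** — straight-ray time-of-flight echoes from point
  scatterers for a 64-element, 20.48 mm sub-aperture phased array
  (element count, pitch and sampling rate are undocumented in the
  sources and are package assumptions), with 1/r decay on both legs, a
  virtual source half an aperture behind the array, per-event polarity,
  and a stated second-harmonic fraction. Pulse inversion and
  delay-and-sum beamforming are exercised on this model; multiple
  scattering and aberration are deliberately absent.

# The desk-scale sweep (stated world)

`cmd_sweep()` reproduces the eight-simulation incidence/attenuation
experiment at desk scale:

* geometry scaled by 70/110 (focus 70 mm; f-number and ID/OD preserved);
* the slab's outer surface 30 mm proximal to the focus — the stated
  placement of the geometric focus below the skull surface — where the
  focusing cone radius is 15 mm;
* eight tilts, 5–40° in 5° steps (incidence ≈ 50–85°), the range the
  sweep property is specified over; no tilt at exactly 0° because a
  perfectly flat slab at exact normal incidence forms a degenerate
  resonator with the source;
* bone of 1500 HU and 4 mm thickness; absorption map from 0 (water) to
  10.8 dB/cm/MHz² (bone maximum); 15-cycle 250 kHz bursts; CFL 0.2;
* 2D propagation at Δx = 0.6 mm (≈10 ppw in water). The spec'd
  desk-scale band is 6–10 ppw; at 7.4 ppw (0.8 mm) the attenuation
  *ordering* of the two near-normal tilts was not grid-converged (a
  0.16-percentage-point inversion that disappears at 10 ppw), so the
  default sits at the converged top of the band.

The measured outcome (computed by the acceptance test, not asserted from
memory): attenuation falls monotonically as incidence → 90°, linear fit
slope ≈ −0.36 %/degree, R² ≈ 0.92, axial focal shifts of a few mm. The
published R² values (0.84 simulated, 0.81 ex vivo) are *not* reproducible
targets: they belong to two specific primate skulls that were never
deposited; the package reproduces the relationship, not the sample.

# Numerical choices and degenerate inputs

* FWHM is measured on the pressure (−6 dB) profile by linear
  interpolation at the half-maximum crossings of the contiguous
  above-half region containing the peak; truncated profiles raise an
  error instead of returning a lower bound.
* Focal peaks use a separable three-point quadratic refinement, ties
  breaking to the lowest column-major index.
* Registration maximizes a soft Dice overlap: centroid-difference
  translation initialization, coarse Euler-angle grid, Nelder–Mead
  refinement; rotation convention is extrinsic X-Y-Z about the moving
  centroid. It is a deterministic surrogate for external tools, adequate
  for the ≤1 voxel / ≤1° recovery the tests require, not a general
  registration engine.
* Thickness is measured along the probe line (column convention), not
  along the local surface normal — whether the published caliper lines
  were columns or normals is unstated; columns were chosen and the
  obliquity map is provided to convert.
* `segment_slice` thresholds at exactly ≥ 0.19 of normalized amplitude;
  polygon restriction and minimum-component filtering are deterministic.
* Water constants (1482 m/s, 1000 kg/m³) appear once in
  `water_constants()`.
* Empty scatterer lists give all-zero traces; empty masks error; a bowl
  clipped by the PML errors with the overhang listed.

# Known limitations

* Pure-R pseudospectral stepping makes full-3D transcranial runs at
  publication resolution impractical; 3D is reserved for small grids and
  the free field is validated against the analytic oracle instead.
* Fluid-only bone model: no shear conversion, so very oblique incidence
  is less attenuating than in elastic reality.
* The delay-and-sum beamformer assumes a homogeneous sound speed
  (1482 m/s) — no refraction or aberration correction.
* The angle–attenuation relationship is demonstrated on flat slabs;
  curved skulls mix incidence angles across the footprint and flatten
  the plateau near normal incidence.
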