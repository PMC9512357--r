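---
title: "A dual-source phase-space model with a simplified voxel Monte Carlo photon engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-source phase-space model with a simplified voxel Monte Carlo photon engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Monte Carlo dose calculation starts from a *phase space*: the positions,
directions and energies of the photons crossing a plane below the
accelerator head.  Simulating the head itself is far too slow for routine
use, so `vsmDose` replaces it with a *virtual source model*: a small number
of Gaussian-shaped photon sources on the beam axis.  Two sources are used
for a 6 MV Versa HD-type head, for both the flattened and the
flattening-filter-free (FFF) beam quality: a narrow source at the nominal
target position (sigma 1.5-2 mm) carrying ~95% of the weight, and a broad
source (sigma 24 mm) at the flattening-filter / primary-collimator level
(150 mm downstream) representing head scatter.

The coordinate system has its origin at the nominal source, +z toward the
patient (IEC61217 rotated 180 degrees about x).  A fluence grid of
`I x J = 800 x 800` points with 0.5 mm spacing is defined at the isocenter
plane (`d` = 1000 mm), starting at `g = -200 mm`:
`x_d = g_x + i dx`.  For a source at `s_n`, each grid point projects onto
the phase-space plane (`p` = 548 mm, the accessory ring) at
`x_p = x_d (p - s_n)/(d - s_n)`, and the emitted particle travels from the
source through that point.

Collimator settings and the radial fluence profile are expressed at the
isocenter plane *with primary-source divergence*.  Seen from a secondary
source, a grid point must therefore be mapped through the collimator plane
(`c` = 401.8 mm, the bottom of the MLC leaves) into primary-divergent
coordinates, `x'_d = x_d d (c - s_n) / (c (d - s_n))`, before testing it
against the aperture or looking up the profile.  The point-source fluence is

> `Phi(i,j) = phi(r'_d) * omega(x'_d, y'_d)`,

where `phi` is the tabulated radial profile (flat with ~3-6% horns for the
flattened beam; monotonically falling for FFF) and `omega` is the aperture
function of the y-jaws plus the 160-leaf, 5-mm-pitch MLC (1 inside, MLC
transmission outside; transmission defaults to 0).

Finite source size enters by convolving `Phi` with a 2-D Gaussian whose
width at the phase-space plane follows from projecting the source through
the collimator aperture: `sigma_p = sigma (p - c)/(c - s_n)`.  The
calibrated map for one segment is

> `Phi'(i,j) = w_n * M * A * F(sqrt(A)) * C * (Phi (x) Omega)`,

with `M` the segment monitor units, `A` the open aperture area at
isocenter, `F` the collimator scatter factor, and `C` an absolute
calibration factor (2.02e-14 flattened, 2.18e-14 FFF).

### Aperture-area bookkeeping

The scalar product `M * A * F * C` fixes the *total* particle content of the
beam.  Because the grid integral of `Phi` already grows linearly with the
open area, the package interprets the per-cell particle content as fluence
density times cell area: each segment contributes
`w_n * M * F(sqrt(A)) * C * dx * dy * (Phi (x) Omega)`, so the beam total is
proportional to `M * A * F * C * mean(phi)` and the *central density* is
proportional to `M * F * C * phi(0)`.  Carrying the literal `A` into the
per-cell content as well would make central-axis dose scale with aperture
area, i.e. a 100 mm field would deliver 100x the central dose of a 10 mm
field at equal monitor units, which contradicts both measured output-factor
behaviour and the stated purpose of the factor (scaling the number of
transported particles with the aperture).  `composeFluence()` retains the
literal scalar product for single-segment maps; `computePhaseSpace()`
applies the per-cell form, and all dose results flow from the latter.

### Masking and sampling

Per beam, cells below 1% of the beam's maximum intensity (after
calibration; the threshold is relative, so the stage at which scalars are
applied is immaterial within one beam) are excluded from both the sampling
mask and the integral fluence.  This reproduces the practical efficiency
cutoff of rejection sampling: without it most proposals land in the
near-zero halo.

Particles are emitted by rejection sampling: the source in proportion to
its masked integral, the cell uniformly-proposed and accepted with
probability `Phi'/max(Phi')`, the energy by rejection sampling of the 10
tabulated spectrum lines (0.5-6 MeV; the spectrum was hardened during
commissioning so that the 100 mm depth dose is matched, and is treated as
discrete lines).  A uniform intra-cell jitter (one design choice the model
leaves open) is applied so that 0.5 mm lattice structure does not alias
into 2 mm dose voxels; expected fluence is unchanged.  Streams are
reproducible given a seed.

## The transport engine

The dose engine is a deliberately *simplified* voxel Monte Carlo: the
phase-space model is the contribution here, and central-axis dose ratios at
100 mm depth are insensitive to fine electron-transport detail.  It is not
a condensed-history code; the interface (`simulateDose()`) accepts any
particle stream, so a higher-fidelity engine can be substituted.

* **Photons** are tracked with Woodcock (fictitious-interaction) sampling
  through the voxel grid — simple and unbiased in mostly-water phantoms.
  Interactions: Compton scattering with Klein-Nishina-sampled energy/angle
  (closed-form total cross section times electron density), photoelectric
  absorption (compact power-law tables), pair production above 1.022 MeV
  with the annihilation photons emitted back-to-back at the interaction
  site.  Rayleigh scattering is omitted (a few percent of interactions, no
  dose transport effect at these energies).
* **Electrons** (and positrons) travel in straight lines with
  continuous-slowing-down energy loss deposited along 1 mm steps and
  Highland-model Gaussian angular diffusion per step.  Cutoffs: photons
  0.05 MeV, electrons 0.2 MeV (residual range < half a voxel), deposited
  locally.  Bremsstrahlung is neglected.
* **Materials**: water, air, lung (tissue composition at low density) and
  bone, assigned from density ranges; CT input goes through a
  Hounsfield-to-electron-density table and a linear empirical
  density formula (`huToDensity()`), both packaged as an editable config.
* **Uncertainty** is estimated from history-batch variance per voxel; the
  stopping rule averages it over voxels above 50% of the current maximum
  (the assessment region is a package choice; a 1.5% target is typical for
  clinical reconstruction).
* **Scaling**: the accumulated dose is multiplied by
  `integral fluence / histories`, converting to dose per particle and then
  to the particle count implied by the monitor units and `C`.  Output
  factors are invariant to `C` by construction.
* **Filtering**: a median window filter (radius 3 voxels; radius 1 for
  10 mm fields, whose high-dose core would otherwise be smoothed away)
  suppresses residual statistical noise.

Dose is scored to medium in medium.  The absolute scale inherits the
units convention of `C` (which the source model leaves implicit); all
evaluation quantities shipped here — output factors, profiles, gamma pass
rates on a common scale — are ratios and are unaffected.

## Evaluation protocol

The standard benchmark is a 300 mm water cube at 2 mm voxels with the
beam axis normal to a face.  The model geometry does not fix the SSD; the
package places the isocenter at 100 mm depth (SSD 900 mm) so that the
output-factor point lies at the isocenter.  Output factors are the dose at
the (possibly offset) field center at 100 mm depth relative to the centered
100 x 100 mm field at the same depth; point doses are read as 3 x 3 x 3
voxel neighborhood means, an explicit noise-control choice applied
identically to test and reference.  Histories per run scale with the open
area (clipped to 1e6-8e6, 2e6 for the reference field), mirroring how
history counts must grow with aperture at fixed point-dose statistics.

The gamma comparison (`gammaPassRate()`) is global and one-directional
(reference versus evaluated): per reference voxel above a 10%-of-maximum
threshold, the minimum over a search sphere of radius 3 DTA of
`sqrt((dose diff / criterion)^2 + (distance / DTA)^2)`, with trilinear
sub-voxel interpolation of the evaluated grid on a 0.2 mm lattice.  The
pass rate is the percentage of evaluated voxels with gamma < 1.  Pass
rates are monotone in both criteria; swapping the grids is not exactly
symmetric, which is inherent to the definition.

## Synthetic fixtures

`generateFixture()` builds every input needed to exercise the pipeline
without external data: centered and offset square fields on the water cube,
and two toy step-and-shoot IMRT plans — 7 equally spaced coplanar beams
with 28 segments (prostate-like) in water, and 15 beams with 30 segments
(lung-like) on a phantom with a 0.26 g/cm^3 low-density block surrounding a
20 mm unit-density target.  The toy plans match realistic beam/segment
counts, MU scales and gantry spacing, but their aperture shapes are
synthetic (jittered conformal openings); they exercise multi-beam,
multi-segment accumulation and heterogeneity handling, not any patient's
anatomy.  All fixtures are deterministic in (kind, parameters, seed).

What passing tests on these fixtures shows: geometric faithfulness of the
projections, conservation and statistical correctness of sampling and
transport, and correct composition of multi-segment beams.  What they do
not show: agreement with measured data of any specific machine, electron
contamination (absent from the source model, hence the low surface dose),
or tongue-and-groove/rounded-leaf-end MLC detail (transmission is zero).

## Numerical choices

* Table lookups (`interpProfile()`) are piecewise linear, clamped to the
  last value beyond the final knot (profiles end at zero by construction);
  `F(A)` for arbitrary apertures is looked up at the equivalent square
  `sqrt(A)` — the table is indexed by square-field width and the
  calibration is defined on square beams.
* Gaussian kernels are truncated at 5 sigma and renormalized to unit sum
  (< 1e-5 mass perturbation); the convolution runs as separable 1-D FFTs
  with power-of-two zero padding, and equals direct summation to < 1e-6.
  Per-source kernels use the source's own plane spacing
  `dx (p - s_n)/(d - s_n)`.
* Aperture intervals are half-open `[low, high)`, so boundary points belong
  to exactly one leaf and areas are additive; closed leaf pairs park with
  zero gap (dosimetrically irrelevant at zero transmission, but
  representable).  Leaf ends are straight.
* Degenerate inputs: a zero-area aperture composes to an all-zero grid; an
  all-zero (fully masked) beam refuses to sample; empty particle streams,
  crossed jaws and wrong leaf counts raise descriptive errors.
* Test problem sizes: module tests run 1e5-4e5 histories on coarse (4 mm)
  or standard grids; the output-factor benchmark runs 1e6-8e6 histories
  per field at 2 mm voxels, the scale at which point-dose noise after
  filtering is a few tenths of a percent to ~1%.

## Known limitations

* The engine is simplified by design (straight-line CSDA electrons, no
  bremsstrahlung, no Rayleigh, discrete spectrum).  Depth of maximum is
  slightly deep and surface dose low relative to a full condensed-history
  code with electron contamination; field-size-dependent ratios agree with
  standard water dosimetry at the few-percent level.
* A collimator scatter factor table `F(A)` of the kind packaged here is
  commissioned *on a particular pipeline*: it absorbs whatever field-size
  dependence that pipeline's head model already produces.  This package
  models the occlusion of the broad secondary source by small apertures
  explicitly (it is the physical mechanism of the head-scatter-factor drop,
  ~4% at 30 mm for a 6% source-2 weight).  Combining that explicit
  occlusion with an `F(A)` table commissioned on a pipeline in which the
  occlusion did not reach the measurement point double-counts part of the
  small-field output drop; full-pipeline output factors then sit 2-5%
  below such a table's reference column, worst for the 10 mm field.  The
  table is data: recommissioning `F(A)` against a local reference (set
  `F = 1`, run the square fields, divide) removes the bias for a given
  engine.
* Electron contamination is not modeled at all, so buildup-region
  comparisons against convolution-type references are expected to fail
  gamma locally.
* MLC transmission defaults to zero; setting it nonzero is supported by the
  aperture function but uncalibrated.
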