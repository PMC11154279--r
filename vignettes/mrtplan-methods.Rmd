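---
title: "Microbeam dose calculation in mrtplan: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbeam dose calculation in mrtplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtplan)
```

## The problem

Microbeam radiation therapy (MRT) irradiates tissue with an array of planar
X-ray beamlets a few tens of micrometres wide, spaced a few hundred
micrometres apart.  The biologically relevant quantities — peak dose, valley
dose, and their ratio (PVDR) — live on the micrometre scale, while photon
transport through a subject happens on the centimetre scale.  Simulating
both at once is wasteful; `mrtplan` therefore uses a hybrid two-stage
algorithm, adapted to a *divergent* kilovoltage source such as a collimated
small-animal irradiator (synchrotron MRT beams are quasi-parallel, and the
divergence changes the physics qualitatively: beamlets widen with depth, and
adjacent penumbras eventually overlap).

## Stage 1: macroscopic photon dose

`simulate_photon_dose()` transports photons through the voxel phantom and
scores, per voxel, the dose from first-time interacting photons
(`d_primary`) separately from all later interactions (`d_scatter`).

* **Source model.**  Photon positions are drawn from a 2D Gaussian focal
  spot (standard deviation `sigma_mm`), energies from the tube spectrum,
  and directions through a uniformly sampled point of the field aperture at
  the collimator plane.  Inverse-square fall-off emerges from the geometry
  rather than being imposed.
* **Collimator.**  The micrometre slit structure is *not* simulated at this
  stage; the aperture fluence is scaled by the collimator's mean
  transmittance (duty cycle plus septum leakage).  This matches the
  unit-period-mean normalisation of the fluence pattern in stage 2, so that
  `d_primary` is exactly the period-averaged primary dose of a voxel.
* **Physics.**  Photoelectric absorption and incoherent scattering with the
  Klein–Nishina differential cross-section (Kahn sampling).  The
  photoelectric channel is obtained as the difference between the tabulated
  total attenuation and the Klein–Nishina cross-section, so the total
  attenuation is exact by construction.  Coherent (Rayleigh) scattering is
  not transported; its small cross-section at these energies remains in the
  absorption channel.  Photons below 10 keV (the table floor) deposit
  locally.
* **Scoring.**  Kerma approximation: the energy transferred to electrons is
  deposited at the interaction site.  This is correct *by construction*
  within the hybrid algorithm, because lateral electron transport is applied
  in stage 2 and only matters on the micrometre scale.
* **Tracking.**  Woodcock (delta) tracking against a per-energy majorant,
  fully vectorised; batches (default 10) provide a per-voxel statistical
  uncertainty estimate.  All randomness flows from the single `seed`
  argument; identical seeds give bit-identical grids.

`primary_dose_deterministic()` is a noise-free companion (polyenergetic
Beer–Lambert ray trace with the same cross-sections and energy-transfer
weighting) used in calibration loops; the Monte Carlo primary converges to
it.  Attenuation paths are taken along the depth axis of each voxel column —
the divergent rays of the fields considered here deviate from the column by
under 3°, a sub-percent path-length effect.  `scatter_kernel_estimate()` is
a single-scatter point-kernel surrogate, flagged `approximate`; it is useful
for qualitative build-up behaviour, not for plan numbers.

## Stage 2: micrometre profile reconstruction

Inside a voxel at source distance `y`, the lateral dose profile is

\[ D(x) = D_{primary}\,(\vartheta \circledast K_{el})(x) + D_{scatter}, \]

with the primary fluence pattern
\(\vartheta(x)=\int f_s(x')\,f_c(x''(x,x'))\,dx'\) built from the focal-spot
profile \(f_s\) and the collimator transmittance \(f_c\), and the scatter
dose added as a flat pedestal (scattered photons are taken as uniformly
distributed within a voxel).  Two equivalent evaluations of \(\vartheta\)
are implemented and cross-checked in the tests:

* a **direct evaluation** of the integral, which for a Gaussian source and a
  piecewise-constant transmittance reduces exactly to sums of normal-CDF
  differences over the slits (no discretisation in the source variable); and
* the **rescaled-convolution fast path**: the transmittance magnified by
  `y/sd` convolved with the focal-spot profile rescaled by `(y - sd)/sd`.
  The mirror sign of the rescaling for planes beyond the collimator is a
  reflection, irrelevant for the symmetric Gaussian but preserved in the
  direct form through the absolute value of the rescaling factor.

Convolutions run on a zero-padded FFT grid; the transmittance is sampled
with area-weighted (anti-aliased) pixels so that slit edges do not alias at
the default 1 µm pitch (30 samples across the slit).  The pattern is
normalised to unit mean over one projected period, giving the testable
conservation law *period mean of the profile = `d_primary` + `d_scatter`*.

**Electron kernel.**  The 1D lateral electron scatter kernel is a
spectrum-weighted sum of two exponentials whose ranges scale as the inverse
mass density; the long range follows the continuous-slowing-down range of
the mean Compton electron set in motion by the spectrum (a power-law fit
\(R \approx 1.43\cdot10^{-2}\,(T/100\,\mathrm{keV})^{1.7}\) g/cm²), the
short range (¼ of it) models the dense low-energy electron cloud.  At
kilovoltage energies secondary electrons have micrometre-scale ranges, so
the kernel is narrow and the beamlet width is dominated by the geometric
penumbra — consistent with the observation that the profile FWHM grows
rapidly with depth.  This parameterisation is a deliberate stand-in for a
Monte Carlo–derived kernel: any measured kernel can be supplied as a
two-column CSV and replaces it.

**Metric extraction.**  `profile_metrics()` finds peaks by local-maximum
search, merges candidates not separated by a real dip (>1% prominence,
which collapses plateau tops to their centre), refines positions
parabolically, and reports: mean interior peak height; valley dose (default:
profile value at inter-peak midpoints; alternative: mean over the central
50% of each inter-peak interval — both are reported by `compute_plan()`
because "valley dose" has no unique operational definition); FWHM from
interpolated half-maximum crossings; and the measured period as the mean
peak spacing.  Beyond the depth where adjacent peaks merge above half
maximum, FWHM ceases to exist and is reported as `NA`.

## Materials, spectrum, and CT input

* **Attenuation tables** for air, lung, water, soft tissue, PMMA, cortical
  bone, aluminium, tungsten and lead ship as CSV (10–300 keV, log-log
  interpolation).  They are transcriptions of the standard photon
  cross-section compilations; the tungsten and lead tables simplify the
  L-edge fine structure (noted in the files), which only matters for septum
  leakage where the transmitted fraction is below 10⁻³ anyway.
* **Spectrum model.**  `generate_spectrum()` uses the Kramers law —
  bremsstrahlung *intensity* proportional to `(kvp − E)`, hence photon
  fluence proportional to `(kvp − E)/E` — plus the tungsten K lines above
  their excitation threshold (8% of the unfiltered fluence, split by the
  standard relative line intensities), Beer–Lambert-hardened by the
  aluminium filtration.  For 225 kVp + 1 mm Al this gives a mean energy of
  ~64 keV.  The distinction between the intensity and fluence reading of
  Kramers' law is not cosmetic: a fluence-proportional continuum is
  substantially harder (~88 keV mean) and visibly distorts the depth
  structure of the valley dose.  A measured spectrum can be supplied as a
  two-column table.
* **HU mapping.**  A standard four-segment scheme (air / lung-like / soft
  tissue / bone at −850, −100, +120 HU) with a piecewise-linear density
  ramp, continuous inside each segment and monotone overall.  This is a
  documented stand-in for a scanner-specific stoichiometric calibration,
  and it round-trips exactly for the four CT classes.  Phantoms are
  exchanged as NIfTI HU volumes with a JSON sidecar.

## Planning

`compute_plan()` runs stage 1, reconstructs per-depth normalised profiles,
and aggregates over the target ROI: per-voxel peak and valley dose rates use
the voxel's own `d_primary` but the slab-averaged `d_scatter` as the
pedestal (the model already treats scatter as uniform within a voxel, and
per-voxel Monte Carlo scatter estimates are noise-dominated at practical
history counts).  The mean PVDR is reported both as the ratio of ROI means
and as the ROI mean of per-voxel ratios, since either convention is
defensible.  Report identities — irradiation time = prescription / mean peak
rate, accumulated valley dose = valley rate × time — hold to machine
precision.  Gantry/couch rotations resample the phantom onto the beam frame
(nearest-neighbour), since the transport fast paths assume a fixed beam
axis.  Stage positioning offsets are checked against the 50 mm travel of the
motorised stages.

**Absolute dose scale.**  The engine computes dose per photon history.  One
scalar machine-output factor (histories per minute per mm² of field
aperture, so that dose rates compare physically across field sizes) converts
to dose rate; it is fixed once against the measured mean peak dose rate of
the reference brain treatment (2.3 Gy/min under the 20 × 20 mm² field) and
is overridable per plan.  All shape quantities (PVDR, FWHM, period, depth
structure) are independent of it.

`depth_dose_report()` produces the depth table of peak/valley/PVDR/FWHM/
period.  The valley-vs-depth curve is smoothed with a 5 mm running mean and
its interior local maxima are annotated after a 2% prominence filter (below
the Monte Carlo noise floor at the default history counts, maxima would
otherwise be spurious).  Physically, the shallow maximum is scatter
build-up; the deep one arises where the diverging beamlet penumbras overlap
— `penumbra_overlap_depth()` gives the closed-form geometric onset, about
37 mm beyond the collimator for the calibrated source.

## Calibration

* **Focal spot.**  `fit_focal_spot_sigma()` is a bounded 1D least-squares
  over `σ ∈ [0.05, 3]` mm against measured profiles, with a per-profile
  amplitude scale fitted in closed form so that shape calibration is
  decoupled from absolute dosimetry.  A curvature-based interval accompanies
  the estimate.  On synthetic profiles the objective is unimodal, noiseless
  recovery is exact to <0.5%, and 2% multiplicative noise perturbs the
  recovered σ by well under 5%.
* **Film.**  `fit_film_calibration()` fits the rational radiochromic dose
  response `D(gv) = a + b/(gv + c)` by nonlinear least squares
  (Levenberg–Marquardt).  The alternative linear reading of that three-
  parameter form is degenerate (two parameters collinear) and is therefore
  not offered.  Application outside the fitted gray-value range clamps and
  flags rather than extrapolating.

## Protracted exposures

At ~0.1 Gy/min valley dose rates, irradiations last long enough for
sublesion repair.  `lea_catcheside_g()` evaluates the protraction factor for
constant-rate exposure under mono-exponential repair (series expansion below
`λT = 10⁻⁴` keeps the acute limit exact), and `equivalent_short_dose()`
returns the acute dose with equal biologically effective dose, i.e. the
positive root of \(D_s^2 + (\alpha/\beta)D_s = (\alpha/\beta)D_p + G D_p^2\).
This is the unique reading consistent with the identity \(D_s = D_p\) at
`G = 1`; the repair rate carries units of 1/h (a rate, not a dose rate).
With the stated reference inputs (α/β = 2 Gy, λ = 0.5/h, T = 1 h,
D_p = 10 Gy) the root is ≈ 9.3 Gy.

## What the synthetic generators do and do not emulate

`make_slab_phantom()` reproduces the homogeneous dosimetry phantoms;
`make_mouse_head_phantom()` is an idealised layer stack (PMMA bed, soft
tissue, skull, brain, skull, skin) that places the brain target at 9–15 mm
depth.  These capture the radiological path lengths and material contrasts
that drive the dose calculation, but not anatomical curvature, CT noise,
partial-volume HU, or positioning uncertainty — so passing tests demonstrate
the correctness of the transport and reconstruction machinery, not clinical
accuracy on real images.  Film-versus-calculation agreement claims require
physical film measurements and are outside what this package can verify.

## Numerical choices and problem sizes

Default profile pitch 1 µm (≥30 samples per slit; coarser than slit/10 is
refused); FFT grids padded to the next power of two, patterns built with a
margin of 5 projected source sigmas plus the kernel support to avoid
wrap-around; log-log interpolation for all cross-sections with hard errors
outside 10–300 keV; 1 mm voxels by default.  The depth-structure studies in
the tests and the acceptance script use the 100 × 54 × 54 mm³ PMMA phantom
at 1 mm voxels with 1–2 × 10⁶ histories — enough to pin the deeper valley
maximum to ±2 mm — and the mouse-head plan uses 4 × 10⁵ histories, at which
ROI-mean rates are stable to ~1%.

## Known limitations

* Kilovoltage cross-sections are interpolated from bundled tables with
  simplified high-Z edge structure; no separate coherent channel.
* The electron kernel is an analytic stand-in; replace it with a
  Monte Carlo kernel via CSV for quantitative beamlet-edge work.
* The 8° collimator tilt is absorbed into the calibrated σ rather than
  modelled geometrically, exactly as in the calibration that defines σ.
* The deterministic primary path ignores ray slant within a voxel column;
  the single-scatter estimate assumes a homogeneous effective medium.
* No DICOM-RT export, no GUI, no registration; CT input is NIfTI HU.
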