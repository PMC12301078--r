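---
title: "Methods: automated 4DCT imaging QA on a simulated motion phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated 4DCT imaging QA on a simulated motion phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Four-dimensional CT (4DCT) reconstructs a breathing-resolved image set by
retrospectively sorting projections into respiratory bins. Radiotherapy
departments that treat moving thoracic and abdominal targets must verify,
periodically and after scanner changes, that (a) a moving object's measured
dimensions and motion range in the binned images agree with the physical
truth (spatial integrity), (b) CT numbers are stable across bins (HU
consistency), and (c) image quality — spatial resolution, low-contrast
performance, noise, uniformity — is consistent with the stationary baseline.
The standard instrument is a Catphan-style modular image-quality phantom
riding on a programmable motion platform: the phantom's sensitometry plugs
double as high-contrast motion surrogates, while its other modules carry the
image-quality test objects.

`qa4dct` implements the analysis side of this workflow as a library plus a
small CLI, and adds a synthetic phantom/4DCT simulator that stands in for
the physical phantom + motion platform + scanner chain so the entire
pipeline can be exercised, tested and regression-checked at desk scale.

## Phantom model

A `phantom_geometry` is purely declarative: a material table (name, nominal
HU), a background cylinder, and axial modules (sensitometry, uniformity,
spatial-resolution, low-contrast). The packaged geometries for phantom
models 504 and 604 use the manufacturer-nominal sensitometry plug
dimensions — 12.3 mm diameter, 25.0 mm length, with the model-604 air plug
33.0 mm long — and conventional nominal CT numbers (air −1000 HU, LDPE
−100 HU, acrylic 120 HU; Teflon 990, polystyrene −35, PMP −200, Delrin 340
as configuration defaults). Plug angular positions, the 50 mm marker
spacing, the bead position and the low-contrast target set follow common
Catphan module conventions; none of these is an algorithmic constant — all
are overridable through the YAML geometry config (`load_geometry()`),
because a phantom revision is configuration, not code.

Coordinates are right-handed patient-style axes (X lateral, Y
anterior-posterior, Z axial = table/motion direction), in mm relative to
the sensitometry module center. Distance markers are modeled as short
z-aligned rods rather than points so their in-plane centroids remain sharp
under axial motion blur, which is what a distance measurement needs.

## Synthetic data generator

The simulator is first-class, tested code; its defaults are the study
conditions the rest of the package is validated under.

**Rendering.** Each primitive (body cylinder, module fills, plugs, rods,
low-contrast discs, bead sphere) is rasterized with partial-volume
coverage: exact interval overlap along Z for z-aligned cylinders,
`supersampling^2` sub-pixel samples for in-plane rim pixels (default 4),
and `supersampling^3` (minimum 4) for the bead sphere. Primitives are
alpha-blended in order, so a plug embedded in the body gets the correct
mixed HU at its rim. The volume is then convolved with an isotropic
Gaussian PSF (default sigma 0.5 mm, chosen to put the 10%-MTF near
6.8 lp/cm, typical of a clinical body kernel at 1 mm pixels); kernels are
sampled at the voxel pitch, renormalized, and near-delta kernels skipped.
Default grid: 1 x 1 mm in-plane, 2 mm slices (a typical lung 4DCT
protocol), sized from the geometry with fixed margins so renders at
different displacements share one grid.

**Motion and binning.** Rigid displacement of the whole phantom follows
either an analytic sinusoid (default: 15 mm peak-to-peak along Z — the
standard QA amplitude — with periods 3/6/10 s used by the acceptance runs)
or a sampled trace. Phase 0 is anchored at peak displacement; with one
sub-sample per bin, bins are sampled at their start so a 10-bin set hits
both trace extremes exactly — this makes noiseless amplitude recovery exact
by construction, which is the property the amplitude test verifies.
Intra-bin motion blur is modeled by averaging renderings at
`intra_bin_samples` (default 3) sub-displacements per bin rather than
simulating slice-by-slice acquisition; this captures the dominant
motion-blur effect the analysis must be robust to, at desk-scale cost.
Amplitude-mode binning splits the principal-axis displacement range into
equal intervals and represents each interval by evenly spread order
statistics of its trace samples (deterministic; inhale/exhale direction is
not separated). A deterministic "patient-like" trace — two incommensurate
sinusoids plus a slow drift on Z, smaller correlated X/Y components — is
bundled for the 3D-motion and binning-mode comparisons, since real patient
traces are not shipped.

**Noise.** Additive, Gaussian, independent per voxel, applied after
intra-bin averaging, seeded per volume from the acquisition seed (default
10 HU, in the range clinical protocols show). The simulator does not model
helical acquisition timing, reconstruction kernels, tube-current
modulation, or irregular-breathing binning artifacts — passing tests say
the *analysis* is accurate on well-formed binned data, not that any
scanner's artifacts are benign.

## Localization and FWHM dimensioning

The phantom pose is the centroid of the body-threshold mask (midpoint of
air and background nominal HU; a 1 mHU offset makes knife-edge
partial-volume voxels deterministic), corrected by the known body-center
offset; in-plane rotation comes from the marker constellation when
resolvable. Because the mask centroid tracks the displaced phantom, plug
search boxes follow the motion automatically.

Each plug is segmented by thresholding at the midpoint of its nominal HU
and the local background nominal HU — a reproducible, config-visible
definition of the half-maximum level — inside a search box around the
expected position (in-plane margin: half the plug diameter, capped at
6 mm, so ring neighbors and markers stay outside). The largest 6-connected
component is kept; its unweighted voxel centroid is the plug position
(intensity weighting is deliberately not used; the cost is a sub-voxel
quantization of centroids, well inside the 1 mm bounds at 2 mm slices with
25 mm plugs). ROI HU statistics use the region core after eroding a
~1.8 mm rim (at least one voxel per axis), which excludes both
partial-volume and motion-blur ramp voxels; with plain one-voxel erosion,
fine-sliced scans leak blurred rim voxels into the mean and bias moving-bin
HU by a few HU.

Dimensions are full widths at half maximum of axis-parallel profiles
through the centroid, each averaged over a 3x3 perpendicular neighborhood
to stabilize noisy bins (this does not bias flat-topped profiles). The
half level is baseline + (peak − baseline)/2 with the background nominal
HU as baseline and the profile extremum as peak; crossings are linearly
interpolated, scanning outward from the extremum and keeping the outermost
crossing (ties resolve toward the wider width). Air-like plugs are handled
by negation and give exactly the mirrored result. FWHM at a fixed fraction
is the reason the method tolerates blur: convolving a flat-topped profile
with a unimodal kernel moves both half-crossings with the kernel median,
so the width is nearly preserved even when edges smear.

An independent contour-based oracle (`contour_plug_measure()`) re-measures
plugs at the same half level but by brute-force iso-contour bounding
extents (outermost sub-voxel crossings over every grid line, maximum over
lines) with no component filtering, profile averaging or erosion shared
with the pipeline; agreement within 1 mm on simulated bins is an
acceptance criterion, mirroring a manual contour measurement in a
treatment-planning system.

## Spatial integrity, projections, image quality

Per plug and axis, the spatial-integrity dimension metric is the mean FWHM
over all bins minus the stationary FWHM (all bins enter the mean; no
outlier rejection). Motion amplitude is the extent (max − min) of the plug
centroid across bins, per axis, compared to the trace peak-to-peak; for 1D
motion the Z component is the headline number, and surrogates are reported
per plug. The average CT, MIP and MinIP are voxelwise mean/max/min across
bins; the projection check measures the plug z-FWHM in the paired
projection (Teflon–MIP, Air–MinIP) against stationary z-FWHM plus the
input amplitude. On the simulator this check shows the same ~0.5 mm
underestimation seen on real scanners — envelope edges are built from
extreme-displacement renderings that spend little time at the extremes, so
their half-level crossings pull slightly inward.

Image-quality metrics follow their conventional definitions: geometric
distortion as |mean measured marker-pair distance − nominal|; spatial
resolution as the 10% crossing of the MTF computed from the 2D FFT of the
background-subtracted, z-summed bead image, radially averaged, normalized
at DC, with the analytic uniform-sphere transform divided out (capped at
80% of Nyquist; if the modulation never falls to 0.10 below the cap, the
cap frequency is reported with a saturation flag — unavoidable at 1 mm
pixels whenever the true f10 exceeds the 5 lp/cm Nyquist limit, e.g. for
any Gaussian PSF narrower than ~0.68 mm, so the closed-form MTF validation
runs on 0.25 mm grids); low-contrast detectability as the smallest
1%-contrast disc whose ROI contrast over the annulus standard deviation
reaches a configurable decision threshold (default 2.0 — deterministic and
auditable, unlike human reading); HU constancy as the maximum absolute
deviation of the air/LDPE/acrylic means from −1000/−100/120 HU;
uniformity as the maximum |peripheral − center| over four 10%-diameter
ROIs at 80% radius (center-ROI only is prescribed by convention; the
peripheral sizes are config defaults); noise as the sample SD in the
central disc of 40% module diameter; CNR as (polystyrene − LDPE) mean
difference over the quadrature sum of their SDs (an arithmetic-sum
denominator is available for software-matching studies). Per-bin metrics
aggregate as unweighted mean ± sample SD across bins.

## Reporting and tolerances

`run_qa()` orchestrates localization, spatial integrity, derived volumes,
HU consistency and the IQ suite, degrading per-test failures to `"error"`
and absent inputs to `"skipped"`, never aborting the report; a corrupt bin
is recorded in `bin_errors` and the remaining bins still produce results.
Default tolerances (1 mm spatial, 2 HU consistency) are labeled initial
values — they match what a well-commissioned scanner achieves, but sites
are expected to derive their own action limits from longitudinal data,
which is what `compare_to_baseline()` supports. Reports serialize to JSON
(canonical) and CSV; an HTML rendering is intentionally out of scope.

## Numerical choices and problem sizes

Worth stating explicitly:

* Sub-voxel FWHM crossings are linear interpolations of the piecewise
  coverage profile; at 2 mm slices a flat-ended plug measures ~0.33 mm
  short when its end falls mid-gap — within the half-slice tolerance the
  dimension checks use.
* Thresholds at exact partial-volume midpoints are knife-edge; all
  threshold comparisons carry a 1 mHU offset so inclusion is deterministic.
* The body-mask pose, plug detection and all ROI metrics are pure
  functions of the volume; the whole metric suite is bit-reproducible for
  a fixed simulation seed.
* Validation problem sizes: unit tests run a one-third-scale geometry
  (renders in ~0.2 s) with 1 mm slices so plugs span as many slices as the
  full-size phantom at 2 mm; the acceptance runs use the full 200 mm
  geometry, 10 bins, 3 sub-samples per bin, three trace periods and fixed
  seeds — about a minute per simulated scan.

## Known limitations

* The simulator's blur/noise model is deliberately minimal; vendor
  reconstruction effects, binning artifacts from irregular breathing, and
  absolute scanner-specific metric values are out of scope.
* Binary (unweighted) centroids quantize at coarse slice spacing; with
  very short plugs on thick slices the amplitude quantization error grows
  toward the slice thickness.
* Amplitude binning does not separate inhale from exhale directions.
* Phantom rotation handling is limited to small in-plane rotations from
  the marker constellation; deformable or large-rotation registration is a
  non-goal.
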