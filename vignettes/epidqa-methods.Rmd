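---
title: "epidqa: models and methods for automated linac QA image analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{epidqa: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidqa)
```

## Scope and data model

`epidqa` automates the image-analysis half of periodic linear-accelerator
quality assurance: it *builds* the QA delivery (jaw/MLC control-point
sequences serialized as DICOM RT-Plan or a JSON instruction format),
*renders* the EPID portal image such a delivery would produce (with
injectable delivery errors, so every analyzer is testable offline), and
*analyzes* portal images for the standard periodic tests: jaw junction,
light-radiation coincidence, picket fence, Winston-Lutz, and VMAT
constancy (gamma and band statistics).

One coordinate convention is shared by all three stages: IEC 61217, all
positions in millimetres *in the isocenter plane*, `x` crossplane (image
columns), `y` inplane (image rows). A detector pixel `(r, c)` maps to
isocenter-plane mm as `(index - cax) * spacing * SAD/SID`. Keeping a
single convention avoids the double magnification bookkeeping that
otherwise creeps in between plan, phantom and detector frames.

## The test statistics

**Junction.** Abutting jaw-delimited half fields should deliver a flat
dose across their match line. The statistic is

$$J = \frac{I_{junc} - I_{BG}}{I_{rad} - I_{BG}} - 1,$$

with `I_junc` the junction-line intensity, `I_rad` the open-field
reading and `I_BG` the background. `J = 0` is a perfect match, `J = +1`
a doubled junction dose, `J = -1` a cold gap; the test passes within
±0.3. `J` is invariant under any affine intensity rescaling applied to
all three readings, so it needs no dosimetric calibration. The
literature defining this statistic names the three readings but not
their sampling regions; we take `I_junc` as the extremum within ±3 mm of the
nominal line (largest excursion from the plateau, so gaps and overlaps
are both caught), `I_rad` as the profile mean at least 10 mm from the
junction and the field edges, and `I_BG` from the image corners. When a
plan carries both a vertical and a horizontal junction, each is
evaluated and the worst decides the verdict; the perpendicular profile
is sampled 10-30 mm away from the crossing junction so the two lines do
not contaminate each other.

**Light-radiation coincidence.** A phantom places radio-opaque ball
bearings at known positions in the *light* field; their projected
image positions are compared with the detected *radiation* field
edges. The innermost BBs sit nominally 5 mm inside each field edge, so
`deviation = (distance to nearest 50% edge) - 5 mm` per inner BB, with
a 2 mm default tolerance. The synthetic phantom uses eight BBs (per
field side: one inner at 5 mm, one outer at 25 mm inset); the exact
outer layout of the clinical phantom is not fully specified anywhere,
so the outer ring is configurable and excluded from the deviation
statistic. An SSD misplacement magnifies the whole BB pattern by
`SAD/SSD`; an in-plane shift translates it; the radiation edges are
unaffected by either -- this is exactly what the analyzer must detect.

**Picket fence.** A narrow DMLC slit dwells at regularly spaced
positions, leaving intensity stripes. Per active leaf pair, the
crossplane profile is averaged over the central 60% of the pair's row
band; per picket, the stripe position is the parabolically interpolated
maximum within ± half the picket spacing of the expected control-point
center. Deviations are reported as `expected - measured`, so a +2 mm
delivered leaf offset appears as a -2 mm mean deviation, and the leaf
passes when |deviation| <= 1 mm. Stripes with no maximum above half the
stripe plateau are flagged undetected and excluded from the passing
denominator rather than counted as failures.

**VMAT bands.** For dose-rate/gantry-speed (7 bands) and MLC-speed
(4 bands) constancy tests, each band ROI's mean reading `R` is
corrected by the matching open-field reading, `R/R_open`, removing the
off-axis beam shape; per-band percent differences are taken from the
mean corrected reading and the summary is the mean absolute percent
difference, with a ±1.5% per-band tolerance. The printed source formula
for this statistic is typographically garbled, so the implementation
follows the prose definition; the invariances (separate global
rescalings of either image cancel; signed differences average to zero)
are enforced by tests. Band ROIs are inset 5 mm from the band
boundaries so delivery penumbra does not dilute the band means.

**Gamma.** The static-gantry VMAT images are compared against the
0-degree image by a global-normalization 2D gamma (dose difference as a
percentage of the reference maximum; sub-pixel spatial search by
bilinear interpolation over a disk of radius 3×DTA). Criteria default
to 3%/3 mm with a 10% low-dose cutoff but are fully configurable, since
published tolerance guidance for these fields is deliberately left to
the institution. The implementation is verified against an exhaustive
brute-force search oracle on small grids.

**Winston-Lutz.** Field center from the midpoints of the 50% edges, BB
center from the blob detector, offset vector and magnitude in mm.

## The synthetic EPID renderer

The renderer is the package's stand-in for linac acquisition and the
test bed for every analyzer. Its model is deliberately minimal:

* **Edges** are error functions: a field `[a, b]` projects to
  `pnorm((x-a)/sigma) - pnorm((x-b)/sigma)` with `sigma` = 1.5 mm at
  isocenter by default. Two abutting erf edges sum exactly to a flat
  profile, which is what makes the junction test meaningful.
* **BBs** are multiplicative attenuation disks (default 4 mm diameter,
  25% contrast) blurred by the same sigma.
* **Picket stripes** are the meterset-weighted integral of the slit
  fluence over the control-point sequence, confined per leaf pair to
  its transverse band.
* **Noise** is additive Gaussian with sd = `noiseSigma` × plateau
  (default 0.01 where a study needs noise), always behind an explicit
  seed; every render is deterministic given (plan, config, error, seed).
* **Geometry**: the default grid is 512×512 at 0.75 mm detector pixels,
  SID 1500 / SAD 1000 mm — 0.5 mm sampling over a ±128 mm isocenter
  field of view, which resolves sub-0.1 mm positions through sub-pixel
  interpolation while keeping a full render under a second.

What the renderer does *not* model: scatter, EPID glare/ghosting,
tongue-and-groove, rounded leaf ends, beam spectra, absolute dose. Tests
passing on these renders therefore demonstrate the *analysis* chain
(geometry, statistics, detection logic, serialization) under controlled
truth, not detector physics; clinical commissioning of tolerances is
still the institution's job.

With the default 1.5 mm penumbra, 2 mm junction gaps/overlaps land at
|J| ≈ 0.25 (inside the ±0.3 tolerance) and 4 mm errors at |J| ≈ 0.41
(outside). On a machine with a sharper effective penumbra the 2 mm
errors would fail too; the sensitivity study's ground truth is defined
as the analyzer verdict on the noiseless render, which keeps the
contingency tables internally consistent whatever the penumbra.

## Numerical choices

* Field edge = 50% of the background-subtracted plateau, located by
  linear interpolation between the bracketing pixels; outermost
  crossings are used so a junction dip inside the field cannot be
  mistaken for an edge.
* BB segmentation first *flat-field corrects* the image by the fitted
  erf-edge model, so blobs near the field border keep their circular
  footprint instead of smearing into the penumbra; a 1-pixel Gaussian
  smoothing stabilizes blob boundaries under noise. Circularity is
  scored as `area / (pi * r_max^2)` (1.0 for a disk, ≈0.64 for a
  square), cutoff 0.9; blob radius must be within ±50% of the expected
  BB radius. A centroid closer than 1.5 penumbra widths + 0.5 mm to a
  50% edge is treated as merged with the edge and not returned -- the
  analyzer reports that BB as undetected, mirroring how automated
  detection loses edge-adjacent markers that a human could still mark.
  Note that a BB-sized square attenuator genuinely *becomes* a disk
  after penumbra blurring; shape rejection is only meaningful above
  roughly twice the penumbra width.
* Stripe maxima use three-point parabolic interpolation; at 0.5 mm
  sampling this recovers positions to well under 0.05 mm on noiseless
  renders.
* Percent-passing denominators count detected leaves only; undetected
  stripes warn.
* Control-point resampling is linear per machine axis between
  neighbouring control points, endpoint-preserving and idempotent once
  the spacing bound is met. Dwell-and-move sequences (picket fence) are
  piecewise constant in meterset, so "trajectory passes through the
  original nodes" is only meaningful for strictly increasing weights.
* DICOM: explicit VR little endian, one MLCX boundary table per plan
  (Millennium-120 default: 10×10 mm, 40×5 mm, 10×10 mm pairs spanning
  ±200 mm), deterministic UIDs from a seed so repeated writes are
  byte-identical. DS values are formatted to 10 significant digits;
  round trips are identities to 1e-6 mm. Analyzer metadata (nominal
  junction lines, expected picket centers, band ROIs, BB layout) is
  serialized as JSON in RTPlanDescription so a plan file is
  self-contained for analysis. RT-Images store 16-bit pixels with a
  rescale slope (round trip to ~1e-5 of the maximum); a plain-text
  sidecar format (JSON header + whitespace float grid) is provided so
  fixtures never require DICOM tooling.

## Design decisions that were genuinely open

* The picket "position" is the slit center: the mean of the two bank
  positions at the picket's control point; the default slit width is
  2 mm (the source is silent on it).
* The junction test supports 2 abutting half fields per axis and both
  axes in one plan (default), reporting the worst of the four junction
  statistics when all are present.
* The instruction JSON schema is this package's own (versioned,
  documented in `R/instructions.R`): the format it re-creates was
  described only by its parameters, not its fields.
* "Fail" is the positive class for sensitivity in contingency tables:
  the study asks how often an injected error is *caught*.
* Cross-software comparison against manual commercial analysis tools
  on clinical image sets is out of scope; the sensitivity study here is
  the synthetic error-injection analogue (junction errors 0, ±2, ±4 mm;
  phantom SSDs 950-1050 mm) with the noiseless render as ground truth.

## Problem sizes used by the tests

Renders in the test suite and acceptance script use the default
512×512 grid (0.5 mm isocenter sampling) for the picket-fence and
light-rad chains, 256×256 at 1 mm-equivalent sampling for junction and
band tests, and 128×128 for Winston-Lutz; gamma-oracle comparisons run
on grids up to 32×32 with a 0.5 mm search step. These sizes resolve
every tolerance in play by an order of magnitude while keeping the full
suite in the tens of seconds.

## Known limitations

* No dose calculation, MU optimization or deliverability checking
  (leaf speed/dose-rate limits) beyond position bounds.
* The DLG sweeping-gap plans are built (gap widths configurable) but no
  DLG analyzer is provided.
* Electron and setup fields are rejected on read, not modelled.
* The DICOM codec covers the explicit-VR little-endian subset this
  package writes plus defined/undefined-length sequences; it is not a
  general-purpose DICOM library.
* The renderer's noise is uncorrelated Gaussian; real EPID noise is
  spatially correlated and dose-dependent.
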