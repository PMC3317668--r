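---
title: "Quantitative cochlear micro-tomography: models, phantoms and measurement"
author: "cochleaCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative cochlear micro-tomography: models, phantoms and measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cochleaCT)
```

## The measurement problem

Synchrotron phase-contrast micro-tomography can image the soft-tissue
anatomy of an intact mouse cochlea: the three fluid-filled spiral channels
(scala tympani, scala media, scala vestibuli), the basilar and Reissner's
membranes that separate them, and the organ of Corti whose pillar-cell
heads form a continuous ridge from base to apex.  Two quantities summarize
the morphometry: the length of a polyline drawn along the pillar heads
(about 6.7 mm in the adult C57BL6 mouse) and the cross-sectional area of
each scala measured in planes perpendicular to that line (scala tympani
about 0.16 mm^2 at the base declining to about 0.031 mm^2; scala media
roughly constant near 0.035 mm^2; scala vestibuli from about 0.11 mm^2
down to about 0.011 mm^2 at the apex).

None of the raw projection data behind such experiments are public, so the
accuracy of the measurement chain cannot be audited on real scans.  This
package instead closes the loop synthetically: it generates a spiral
cochlea phantom whose centerline length and per-scala area profiles are
*analytically exact*, pushes it through a complete simulated acquisition
and reconstruction, segments and measures it with the same semi-automated
procedures an operator would use, and compares the measurements with the
built-in ground truth.

## The phantom

The phantom centerline is the pillar-head ridge: a logarithmic spiral in
radius (log-interpolated between a base and an apex radius) with a linear
axial rise per turn.  The curve is rescaled uniformly so its analytic arc
length equals the design length exactly (Gauss-Legendre quadrature of the
speed, 64 nodes); the rescaling is why the `baseRadiusMm`, `apexRadiusMm`
and `pitchMm` fields are nominal.  The default is two turns of 6.67 mm
total ridge length.

Cross-sections are built in planes perpendicular to the local tangent.
Each scala is an ellipse of exactly the design area at that arc position;
the three ellipses are stacked along the local vertical with the basilar
membrane between scala tympani and scala media and Reissner's membrane
between scala media and scala vestibuli (both 16 um slabs by default).
A limbus-like wedge of soft tissue on the modiolar side joins the two
membranes so the membrane system is a single connected sheet, as it is
anatomically.  The organ-of-Corti ridge is an 18 um tube resting on the
basilar membrane, centred just above the centerline so the membrane
continues beneath it.  An exponent-4 superellipse envelope (plus a 25 um
bony wall) closes the duct; the envelope exponent matters: a true ellipse
wide enough to contain the flat scala-tympani section would have to be far
taller than the stack and the two-turn spiral would not fit its grid.

Two geometric choices deserve comment:

* **Ellipse aspect ratio.**  The sections are 2.8:1 (width:height)
  ellipses.  Narrower shapes (e.g. 1.6:1) stacked three-high with the
  printed base areas produce a duct almost 0.9 mm tall; with two turns the
  windings would then have to be spaced by more than 0.9 mm of pitch and
  the default 256^3 grid at 8 um (2.048 mm cube) cannot contain the
  result.  The flatter 2.8:1 sections are also the better match to
  histological cross-sections of the mouse scalae.
* **Winding ownership.**  Voxels are classified by the centerline sample
  whose section centroid is nearest (a Voronoi rule along the duct), so
  where consecutive windings approach each other the boundary falls midway
  between them and no winding writes into another's lumen.

Voxelization is exact-by-construction in the sense that a voxel takes a
scala label iff its center lies inside the analytic ellipse of its nearest
section; measured voxel areas and volumes therefore agree with the design
to first order in the voxel size (2-4% at 8 um voxels; the residual grows
toward the apex where sections are smallest).  The ground truth attached
to the phantom (`centerlineTruth`, `areaTruth`) is the analytic design,
never a voxel count.  The duct is extended 0.08 mm beyond both ends of
the measured centerline so that end stations measure full sections even
under slightly tilted end tangents.

Attenuation is assigned per tissue class, in mm^-1: exterior 0, fluid
(all three scalae) 0.2, soft tissue (membranes, organ of Corti) 0.5,
bone/wall 1.0.  The moderate bone value reflects the partial
decalcification used to reduce absorption by the cochlear wall in the
experiments this pipeline emulates.

## The forward model

The simulator produces a parallel-beam scan: by default 180 projections at
1 degree increments over [0, 180), one detector row per volume slice.
For each angle the attenuation is integrated along rays by bilinear
resampling in the volume frame at 0.5-voxel steps (the volume is never
rotated, so the forward model is grid-independent).  Transmitted intensity
is

```
I = photonScale * flatProfile * columnGain * exp(-integral)
```

followed, in order, by a phenomenological edge enhancement
`I - alpha * Laplacian(I)` standing in for near-field in-line phase
contrast (the canonical small-propagation-distance approximation; wave
optics is out of scope), Poisson photon noise, a dark-current offset with
Gaussian read noise, and 16-bit quantization (round-half-to-even, clipped
to [0, 65535]).  Ring/line artifacts, the classic fixed-pattern artifact
of flat-field-corrected synchrotron scans, are modelled as per-column
multiplicative gain jitter constant across angles.  A flat field (no
object) and a dark field (beam blocked) are produced with the same
statistics.  The rotation axis may sit off the detector center by a
sub-pixel column offset.

The noise magnitudes (`artifactModel()` defaults) are testing placeholders
chosen to *look* like the artifacts reported for such scans - granular
background, faint horizontal lines, enhanced interfaces - not calibrated
physical estimates; no published noise characterization exists to fit.

## Preprocessing and reconstruction

Frames are corrected as `(raw - dark) / (flat - dark) * 65536`, the
standard flat/dark-field normalization rescaled to the 16-bit range.  The
output stays floating-point; pixels where flat equals dark are set to 0
and counted (a warning above 1%).  Optional 2x2 binning averages blocks
(preserving the corrected scale) and doubles the effective pixel size.
Correction precedes binning; for noise-free means the order is
indifferent, it is fixed for reproducibility.

The rotation-axis offset is estimated by correlating the 0-degree frame's
column profile with the horizontally mirrored last frame (at 179 degrees):
for a 180-degree scan these are mirror images about the axis, so the
correlation peak sits at twice the offset; parabolic interpolation around
the peak gives sub-pixel precision (about 0.07 px on the disk phantom).
Mirror correlation was preferred over center-of-mass symmetry because it
tolerates objects truncated by the field of view.

Each detector row yields one sinogram.  Corrected intensities are mapped
to line integrals with `-ln(c / 65536)`, c clamped to [1, 65536] so the
transform is finite everywhere; the flag `applyLog = FALSE` reconstructs
intensity directly instead, mimicking reconstructions that feed
phase-contrast images straight into filtered backprojection (edge-enhanced
input then simply yields edge-enhanced slices).  Filtering uses the exact
discrete Ram-Lak kernel transformed to the frequency domain (this, rather
than sampling |f|, keeps the DC term unbiased), zero-padded to the next
power of two at least twice the column count, with optional Shepp-Logan or
Hann apodization.  Filtered projections are shifted by `-axisOffsetPx`
(linear interpolation) and backprojected with linear interpolation and
angular weight pi/(2N).  Uniform angular spacing is required and enforced;
non-uniform sets are rejected rather than silently mis-weighted.  With the
log transform active, slices are rescaled to attenuation per mm.

On analytic oracles the chain is accurate to a few percent: the
reconstruction of a disk's closed-form sinogram recovers the interior
value within 5% with background residuals below 1e-3, and tissue-class
means of a fully simulated phantom are recovered within 10%.

## Segmentation

The binary stage follows interactive-segmentation semantics exactly:
voxels with value below the threshold become Exterior, voxels at or above
it Interior; `"auto"` picks the threshold by Otsu's method on the volume
histogram.  The "remove couch" step keeps only the largest connected
Interior component (26-connectivity by default; 6 and 18 available), with
size ties broken deterministically toward the component containing the
smallest linear voxel index.  Note that Otsu assumes an approximately
bimodal histogram; on a three-class phantom (air / fluid / bone) it can
legitimately settle between the tissue classes instead of the air-tissue
gap, which is why the pipeline also accepts an explicit operator threshold
as the original workflow did.

Compartment (multi-label) segmentation is operator-driven, as in the
semi-automated workflow it reproduces: sparse annotated slices are
propagated through the stack by signed-distance interpolation - each
label's signed Euclidean distance field is computed on the two bracketing
annotated slices, blended linearly, and every voxel takes the label with
the largest positive blended value (exterior if none).  A label absent
from one bracketing slice is blended against a shallow negative field
(depth equal to the gap in pixels) so that disappearing structures shrink
across the gap instead of vanishing at the first interpolated slice; with
a deep sentinel instead, the thin apical scala vestibuli loses its end
caps and its minimum area reads ~15% low.  Slices outside the annotated
range copy the nearest annotated slice, and a fully annotated stack is
reproduced exactly.  Manual corrections are overlay images with a reserved
no-change code, applied voxel-wise and counted.

## Morphometry

The length is the sum of Euclidean distances between consecutive
landmarks, converted with a calibration factor (1.22 um/px for real
detector data, calibrated with a grid; phantom runs use the voxel size).
It is deliberately computed on the raw polyline, not a fitted spline,
matching how operators trace the pillar heads.

Section planes are perpendicular to tangents estimated by centered finite
differences on an optionally smoothed polyline (running mean, window 5 by
default, shrinking symmetrically at the ends so end tangents stay
unbiased).  The in-plane basis is parallel-transported from the first
frame (rotation-minimizing); Frenet frames were rejected because they are
undefined where curvature vanishes and flip across inflections.  Each
plane is sampled on a regular grid (half a voxel by default) with
nearest-neighbor label lookup - labels are categorical, interpolating them
would invent tissue.  Because a perpendicular plane of a coiled organ can
also graze sections of neighboring turns within the sampling window, only
the connected in-plane section nearest the plane center is counted;
sliver components below 9 samples (or 2% of the largest) are ignored so a
grazing cut cannot hijack that choice.  A station is flagged invalid with
reason `"fov"` when an out-of-bounds grid sample neighbors compartment
label - the analogue of excluding sections truncated by the field of view
at the cochlear base.

Station minima reported by the pipeline are taken after a running-median
smoothing (window 3), since the pointwise minimum of a noisy profile is
biased low.

## The orchestrated run

`runPipeline()` executes phantom -> simulate -> correct (-> bin) ->
estimate axis -> reconstruct -> threshold + couch removal -> propagate
operator slices -> landmarks -> length + area profile, persists
intermediates and a resolved config, and emits a deterministic JSON report
comparing every measurement with the analytic truth.  One run seed feeds
named substreams per stage, so toggling noise in one stage does not
perturb another; identical config and seed give byte-identical reports.

Operator input is emulated from the phantom: every fourth slice of the
ground-truth labels acts as an annotated slice (the workflow this mirrors
checked and corrected every slice, so dense operator input is the faithful
default), and ridge landmarks are centroids of the organ-of-Corti label in
the *propagated* volume near guide points spaced 0.05 mm along the arc -
the operator clicks near the ridge, the segmentation decides where the
landmark lands.  The binary Otsu stage is computed and reported but does
not mask the compartment labels by default (`maskToInterior`), mirroring
the original role of couch removal as specimen/background separation
rather than scala delineation.

## Problem sizes and what passing shows

The reference configuration is the paper-matched phantom at 256^3 voxels
of 8 um - the scale at which all end-to-end claims are validated (about
4 minutes on one core; the forward projection and backprojection kernels
are C++).  Unit and property tests run on 32-128^3 volumes.  At 8 um the
smallest structure, the apical scala vestibuli (35 um semi-height), spans
about 4 voxels and its area is recovered within ~6%; phantoms pushed to
12 um voxels show scala media (30 um semi-height there) at the resolution
limit with ~20% area error - a useful reminder that these tolerances are
resolution statements, not algorithmic ones.

The generator emulates the acquisition geometry (180 x 1 degree, off-center
axis, 16-bit frames), flat/dark statistics, Poisson and read noise, ring
artifacts and edge enhancement.  It does not emulate wave-optics phase
contrast, beam hardening, scatter, detector point-spread, motion, or
anatomical irregularity (the real organ's scalae are not elliptical and
its spiral is not a perfect log-spiral).  Passing the recovery tests
therefore shows the *measurement chain* is unbiased at the stated scales
on geometry it can represent; it does not certify accuracy on real
specimens.

## Known limitations

* Areas between the printed anchor values are linear interpolations by
  construction; the real profiles are not linear (the published scala
  tympani curve has a local maximum slightly apical of the base).
* The organ-of-Corti tube displaces about 2.5% of scala media's design
  area; measured scala media runs correspondingly low.
* Otsu's sentinel is not a robust specimen/air separator on multi-class
  histograms (see above); real runs should pass an operator threshold.
* The edge-enhancement operator sharpens interfaces but is not a transport
  model; quantitative attenuation values under strong edge enhancement
  drift near boundaries.
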