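---
title: "Correcting detector saturation in cone-beam CT with a low-dose scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting detector saturation in cone-beam CT with a low-dose scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(satucorr)
```

## The model

Cone-beam CT of both knees with automatic exposure control (AEC) raises
the tube output in lateral views, where rays must penetrate two femurs.
The same output overexposes detector pixels behind weakly attenuating
paths: every detected intensity above the maximum measurable value
$I_{max}$ is clipped, so background (air) pixels and thin-border pixels
become indistinguishable, and the skin border and anterior structures are
lost in the reconstruction. A second, low-dose scan at constant output
never saturates (its unattenuated intensity lies below $I_{max}$) and
depicts the border correctly; it starves photons only behind dense
structures, which the correction never samples.

The correction works entirely in the projection domain. Per AEC view, a
threshold separates valid pixels from background/overexposed pixels; the
invalid pixels are replaced by scaled low-dose pixels; the combined stack
is reconstructed with a standard FDK pipeline. When the subject moved
between the two scans, the low-dose projections are first re-synthesized
in the AEC pose via a marker-driven deformed reconstruction.

### Saturation model

The simulator defines
$$I_{max} = (1 - t)\,I_{0,low} + t\,I_{0,high}, \qquad t = 0.2,$$
with $I_{0,low} \ll I_{0,high}$ the unattenuated detected intensities of
the two spectra. Intensities are quantized by flooring to bins of width
$I_{max}/2^{14}$ (a 14-bit detector); the reference scan skips the
clipping but keeps the bin width, emulating a higher-dynamic-range
detector with comparable values. Intensities that quantize to zero
(photon starvation) are floored to one bin and flagged; the paper-level
method never uses them, because they only occur in the dense interior
where the AEC mask keeps the AEC data.

The quantization floor is a choice — "binning" does not specify the
rounding rule — and flooring has the convenient property that the clipped
value maps exactly onto the top bin.

### Mask generation

The histogram of a saturated line-integral image has a sharp peak at the
low end: all clipped pixels share the value $-\ln(I_{max}/I_0)$. The
threshold algorithm (fixed bin width 0.02; lower quarter of the bins;
mean-count rule for the background peak; first local minimum to the
right) finds the first gap after that peak. Two deliberate
interpretations, both configurable:

* *Local minimum*: the first bin whose count is less than or equal to
  both neighbors (leftmost on ties). The threshold is the left edge of
  that bin.
* *Peak merging*: at most one additional above-mean peak merges into the
  background when the gap between the two peaks is below 10 bins (the
  "CT table in the background" case). Merging must not chain: in
  simulated lateral views the foreground continuum starts a few bins
  after the clip value, and chained merging walks deep into the
  foreground, misplacing the threshold by a factor of two.

The AEC mask keeps pixels above the threshold; per detector row, runs
shorter than 5 pixels are removed (speckle), and the low-dose mask is the
complement.

### Row-wise scaling and combination

The two scans use different tube voltages, so their line integrals differ
in scale (soft spectra attenuate more). For every masked-out segment of a
detector row, scale factors are anchored at the adjacent valid AEC
pixels: $f = \mathrm{aec}/\mathrm{lowdose}$ at the anchor. A segment with
two anchors interpolates the two factors linearly across the segment —
this makes the seam exact on *both* sides, which a single averaged factor
cannot. Segments without usable anchors (starved anchor value, factor
outside $[0.2, 5]$, or a fully masked row) inherit the nearest row's mean
factor. Combination is only applied to the lateral view range (80 of 248
views per side at full scale, proportionally otherwise): the exposure
control only raises the output there, so other views carry no
overexposure.

### Marker-driven 3D non-rigid alignment

The legs can move independently between the scans (opening angle, inward
or outward rotation), so a 2D projective alignment cannot match the
projections; the alignment operates in 3D:

1. **Tracking.** Each projection is background-suppressed by subtracting
   a 3×3 median (markers are compact, nearly sub-pixel spots at the
   binned desk resolution; edges are extended), then transformed with the
   fast radial symmetry transform. Backprojecting the response stack
   yields a blurry 3D blob per marker.
2. **Localization.** The blob volume is binarized (Otsu) and labeled with
   26-connected components; *local maxima* of the response serve as
   candidates, because a single component can fuse a marker with the
   diffuse response of the skin surface it sits on. Candidates are ranked
   by reprojection consistency — the median response at their projected
   position across all views — which separates physical markers from
   streak-intersection ghosts by more than an order of magnitude, and an
   absolute consistency floor makes marker-free scans fail loudly rather
   than return clutter.
3. **Correspondence.** Rigid Procrustes iteration with a globally greedy
   bijective assignment; when no single rigid motion explains the match
   (severe motion displaces markers beyond their spacing), both sets are
   split into their two leg groups (deterministic 2-means) and matched
   per group. Ambiguity is an error, never a guess.
4. **Deformation.** Affine moving least squares with weights
   $w_i(v) = 1/|p_i - v|^{2\alpha}$, $\alpha = 1$. Because all markers
   sit on the anterior surface, the control set is nearly coplanar: the
   affine solve is ill-conditioned in the depth direction and amplifies
   localization noise into large posterior shears. Queries whose weighted
   covariance has an eigenvalue ratio below $10^{-2}$ therefore use a
   weighted rigid (Kabsch) solve. For genuinely 3D control sets the
   affine solve is exact to the weighted least-squares optimum.
5. **Backward–forward projection.** The low-dose stack (markers
   inpainted by a harmonic disk fill) is FDK-filtered and backprojected
   with the deformation applied per voxel: each output voxel, an AEC-pose
   position, is mapped through the AEC→low-dose deformation to its
   low-dose-pose position, projected, read bilinearly, and accumulated at
   the original voxel. Note the direction: mapping voxels through the
   low-dose→AEC deformation instead displaces the reconstruction by twice
   the motion — the read position must live in the pose of the data being
   read. The deformed volume is reduced to its object support (voxels
   outside the field-of-view cylinder, or below 0.009 mm⁻¹ ≈ half the fat
   attenuation, are air) and forward-projected; per view, a global
   least-squares gain against the original low-dose projection absorbs
   the amplitude deficit that lateral truncation imposes. Without the
   support reduction, starvation-inconsistent data and truncation leave a
   diffuse halo around the object whose reprojection contaminates the
   synthesized background by 0.2–0.5 line-integral units — more damage
   than the motion itself.

The backward–forward process has inherent losses: the volume cannot
contain laterally truncated object parts, and rays near the top and
bottom of the detector traverse partially reconstructed regions. The
registration grid therefore uses detector-matched in-plane resolution
over the full lateral field of view and an axial extent covering the
whole illuminated cone, and the row-wise scaling of the combination
re-anchors every pasted segment at the seam, absorbing the residual
global deficits.

### FDK reconstruction

Cosine weighting $SDD/\sqrt{SDD^2+u^2+v^2}$; Parker short-scan weights
with the effective half-fan $\Gamma = (\mathrm{span} - \pi)/2$ (conjugate
rays sum to one; fan angles beyond $\Gamma$ are clamped — the desk span
of 198.4° is marginally short of $180° + $ full fan); truncation
correction by mirror extension of each row over 25% of the detector width
with a cosine taper; Shepp–Logan ramp filtering by zero-padded FFT
convolution at isocenter-plane sampling; voxel-driven backprojection with
the $(SID/s)^2$ distance weight. A uniform water cylinder reconstructs to
its true attenuation within a fraction of a percent.

## The synthetic data generator

The generator stands in for a licensed anthropomorphic model. Each leg is
an elliptic-cylinder fat envelope (138 × 146 mm) containing a muscle-like
soft-tissue bulk and femur, tibia, patella and fibula as cortical-bone
primitives with marrow cores; eleven 1 mm metal spheres sit on the
anterior surfaces near the joint (6 left, 5 right, non-overlapping in
projection). Attenuation uses embedded tables adapted from published
photon cross-section data (log-log interpolated, 10–150 keV); spectra are
filtered Kramers models at 60 kVp / 0.21 mAs and 120 kVp / 2.5 mAs
(intensity ratio ≈ 0.03). Projections are computed by exact analytic
ray–primitive intersection with priority resolution (innermost material
wins) and 2×2 sub-rays per pixel, so that the sub-pixel markers remain
visible at the binned desk resolution.

Geometry defaults encode the acquisition premise rather than free knobs:
SDD 1198 mm; SID 650 mm, chosen together with the leg dimensions (legs
pressed together, overlapping 10 mm at the midline with a soft-tissue
contact bridge) so that in anterior-posterior-ish views the silhouette of
the leg pair extends beyond the lateral field of view and every ray
inside it is attenuated above the clip level. Overexposure then occurs
*only* in the lateral view range — exactly the situation the correction
targets, and the reason combining only the lateral views suffices. The
trajectory (248 × 0.8° at full scale; desk preset 62 × 3.2° with 4×4
detector binning; a further halved "micro" preset for fast experiments)
is centered on the anterior-posterior direction, starting and ending at
lateral-ish views. The reconstruction grid of the desk preset is 96³ with
2.2 mm in-plane and 1.4 mm axial spacing, keeping the axial extent within
the fully illuminated cone.

What the generator does *not* emulate: scatter, detector blur and lag,
focal-spot size, heel effect, tube-output modulation curves, noise
(Poisson noise exists but is off by default, making the whole pipeline
bit-reproducible), and the soft-tissue detail of real knees (tendons,
ligaments, muscle boundaries). Passing tests therefore demonstrate the
*mechanism* — thresholding, seam-exact combination, marker-driven
alignment, quantitative reconstruction — under controlled conditions; on
real scans the histogram shapes are noisier and the manual parameters
(bin width, peak gap, despeckle length) may need study-specific tuning.

## Problem sizes and numerical choices

Routine runs and the test suite use the desk preset (62 views of
160 × 120 pixels, 96³ volumes; the complete motion-free experiment in
roughly fifteen seconds, the motion experiment with registration in about
a minute); the paper-scale preset (640 × 480, 248 views) is provided for
full-resolution runs. Ray marching steps at half the smallest voxel
spacing with trilinear interpolation; quantization floors; ties in the
local-minimum search resolve leftmost; the MLS exact-interpolation branch
triggers within $10^{-9}$ mm of a control point; degenerate inputs error
with stage-tagged messages rather than propagate.

## Evaluation

Volume quality uses SSIM (Gaussian window, σ = 1.5, standard constants,
computed per axial slice and averaged; a full 3D window is available) and
nRMSE (RMSE normalized by the reference value range), both on the volume
excluding a 2-voxel boundary shell, with the SSIM data range anchored to
the reference volume. On the desk-scale motion-free experiment the
correction raises SSIM from ≈ 0.71 to > 0.999 and lowers nRMSE from
≈ 0.031 to ≈ 0.0003 against the unclipped reference; with simulated
inter-scan motion, combination fails without registration and succeeds
with it (the test suite asserts the ordering, not specific values).

## Known limitations

* The correction assumes saturated and background pixels share one value
  range; strongly modulated exposures within the lateral range would
  smear the background peak.
* Marker-based alignment degrades wherever markers are far away —
  posterior regions recover only the blended per-leg rigid motion, and
  deformations that are non-rigid *within* a leg are out of reach of 11
  surface markers.
* The backward–forward synthesized projections lose laterally truncated
  and axially under-covered content; the per-view gain and the row-wise
  seam scaling compensate globally, not locally.
* Dose estimation for the additional low-dose scan is out of scope.
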