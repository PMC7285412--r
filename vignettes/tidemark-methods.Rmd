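---
title: "Quantifying the 3D tidemark from paired ultrasound and micro-CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the 3D tidemark from paired ultrasound and micro-CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidemark3d)
```

## The problem

The tidemark is the interface between noncalcified articular cartilage and
the calcified cartilage zone. Its three-dimensional morphology — overall
undulation (waviness) and fine texture (roughness) — changes in
osteoarthritis, and high-frequency B-mode ultrasound can image it
nonionizingly: the tidemark is the second bright echo line in an
osteochondral B-scan. `tidemark3d` implements the complete quantitative
chain for validating such ultrasound surface reconstructions against
micro-CT: surface extraction from both modalities, rigid registration with a
mean surface-discrepancy statistic, areal waviness/roughness indices, and
en face slab projections. Because real paired scans of osteochondral disks
are not freely distributable, the package ships a synthetic phantom
generator that produces paired volumes from a known analytic ground-truth
surface, so every stage can be tested against truth.

## The synthetic phantom

A disk's true tidemark surface is

$$z(x, y) = z_0 + g_x x + g_y y + w(x, y) + r(x, y),$$

where the plane carries a gentle specimen inclination (default 0.5°), the
waviness $w$ is a sum of six random-phase cosines with wavelengths of 1.15–2
field lengths, and the roughness $r$ is a band-limited sum of forty cosines
with wavelengths of 1–3 correlation lengths (default 150 µm). Writing both
components as finite cosine sums makes the surface analytic: it can be
sampled exactly on the anisotropic ultrasound grid (15 × 15 µm pixels,
32 µm elevational step; 220 frames over a 7 mm field) and on the isotropic
21 µm micro-CT grid, and the amplitude parameters are exact RMS values. The
waviness wavelengths are deliberately at or above the field length so that a
fifth-order polynomial reference surface can absorb them — the premise of
separating roughness from waviness by polynomial detrending; undulation much
shorter than the field would leak into the roughness index under any
implementation of that definition.

The ultrasound volume contains a dark saline band (uniform noise bounded by
the noise-floor parameter), a cartilage-surface echo band, and a brighter
tidemark band centred on the true surface with a Gaussian axial profile
(σ = 17 µm, emulating the ≈40 µm axial resolution of a 25 MHz transducer),
multiplied by Rayleigh speckle of adjustable contrast. Crack columns
(default 3%) carry no tidemark echo. The surrogate for the manually drawn
approximate profile is the true surface plus a smooth in-frame perturbation
bounded by 80 µm — comfortably inside the 20-pixel (≈0.30 mm) search window,
as a human tracing would be.

The micro-CT volume is a high-intensity half-space below the same surface,
expressed in its own frame through a random rigid transform (rotation ≤ 3°,
translation ≤ 0.8 mm) plus a small in-plane tilt (1.5°), with additive
Gaussian noise and one-voxel partial-volume ramping at the interface.
Perforations are zero-intensity cylindrical channels (radius 60 µm, ≈3% of
columns) running along the specimen's mean surface normal, as anatomical
channels traverse the calcified plate. The CT field extends 1.2 mm beyond
the ultrasound field on every side — the real reference scan covers the
whole disk — which guarantees full lateral overlap for any admissible rigid
offset.

What the phantom does *not* emulate: refraction and speed-of-sound errors,
attenuation with depth, angle-dependent specular reflection loss, RF-domain
speckle correlation, CT beam hardening, or trabecular structure below the
plate. Passing tests therefore demonstrate the correctness of the
*processing chain*, not the physics of acquisition; on real data the
US–CT discrepancy additionally contains acoustic effects the phantom
excludes.

```{r phantom, eval = FALSE}
p <- synth_params(field_size_mm = 3, seed = 1)
gt <- generate_ground_truth(p)
us <- simulate_us_volume(gt)   # B-scan stack + surrogate manual profile
ct <- simulate_ct_volume(gt)   # tilted, rigidly offset micro-CT volume
```

## Surface extraction

**Ultrasound.** The noise level is estimated from the saline region as
mean + *k*·SD (population SD; *k* = 3 by default — the reference region is
prescribed, the statistic is our choice and is exposed in the
configuration). In each frame, each vertical line is searched for the first
(shallowest) strict local maximum above the noise level within a 20-pixel
window centred on the approximate profile; plateaus resolve to their
shallowest index. Lines with no supra-threshold peak are cracks and are
filled by 1D linear interpolation between the nearest valid neighbours
(nearest-value extension at the edges). Sub-pixel parabolic refinement
exists but is off by default: integer-row peaks are the baseline behaviour,
and at a 15 µm pixel the quantization floor (15/√12 ≈ 4.3 µm RMS) is already
well below the inter-modality discrepancy being measured.

**Micro-CT.** The stack is first levelled: frames are averaged, the
interface line of the averaged image is fitted by least squares, and every
frame is rotated by the negated angle (bilinear resampling, minimum-value
fill). After global Otsu thresholding (256 bins, ties to the lower cut;
global rather than per-frame, since the phantom and the scanner have
stationary intensity statistics across frames), the surface in each vertical
line is the first background-to-calcified transition that starts a run of at
least 2 voxels. A transition is accepted only within ±0.5 mm of the *local*
interface level, defined by a 31-column running median of the detected
depths. The local reference matters: with waviness excursions of several
hundred µm, a window around the single global median either rejects genuine
relief or accepts spurious deep transitions where a scan line exits a
slanted perforation channel below the true surface. For noisy volumes the
window can additionally shrink to *k* = 4 robust standard deviations
(1.4826·MAD) of the detection residuals (`mad_k`), floored at 3 voxels; this
is off by default and used by the cohort analysis. Rejected and empty
(perforation) columns are filled by the same 1D interpolation as cracks.
One caveat is inherited from the geometry: voxels on a channel wall are
partial-volume ambiguous, so recovery can only be guaranteed to one voxel
outside a one-voxel ring around each perforation.

## Registration and the discrepancy statistic

The US surface becomes a point cloud (one point per grid node), the CT
surface a triangle mesh (two triangles per grid cell). Registration is
point-to-point rigid ICP: nearest-neighbour correspondence, closed-form
least-squares rigid fit via the cross-covariance SVD, iterated until the RMS
correspondence distance changes by less than 0.01 µm between iterations
(at most 200 iterations). Options: correspondence trimming (keep the
closest fraction; the cohort analysis keeps 90% so that sparse extraction
artifacts cannot drag the fit) and the choice of initialization.

Initialization deserves emphasis. Because the CT field is larger than the
US patch, centroid alignment starts the patch centred in the reference and
ICP must slide it laterally by up to the true offset across a
quasi-planar surface; on smooth disks this reliably finds a local minimum
tens of µm off. The study this mirrors used a manual coarse alignment
before ICP; the package's data-driven surrogate
(`coarse_align_surfaces()`) exhaustively searches lateral shifts on a
100 µm grid, scoring each by the median-offset-corrected mean absolute
height mismatch on the overlap, and returns the best translation. ICP then
refines rotation and residual translation.

After registration the discrepancy is

$$D_\mathrm{diff} = \frac{1}{N}\sum_{i=1}^{N} d(p_i, S_\mathrm{ref}),$$

the mean unsigned Euclidean distance from every US point to the CT mesh
(exact point-to-triangle distance over interior, edges and vertices;
computed in C++ with lateral binning, and verified in the tests against a
brute-force all-triangle scan). The standard deviation of the per-point
distances is reported alongside. Distances are unsigned because the mean
discrepancy statistic averages magnitudes; no sign convention is imposed.

## Waviness and roughness

For a surface $s(i,j)$ on an $M \times N$ grid and a reference surface
$SR(i,j)$,

$$S_a = \frac{1}{MN}\sum_{i,j} \lvert s_{i,j} - SR_{i,j}\rvert,
\qquad
S_q = \sqrt{\frac{1}{MN}\sum_{i,j} \left(s_{i,j} - SR_{i,j}\right)^2}.$$

The waviness pair SWa/SWq uses the first-order reference (the plane
{1, x, y}, absorbing tilts); the roughness pair SRa/SRq uses the fifth-order
reference (all 21 monomials of total degree ≤ 5, absorbing the waviness as
well). Fits are ordinary least squares on lateral coordinates centred and
scaled to [−1, 1] for conditioning; all grid nodes are weighted equally,
including interpolated crack/hole nodes (a mask-aware option excludes them
from the fit). These definitions imply SWa ≤ SWq and SRa ≤ SRq (power-mean
inequality) and SRq ≤ SWq (nested bases), which the tests assert on random
surfaces, and the analytic checks: a dense full-period sinusoid of
amplitude A gives Sa → 2A/π and Sq → A/√2 after order-1 detrending.

When comparing modalities, the CT panel is computed on the CT surface
cropped to the registered US footprint: both numbers then describe the same
physical patch of tidemark, as they do in a real paired scan. Pearson
correlation (two-sided t test, n − 2 degrees of freedom, p < 0.05) is the
association report across a cohort.

```{r indices, eval = FALSE}
s <- generate_ground_truth_surface(synth_params(seed = 1))
smoothness_panel(s)       # SWa, SWq, SRa, SRq in um
```

## En face imaging

Each lateral column of a volume is resampled along depth so the extracted
tidemark sits at a common index (1D linear interpolation; out-of-range
depths filled with zero and masked), then a slab [offset, offset +
thickness) measured downward from the tidemark is projected per column by
maximum (MIP) or average (AIP) intensity. AIP excludes fill voxels from the
mean, avoiding edge darkening. MIP ≥ AIP pointwise for non-negative
volumes, and MIP is monotone in slab thickness — the brightening with
thicker slabs seen in the en face images. Perforation channels appear as
dark spots in the CT en face image. Flattening relative to the extracted
surface is the default; axis-aligned slabs after tilt correction can be had
by projecting the unflattened volume.

## Numerical choices and degenerate inputs

* Coordinates: 1-based array indices with physical position
  (index − 1) × spacing + origin, depth increasing downward, all lengths in
  µm. STL export converts to mm (the conventional unit at this scale);
  CSV/PLY stay in µm.
* The first-peak rule breaks plateaus to the shallowest index; peaks are
  compared against immediate neighbours, which may lie just outside the
  search window.
* Otsu ties break toward the lower cut; a constant volume is an error, as
  are an all-flagged profile, an all-empty binary volume, a rank-deficient
  polynomial design, and a collinear ICP source.
* ICP's recorded RMS is evaluated after each incremental fit on the
  correspondence that produced it, which makes the recorded history
  non-increasing for untrimmed ICP; the 0.01 µm stopping rule compares
  successive entries of that history.
* Rotation uses bilinear interpolation with minimum-value fill; a round trip
  (+θ then −θ) is exact only to resampling, so the tests bound the interior
  mean absolute difference by 2% of the dynamic range.

## Problem sizes

The test suite and the acceptance script validate the noise-free recovery
contract once at the full acquisition geometry (7 × 7 mm field: a
220 × 188 × 468 US stack and a 449 × 134 × 449 CT volume), and run the
15-disk cohort — waviness 50–180 µm and roughness 20–40 µm RMS, assigned in
randomized pairing — on 3 × 3 mm fields at the same voxel spacings. The
smaller cohort field keeps a full simulate–extract–register–quantify cycle
of 30 volumes inside a few minutes on one CPU while preserving every
per-voxel property of the method; only the number of columns per disk
changes.

## Known limitations

* Point-to-point ICP with closest-vertex correspondence has a small bias
  floor set by the grid-sampling mismatch between the two modalities; it is
  well below the per-column extraction noise here but would matter for
  sub-µm applications (point-to-plane correspondence would be the upgrade).
* The roughness index inherits an upward bias of roughly
  √(SR² + σ²) − SR from per-column detection noise σ; it is common to both
  modalities and does not disturb their correlation, but absolute roughness
  values are modality-dependent — consistent with the reference-method
  observation that CT indices run slightly larger than US ones.
* No distance-scale cross-calibration between modalities is attempted, and
  speed-of-sound correction is deliberately out of scope.
* The hole/crack interpolation is 1D along the lateral axis (matching the
  per-frame processing); 2D inpainting would use elevational neighbours too.
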