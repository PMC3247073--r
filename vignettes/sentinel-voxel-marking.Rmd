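---
title: "Sentinel-voxel marking of intraoperative tumor landmarks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sentinel-voxel marking of intraoperative tumor landmarks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endicom)
```

## The problem

In skull-base and craniomaxillofacial tumor surgery, the locations where
frozen sections and resection margins are sampled carry information that the
downstream disciplines — pathology and radiotherapy — normally receive only
as free text. `endicom` implements a workflow that keeps this information
three-dimensional and machine-readable: landmark positions recorded with a
navigation pointer during surgery are classified by final histology, and the
tumor-positive ones are written into a *copy of the patient's own CT DICOM
series* as voxels with a sentinel intensity of 3500 HU. Because conventional
CT data never exceeds roughly 3100 HU (a 12-bit encoding with rescale
intercept −1024 tops out at 3071 HU), any radiotherapy planning platform can
recover the marks with a single threshold operation and no proprietary
interface. The marked series is ordinary DICOM; the sentinel value is
simultaneously the payload and the proof of manipulation.

The package covers five stages: (1) preparation — tumor segmentation by HU
thresholding, margin augmentation, mask mirroring for reconstruction
templates; (2) registration of the navigation frame to the image frame from
paired fiducials, with an RMS acceptance gate; (3) point acquisition and
histology classification; (4) sentinel-voxel encoding and DICOM export;
(5) threshold recovery and rigid fusion onto another volume.

## Coordinate conventions

All patient-frame coordinates are millimetres in the DICOM LPS frame (x
toward the patient's left, y posterior, z superior); the navigation system's
export frame is not standardized across vendors, so the package fixes LPS
for both frames and documents it here. Voxel indices are 1-based triples
`(k, i, j)` = (slice, row, column), the natural R convention. A
`volume_geometry` maps indices to the patient frame affinely; the origin is
the *center* of voxel `(1, 1, 1)`, matching ImagePositionPatient semantics.
Nearest-voxel lookup rounds half-to-even on each axis so ties are
deterministic and reproducible. Inter-slice spacing is always derived from
successive slice positions rather than the SliceThickness attribute, because
gapped or overlapping acquisitions are common and positions are
authoritative; a non-uniform position ladder (tolerance 1e-3 mm) is refused
rather than resampled.

## Registration and the 0.8 mm gate

The navigation-to-image transform is estimated from ≥ 3 paired fiducials
(clinically: four titanium miniscrews or a dental splint) by the closed-form
orthogonal-Procrustes solution — centroid alignment, SVD of the
cross-covariance, and a sign correction that excludes reflections. The
attached residual is the fiducial registration error,
\(\mathrm{FRE} = \sqrt{\tfrac1n\sum_i \|R p_i + t - q_i\|^2}\), which is what
a navigation console displays at registration time; target registration
error elsewhere in the volume is out of scope. Intraoperative practice
accepts a registration only when this RMS is below roughly 0.5–0.8 mm, so
`registration_gate()` defaults to 0.8 mm; whether that range is a device
specification or site policy is not something the workflow can decide, so
the threshold is an explicit parameter. Collinear fiducials, duplicate
image-side points (< 1e-6 mm apart) and unrecoverable reflections raise
errors instead of returning a degenerate fit.

With four fiducials spanning ~100 mm and isotropic per-axis localization
noise of σ = 0.25 mm — a realistic pointer-touch scale — the expected FRE is
\(\sigma\sqrt{3(1 - 2/n)} \approx 0.31\) mm, comfortably inside the gate;
the Monte-Carlo checks in the test suite and acceptance script reproduce
this at 1000 replicates.

## The sentinel codec

`endicom_encode()` maps each selected point to its nearest voxel and sets it
to the sentinel (default 3500 HU). Design choices that matter:

* **Separability is verified, not assumed.** Encoding refuses a volume whose
  native maximum exceeds `max_native_hu` (default 3100): with, say, a dense
  metal artifact at 3400 HU, threshold recovery would be ambiguous, and the
  package fails loudly rather than silently clipping.
* **Bit-depth widening.** 3500 HU is not representable in the common 12-bit
  CT pixel encoding, so the writer widens the output to signed 16-bit
  (slope 1, intercept unchanged) exactly when needed; everything else in the
  rewritten series is copied attribute-for-attribute, with fresh SOP
  instance UIDs so modified objects never collide with the originals while
  keeping the study and frame-of-reference UIDs (the marked series stays
  co-registered).
* **Single-voxel marks** by default, matching the clinical display of
  tumor-positive points as individual voxels; a spherical `mark_radius_mm`
  is available purely for visibility in planning software.
* **Collisions merge with a warning** (two frozen sections within one voxel
  are plausible; hard failure would block an export), and out-of-volume
  points are an error unless the policy says skip.
* **Labels travel in a sidecar.** One intensity value cannot carry names,
  sequence numbers or histology, so the exported series is always
  accompanied by a flat point table; the DICOM payload alone identifies
  *where*, the sidecar says *what*.

`endicom_extract()` recovers one point per voxel at or above the threshold,
positioned at the voxel center, numbered in lexicographic `(k, i, j)` order.
The default threshold of 3200 HU sits strictly between the native ceiling
(~3100) and the sentinel (3500), maximizing the margin on both sides.
Quantization to voxel centers bounds the round-trip position error by half
the voxel body diagonal (0.87 mm at 1 mm isotropic spacing); only benign
histology — never an unknown — is treated as exportable-negative, and only
confirmed malignant points are encoded at all.

## Margin augmentation and mirroring

The "at least 1 cm in every dimension" resection-margin rule is implemented
as a metric dilation: a voxel joins the augmented mask iff its center lies
within `margin_mm` of an input-voxel center, computed with a separable
anisotropic Euclidean distance transform (Felzenszwalb–Huttenlocher, in
C++) in millimetres. The phrase could also be read per-axis; Euclidean was
chosen as the geometrically honest reading (a box margin over-dilates along
diagonals), and the per-axis interpretation remains available as
`method = "box"`. Sagittal mirroring for reconstruction templates reflects
voxel centers across `x = plane_x_mm` and resamples by nearest neighbour;
on a grid-symmetric plane it is an exact involution, and clipped reflected
voxels are reported, never dropped silently.

## The synthetic phantom

No clinical data ship with the package. `make_phantom()` rasterizes a
deterministic head-scale test object: a soft-tissue ellipsoid (40 HU) with a
cortical bone shell (1200 HU, outer 12%), an 8 mm 120 HU tumor sphere, and
four 2 mm fiducial blobs at 3000 HU — metal-bright yet below the native
ceiling, preserving the separability premise. The default volume is
64×128×128 at 1 mm isotropic: large enough for head-like fiducial spans
(~110 mm), small enough that every test runs in seconds. All intensities are
integers storable as 12-bit unsigned with intercept −1024, so the phantom
also exercises the bit-widening path. `simulate_navigation()` draws a random
rigid navigation pose (from the spec's seed), perturbs the physical-side
fiducials with isotropic Gaussian noise (σ = 0.25 mm default), and samples
acquisition points uniformly inside the head with a reproducible histology
assignment (40% malignant, 40% benign, 20% never released).

What the phantom does *not* emulate: CT noise and streak artifacts, beam
hardening, partial-volume effects at the skull, soft-tissue deformation
between scan and surgery, and real tracking-camera error distributions.
Passing tests therefore demonstrate the correctness of the geometry,
encoding and recovery machinery — not clinical accuracy, which depends on
patients and hardware outside any software's control.

## Fusion

`fuse_volumes()` resamples a source volume onto a target grid under a rigid
transform (from landmark pairs via the same registration machinery);
intensity-driven fusion as found in commercial platforms is out of scope.
Trilinear interpolation is the default, with one deliberate exception:
source voxels at or above the sentinel threshold are always transferred by
nearest neighbour, because interpolation would smear a 3500 HU mark below
the extraction threshold — the one failure mode the marking scheme cannot
survive. `fuse_points()` is the lossless point-level alternative and agrees
with extract-after-fuse within the composed quantization bound (half source
plus half target voxel diagonal).

## Numerical choices and degenerate inputs

* Direction vectors must be unit (1e-9) and orthogonal (1e-6); sheared or
  gantry-tilted acquisitions are rejected, not corrected.
* Out-of-volume lookup allows half a voxel beyond the outermost centers,
  the DICOM convention for the voxel's extent.
* DICOM I/O supports uncompressed explicit-VR little-endian single-frame CT
  only — sufficient for planning exports — and refuses other transfer
  syntaxes explicitly. Slice order always comes from spatial positions, so
  reading is invariant to file renaming.
* The full test suite runs on problem sizes of 24×32×32 (unit tests) and
  the default 64×128×128 phantom (pipeline checks); registration
  Monte-Carlo uses 1000 replicates, chosen so the mean FRE estimate has a
  standard error well under 0.01 mm.

## Known limitations

Multi-frame (enhanced) CT objects, compressed transfer syntaxes, DICOM
networking, RT Structure Sets and deformable registration are out of scope.
The histology of a mark is not recoverable from the voxel value — by
design, one sentinel band only — so the sidecar table is a required part of
any archive. Finally, the clinical navigation accuracy reported for this
kind of workflow (on the order of 1.3 ± 0.6 mm mean deviation in patients)
cannot be reproduced without patients and tracking hardware; the package's
quantitative claims are limited to what its phantoms can measure.
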