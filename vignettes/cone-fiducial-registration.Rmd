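---
title: "Cone-fiducial registration of hard-tissue histology into microCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cone-fiducial registration of hard-tissue histology into microCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(conereg)
```

## The problem

Hard-tissue histology destroys the 3D context it samples: once a
resin-embedded bone specimen has been sectioned, stained and imaged, there
is no direct record of where in the specimen the section plane lay. When a
microCT scan of the intact block exists, that context can be recovered —
provided something in the block ties the 2D section to the 3D volume.

`conereg` implements a fiducial-based solution: three cone-shaped phantoms
are embedded in the resin alongside the specimen. A cone has the useful
property that every cross-section perpendicular to its axis is a circle
whose diameter encodes the position along the axis. A physical section
therefore cuts each cone in an (approximately) elliptic cross-section whose
**minor axis** estimates the local circular diameter, and hence the height
at which that cone was cut. Three cones give three points in the CT frame;
three points span the section plane.

## The model, step by step

### Cone modelling from CT (per phantom)

1. **Segmentation.** The phantoms are much brighter than resin and tissue,
   so an intensity band `[ct.threshold_low, ct.threshold_high]` isolates
   them. Connected components are labeled in 3D (6- or 26-connectivity) and
   ranked by voxel count; the three largest candidates are the cones (with
   `ct.specimen_in_band = TRUE` the largest is the specimen and the next
   three are the cones).
2. **Centroid and axis.** The center of gravity is the unweighted mean of
   voxel-center positions. The inertia axis is the eigenvector of the
   centralized covariance of those positions with the largest eigenvalue;
   an object whose top two eigenvalues coincide (relative gap below 1e-6)
   is rejected as not elongated.
3. **Diameter profile.** The cone is sliced on the plane through the
   centroid containing the axis, sampled nearest-neighbor at the voxel
   spacing so that foreground pixels stay countable. Summing pixels per
   constant-height row and scaling by the spacing gives diameter as a
   function of height (height centered on the centroid). The raw profile
   is smoothed with a Savitzky–Golay filter (third-degree polynomial;
   window default 11 samples) and then projected onto the strictly
   increasing cone by isotonic regression plus a vanishing (1e-9-scale)
   ramp, so the mapping is invertible. The axis sign is fixed so diameters
   grow with height — the apex sits at the most negative height.

### Section processing

The stained RGB image is split into channels; the channel whose Otsu split
has the largest between-class variance ("strongest contrast") is
binarized, the foreground being the class with the smaller area fraction.
A five-step morphological chain then cleans the mask, with disk "sizes"
read as diameters: dilation (5 px) to close holes, erosion (30 px) to
remove small objects, topological hole filling, and a final erosion (5 px)
/ dilation (25 px) pass. All disc operations are exact Euclidean discs
implemented by thresholding distance transforms, so the even 30 px
diameter maps to radius 14.5 without rounding. External contours of the
remaining components are fitted with a direct least-squares ellipse fit
(numerically stable Halir–Flusser form); fitted axis lengths are corrected
by +1 px because traced contours pass through pixel centers, about half a
pixel inside the true edge on each side. Fits whose minor axis falls
outside the configured physical range (`histo.minor_range_mm`, default
0.6–5.2 mm) are suppressed — this removes the much larger tissue
cross-section — and exactly three must survive.

### Plane solving

Each measured minor axis (in mm) is pushed through a cone's inverse
profile to get a height, and the corresponding point
`centroid + h * axis`. Because the assignment of ellipses to cones is not
known a priori, all six permutations are scored by comparing the pairwise
2D distances of the ellipse centers with the pairwise 3D distances of the
resulting axis points (pairwise distances are invariant to the section's
unknown in-plane pose); the permutation with the smallest summed absolute
discrepancy wins, and a best-to-second-best ratio above
`plane.max_ambiguity_ratio` (default 0.95) raises an ambiguity warning. A
manual permutation can be forced. The plane through the three points is
resampled from the volume by trilinear interpolation on a square grid at
the CT voxel spacing.

### Registration and scoring

The in-silico plane is thresholded with the same CT band to produce the
fixed cone mask; the histology cone mask (only the three detected
components — matching is performed for the phantoms, not the tissue) is
area-fraction downsampled to CT resolution and rigidly registered:
rotation, translation and an optional mirror, optimized by Nelder–Mead on
a soft-Dice objective over Gaussian-smoothed masks. The search is seeded
with a closed-form 2D Procrustes fit of the three ellipse centers onto the
three axis points (both chiralities), which resolves pose and mirror
before refinement; when no landmarks are available the seeding falls back
to centroid alignment plus the second-moment principal angle with both
180° alternatives. A final Dice below 0.2 is reported as registration
failure.

With the CT plane as ground truth, pixels are classified as TP (object in
both), FN (CT only) and FP (histology only). A boundary band of total
width `score.exclusion_band_px` (default 2 px at CT resolution) around the
CT cone contours is excluded before counting — the physical phantoms are
porous and fray at cut edges, and those pixels carry no information about
registration quality. The scores are

\[
\mathrm{IoU} = \frac{TP}{TP + FP + FN}, \qquad
\mathrm{DSC} = \frac{2\,TP}{2\,TP + FP + FN},
\]

which obey $\mathrm{DSC} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$ identically;
the test suite asserts this to 1e-12 on every scored case.

## The synthetic phantom generator

Real blocks and sections are large and not redistributable, so the
package ships a ground-truthed generator used by the tests and the
benchmark:

* **Block**: 256³ voxels at 0.08 mm (a half-scale stand-in for a 512³
  scan at the same spacing, keeping simulations around a second each);
  resin base intensity 200, tissue 1200, cones 3000, optional Gaussian
  intensity noise. Solids are voxelized by exact point-in-solid tests.
* **Geometry**: three cones, base diameter 4–6 mm and height 10–14 mm
  (phantoms that fit a 25 mm mold), apex down, placed on a 120° ring of
  radius 6.5 mm (±0.5 mm jitter) around a central tissue sphere of radius
  3 mm; cone axes tilt up to 5° and only toward the block center so no
  solid leaves the grid. The cutting plane tilts 2–15° from vertical and
  its height is drawn uniformly from the (analytically computed) set of
  heights that cut every cone between 30% and 80% of its height — every
  generated case is solvable by construction.
* **Section**: rendered analytically on the true plane in a randomly
  rotated, offset and possibly mirrored view frame (the physical section's
  framing is arbitrary, and it can be imaged from either side): bright
  resin background, stain-red tissue disk, dark exact cone ellipses. The
  boundary of each cone is perturbed radially by a smooth periodic "fray"
  (harmonics 2–6, amplitude default 2 px) and Gaussian pixel noise is
  added, then quantized to 8 bits. Pixel pitch defaults to 0.007 mm.

What the generator does **not** emulate: CT physics (beam hardening,
partial-volume blur, ring artifacts), real staining texture and
inhomogeneity, tissue deformation during sectioning, and print defects
beyond radial fray. Passing the synthetic benchmark therefore demonstrates
the geometric and algorithmic correctness of the chain, not robustness to
every imaging artifact of a particular scanner or stain.

## Numerical choices

* Trilinear interpolation for plane resampling (linear in intensities —
  property-tested); nearest-neighbor for the binary cone sections.
* Profile smoothing window 11 samples: cones are 125–175 voxels long at
  0.08 mm, so 11 samples smooths print-scale roughness without biasing the
  slope; the polynomial degree (3) preserves the ideal linear ramp
  exactly.
* Isotonic projection guarantees invertibility; degenerate (flat) profiles
  are flagged rather than silently inverted.
* Ellipse fits on contours shorter than 5 points are discarded as
  non-candidates.
* Area-fraction downsampling thresholds at 0.5 with ties resolved to
  foreground (deterministic).
* The correspondence search treats a diameter outside a cone's profile
  range as infeasible (residual ∞) rather than clamping.
* Registration smoothing sigma 2 px makes the soft-Dice objective smooth
  enough for sub-pixel Nelder–Mead refinement; recovery of imposed
  perturbations is tested to 0.5 px / 0.5°.

## Design choices where the design was open

* **Minor axis ≙ local diameter.** For tilted cuts the ellipse minor axis
  only approximates the circular diameter at the cut; the approximation is
  adopted as-is and validated in the ≤ 15° tilt regime the benchmark
  exercises. No tilt correction is applied.
* **Disk "size" = diameter.** The one unambiguous kernel phrase ("30
  pixels in diameter") fixes the reading for all five kernels.
* **Order of the cleanup chain** is fixed as dilate → erode(30) → fill →
  erode(5) → dilate(25) and exposed in configuration; kernel sizes may
  need small (5–10 px) adjustments for unusual section imagery.
* **Small-object removal by erosion**, literally, rather than
  area-opening: the erosion-based route also shaves large objects by a
  predictable margin (net −2.5 px radius over the whole chain for a large
  convex object), which cancels between the two modalities in scoring and
  stays well inside the frayed-edge exclusion band.
* **In-plane basis convention** of the resampled plane is arbitrary;
  registration absorbs it, so the choice is benign.
* **Flip search is mandatory** in registration: a section can be viewed
  from either side and nothing upstream determines the chirality.
* **Sample SD** (n−1) is used in batch summaries.
* The central cross-section uses a **1-voxel-thick plane** (not a slab).

## Problem sizes used by the shipped validation

The acceptance benchmark runs 20 noisy cases and 10 noiseless cases at the
full study geometry above; unit tests use a compact 96³ fixture with
proportionally smaller cones (and proportionally relaxed plane-recovery
bounds, since angular sensitivity scales with the fiducial lever arms).

## Known limitations

* Cuts steeper than the cone slant produce unbounded conics and are
  rejected, as are planes missing any cone: the method needs all three
  fiducials in the section.
* Minor-axis bias grows with tilt; beyond ~20° the plane estimate degrades
  and is not corrected.
* The registration is rigid by design; sectioning-induced deformation is
  out of scope.
* Cone-to-ellipse correspondence can be ambiguous for near-symmetric
  layouts with near-equal cut diameters; the ambiguity is detected and a
  manual override is provided.

## A worked example

```{r example}
library(conereg)

truth <- benchmark_suite(1, master_seed = 42, difficulty = "noisy")[[1]]
vol <- simulate_block(truth)          # 256^3 block, 0.08 mm voxels
sec <- simulate_section(truth)        # stained-section render, 0.007 mm/px

report <- run_case(vol, sec$image)
report$scores
report$correspondence
report$plane
```
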