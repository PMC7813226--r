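---
title: "Methods: headless segmentation and meshing of micro-CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: headless segmentation and meshing of micro-CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomoseg)
```

tomoseg is a scriptable, headless re-implementation of the segmentation stack
of an interactive micro-CT painting tool: value + gradient thresholding, 3D
binary morphology, a spherical-brush painter writing integer tags, seeded
segmentation (region growing, graph cut, livewire, contour interpolation),
tag-based sub-volume extraction, and isosurface meshing with smoothing and
decimation. This vignette explains the models and the numerical choices; the
README walks through the pipeline itself.

## Conventions

Volumes are `[z, y, x]`-indexed arrays, 1-based, with voxel centres at
integer coordinates; raw files are stored slice-major (x fastest, z slowest)
with a JSON sidecar (dims, bit depth, endianness, voxel size in µm). Only
unsigned 8/16-bit samples are accepted: these are the depths CT
reconstructions are exported at, and rejecting float volumes keeps
`normalize()` — `v / (2^bit_depth − 1)` — exact and monotone. All voxel
operators work on the normalized `[0, 1]` scale, where the clamp of the
gradient measures is meaningful (it mirrors transfer-function convention in
volume-rendering tools).

## Gradient thresholding

Three per-voxel gradient measures, each clamped to `[0, 1]`:

* **type 1** — `g = ||∇v||`, the Euclidean norm of central differences
  `gx = (v[x+1] − v[x−1]) / 2`, etc.
* **type 2** — `g = |v − S/10|`, `S` the sum over the 3×3×3 box minus the
  centre (26 neighbour values).
* **type 3** — `g = |v − S/70|`, `S` the sum over the 5×5×5 box minus the
  centre (124 neighbour values).

The divisors 10 and 70 are taken literally from the tool being re-implemented;
they are not the neighbour counts, so on a *constant* volume types 2 and 3
respond with `1.6·v` and `(124/70 − 1)·v` — the measure is intensity-shifted
(brighter phases give larger "gradients"). This is a feature for separating
phases of different density and a caveat for quantitative use: in a dense
phase with `v > 0.625` the type-2 measure saturates at the clamp, so the
discriminative signal at an interface is the contrast between the interface
band and the low-intensity side, not a peak above the dense interior.

Borders use **replicate padding**. This keeps constant volumes exactly
constant everywhere (making the analytic values above testable to 1e-9 at
border voxels too) and avoids inventing out-of-scan data. A brute-force
per-voxel oracle (`gradient_field_oracle()`) with explicit neighbourhood
loops ships in the package and the tests require agreement within 1e-9.

Selection (`threshold_select()`) is the closed-interval conjunction of a
value range and a gradient range ("multiple-thresholding"); closed intervals
match the histogram-bracketing workflow (`histogram2d()` gives the joint
value×gradient counts practitioners bracket on).

## Morphology

Binary dilation and erosion with radius-1 structuring elements of
connectivity 6, 18 or 26 (default 6, the most conservative growth; the
original tool does not document its neighbourhood, so it is a flag).
Out-of-volume voxels count as *unset* for both operators: deterministic, and
consistent with "no object beyond the scan". The price is that erosion always
clears the border shell, so dilation/erosion duality and closing-extensivity
hold on interior voxels only — tests check them there, against brute-force
loop oracles. Per-tag morphology (`morph_tags()`) resolves contested growth
deterministically: tags are processed ascending and the first claim wins;
existing foreign territory is never overwritten.

## Painter, components, extraction

The brush is a Euclidean sphere in voxel units (anisotropy is deliberately
ignored at paint time; a world-unit brush would couple the footprint to the
sidecar voxel size, which is better done explicitly by the caller). Stroke
polylines are sampled at half-radius spacing so the swept tube has no gaps.
Painting overwrites (last write wins, and order matters only inside footprint
overlaps — the tests assert exactly that); erasing clears only the stroke's
own tag, protecting multi-structure labelings; an optional restriction mask
confines modification to the active selection, the scriptable counterpart of
painting inside a threshold selection. Tags are 1–255 (8-bit storage).
`connected_components()` labels in first-encounter raster order (z, y, x) so
labelings are reproducible; `extract_tag()` crops to the tag's tight bounding
box, keeps tagged voxels and pads the rest — the "export the region of
interest as its own volume" step.

## Seeded segmentation

The upstream tool names its two seeded modes but publishes neither an energy
nor a cost model, so tomoseg adopts the field-standard formulations and fixes
every constant for determinism:

* **Graph cut**: hard-seeded binary labeling minimizing
  `Σ D(p, L_p) + λ Σ exp(−(v_p − v_q)² / 2σ²)·[L_p ≠ L_q]`, with data terms
  `−log P` from 32-bin histograms of the seed intensities (probability floor
  1e-6). Solved exactly: the max-flow solve is delegated to igraph, and the
  returned labeling is the *minimal source side* of the residual graph, so
  voxels indifferent between the labels go to background — a documented,
  deterministic tie-break. Tests enumerate all labelings on ≤16-voxel
  instances and require the returned energy to equal the exhaustive minimum.
  Graph memory scales with voxel count; run it on cropped sub-volumes.
* **Livewire**: per-slice minimal-cost 8-connected path, step cost into pixel
  `q` of `(w_g (1 − G(q)) + w_u)·len` with `len ∈ {1, √2}` and `G` the
  slice-normalized central-difference gradient magnitude (defined 0 on a
  constant slice). Defaults `w_g = 1`, `w_u = 0.1`. Dijkstra is hand-rolled
  for tie-break control (lexicographically smallest node expanded first,
  strict-improvement relaxation); an igraph shortest-path on the same
  weighted lattice is the independent oracle in the tests. Note the
  central-difference `G` vanishes *on* a one-pixel dark ridge line and peaks
  on its flanks — paths hug the flanks of such a ridge.
* **Contour interpolation**: intermediate masks are zero-sublevel sets of the
  blended signed Euclidean distance fields, `(1−t)·d_a + t·d_b ≤ 0` at
  `t = k/(n+1)` (EBImage's distance transform supplies `d`). For widely
  separated shapes the blend can have an empty zero-sublevel set at
  intermediate `t`; the area-interpolation property holds when the distance
  fields overlap. The function always raises a
  `tomoseg_warning_reproducibility`: interpolated slices are synthesized
  anatomy, discouraged for palaeontological material.

## Meshing

Isosurfaces are extracted at iso 0.5 from the binarized mask after a 1-voxel
zero pad (boundary-touching selections still close) by **marching tetrahedra
on the Kuhn 6-tetrahedra cell decomposition** rather than the classic
256-case cube table: the decomposition is translation-invariant and
face-consistent, has no ambiguous configurations, and therefore guarantees a
closed, consistently outward-oriented 2-manifold for *every* input — the
watertightness invariant the rest of the pipeline (enclosed volume by signed
tetrahedra) relies on. On a digital ball of radius 10 voxels the enclosed
mesh volume is within ~1% of the analytic sphere.

The "smoothing factor" is the number of shrink/inflate
(`λ = 0.5, µ = −0.53`) uniform-weight fairing steps — volume-preserving by
construction, unlike plain averaging which would thin laminae; factor 2
changes the ball volume by ~0.01%. "X% decimation" removes X% of triangles by
quadric-error edge collapse down to `ceil(F·(1 − X/100))` faces (candidate
positions: endpoints and midpoint — robust, no 4×4 solve), with the link
condition and a normal-flip check protecting the manifold; collapses stop
early only if no legal collapse remains. The recommended pipeline setting,
smoothing factor 2 + 50% decimation, halves the triangle count (and roughly
the file size) while keeping the ball volume within 5%. Meshes export to
binary STL (84 + 50·F bytes), ascii PLY and ascii OBJ; STL is a triangle
soup, so reload re-merges vertices at 1e-6.

## The synthetic phantom

`generate_phantom()` paints ordered phases (ellipsoid / spherical shell /
box; later phases overwrite) into a unit-scale field, applies Gaussian
partial-volume blur *then* seeded Gaussian noise (the physical order:
reconstruction blur before detector noise), clips and quantizes. Noise is
Gaussian at a stated fraction of full scale — adequate for operator testing
with one fewer parameter than Poisson. A private, seed-controlled RNG stream
makes output bit-identical under a fixed spec + seed without touching the
caller's RNG.

`preset_fossil_cheek()` emulates a cropped scan of a fossil cheek region at
the case-study characteristics (16-bit, 21 µm voxels): matrix 0.15, dermal
plate 0.85, two ossicle-like inclusions 0.55, blur 0.7 voxels, noise 2% of
full scale. The geometry is a thick (≈0.47·min(dim) voxels, ≈0.44 mm at
21 µm — a realistic dermal-plate thickness), gently curved plate: a spherical
shell whose centre lies far below the volume, so the plate crosses the lower
field-of-view boundary exactly as a real cropped region of interest does.
This choice is deliberate and was made analytically before implementation:
with blur σ = 0.7 the first voxel layer at any in-volume phase boundary
blurs to ≈0.70 < 0.75 and is lost to a [0.75, 1.0] bracket, so a free-floating
shell (or even a solid ball) at 64³ cannot reach Dice 0.95 against its ground
truth — its surface-to-volume ratio is too high. A plate cropped by the field
of view has only its *outer* face as an in-volume boundary, and replicate
padding keeps boundary-crossing faces loss-free; the predicted Dice ≈ 0.98
is what the tests measure. What the phantom does *not* emulate: beam
hardening, ring artifacts, reconstruction streaks, intensity inhomogeneity.
Passing tests therefore demonstrate operator correctness, not robustness to
every real-scan artefact — the gradient operators in particular are known to
be noise-sensitive.

## Problem sizes and determinism

The test suite runs the phantom at 32–64³, oracle equivalences at ≤8³
(gradients) and 6³ (morphology/components), graph-cut enumeration at ≤16
voxels × 20 instances, livewire oracles at ≤10×10 × 20 slices, and meshing
on a radius-10 ball — sizes chosen so every exhaustive oracle stays
exhaustive while exercising the same code paths as production volumes. All
randomness is seed-controlled; identical config + seed reproduces every
volume, mask, tag and mesh artefact byte-exactly, and the CLI writes a JSON
manifest (parameters, input MD5s, package version) next to each output.

## Known limitations

* Whole-scan graph cuts are memory-bound (voxel-count-scaled graph); crop first.
* Livewire's O(V²) node selection targets interactive slice sizes, not full-frame batch tracing.
* No out-of-core volumes, DICOM/NIfTI/NetCDF containers, grayscale morphology, or GPU max-flow.
* The upstream tool's own energies, cost features and mesher are unpublished; tomoseg's formulations are standard, deterministic stand-ins, and no bit-level equivalence with the GUI is claimed (its binary volume container is likewise not parsed — the raw + sidecar format replaces it).
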