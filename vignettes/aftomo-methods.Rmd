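---
title: "Methods: autofluorescence OPT analysis with aftomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autofluorescence OPT analysis with aftomo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aftomo)
```

## Scope and model

`aftomo` implements the computational chain of a label-free
autofluorescence (AF) optical projection tomography (OPT) study of
pancreatic tissue: raw projection stacks are range-cut and
contrast-equalized, the center-of-rotation (COR) misalignment is estimated
and corrected, tomographic sections are reconstructed by filtered
back-projection (FBP), bright islets of Langerhans and dark
(low-AF, tumor-like) regions are segmented in 3D, and per-islet statistics
are binned into size distributions comparable with stereological reference
tables.

The optical model is parallel-beam: OPT scanners image through a telecentric
path, so each detector pixel integrates fluorescence along a straight ray,
and rotating the specimen by `theta` is equivalent to rotating the
integration direction. Under this model the 2D Radon transform applies
slice-by-slice along the rotation (z) axis, and FBP is the exact inverse in
the noiseless dense-angle limit. We deliberately do not model the optical
point-spread function, light-sheet thickness, scattering, refractive-index
mismatch, or cone-beam geometry.

## The synthetic phantom

Real AF-OPT biopsies require donors, clearing chemistry and a scanner; every
stage here is instead validated by parameter recovery on a synthetic phantom
whose ground truth is known voxel-exactly:

* an ellipsoidal *parenchyma* block (semi-axes 90% of the inscribed
  half-extents in-plane, so projections never truncate) of constant
  intensity;
* spherical *islets* with diameters drawn from a lognormal law (default
  `meanlog = log(100)` µm, `sdlog = 0.4`, the right-skewed 50–300 µm range
  reported for human islets), placed by rejection sampling so that they are
  pairwise non-overlapping;
* optional straight cylindrical *vessels* and an optional darker embedded
  ellipsoid standing in for *tumor* tissue (`intensity_factor < 1`;
  pancreatic ductal adenocarcinoma shows markedly lower AF than normal
  parenchyma);
* acquisition artifacts: a COR offset applied to every frame, Gaussian or
  Poisson–Gaussian noise, and an optional smooth illumination gradient.

Two generator choices deserve justification:

**Minimum islet separation.** `phantom_spec(min_separation_vox = 3)`
enforces a 3-voxel clearance between islet surfaces. Two tangent spheres are
already connected in the voxel grid after rasterization, and objects closer
than the reconstruction point-spread width (~2–3 voxels for a Hann-filtered
FBP) are unresolvable by any threshold-plus-connected-components
segmentation; at the default islet load roughly a quarter of zero-clearance
islets would have a neighbor within 2 voxels. A phantom intended to
*validate recovery* must therefore keep distinct objects separated by at
least the system resolution — this is a well-posedness requirement, not a
difficulty dial. Biologically, islets are embedded in exocrine tissue and a
30 µm (at 10 µm voxels) separation is unremarkable.

**Noise reference level.** The noise amplitude is specified as a fraction of
the stack's *parenchyma signal level*, operationalized as the median
positive projection value. The acquisition description cannot see phantom
intensities, and the median line integral through a mostly-parenchyma
specimen is the natural scanner-side analogue of "percent of tissue
signal". `poisson_gaussian` maps that same reference level to 10^4 expected
photons before adding Gaussian read noise.

The islet:parenchyma AF contrast in the near-infrared channel is not a
published tissue constant; the default 3:1 is a free configuration
parameter, and all segmentation thresholds are scale-invariant so absolute
contrast only affects the signal-to-noise ratio.

What the phantom does *not* emulate: spatially varying PSF blur,
autofluorescence texture inside parenchyma (it is piecewise constant),
bleaching gradients, refraction at the specimen surface, and mechanical
wobble of the rotation stage. Passing the recovery benchmarks therefore
demonstrates the correctness of the *algorithms*, not the performance of the
chain on arbitrary real biopsies.

## Preprocessing

`cut_range()` clips the stack at global percentiles (defaults 1 / 99.5 —
hot-pixel removal without flattening islet signal; the exact cut values used
on the original scanner data are not documented anywhere authoritative) and
rescales to [0, 1]. `apply_clahe()` performs contrast-limited adaptive
histogram equalization per frame on a 32 × 32-pixel tile grid with clip
limit 0.01 (fraction of tile pixels; mild limiting). The tile machinery is
EBImage's; frames not divisible by the tile are edge-padded and cropped
back, and a degenerate 1 × 1 grid falls back to global clipped equalization.

CLAHE is non-linear and alters relative intensities, so the pipeline
separates its two uses: the COR *estimation* runs on the CLAHE-equalized
stack (registration benefits from normalized contrast), while the
*reconstruction* consumes, by default, the range-cut-only projections
(`pipeline_config(reconstruct_from = "range_cut")`). Quantitative islet
statistics are therefore computed on an intensity scale that is an affine
map of the raw line integrals.

## Center-of-rotation alignment

For conjugate frames, the 180°-rotated projection mirrored about the
detector center equals the 0° projection translated by twice the COR
offset. `estimate_cor()` registers each conjugate pair by discrete-Fourier
phase correlation: Hann-windowed frames, normalized cross-power spectrum,
coarse peak from the inverse FFT, then refinement by evaluating the
correlation surface on a 1/10-pixel grid within ±0.75 px of the coarse peak
(a small matrix-product DFT). Half the horizontal shift is the pair
estimate; the robust aggregate is the median over pairs, with pairs below a
peak-quality floor (0.2) discarded and an all-weak stack raised as an
error. `apply_cor_correction()` translates every frame by the negated
offset using an exact Fourier phase ramp (the Nyquist bin is zeroed for
even widths); a zero offset bypasses interpolation entirely, and offsets
beyond a quarter frame width are refused as implausible. Only the
horizontal offset is modelled — vertical drift and axis tilt are out of
scope.

Measured behavior on simulated stacks: recovery of injected integer and
sub-pixel offsets to ±0.1 px noise-free and ±0.25 px at 2% Gaussian noise,
estimate–correct–re-estimate residuals ≤ 0.1 px, and exact ±k equivariance
under integer detector shifts.

## Reconstruction

`reconstruct_volume()` rearranges the stack into per-row sinograms
(lossless transpose, with a uniform-angle check), folds full-turn data by
averaging conjugate rays into a 180° sinogram (halves the work and the
noise; an odd full-turn angle count is instead back-projected directly with
the scale doubled), filters each angular row in the frequency domain and
back-projects with linear interpolation at scale `pi / (2 n_angles)`.

The filter is built from the band-limited spatial ramp (`h(0) = 1/4`,
`h(odd k) = -1/(pi k)^2`, zeros elsewhere) evaluated on a zero-padded
power-of-two grid — constructing the ramp in the spatial domain avoids the
DC bias of a naively sampled `|f|` — times a window: Hann (default),
Shepp-Logan, or none. With this convention a uniform disc of density 1
reconstructs to interior mean 1.000 and interior normalized RMSE 0.0013 at
400 angles, and interior error decreases monotonically over 50–400 angles.
Voxels outside the inscribed circle, which parallel-beam data do not
determine, are zeroed by default.

No ring-artifact, beam-hardening or smoothing corrections are applied: AF
phantoms have neither detector rings nor beam hardening, and commercial
reconstruction software's proprietary corrections are deliberately not
imitated, so reconstructions are comparable in structure rather than in
absolute gray values.

## Segmentation

`tissue_mask()` is global Otsu + largest 26-connected component + closing
(2-voxel ball) + 3D hole filling. Hole filling matters: a dark tumor
interior would otherwise be classified as background and escape all
downstream in-mask statistics.

`subtract_baseline()` estimates the diffuse background as a heavily
smoothed copy of the in-mask intensity (default sigma 200 µm, far above
islet diameters) by *masked normalized convolution* — smoothing `v·w` and
`w` separately and dividing — so tissue edges do not bleed into the
estimate. Because bright islets occupy a substantial volume fraction, a
single smoothed copy is biased upward; a second pass excludes voxels more
than 2 robust SD above the first-pass residual. The smoother is a cascade
of three box filters matched to the requested sigma (near-Gaussian by the
central limit theorem, O(1) per voxel regardless of sigma). The robust
background spread, estimated from the *lower* residual tail (bright objects
only populate the upper tail), is recorded in the output metadata. The
subtracted volume is clipped at zero.

`label_islets()` thresholds inside the mask, labels connected components
(26-connectivity by default, so islets are not split across diagonal voxel
contacts), applies the voxel number filter (default 27 voxels = a 3×3×3
minimum resolvable islet) and relabels consecutively. The default threshold
is in-mask Otsu rather than a low k·sigma detection threshold: on the
standard recovery phantom a 4-sigma-above-background threshold sits at
~10% of the islet amplitude, where the FBP point-spread skirt is included —
measured effect, median diameter +15% and dozens of merged neighbors —
whereas Otsu lands near half-amplitude, the full-width-at-half-maximum
convention that sizes blurred spheres essentially without bias (measured
median diameter error 1.9%). `k_sigma` remains available for
low-contrast detection work.

`remove_artifacts()` drops components whose bounding-box elongation
(longest/shortest extent) exceeds 6 — hairs and streaks are thin and long,
islets compact — and components touching the volume border. This replaces
interactive curation with reproducible rules.

`delineate_low_af_region()` splits the in-mask intensities at Otsu and
keeps connected low components above the voxel filter, after eroding the
mask by 2 voxels: the partial-volume shell at the specimen surface is dark
for optical, not histological, reasons. An empty low region is a valid
(tumor-free) outcome and produces a warning, not an error.

## Quantification

`measure_islets()` reports, per component: voxel count, physical volume
(count × voxel³), axis-aligned bounding-box extents in µm (spanned voxels ×
voxel size), the **mean 3D diameter** — the arithmetic mean of the x, y and
z extents, the categorization norm used for islet size distributions —
centroid, and intensity sum. Principal-axis (Feret) lengths would be less
orientation-sensitive but the bounding-box reading is the documented
convention and is kept. `size_distribution()` bins diameters into half-open
categories `[lo, hi)` (an edge value goes up; default 25 µm bins over
0–400 µm — the published categorizations do not state their edges, so they
are fully configurable) and also emits per-category summed volume, since
"islet mass distribution" can mean count- or volume-weighted; both are
reported. `compare_to_reference()` computes per-category fraction
differences, total-variation distance and the chi-square statistic against
reference fractions (dof = categories − 1) with no verdict attached; the
reference (e.g. a published stereological table) is user-supplied CSV.
Export is full-precision CSV (`%.17g`): open, diffable, and exactly
round-trippable.

## Pipeline, provenance, reproducibility

`run_pipeline()` chains simulate (or ingest) → preprocess → align →
reconstruct → segment → quantify into a run directory, with a YAML
configuration validated fail-fast (unknown keys are errors), the effective
config written beside the outputs, and a per-stage provenance record
(parameter-chain hash, wall time). Stage identities are *chained parameter
hashes* — a stage's hash folds in everything upstream — so cache validity
does not depend on bit-identity of lossy float32 intermediates, a stage
re-executes whenever its record, outputs or upstream change, and identical
configurations reproduce identical output hashes. One global seed fans out
to per-stage seeds by a fixed affine derivation, so stochastic stages are
independently reproducible. All volumes travel as multi-page TIFF with YAML
sidecars (geometry, value scaling); integer data within 16 bits round-trip
losslessly, float data as float32.

The spec-style command-line surface is covered by the exported functions
plus `run_pipeline()` on a YAML config; users of this package drive it from
R.

## Validation problem sizes

The shipped test suite validates, among ~50 properties: end-to-end recovery
on a 192³-voxel phantom with 500 islets, 400 projections, +3.7 px COR
offset and 2% noise (COR error ≤ 0.5 px, count within 5% of the islets at
least 4 voxels wide, matched median diameter error ≤ 10%, two-sample KS
distance < 0.1); disc reconstruction fidelity (interior mean ±5%, nRMSE
< 0.10, monotone in angle count); alignment fixed-point and equivariance
over ±8 px; exact voxel-filter and connectivity semantics; tumor recovery
(Dice ≥ 0.9, volume ±10%) on a 128×128×96 phantom at 240 angles; and exact
closed forms for the diameter, chi-square and intensity-sum statistics.
Unit tests use 48³–96³ phantoms so the whole suite runs in a few minutes on
one CPU; the same quantities at the full sizes above are recomputed by
`scripts/acceptance.R`.

## Known limitations

* Parallel-beam only; no PSF or scattering model, so absolute sizing on real
  data inherits any scanner-specific blur bias.
* Low-AF delineation assumes a bimodal in-mask intensity split; specimens
  with islets *and* tumor would need the bright voxels masked out first
  (compose `label_islets()` and `delineate_low_af_region()` accordingly).
* Only horizontal COR misalignment is corrected; axis tilt and per-frame
  jitter are not modelled.
* Vessel-like structures are generated and labeled but not quantified
  (no centerline extraction).
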