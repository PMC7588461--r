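# aftomo

Label-free autofluorescence optical projection tomography (OPT) analysis
for pancreatic tissue, in R.

Optically cleared pancreatic specimens imaged in an OPT scanner show strong
endogenous fluorescence contrasts without any staining: islets of
Langerhans appear as bright droplet-like objects in the near-infrared
channel, while pancreatic ductal adenocarcinoma (PDAC) tissue is markedly
*darker* than normal parenchyma. `aftomo` implements the full computational
chain that turns raw projection stacks into quantitative 3D islet and tumor
measurements, for imaging scientists and quantitative pathologists who want
an open, scriptable, fully testable alternative to the commercial
reconstruction/surfacing tools usually used for this work:

1. **Projection preprocessing** — global percentile range cutting and
   per-frame CLAHE (32 × 32 tile grid).
2. **Misalignment correction** — center-of-rotation (COR) estimation by
   DFT phase correlation of conjugate (θ, θ+180°) frame pairs with 0.1 px
   sub-pixel refinement, then Fourier-interpolated correction.
3. **Reconstruction** — parallel-beam filtered back-projection with a
   windowed band-limited ramp (Hann default), conjugate-ray folding of
   full-turn data, `π/(2 n_angles)` scaling.
4. **3D segmentation** — tissue mask (Otsu + largest component + closing +
   hole filling); islet extraction by baseline subtraction, scale-invariant
   thresholding, 26-connected components, a voxel number filter and
   rule-based artifact (hair) removal; low-AF tumor delineation.
5. **Quantification** — per-islet records (voxel count, volume, bounding-box
   extents, the mean 3D diameter `(x + y + z)/3`, intensity sum), half-open
   size-category distributions (count- and volume-weighted), chi-square /
   total-variation comparison against user-supplied stereological reference
   tables, MIPs, and full-precision CSV export.
6. **Synthetic phantoms** — a ground-truthed generator (lognormal islets,
   vessels, low-AF tumor ellipsoid, COR offset, noise, illumination
   gradient) plus a parallel-beam forward projector, so every stage is
   validated by parameter recovery without any specimen data.

The core statistic is the *mean 3D islet diameter*: for each segmented
islet the arithmetic mean of its axis-aligned extents, `d = (dx + dy +
dz)/3`, binned into half-open size categories `[lo, hi)` to form the islet
size distribution that is compared against stereological reference data via
per-category fraction differences, total-variation distance and
`χ² = Σ (Oᵢ − Eᵢ)²/Eᵢ` with `dof = categories − 1`.

## Worked example

Simulate a 96³ phantom with 40 islets, acquire 200 noisy projections with a
+2.4 px COR offset, and recover the islets:

```r
library(aftomo)

spec <- phantom_spec(shape_vox = c(96L, 96L, 96L), voxel_size_um = 10,
                     n_islets = 40L, islet_diameter_log_mu = log(100),
                     islet_diameter_log_sigma = 0.3, seed = 7L)
phantom <- generate_phantom(spec)
stack <- forward_project(phantom$volume,
                         acquisition_spec(n_angles = 200L, cor_offset_px = 2.4,
                                          noise_model = "gaussian",
                                          noise_scale = 0.02, seed = 7L))
stack <- cut_range(stack, preprocess_params(clahe_enabled = FALSE))
(alignment <- estimate_cor(stack))
#> <alignment_result> cor_offset_px = 2.425 (median of 100 conjugate pairs, phase_correlation)

volume <- reconstruct_volume(apply_cor_correction(stack, alignment))
params <- segmentation_params()
mask <- tissue_mask(volume)
labels <- remove_artifacts(
  label_islets(subtract_baseline(volume, params, mask), params, mask), params)
islets <- measure_islets(labels, volume)
nrow(islets)                                   # 40 of 40 islets recovered
median(islets$mean_diameter_um)                # 105 um (truth: 105.2 um)

size_distribution(islets, seq(0, 400, 50))$counts
#> [1]  0 16 19  3  2  0  0  0
```

The injected 2.4 px axis offset is recovered to 0.025 px, all 40 islets are
found, and the median mean-diameter of the recovered set differs from the
generating truth by 0.2 µm. The same chain runs as one reproducible,
cached, provenance-tracked pipeline from a YAML config via
`run_pipeline(config, out_dir)` — see the methods vignette
(`vignettes/aftomo-methods.Rmd`) for the model, parameter and design
discussion.

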