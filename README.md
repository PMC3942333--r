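# choroidseg

Fully automatic segmentation of the **choroid** in enhanced depth imaging
OCT (EDI-OCT) B-scans, for researchers who need choroidal thickness
measurements without manual tracing.

The choroid is the vascular layer between Bruch's membrane (BM) and the
sclera. Its lower boundary, the choroid–sclera interface (CSI), is too
faint and the layer too heterogeneous for intensity-based retinal layer
segmentation — but the choroid differs from the sclera in *texture*
(dark vessel lumina vs. a homogeneous matrix). `choroidseg` implements a
texture-based pipeline:

1. **RPE** — minimum-cost path by dynamic programming on the inverted
   brightness, `C(x_k^{m+1}) = min_{i∈{-1,0,1}} C(x_{k+i}^m) + c(x_k^{m+1})`,
   with deterministic tie-breaking;
2. **BM** — the maximal axial gradient magnitude within 8 px below the
   RPE, median-smoothed; all pixels above BM are zeroed;
3. **texture model** — per-pixel 5-d descriptors from a 4-level
   undecimated Haar wavelet frame (`H(z) = (1+z)/2`, `G(z) = (z−1)/2`;
   windowed energies of 4 detail levels + the approximation), modeled by a
   3-component Gaussian mixture `Σ_k π_k N(μ_k, Γ_k)` fitted *supervised*
   from labeled masks (no per-image EM; `em_refine()` optional);
4. **CSI** — per-pixel posteriors `p_jk` enter unary costs
   `−log(p + eps)`, a constant Potts term (`r = 4`) enforces spatial
   coherence, the 3-label energy is minimized by α-expansion
   (each move an exact s–t min-cut via a compiled Dinic max-flow), and
   the CSI is the deepest choroid-labeled row per column.

Also included: a seeded synthetic phantom generator with ground-truth
RPE/BM/CSI curves and masks, k-means / intensity-graph-cut / DP
comparison baselines, signed and unsigned border positioning error
metrics (px and µm at 3.9 µm/px axial resolution), raster/CSV/JSON I/O,
and a thin CLI (`inst/cli/choroidseg.R`).

## Worked example

```r
library(choroidseg)

# 100 synthetic EDI-OCT phantoms (248 x 384), 10 for training
ds    <- generate_dataset(phantom_spec(), n_images = 100, base_seed = 1)
train <- ds$samples[ds$manifest$train]
test  <- ds$samples[ds$manifest$test]

fit <- fit_choroid_model(lapply(train, `[[`, "image"),
                         lapply(train, `[[`, "mask"))
print(fit)
#> Choroid segmentation model
#>   trained on 10 image(s), supervised moment fit
#>   mixture: K = 3 over 5-d wavelet energy descriptors
#>   class weights: 0.258 0.282 0.460

seg <- predict(fit, test[[1]]$image)
print(seg)
#> Choroid segmentation of a 248 x 384 B-scan
#>   mean rows: RPE 60.0, BM 64.2, CSI 135.9 (thickness 71.7 px = 280 um)
#>   graph-cut energy: 4965.50

boundary_errors(seg$csi, test[[1]]$csi_true)
#> $signed_px   [1] 1.924479
#> $unsigned_px [1] 3.127604
#> $signed_um   [1] 7.505469
#> $unsigned_um [1] 12.19766
```

The mean row positions and the per-boundary errors are in pixels; one
axial pixel is 3.9 µm. A signed error > 0 means the predicted boundary
lies deeper than the truth; the unsigned error is the mean absolute
per-column deviation. `plot(seg, test[[1]]$image)` overlays BM (green)
and CSI (red) on the scan.

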