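# ihcnorm

Color normalization and unsupervised nuclei classification for breast-cancer
immunohistochemistry (IHC) images.

IHC slides carry two stains — hematoxylin (blue, counterstains every
nucleus) and DAB (brown, marks immunopositive nuclei). Staining protocol and
scanner response shift the colors from slide to slide, which degrades both
pathologist scoring and automated analysis. `ihcnorm` maps a source image
onto the color appearance of a preferred target image while preserving the
tissue structure, and provides the metric and classifier needed to evaluate
the result. It is written for image-analysis researchers and pipeline
builders; everything is exercisable on synthetic scenes with full ground
truth, so no clinical data are required to test it.

## What is inside

Working in Beer–Lambert optical density, where a two-stain image is a
non-negative linear model `OD = V S` (V: 3×2 unit-norm stain color vectors,
S: 2×n per-pixel stain densities):

* `rgb_to_od()` / `od_to_rgb()` — Beer–Lambert transform and inverse.
* `stress_image()` — STRESS local contrast stretching: per pixel, random
  "sprays" of M samples over a disk of radius R, repeated N times, estimate
  white/black envelopes `E_max`, `E_min` and the pixel maps to
  `(p0 − E_min)/(E_max − E_min)`.
* `macenko_stain_vectors()` — SVD angle-percentile stain estimation;
  `nmf_factorize()` / `snmf_factorize()` — (sparse) non-negative matrix
  factorization `min ½‖OD − VS‖²_F + λ Σ_j ‖S(j,:)‖₁`, with exact reduction
  to plain NMF at λ = 0; `sparse_code()` — per-pixel non-negative lasso.
* `spcn_normalize()` — structure-preserving color normalization: rescale
  each source density row by the ratio of target to source pseudo-maxima
  (99% quantiles), recombine with the target basis,
  `OD_norm = V_target S_source_norm`.
* `rssfca_fit()` / `segment_image()` — robust self-sparse fuzzy clustering:
  memberships minimize `Σ u_ij Φ′(x_j|v_i, Σ_i) + γ Σ u_ij²` on the simplex
  under a Gaussian (Mahalanobis) dissimilarity, giving exactly-sparse
  memberships; used to split nuclei from background.
* `qssim_score()` — quaternion structural similarity for color images
  (each pixel a pure quaternion `r·i + g·j + b·k`).
* `classify_pixels()` / `classification_accuracy()` — unsupervised
  immunopositive/immunonegative calls at annotated pixels via automatic
  color deconvolution.
* `normalize_ihc()` — the full pipeline: STRESS both images → SPCN →
  RSSFCA segmentation of the stretched source → merge (nuclei pixels from
  SPCN, background pixels from STRESS).
* `make_scene()` — synthetic IHC scene generator with known basis,
  densities, masks and labels, the test oracle for everything above.

A command-line interface (`inst/cli/ihcnorm.R`) exposes the stages as
subcommands: `stress`, `stains`, `normalize`, `segment`, `qssim`,
`classify`, `synth`, `run`.

## Worked example

```r
library(ihcnorm)

source_scene <- make_scene(synth_config(height = 128, width = 128, n_nuclei = 12,
                                        radius_range = c(7, 11), seed = 31))
target_scene <- make_scene(synth_config(height = 128, width = 128, n_nuclei = 12,
                                        radius_range = c(7, 11), seed = 32))

res <- normalize_ihc(source_scene$image, target_scene$image,
                     pipeline_config(seed = 5), keep_intermediates = TRUE)
print(res)
#> IHC normalization result: 128 x 128 image
#>   stress_source   14.72 s
#>   stress_target   14.44 s
#>   spcn             0.67 s
#>   segment          0.81 s  (converged: TRUE, 37 iterations)
#>   merge            0.00 s

qssim_score(res$intermediates$stress_source, res$image)
#> 0.9984
```

The printed block reports per-stage timings and convergence; the QSSIM score
of 0.9984 says the normalized result is structurally almost identical to the
contrast-stretched source — the normalization changed stain appearance, not
tissue structure (1.0 would be pixel-for-pixel structural identity).

Classifying the scene's nucleus centers against their generating labels:

```r
ann <- scene_to_annotations(source_scene)
pred <- classify_pixels(source_scene$image, ann)
classification_accuracy(pred, ann$label)
#> accuracy 1.000 (TP 6 TN 6 FP 0 FN 0)
```

and the estimated stain basis (columns: hematoxylin, DAB; rows: R, G, B
optical densities) recovers the generator's ground truth:

```r
round(macenko_stain_vectors(od_flatten(rgb_to_od(source_scene$image))), 3)
#>      hematoxylin   dab
#> [1,]       0.662 0.247
#> [2,]       0.703 0.558
#> [3,]       0.259 0.792
```

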