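---
title: "Methods: stain normalization and nuclei classification for IHC images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stain normalization and nuclei classification for IHC images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcnorm)
```

## The problem

Immunohistochemistry (IHC) slides of breast tissue carry two stains:
hematoxylin, a blue counterstain that marks every nucleus, and DAB, a brown
chromogen that marks immunopositive nuclei. Staining protocol, reagent batch
and scanner response all shift the colors from slide to slide, which degrades
both visual scoring (e.g. Allred-style positivity assessment) and automated
feature extraction. Color normalization maps a source image onto the color
appearance of a pathologist-preferred target image. Doing this naively in RGB
destroys tissue structure; this package implements a structure-preserving
pipeline that works in optical-density space and recombines per-pixel stain
amounts with the target's stain colors, together with the quality metric and
the unsupervised nuclei classifier used to judge it.

## Models and procedures

### Beer–Lambert optical density

Transmitted intensity relates to stain amount exponentially, so RGB values
are not linear in concentration. The package works in optical density,
$OD_c = -\log(I_c / I^{blank}_c)$, with $I^{blank} = 255$ per channel for
8-bit images. In OD space a two-stain image is a non-negative linear model
$OD = V S$: $V \in \mathbb{R}^{3\times 2}$ holds unit-norm stain color
vectors and $S \in \mathbb{R}^{2\times n}$ the per-pixel stain densities.
Zero intensities are clamped to 1 before the log, bounding OD at
$\log 255 \approx 5.54$; the inverse transform clips to $[0, 255]$. Round
trips on $[1, 255]$ are exact to floating-point rounding.

### STRESS contrast stretching

STRESS estimates, per pixel and per channel, local white and black envelope
points from random "sprays": $M$ samples drawn uniformly over a disk of
radius $R$ (radius drawn as $R\sqrt{u}$), repeated $N$ times. Each spray
yields a sample range $r_i$ and the relative position $v_i$ of the pixel
inside that range ($v_i = 1/2$ when the range is zero); averaging gives
envelopes $E_{min} = p_0 - \bar v \bar r$ and $E_{max} = E_{min} + \bar r$,
and the output $(p_0 - E_{min})/(E_{max}-E_{min})$, which algebraically
equals $\bar v$. When $\bar r = 0$ (a constant neighborhood) the output is
defined as $1/2$, the limit consistent with the zero-range convention for
$v_i$.

Conventions this implementation fixes where the procedure leaves them open:
the spray excludes the center pixel, but the sample extremes include $p_0$
(the sample index set starts at the center), so $E_{min} \le p_0 \le
E_{max}$ holds by construction; samples falling outside the image are
redrawn up to a bounded retry count, then clamped to the border; repeats are
allowed. Defaults are $R = \max(H, W)$ — reading the whole image as one
illumination context — with $M = 30$, $N = 100$; noisier images need larger
$M, N$ since sampling error decays as $1/\sqrt{MN}$. The per-pixel sampling
loop runs in compiled code with a dedicated deterministic RNG stream seeded
from R's RNG, so `set.seed()` (or the `seed` parameter) fully determines the
output.

### Stain separation

Three estimators are provided:

* **SVD angle percentiles (Macenko)** — drop pixels whose max-channel OD is
  below $\beta$ (default 0.15), project the rest onto their rank-2 singular
  plane, normalize to unit length, and take the directions at the 1st/99th
  percentiles of the angle distribution as the stain vectors. Sign
  conventions (mean projected coordinate non-negative) make results
  reproducible across linear-algebra backends. Rank-deficient clouds (a
  single stain) raise an error rather than returning a fabricated second
  vector.
* **NMF** — alternating exact block minimization of
  $\tfrac12\|OD - VS\|_F^2$ with $V, S \ge 0$ and unit-norm columns of $V$
  (the scale lives in $S$). The density block is solved by vectorized
  non-negative least squares, the dictionary block column-wise in closed
  form over the non-negative unit sphere, so the objective is monotone
  non-increasing.
* **SNMF** — the same engine with an $\ell_1$ penalty
  $\lambda \sum_j \|S(j,:)\|_1$ on the density rows (default
  $\lambda = 0.1$); $\lambda = 0$ reduces exactly to NMF. Although the
  surrounding text of the method's source describes the sparsity as applied
  to $V$, the formula penalizes rows of $S$, and this package follows the
  formula. A grid-search helper over $\lambda$ is provided but off by
  default.

Initialization uses the SVD estimate when $r = 2$ (falling back to seeded
random data columns), which avoids the local minima of cold-started NMF.
Estimated bases are put in a canonical order — hematoxylin-like column
first, DAB-like second — by angular proximity to fixed canonical OD
directions (Ruifrok-style constants, documented in the source), with a
blue-channel-weight tie-break.

### Structure-preserving color normalization (SPCN)

Both images are factorized; the source density rows are rescaled by
$RM_t(j)/RM_s(j)$, where $RM$ is the row pseudo-maximum — the 99% quantile
(linear interpolation between order statistics; quantile dialects differ
across ecosystems, so the convention is fixed and documented). The
normalized image is $OD^{norm} = V_t S^{norm}_s$, mapped back to RGB. A row
rescaling never changes the support or spatial pattern of a stain — that is
what "structure-preserving" means operationally (rank correlation 1 per
row).

One design choice is deliberate: the $\ell_1$ penalty is used to *learn* the
bases, but the density maps entering the normalization are the unpenalized
non-negative projections onto those bases. Reconstructing from penalized
densities would bias every stained pixel brighter by roughly
$e^{\lambda}$-scale shrinkage, breaking the near-identity of
self-normalization; the penalty's job is identification, not
reconstruction. Degenerate all-zero density rows (single-stain sources) pass
through unscaled with a warning instead of dividing by zero.

### Robust self-sparse fuzzy clustering (RSSFCA)

Pixels are clustered by minimizing
$\sum_{ij} u_{ij}\,\Phi'(x_j\,|\,v_i,\Sigma_i) + \gamma\sum_{ij} u_{ij}^2$
over memberships on the probability simplex, with $\Phi = -\ln \rho$ the
negative log of a Gaussian density. (The source prints $\ln(-\rho)$, which
is undefined for a positive density; its own handling of negative $\Phi$
values makes clear $-\ln\rho$ is intended.) Tight covariances push $\Phi$
negative, so when the global matrix minimum is negative the whole matrix is
shifted up by it — a uniform shift that never changes a column's best
cluster. We read "the minimum" as the global matrix minimum rather than
per-column; a per-column shift would re-weight pixels relative to each
other.

The membership update is not printed in the source; completing the square
shows each column solves a Euclidean projection of $-\Phi'_j/(2\gamma)$ onto
the simplex, computed by the standard sorting algorithm and certified in the
tests against exhaustive support enumeration. The quadratic regularizer
yields *exact* zeros (self-sparsity). Centers and covariances are
membership-weighted means and covariances; every covariance gets
$10^{-6} I$ diagonal loading so it stays positive-definite when a cluster
collapses. Initialization is 20 iterations of standard fuzzy c-means
(fuzzifier 2, seeded draw of centers from data points).

Defaults: $c = 2$ (background vs nuclei — the pipeline's segmentation task
names only those two classes; $c$ is configurable for finer partitions),
$\gamma = 3$ on $[0,1]$-scaled RGB features (small enough relative to the
$\Phi'$ spread of separated clusters that memberships are hard almost
everywhere), convergence threshold $\eta = 10^{-5}$ on the objective change,
at most $T = 100$ iterations. Segmentation calls the cluster with the
highest-luminance center "background" (IHC backgrounds are near-white) and
reassigns connected nuclei components smaller than $10^{-4}$ of the image to
background — a simple, documented area filter standing in for
connected-component post-processing described only in prose in the original
clustering method.

### QSSIM

Each RGB pixel becomes a pure quaternion $r\,i + g\,j + b\,k$ on the $[0,1]$
scale. Over 8×8 windows (stride 1, uniform weights; a `global` flag
evaluates the formula once over the whole image), the score is the modulus
of the product of a luminance term
$2\mu_{ref}\,\overline{\mu_{deg}} / (|\mu_{ref}|^2 + |\mu_{deg}|^2)$ and a
structural term $2\sigma_{ref,deg}/(\sigma^2_{ref} + \sigma^2_{deg})$, where
$\sigma_{ref,deg}$ is the quaternion cross-covariance (Hamilton product with
conjugation of the second factor). The formula as printed has no
stabilizing constants; we add $\varepsilon = 10^{-12}$ to each denominator
*and to the scalar part of each numerator*, which defines the
constant-window limit so that two identical flat windows score exactly 1 —
with $\varepsilon$ in the denominators only, a flat pair would score 0. The
implementation evaluates window moments with summed-area tables and caps the
cross-covariance modulus at its Cauchy–Schwarz bound
$\sqrt{\sigma^2_{ref}\sigma^2_{deg}}$ — mathematically a no-op that
suppresses catastrophic cancellation in flat windows. Windowing and pooling
conventions are this package's (the metric's reference script is not
recoverable); they are exposed in `qssim_params()`.

### Nuclei classification (CNACD)

The basis is estimated from the image, per-pixel densities are sparse-coded
($\lambda_1 = 0.1$), each stain's rank-1 OD contribution is rebuilt as an
RGB image and converted to grayscale with fixed luma weights
(0.299, 0.587, 0.114), and an annotated pixel is called immunonegative when
the DAB reconstruction is strictly lighter than the hematoxylin one, with
ties going to "+". Accuracy is $(TP+TN)/(TP+FN+TN+FP)$ with "+" the positive
class.

One deviation from the procedure as printed deserves emphasis. The source
invokes the stain-vector search with an infinite OD threshold, which read
literally ("remove data with OD less than infinity") deletes every pixel, and
read as "no filtering" makes the estimator collapse on any image whose
near-white background carries noise: background OD vectors of near-zero
magnitude get normalized to unit length, their directions are essentially
random, and the robust angle extremes land in that noise (measured here:
classification accuracy falls to chance at OD noise $\sigma \ge 0.01$).
`classify_pixels()` therefore defaults to the standard $\beta = 0.15$
filtering, which is precisely the mechanism designed to exclude those
pixels; `beta = NA` still exposes the literal no-filter behavior.

### Pipeline and merge

The end-to-end normalization: STRESS-stretch source and target; SPCN the
stretched source onto the stretched target; segment the stretched source
with RSSFCA; composite the result — nuclei pixels from the SPCN output,
background pixels from the STRESS output. The merge rule is inferred from
the method's published figure panels and complexity table rather than stated
prose, so it is isolated in one function (`merge_images()`) that can be
swapped. Only the source is segmented; the target's segmentation plays no
role. Stage seeds are derived from the master seed by fixed offsets so each
stage can be replayed independently and a run is bitwise reproducible.

## The synthetic scene generator

Real IHC study images are not redistributable, so every oracle in the test
suite is built on `make_scene()`: non-overlapping disk nuclei on a
near-white background, immunonegative nuclei carrying hematoxylin and
immunopositive nuclei DAB with a cosine radial falloff, densities mixed
through a known basis, additive Gaussian OD noise (clamped at zero), and
rendering through the inverse Beer–Lambert transform. Scenes carry their
full ground truth: mask, per-nucleus labels, true basis, true density maps.

Defaults, chosen once as representative of the imaging setting: 256×256
pixels, 25 nuclei with radii 8–16 px, half immunopositive, peak density
drawn from $U(0.8, 1.2)$ (OD magnitudes typical of well-stained nuclei),
flat background density 0.01 (a barely-off-white background), OD noise
$\sigma = 0.01$. By default each nucleus class carries only its own stain —
the generating model the stain-separation oracle presupposes; classifier
tests explicitly configure cross-stain bleed-through (peak $U(0.05, 0.25)$
against main $U(0.8, 1.2)$, i.e. a worst-case density ratio of 3.2) because
a finite positive:negative ratio requires both stains present. Tests use
smaller geometries (e.g. 96×96, 8 nuclei) for speed; density levels and
noise are kept at the defaults.

What the generator does **not** emulate: chromatin texture, overlapping or
non-circular nuclei, stromal tissue, scanner-specific noise, JPEG artifacts.
Passing tests therefore certify the algebra and the estimators against their
own generating model, not performance on clinical material.

## Numerical choices

* Coordinate descent for non-negative lasso coding: tolerance $10^{-8}$ on
  the largest coefficient change, 200 sweep cap; warm-started across
  factorization iterations so the outer objective is provably monotone.
* Factorization convergence: relative objective change below $10^{-6}$,
  200 outer iterations cap, convergence flag returned.
* Rank-deficiency guard in the SVD estimator: second singular value below
  $10^{-6}$ of the first raises an estimation error.
* Covariance ridge $10^{-6}$; quantile type 7; tie in the classifier goes
  to "+"; zero-range STRESS pixels map to 0.5.
* Problem sizes in the checks: default 256×256 scenes for stain-vector
  recovery, 96–128 px scenes elsewhere, 2000 points for the clustering
  benchmark, 200 random instances for the membership oracle.

## Known limitations

* STRESS with the default global radius is $O(HW\,MN)$; large images are
  costly (multi-scale radii are out of scope).
* The segmentation's area filter is a stand-in for the original
  connected-component density-balance mechanism, which is specified only in
  prose elsewhere.
* Single-pixel classification cannot resolve nuclei whose annotated pixel
  mixes both stains; neighborhood pooling is deliberately out of scope.
* QSSIM windowing conventions are package-defined; absolute scores are
  comparable within this package, not necessarily with other
  implementations.
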