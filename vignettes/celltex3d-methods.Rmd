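---
title: "Methods: volumetric texture analysis of abnormal colorectal cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volumetric texture analysis of abnormal colorectal cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Colorectal lesions progress along a continuum from benign hyperplasia (BH)
through intraepithelial neoplasia (IN) to carcinoma (Ca), and the visual
texture of the abnormal cell becomes increasingly disordered along that
continuum. `celltex3d` turns that qualitative observation into a
classification pipeline for multispectral microscopy volumes: a stack of 16
co-registered 8-bit grayscale images of one scene at successive wavelengths,
treated as a 3D array whose z-axis is spectral.

Texture is quantified with second-order statistics. For a displacement
vector `d·(dx, dy, dz)` the gray-level co-occurrence matrix (GLCM)
`P(i, j)` counts ordered voxel pairs with quantized levels `i` at a voxel
and `j` at the displaced voxel, both endpoints inside the segmented cell
(the mask is enforced at every band). Features are computed on the
normalized (probability) form of the matrix: entropy and maximum
probability are only meaningful for probabilities, and all 12 statistics
assume `Σ p(i, j) = 1`. Gray levels are 1-based (`1 … Ng`) in every moment
formula, which is what makes the sum-mean's index start at `i + j = 2`.

Two of the twelve statistics are duplicated by construction — contrast and
inertia are the same sum written two ways, as are homogeneity and the
inverse difference moment — and the package keeps all twelve to preserve
the conventional feature layout. The two members of the contrast/inertia
pair are evaluated through *different* summation orders precisely so the
test suite can verify the algebraic identity rather than an assignment.

## Direction geometry

In 2D, four unit directions (0°, 45°, 90°, 135°) suffice because the
opposite four only transpose the matrix (`P(d, θ) = Pᵀ(d, θ + 180°)`). In
3D the analogous construction takes one member of each antipodal pair of
the 26-neighborhood: 13 directions. Each direction keeps its own GLCM — no
symmetrization — because the grouped feature vectors are defined as
12 functions × 13 directions × offsets, i.e. 156 features per single-offset
group (G1 = offset 1, G2 = 2, G3 = 4, G4 = 8) and 624 for the concatenated
G5. Columns are laid out offset-major, then direction, then function, and
the column names are versioned so saved feature tables are comparable
across runs.

# Pipeline stages and their parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| mean-filter kernel | 3 × 3 | px | smallest standard smoothing window; size is not dictated by the method |
| `work_size` | 64 | px | active-contour working resolution; 512 → 64 makes the evolution ~64× cheaper while the mask resizes back losslessly enough for cell-sized objects |
| `max_iter` / tolerance | 200 / 1e-3 | — | iteration cap plus convergence on the mean level-set change |
| `Ng` | 32 | levels | quantization depth of the equalized cell; 32 keeps 32×32 GLCMs dense enough at cell-sized pair counts |
| offsets | 1, 2, 4, 8 | px | dyadic sweep from fine to coarse texture |
| ANOVA `alpha` | 0.01 | — | raw per-feature cutoff, no multiplicity correction (a Benjamini–Hochberg mode exists but is off by default, matching the raw-cutoff convention) |
| PCA `variance_target` | 0.97 | fraction | smallest component set explaining 97% of variance among the significant features |
| `nn_k` | 1 | neighbors | smallest-n regime; configurable |

**Segmentation.** The contour is the two-region piecewise-constant
(Chan–Vese) level set: region means `c1`, `c2` are recomputed each
iteration and the level set moves by `δ_ε(φ)[μ κ(φ) − (I − c1)² +
(I − c2)²]` with curvature `κ` from central differences, smoothed delta
`ε = 1`, curvature weight `μ = 0.2` on intensities scaled to [0, 1], and a
normalized time step (`dt = 0.5` relative to the maximal force). The
initialization is a centered circle of radius 0.3 × the working size. By
default segmentation runs once on the band-mean image and the mask is
applied to all bands (a per-band mode with majority voting exists). The
largest connected component is kept, standing in for an expert's selection
among multiple detected cells. A zero-variance reference errors out as a
degenerate input, and an empty contour raises a distinguishable
`celltex3d_empty_result` condition.

**Overlap metrics.** FPR and FNR are union-normalized set differences, the
unique definitions compatible with the identity `JSC = 1 − FPR − FNR`;
Dice uses the standard `2|A∩B| / (|A| + |B|)` denominator (with the union
denominator it would equal `2·JSC` and exceed 1).

**Equalization scope.** The cell is equalized with one CDF pooled over all
bands (per-band equalization is available). Pooling keeps gray levels
comparable along z, which matters for the 9 of 13 directions that cross
bands; per-band equalization would make level co-occurrence across bands
depend on each band's own histogram. The mapping is
`level = floor(Ng · CDF(v))` clipped to `Ng − 1`: monotone, and invariant
to strictly increasing intensity transforms because it is rank-based.

**Degenerate cases.** A GLCM with zero valid pairs is flagged rather than
zero-filled, and feature extraction refuses it naming the (sample,
direction, offset). A degenerate marginal (σx or σy = 0) returns
correlation 0 with a `degenerate` attribute instead of dividing by zero.
Zero-variance features are dropped before z-scoring with a warning. If no
feature passes the ANOVA cutoff inside a cross-validation fold, the five
smallest-p features are used, with a warning.

**Standardization and PCA.** The z-score uses the sample SD (n − 1). PCA is
fit on the z-scored significant features; component signs are fixed by
making each loading vector's largest-magnitude entry positive, so outputs
are reproducible and stable under feature permutation (up to sign).

**Cross-validation.** Leave-one-out, with the entire preparation (z-score,
ANOVA filter, PCA) refit on the 26 training samples of each fold and then
applied to the held-out sample. This is the default because selecting
features on all samples before cross-validation leaks the test label into
the feature set; a fit-once mode (`refit = FALSE`) exists for comparability
with protocols that select first. The decision tree is CART with Gini
splits, `minsplit = 2`, `minbucket = 1`, `cp = 0` (small-n regime, no
internal cross-validation); naive Bayes is Gaussian; nearest-neighbor is
Euclidean with `k = 1`. ROC scores for the pairwise AUCs are leaf class
fractions (DT), posterior probabilities (NB) and negative mean distance to
each class's nearest training points (NN); ties are handled by mid-ranks,
so a constant score gives AUC 0.5.

# The synthetic phantom generator

No clinical multispectral cell volumes are publicly deposited, so the
package generates labeled phantoms that emulate the *statistical* structure
the pipeline exploits, not the appearance of stained tissue:

* **Geometry.** One cell per volume: a smooth random-star polygon (radial
  harmonics 2–5, amplitudes ±6%) of mean radius 0.3 × image size, slightly
  off-center — non-circular so the active contour is non-trivially
  exercised. The area fraction stays within (0.05, 0.6).
* **Interior texture.** A band-correlated Gaussian random field:
  per-band Gaussian-smoothed white noise mixed with a shared low-frequency
  component (mixing weight ρ = 0.6) so spectral bands are redundant, as in
  a real wavelength sweep. The field is standardized and scaled, so the
  two class knobs act independently: `correlation_length` (BH, IN, Ca) =
  (8, 4, 2) px controls smoothness and `contrast_amplitude` = (20, 35, 50)
  gray levels controls within-cell spread. These defaults produce the
  monotone class ordering of texture statistics (entropy rising, energy
  falling from BH to Ca) without copying any published magnitudes.
* **Background.** A bright smooth field (185 ± 8, correlation length
  n/8 px) with a mild per-band brightness sweep, giving the contour a
  strong but not noiseless target.
* **Variability.** Each sample jitters the two texture knobs uniformly by
  ±10%, a parameter rather than a claim: intra-class variability across
  patients is unknown, so it is exposed as `jitter`.
* **Determinism.** One seed drives one RNG stream per phantom; cohort
  sample k uses `base_seed + k`. The same spec is bit-identical, and the
  generator restores the caller's RNG state.

What passing tests on phantoms do **not** show: robustness to staining
variation, to multiple touching cells, to uneven illumination, or to any
real H&E appearance — the generator makes no attempt at photorealism or
tunable-filter physics. The phantoms validate the machinery (counting,
formulas, selection, validation protocol), and the class separation is by
construction strong, so perfect LOOCV accuracy on the default cohort is
expected rather than impressive.

# Numerical and design choices

* GLCM counting is a compiled (C++) kernel; an independent brute-force
  enumeration over all voxel pairs serves as its test oracle on random
  masked volumes, for all 13 directions.
* The ANOVA filter computes the classical one-way F statistic vectorized
  over features with `pf()` for the p-value; `stats::oneway.test` is the
  independent oracle in the tests (agreement to 1e-10). The vectorized form
  keeps the per-fold refits of leave-one-out selection cheap.
* Gaussian smoothing (generator) and the mean filter are separable
  clamped-boundary operators applied as matrix products: exact
  edge-replication semantics, no FFT wrap-around, and fast at 512² with
  large kernels.
* Resizing uses block averaging for integer downscale factors and
  nearest-neighbor otherwise; masks are always upscaled nearest-neighbor,
  resizing the contour rather than the image.
* Percent metrics are rounded to 2 decimals only for display; raw
  fractions are retained everywhere.

# Problem sizes used by the tests

The default study conditions are 27 samples of 512 × 512 × 16. The unit
tests exercise the same code paths on smaller phantoms (32–128 px, 2–16
bands) to keep the suite quick; the end-to-end acceptance test and the
acceptance script run the full default cohort. Statistical calibration
tests use 200 null replicates (type-I error of the ANOVA filter at
α = 0.01, checked against binomial 99% bounds), 500 replicates for power
against a planted (0, 3, 6)-mean effect with unit noise, and 200 label
permutations for the LOOCV chance-level check.

# Known limitations

* Single-cell assumption: one region of interest per volume; no instance
  segmentation of touching cells.
* The Chan–Vese parameters are tuned for bright-background/dark-cell
  contrast of the phantom family; strongly textured backgrounds may need a
  different curvature weight.
* Offsets scale all three displacement components, so offset 8 along a
  z-crossing direction needs ≥ 9 bands; with fewer bands those GLCMs are
  empty and reported as errors rather than silently skipped.
* With 27 samples and 624 features the ANOVA filter at a raw p < 0.01
  keeps many correlated features; the PCA step absorbs the redundancy, but
  per-group selected counts are data-dependent and should not be read as
  stable quantities.
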