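# lsbias

Level set segmentation of 2-D grayscale images with intensity
inhomogeneity, with simultaneous estimation of the multiplicative bias
field and a local difference field.

## The problem

MR images (and many camera/CT images) are shaded by a smooth
multiplicative bias field — RF coil non-uniformity is the classic
source — which smears the intensity histogram of each tissue class and
breaks any segmentation method that assumes homogeneous class
intensities.  `lsbias` implements a region-based active contour model
for the forward model

```
I = b · J + d + n
```

where `I` is the measured image, `b` a slowly varying bias field, `J` a
piecewise-constant true image with class means `c_i`, `d` a local
difference field absorbing what `b·J` cannot explain (highlights, fuzzy
boundaries), and `n` additive noise.  A local clustering energy couples
the unknowns: per-class fit maps

```
f_i(x) = ∫ K_σ(y − x) (I(x) − b(y)·c_i − d(y))² dy
```

are weighted by level-set memberships and minimized by alternating
closed-form updates of `(c, b, d)` with explicit evolution of the level
set function(s), under a distance-regularization term
`α ∫ ½(|∇φ|−1)²` and a contour-length term `β ∫ |∇H_ε(φ)|`.  Two-phase
(one φ) and three-phase (two coupled φ, e.g. WM/GM vs background)
formulations are provided, plus the classic local-clustering baseline
(`baseline_li = TRUE`, difference field clamped to zero), overlap
metrics (Jaccard, Dice, false-positive/negative ratios), and a phantom
generator with exact ground truth.

Intended users: image-analysis researchers who need a reference
implementation of clustering-based bias correction, and anyone who wants
a fully testable, self-validating segmentation pipeline without external
image data.

## Worked example

```r
library(lsbias)

# a 128x128 T-shaped phantom: class means 60/160, linear-ramp bias
# 0.8-1.2, Gaussian noise sd 5
ph <- generate_phantom(default_phantom_suite()$tshape_bias)
ph
#> Phantom: 128x128, 2 classes (tshape), bias linear_ramp [0.8, 1.2], noise sd 5, seed 102

# seed: a small circle inside the object, away from its center
h <- 128; w <- 128
rr <- matrix(seq_len(h) - 1, h, w)
cc <- matrix(rep(seq_len(w) - 1, each = h), h, w)
seed <- (rr - 40)^2 + (cc - 70)^2 <= 15^2

res <- segment_two_phase(ph$image, seed)
res
#> Level set segmentation result (2 classes)
#>   iterations: 80 (converged)
#>   class means: 60.04, 159.99
#>   bias field range: [0.7949, 1.2085] (mean 1)
#>   |d| max: 1.7191

overlap_metrics(ph$true_labels == 1, res$labels == 1)
#> Overlap: JS = 1.0000, DSC = 1.0000, RFP = 0.0000, RFN = 0.0000  (|Sg| = 3569, |Sm| = 3569, |O| = 3569)

cor(as.vector(res$b), as.vector(ph$true_bias))
#> [1] 0.9991
```

The recovered class means (60.04, 159.99) match the generating values
(60, 160); the mean-normalized bias field spans 0.79–1.21 against a
true 0.8–1.2 ramp and correlates with it at r = 0.999; the residual
difference field is small (max |d| = 1.7 intensity units) because this
phantom is fully explained by bias times constants.  `res$corrected`
holds the bias-corrected image `(I − d)/b`.

Three-phase segmentation works the same way with two seed regions:
`segment_three_phase(image, outer_seed, inner_seed,
ls_params(n_classes = 3))`; labels follow the membership tree (class 1 =
both level sets positive, class 3 = first level set negative — seed
placement decides which tissue gets which label).

## Command line

A thin CLI over the same functions is installed at
`system.file("cli", "lsbias", package = "lsbias")`:

```sh
lsbias phantom --preset tshape_bias -o out/phantom
lsbias segment out/phantom/image.tif --init "circle 40,70,15" -o out/seg
lsbias evaluate out/phantom/labels.png out/seg/labels.png --class 1
lsbias correct out/phantom/image.tif --init "circle 40,70,15" -o out/corr
```

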