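# poolreg

Feature-based registration of 2D biomedical images across modalities —
histology (H&E) against mass-spectrometry imaging (MALDI, LA-ICP) and
similar pairings where absolute intensities are incomparable but tissue
structure is shared. `poolreg` aligns a *moving* image to a *fixed*
image by estimating the 2D affine transform between them from matched
keypoints, with no training data and no learned parameters.

## Who it is for

Anyone co-registering serial-section or multi-channel 2D images in R:
overlaying elemental maps on molecular images, histology on MSI, or any
single-channel raster pair related by rotation, scale, shear and
translation. Everything runs from plain matrices; TIFF/PNG I/O and a
command-line front end are included.

## The method

1. **Descriptor.** Around every pixel, a $W \times W$ working window is
   partitioned layer by layer into $2^{l-1}$ equal blocks
   ($l = 1 \dots L$); each block contributes its mean intensity. The
   whole-window mean is removed and subtracted from the remaining
   entries, so the length-$2^L-2$ vector encodes relative local
   structure and ignores intensity offsets. Averaging damps pixel noise.
2. **Keypoints.** The per-pixel descriptor norm forms a feature
   magnitude map; maxima are selected greedily under distance
   regulation $\mathrm{Dist}(F_i) > D$ (every new keypoint farther than
   $D$ from all earlier ones), up to $N$ points.
3. **Matching.** The correlation matrix $H$ of Euclidean descriptor
   distances is filtered by the Lowe ratio test
   $H_{[0]} \le 0.75\,H_{[1]}$, then by a seeded perspective-consistency
   consensus (RANSAC over homographies, 3 px inlier threshold).
4. **Transform.** The affine matrix $M$ minimizing the projection error
   $D_{proj} = \sum_i \lVert P_F^i - M P_M^i \rVert$ is fit by QR least
   squares on the inliers, then polished by warp-refinement passes with
   sub-pixel correlation-verified correspondences.

Dice coefficient, Hausdorff distance and histogram mutual information
quantify registration quality. A synthetic fixture generator produces
modality-shifted pairs with known ground-truth transforms, so the whole
pipeline is testable offline. The methods vignette
(`vignettes/pooled-descriptor-registration.Rmd`) documents the model,
parameter meanings, numerical choices and limitations.

## Worked example

```r
library(poolreg)

# a synthetic cross-modality pair: 12 deg rotation, 5% scale,
# (10, -5) px translation, gamma intensity remap
pair <- generate_pair(fixture_config(seed = 7, rotation = 12, scale = 1.05,
                                     translation = c(10, -5),
                                     intensity_remap = "gamma"))
reg <- register_images(pair$fixed, pair$moving)
reg
#> <registration> 174/151 keypoints (fixed/moving), 84 ratio-test pairs,
#>   57 inliers, 74 refined pairs (direct polarity, coarse rotation 10 deg)
#>   rotation 12.00 deg, scale (1.050, 1.050), translation (34.6, -36.3),
#>   mean residual 2.115 px

corner_error(reg$transform, pair$truth, dim(pair$fixed))
#> [1] 0.1818096

warped_mask <- warp_image(pair$moving_mask + 0, reg$transform,
                          out_shape = dim(pair$fixed),
                          interpolation = "nearest") > 0.5
evaluate_registration(pair$fixed_mask, warped_mask, pair$fixed, reg$warped)
#> # A tibble: 1 × 5
#>    dice hausdorff mutual_information  bins pixel_size
#>   <dbl>     <dbl>              <dbl> <int>      <dbl>
#> 1 0.999         1               2.57    32          1
```

The recovered pose (12.00°, scale 1.050) matches the generator; the
translation entries differ from `(10, -5)` because the generator
rotates about the image centre while the matrix reports the composed
offset at the origin. The maximum corner displacement against the
ground-truth transform is 0.18 px, and warping the moving mask with the
recovered transform brings the Dice overlap to 0.999 (Hausdorff 1 px).

`tidy(reg)` returns the pose parameters as a tibble, `glance(reg)` the
match counts and residuals, `autoplot(reg, fixed = ...)` a residual
heat map, and `plot_matches(reg)` the side-by-side matched keypoints.

A thin command-line front end wraps the same functions:

```sh
inst/cli/poolreg register --fixed fixed.tif --moving moving.tif --out run/
inst/cli/poolreg evaluate --fixed-mask a.png --registered-mask b.png
inst/cli/poolreg fixtures --out fixtures/ --n 5 --seed 1
```

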