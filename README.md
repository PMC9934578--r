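# fibrilseg

Segmentation and morphometry of individual collagen fibrils in transmission
electron micrographs (TEM).

Collagen fibril architecture — cross-sectional area, shape, packing —
underlies the stiffness and strength of soft tissues such as the vascular
wall, and changes in it accompany aneurysm, dissection and connective-tissue
disease. TEM resolves hundreds of fibril cross-sections per image as dark,
roughly elliptical profiles on a lighter background, but extracting
per-fibril measurements has traditionally meant hours of manual boundary
tracing per micrograph. `fibrilseg` implements a scriptable segmentation
pipeline for this problem, aimed at vascular-biology and biomechanics labs
that need objective, reproducible fibril morphometrics at realistic sample
sizes. The interactive correction steps a human operator would perform in a
GUI (excluding non-collagenous regions, fixing centroids, discarding poor
ellipse fits) are exposed as file-driven operations so a full analysis is
replayable.

## Method

For an image with filtered intensities `I_filt(u, v)` the pipeline runs:

1. **Exclusions and smoothing.** Polygonal regions without collagen are
   masked out; the image is smoothed with a Gaussian whose standard deviation
   is 0.3% of the smallest image dimension.
2. **Robust illumination trend.** A bivariate quadratic
   `f1(u, v) = Σ_{α,β≤2} c_αβ u^α v^β` is fitted to the smoothed intensities
   by iteratively reweighted least squares with Cauchy weights
   `w(r̂) = 1 / (1 + r̂²)`, where residuals are standardized as
   `r̂_i = r_i / (k·s·√(1 − h_i))` with leverages `h_i`, robust scale
   `s = MAD / Φ⁻¹(3/4)` and `k = 2.3849`, the tuning constant giving the
   estimator 95% asymptotic efficiency under normal errors.
3. **Power-law adjustment and binarization.** Each pixel is mapped through
   `I_adj = I_filt^(ln 0.5 / ln f1)`, so pixels at the local trend land
   exactly on 0.5; Otsu's method then binarizes the adjusted image, dark
   pixels counting as fibrillar.
4. **Centroid detection.** The Euclidean distance field `D` of the binary
   mask is smoothed at bandwidths σ = 0.5…10 px (step 0.5) and the peak
   count `N(σ)` is fitted with a 5th-degree polynomial `p(σ)`; the working
   bandwidth σ* is the lowest positive σ at which `(dp/dσ)²` attains a local
   minimum (computed from the polynomial roots, no iterative search). Peaks
   of the σ*-smoothed field are the fibril centroids; a correction file can
   add, move or remove centroids.
5. **Neighborhood refinement.** The centroid Voronoi tessellation defines
   first-pass neighborhoods; cells touching the image border or an excluded
   region flag their fibrils as boundary fibrils. Each cell's
   *characteristic intensity* (mean adjusted intensity of the pixels closer
   to the centroid than the 5th percentile of in-cell distances) is
   interpolated with Sibson natural-neighbour weights into a smooth field
   `f2`, and the image is re-adjusted and re-binarized against it. This
   recovers the light central cores of large fibrils that the first pass
   misses.
6. **Mixture segmentation.** A Gaussian mixture with one component per
   approved centroid is fitted to the fibrillar pixel coordinates by a
   sequential conditional EM (means and proportions conditional on
   covariances, then covariances and proportions conditional on means).
   Posterior membership fields `P_i(u, v)` define each fibril's neighborhood
   implicitly as `P_i > 0.5`.
7. **Morphometrics.** Per fibril: pixel-count area, moment-ellipse radii
   `r = 2σ` from the eigenvalues of the pixel covariance (exact for a
   uniform elliptical disc), orientation from the leading eigenvector,
   aspect ratio. Population distributions use kernel density estimates of
   log-transformed areas (strictly positive support).

A synthetic phantom generator (`generate_phantom()`) produces TEM-like
images with exhaustive ground truth, so the entire pipeline is testable
without any microscope data.

## Worked example

```r
library(fibrilseg)

# a synthetic adventitial field: 30 fibrils, ~22% packing, 2 nm/px
ph  <- generate_phantom(phantom_spec(n_fibrils = 30, cores = FALSE), seed = 42)
run <- run_pipeline(ph$image)
run
#> <fibril_run> 30 fibrils (14 analyzed), area fraction 21.7%, sigma* = 2.25 px

glance(run)
#> # A tibble: 1 × 8
#>   n_fibrils n_analyzed n_boundary n_rejected area_fraction sigma_star em_cycles em_converged
#> 1        30         14         16          0          21.7       2.25         4 TRUE

head(tidy(run)[, c("id", "area_nm2", "r_major_nm", "r_minor_nm", "aspect_ratio")], 3)
#>      id area_nm2 r_major_nm r_minor_nm aspect_ratio
#> 1     1     1572       23.8       21.1         1.13
#> 2     2     2424       30.7       25.1         1.22
#> 3     3     1664       26.8       19.8         1.35
```

All 30 fibrils are detected (`sigma_star` is the automatically selected
smoothing bandwidth); 16 are flagged as boundary fibrils — their Voronoi
cells touch the image edge, so part of the fibril may be cut off — and only
the 14 interior fibrils enter the population summary. `area_nm2` is the
summed pixel area inside each fibril's posterior boundary; the ellipse radii
and aspect ratio come from the pixel covariance. Against the generator's
ground truth this run scores detection recall 1.00, pixelwise F1 0.9999 and
a median per-fibril area error of 0.0%:

```r
score_against_truth(run$records, ph$truth, mask = run$mask_refined)
```

`autoplot(run)` overlays centroids and fitted ellipses on the image;
`autoplot(run$detect$scan)` shows the bandwidth scan, and
`autoplot(run$summary)` the population densities. Scripted corrections and
a full command-line interface are available:

```sh
Rscript inst/scripts/fibrilseg.R run image.tif --pixel-size-nm 2 \
    --exclusions ex.json --corrections c.json --out results/
```

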