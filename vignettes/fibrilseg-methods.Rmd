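---
title: "Models and design choices in fibrilseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in fibrilseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilseg)
```

`fibrilseg` segments individual collagen fibrils from grayscale TEM
micrographs and measures their cross-sectional geometry. This vignette
explains the statistical models the pipeline relies on, the parameters a
user might want to touch, what the synthetic phantoms do and do not emulate,
and the numerical decisions taken where the method leaves room.

## The intensity model and its correction stages

A TEM field of stained collagen shows dark, approximately elliptical fibril
cross-sections on a lighter resin background, modulated by two nuisances:
a smooth illumination drift across the field, and intra-fibril intensity
structure — the centers of large fibrils are often markedly lighter than
their rims, sometimes as light as the background.

**Illumination drift** is modeled as a full bivariate quadratic (nine
monomials $u^\alpha v^\beta$, $\alpha,\beta \le 2$). The fit must not be
dragged around by the fibrils themselves, which at 20–40% packing are a
substantial, very dark contamination. The package therefore fits by
iteratively reweighted least squares with the Cauchy weight
$w(\hat r) = 1/(1+\hat r^2)$ on standardized residuals
$\hat r_i = r_i / (k\, s\, \sqrt{1-h_i})$. The scale $s$ is the median
absolute deviation about the median divided by $\Phi^{-1}(3/4)$, making it
consistent for the error standard deviation under normality, and
$k = 2.3849$ is the tuning constant at which the corresponding location
M-estimator attains 95% asymptotic efficiency for normal errors —
`cauchy_tuning_constant(0.95)` re-derives it by solving
$\mathrm{ARE}(k) = (\mathbb{E}\,\psi')^2 / \mathbb{E}\,\psi^2 = 0.95$ with
Gauss–Hermite quadrature. The Cauchy family never assigns zero weight, so
the fit stays smooth in the contamination fraction; its 5%-gross-error
behavior is exercised in the test suite against an ordinary least-squares
contrast.

**The power-law adjustment** $I_{\mathrm{adj}} = I^{\ln 0.5/\ln f_1}$ sends
every pixel whose intensity matches the local trend to exactly 0.5, is
strictly increasing in $I$ at fixed trend (so binarization thresholds are
meaningful), and maps $(0,1)$ into $(0,1)$. It is applied twice: against the
global quadratic trend before the first binarization, and against the
per-neighborhood characteristic-intensity field $f_2$ before the second.
The second pass is what recovers light fibril cores: a core's neighborhood
characteristic intensity is the core's own level, so core pixels land at the
0.5 fixed point while background in the same neighborhood (brighter than the
characteristic level) lands well above it.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `smoothing_fraction` | 0.003 | of min dimension | pre-filter bandwidth rule |
| `sigma_range`, `sigma_step` | 0.5–10, 0.5 | px | distance-field bandwidth scan |
| `poly_degree` | 5 | — | count polynomial for σ* selection |
| `cauchy_k` | 2.3849 | — | 95% efficiency under normal errors |
| `char_percentile` | 5 | % | in-cell distance cutoff for characteristic intensity |
| `boundary_level` | 0.5 | probability | posterior level defining fibril neighborhoods |
| `cov_floor` | 0.25 | px² | minimum mixture covariance eigenvalue |
| `peak_min_height` | 0.5 | px | smoothed-peak noise guard |

The first six are the method's defining constants and should normally stay
fixed; the last two are numerical guards of this implementation. The
covariance floor (a quarter-pixel standard deviation) implements the
requirement that no mixture component collapse onto a rank-deficient
covariance: flooring the eigenvalues after every update keeps the ECM
iteration inside the well-posed region without rejecting fits. The peak
guard suppresses spurious single-pixel maxima of the smoothed distance
field whose height is below half a pixel — weaker peaks cannot correspond
to a fibril interior.

## Bandwidth selection

Fibril counts $N(\sigma)$ fall as the distance field is smoothed harder;
the informative bandwidth is where the count is locally *insensitive* to
$\sigma$. With $p(\sigma)$ the 5th-degree least-squares fit to the 20 scan
points, the package forms $q = (p')^2$ and computes the real roots of
$q' = 2 p' p''$ analytically (they are the roots of $p'$ and of $p''$), then
takes the smallest root in the scanned range that is a strict local minimum
of $q$. The polynomial is fitted on $\sigma$ rescaled to $[-1,1]$ to keep
the Vandermonde system conditioned, and roots are mapped back. Outside
degenerate cases a strict minimum exists; when it does not (e.g. a nearly
constant count curve on a sparse field), the scanned $\sigma_i$ minimizing
$|p'|$ is returned with a warning. The analytic selector is verified against
a $10^{-4}$-step grid minimizer on 100 random quintics.

## Voronoi neighborhoods, Sibson interpolation, and their limits

Per-pixel cell membership uses exact nearest-centroid labeling with ties
broken to the lowest centroid index. The geometric cell polygons — needed
only for the boundary-fibril vertex test — are built by half-plane clipping
against a frame twice the image size, which makes "vertex outside the
image" well-defined for cells that are geometrically unbounded.

The characteristic intensities are interpolated with Sibson's
area-stealing weights, computed by convex polygon clipping in compiled
code. Sibson interpolation is exact at the data sites, bounded by the input
value range, has linear precision inside the site convex hull, and is $C^1$
away from the sites themselves (not at them — the method's continuity claim
holds in that "almost-everywhere" sense). Two practical notes:

* The virtual cell of a query just inside the hull can extend far beyond the
  image before the surrounding bisectors close it; the clipping frame is
  therefore 20× the image span, which makes every query at least about one
  pixel inside the hull exact to machine precision. A sub-pixel band at the
  hull edge is frame-limited.
* Outside the hull Sibson weights are undefined; the field continues as the
  nearest-centroid value. Only image-margin pixels are affected, and fibrils
  there are boundary-flagged and excluded from population statistics anyway.

The 5th-percentile rule presumes Voronoi cells not much larger than their
fibrils — in a sparse field the near-centroid pixel set spills into the
background and the characteristic intensity no longer represents the fibril
interior. This is a property of the method, not of this implementation; the
phantom defaults are chosen accordingly (below).

## Sequential conditional EM

With $N$ fixed at the approved centroid count, the mixture is fitted by an
expectation–conditional-maximization scheme: refresh the responsibilities,
update means and proportions holding covariances; refresh again, update
covariances and proportions holding means. Each half-update maximizes the
same observed-data log-likelihood over a parameter block, so the likelihood
trace is non-decreasing (asserted to $-10^{-9}$ in every seeded test run).
An E-step refresh *between* the two half-updates is the standard ECM choice
adopted here. The sequential scheme also biases fitted means toward their
user-approved initializations — a desirable property verified on phantoms
(drift under 3 px). Convergence is declared at a relative log-likelihood
change below $10^{-8}$, capped at 200 cycles; the cap is reached essentially
only on badly initialized fits (e.g. centroids detected from an annular
first-pass mask before correction), where the best iterate is returned with
a warning. Components whose proportion collapses below $1/(10\,n)$ are
frozen at their initial state. Posteriors are evaluated in log space with
log-sum-exp normalization, so even queries hundreds of standard deviations
away normalize to machine precision.

Forcing all covariances to $\varepsilon I$ with equal proportions reduces
the posterior assignment to nearest-centroid (Voronoi) labeling as
$\varepsilon \to 0$; the test suite checks this identity at
$\varepsilon = 10^{-4}$, pixelwise, against a brute-force oracle.

## Morphometrics

For pixels uniformly distributed in an ellipse, the variance of the
coordinate along a principal axis is $r^2/4$; the package therefore reports
$r = 2\sigma$ from the eigenvalues of the per-fibril pixel covariance
(population normalization, 1/n — the choice matching that derivation, and
immaterial at realistic pixel counts). Orientation is the leading
eigenvector's angle folded into $[0, \pi)$; equal eigenvalues give
orientation 0 by convention. Near-circular fibrils have statistically
unidentifiable orientations — an aspect ratio of 1.1 leaves orientation
errors of several degrees that say nothing about the estimator — so
orientation-recovery validation uses phantoms with aspect ratios 1.3–1.7.

Area densities are Gaussian KDEs of $\ln(\text{area})$ with Silverman's
bandwidth, back-transformed as $f_A(a) = f_L(\ln a)/a$ on a log-spaced grid,
which enforces strictly positive support and integrates to one within
$10^{-3}$. Aspect ratios (support $\ge 1$) are shifted by one and treated
the same way; raw histograms are emitted alongside since smoothing choices
for this quantity are not settled.

## The phantom generator

`generate_phantom()` produces the study conditions for every quantitative
claim the package makes about itself: non-overlapping dark ellipses
(rejection-sampled placement with a minimum boundary gap of 4 px), lognormal
areas around 2000 nm² (fibril diameters near 50 nm at 2 nm/px), aspect
ratios 1.05–1.5, rim intensity 0.3 on background 0.7, a lighter core
(0.6, close to the background) in fibrils above 2000 nm², a multiplicative
quadratic illumination surface (±7.5% coefficients), additive Gaussian
noise (sd 0.02), and an optional dark non-fibrillar blob for exclusion
tests. The default field packs ~23% of the canvas, and
`phantom_canvas_side()` scales the canvas with the fibril count so that
varying $K$ emulates changing the field of view at fixed magnification.
These densities and the moderate stain contrast reflect real adventitial
micrographs; they also matter methodologically — the characteristic
intensity rule assumes dense packing, and an exaggerated rim/background
contrast would spread the characteristic intensities over an unrealistic
50-fold range and break the neighborhood re-adjustment in a way real images
do not.

What the phantoms do **not** emulate: electron-optical noise physics (shot
noise, stain granularity), fibril boundary irregularity (phantom fibrils are
exact ellipses), partial-volume texture inside fibrils, and contacting
fibril pairs (placement enforces a positive gap). Passing phantom tests
therefore demonstrates correctness of the algorithms under the method's own
geometric assumptions, not robustness to every pathology of real
micrographs — the scriptable correction interface exists precisely for the
residual cases.

Validation problem sizes — fields of 5–50 fibrils at constant density,
canvases up to roughly 340×340 px — were chosen so each property is
exercised at several scales while a full validation run of the suite
remains a desk-scale computation.

## Degenerate inputs and tie-breaks

* Otsu thresholding uses a fixed 256-bin histogram on $[0,1]$ with class
  means accumulated from the actual pixel values; ties take the lowest
  qualifying bin edge; fewer than two distinct masked values is an error.
* Intensities are clipped to $[10^{-6}, 1-10^{-6}]$ before any logarithm;
  trend surfaces are clipped the same way before use as a power-law base.
* A smoothed-field plateau (8-connected, equal-valued) counts as one peak at
  the centroid of its pixels; plateaus adjacent to a strictly greater pixel
  are shoulders, not peaks. Peaks closer than 1 px are merged, keeping the
  higher.
* The distance transform does not treat the image border as background;
  border-cut fibrils are instead caught by the boundary-fibril flag.
* IRLS declares a perfect fit ($s = 0$) converged immediately; leverages come
  from the unweighted design and are held fixed across iterations.
* Cells with fewer than 20 pixels take the single nearest pixel's intensity
  as characteristic intensity, with a warning; fewer than 3 or collinear
  centroids degrade the interpolant to the nearest-centroid field.

## Known limitations

Aspect ratio compresses genuinely different boundary shapes onto similar
values; boundary-deviation shape metrics are out of scope here. The pipeline
processes one image at a time — cross-group statistical comparison is left
to downstream analysis. Sibson evaluation is exact but $O(N)$ per pixel in
the number of centroids; fields with many hundreds of fibrils pay a few
seconds. Finally, the automatic centroid detector can over- or under-detect
on images whose first-pass binarization is annular (large light-cored
fibrils); the correction API is the intended remedy, mirroring the original
interactive workflow.
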