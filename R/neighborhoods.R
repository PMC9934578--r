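# First-pass fibril neighborhoods: Voronoi tessellation of the centroids,
# boundary-fibril flagging, per-cell characteristic intensities, the smooth
# natural-neighbour interpolant f2 and the refined binarization.

#' Voronoi tessellation of fibril centroids
#'
#' Builds both the operative per-pixel nearest-centroid labeling (ties broken
#' to the lowest centroid index) and the geometric cell polygons, clipped
#' against a bounding frame twice the image size so that vertex tests are
#' well-defined for cells that would otherwise be unbounded.
#'
#' @param centroids A `centroid_set` (or two-column matrix of `(u, v)`).
#' @param image The [tem_image()].
#' @return A `voronoi_tess` object: `labels` (integer matrix, 0 = excluded),
#'   `cells` (list of vertex matrices), `centroids`, `boundary` (logical,
#'   filled by [flag_boundary_fibrils()]).
#' @export
tessellate <- function(centroids, image) {
  stopifnot(inherits(image, "tem_image"))
  pts <- centroid_matrix(centroids)
  if (nrow(pts) == 0L) stop("cannot tessellate zero centroids")
  h <- nrow(image$intensity); w <- ncol(image$intensity)

  labels <- nearest_site_labels(pts, h, w)
  labels[image$excluded] <- 0L

  cu <- (w - 1) / 2; cv <- (h - 1) / 2
  frame <- c(cu - w, cu + w, cv - h, cv + h)      # 2x the image size
  cells <- .voronoi_cells_cpp(pts, frame)

  structure(
    list(labels = labels, cells = cells, centroids = pts,
         boundary = rep(NA, nrow(pts)), frame = frame),
    class = "voronoi_tess"
  )
}

centroid_matrix <- function(centroids) {
  if (inherits(centroids, "centroid_set") || is.data.frame(centroids)) {
    pts <- cbind(centroids$u, centroids$v)
  } else {
    pts <- as.matrix(centroids)
  }
  storage.mode(pts) <- "double"
  pts
}

# per-pixel nearest-site labels; ties go to the lowest index because only a
# strictly smaller distance displaces an earlier site
nearest_site_labels <- function(pts, h, w) {
  u <- rep(0:(w - 1), each = h)
  v <- rep(0:(h - 1), times = w)
  best <- rep(Inf, h * w)
  lab <- integer(h * w)
  for (i in seq_len(nrow(pts))) {
    d2 <- (u - pts[i, 1])^2 + (v - pts[i, 2])^2
    hit <- d2 < best
    best[hit] <- d2[hit]
    lab[hit] <- i
  }
  matrix(lab, h, w)
}

#' @export
print.voronoi_tess <- function(x, ...) {
  cat(sprintf("<voronoi_tess> %d cells, %d boundary-flagged\n",
              nrow(x$centroids), sum(x$boundary, na.rm = TRUE)))
  invisible(x)
}

#' Flag boundary fibrils
#'
#' A fibril is a boundary fibril when any vertex of its Voronoi cell falls
#' outside the image area or inside an excluded region — part of the fibril
#' is then most likely not visible, so it is excluded from population
#' statistics. Cells clipped by the bounding frame (i.e. unbounded cells)
#' always have vertices outside the image and are therefore always flagged.
#'
#' @param tess A [tessellate()] result.
#' @param image The [tem_image()].
#' @return The tessellation with its `boundary` flags filled in.
#' @export
flag_boundary_fibrils <- function(tess, image) {
  stopifnot(inherits(tess, "voronoi_tess"), inherits(image, "tem_image"))
  h <- nrow(image$intensity); w <- ncol(image$intensity)
  tess$boundary <- vapply(tess$cells, function(cell) {
    if (nrow(cell) < 3L) return(TRUE)
    outside <- cell[, 1] < -0.5 | cell[, 1] > w - 0.5 |
               cell[, 2] < -0.5 | cell[, 2] > h - 0.5
    if (any(outside)) return(TRUE)
    ri <- pmin(pmax(round(cell[, 2]) + 1, 1), h)
    ci <- pmin(pmax(round(cell[, 1]) + 1, 1), w)
    any(image$excluded[cbind(ri, ci)])
  }, logical(1))
  tess
}

#' Characteristic intensity of one Voronoi cell
#'
#' The mean adjusted intensity of the cell's pixels whose distance to the
#' centroid is strictly less than the 5th percentile of pixel-to-centroid
#' distances within the cell (linear-interpolation quantile). For cells with
#' fewer than 20 pixels the single nearest pixel's intensity is used, with a
#' warning.
#'
#' @param cell_px Two-column matrix of the cell's pixel `(u, v)` coordinates.
#' @param centroid Length-2 centroid `(u, v)`.
#' @param adjusted Matrix of adjusted intensities `I_adj`.
#' @param percentile Percentile of distances (default 5).
#' @return Scalar characteristic intensity.
#' @export
characteristic_intensity <- function(cell_px, centroid, adjusted, percentile = 5) {
  stopifnot(nrow(cell_px) >= 1L)
  d <- sqrt((cell_px[, 1] - centroid[1])^2 + (cell_px[, 2] - centroid[2])^2)
  vals <- adjusted[cbind(cell_px[, 2] + 1, cell_px[, 1] + 1)]
  if (nrow(cell_px) < 20L) {
    warning("cell has fewer than 20 pixels; using the nearest pixel's intensity")
    return(vals[which.min(d)])
  }
  thr <- quantile(d, percentile / 100, type = 7, names = FALSE)
  sel <- d < thr
  if (!any(sel)) sel <- seq_along(d) == which.min(d)
  mean(vals[sel])
}

#' Characteristic intensities for all cells of a tessellation
#'
#' @param tess A [tessellate()] result.
#' @param adjusted Matrix of adjusted intensities `I_adj`.
#' @param percentile Percentile of distances (default 5).
#' @return Numeric vector, one value per centroid.
#' @export
characteristic_intensities <- function(tess, adjusted, percentile = 5) {
  stopifnot(inherits(tess, "voronoi_tess"))
  n <- nrow(tess$centroids)
  h <- nrow(tess$labels); w <- ncol(tess$labels)
  uv <- pixel_centers(h, w)
  lab <- c(tess$labels)
  vapply(seq_len(n), function(i) {
    px <- uv[lab == i, , drop = FALSE]
    if (nrow(px) == 0L) {
      warning("cell ", i, " contains no analyzable pixels; using its centroid pixel")
      px <- matrix(round(tess$centroids[i, ]), 1, 2)
    }
    suppressWarnings(
      characteristic_intensity(px, tess$centroids[i, ], adjusted, percentile)
    )
  }, numeric(1))
}

#' Natural-neighbour (Sibson) interpolation of characteristic intensities
#'
#' Interpolates the per-centroid characteristic intensities over the pixel
#' grid with Sibson's area-stealing weights derived from the Voronoi
#' tessellation: exact at the centroids, bounded by the input value range,
#' with linear precision inside the centroid convex hull. Outside the hull
#' (image margins, whose fibrils are boundary-flagged regardless) the
#' nearest-centroid value is used. With fewer than 3 or collinear centroids
#' the field falls back to the piecewise-constant nearest-centroid field with
#' a warning.
#'
#' @param centroids A `centroid_set` or `(u, v)` matrix.
#' @param values Numeric vector of characteristic intensities, one per centroid.
#' @param image The [tem_image()].
#' @return Matrix `f2` of interpolated values at every pixel.
#' @export
natural_neighbor_field <- function(centroids, values, image) {
  stopifnot(inherits(image, "tem_image"))
  pts <- centroid_matrix(centroids)
  stopifnot(nrow(pts) == length(values))
  h <- nrow(image$intensity); w <- ncol(image$intensity)
  labels <- nearest_site_labels(pts, h, w)
  nearest <- matrix(values[labels], h, w)

  collinear <- nrow(pts) < 3L ||
    qr(sweep(pts, 2, colMeans(pts)))$rank < 2L
  if (collinear) {
    warning("fewer than 3 non-collinear centroids; using nearest-centroid field")
    return(nearest)
  }

  hull <- grDevices::chull(pts)
  hull_poly <- pts[c(hull, hull[1]), , drop = FALSE]
  uv <- pixel_centers(h, w)
  inside <- mgcv::in.out(hull_poly, uv)

  # wide frame: the virtual cell of a query just inside the hull can extend
  # far beyond the image before closing; 20x the span keeps every query at
  # least ~1 px inside the hull exact to machine precision
  cu <- (w - 1) / 2; cv <- (h - 1) / 2
  span <- 20 * max(w, h)
  frame <- c(cu - span, cu + span, cv - span, cv + span)
  f2 <- nearest
  if (any(inside)) {
    vals <- .sibson_interp_cpp(pts, as.numeric(values),
                               uv[inside, , drop = FALSE], frame)
    f2[inside] <- vals
  }
  f2
}

#' Refined binarization from the natural-neighbour field
#'
#' Re-adjusts the adjusted image against the interpolated characteristic
#' intensities — `out = I_adj ^ (ln 0.5 / ln f2)` — so that each fibril
#' neighborhood is recentred at 0.5, then re-binarizes with Otsu's method.
#' This recovers light fibril cores that the first-pass binarization missed.
#'
#' @param adjusted Matrix `I_adj` (the power-adjusted smoothed image).
#' @param f2 Matrix from [natural_neighbor_field()].
#' @param image The [tem_image()].
#' @return A `binary_mask` (the refined mask).
#' @export
rebinarize <- function(adjusted, f2, image) {
  stopifnot(identical(dim(adjusted), dim(f2)))
  readj <- power_adjust(adjusted, f2)
  binarize(readj, image)
}
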