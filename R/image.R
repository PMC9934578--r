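# TEM image container and elementary image operations.
#
# Coordinate convention used throughout the package: a pixel at matrix position
# [row, col] has 0-based coordinates u = col - 1 (horizontal) and v = row - 1
# (vertical), its center sitting exactly at (u, v). All user-facing coordinates
# (exclusion polygons, centroids, correction files) use this (u, v) system.

#' TEM image object
#'
#' Wraps a 2-D intensity field in `[0, 1]` together with the physical pixel
#' size and a logical exclusion grid marking pixels that are left out of all
#' analysis (for example perivascular regions without collagen).
#'
#' @param intensity Numeric matrix with all values in `[0, 1]`; rows index the
#'   vertical coordinate v, columns the horizontal coordinate u.
#' @param pixel_size Physical pixel size in nm/pixel; must be positive.
#' @param excluded Optional logical matrix of the same dimensions; `TRUE` marks
#'   excluded pixels. Defaults to all-`FALSE`.
#' @return A `tem_image` object.
#' @export
tem_image <- function(intensity, pixel_size, excluded = NULL) {
  stopifnot(is.matrix(intensity), is.numeric(intensity))
  if (anyNA(intensity) || min(intensity) < 0 || max(intensity) > 1) {
    stop("intensities must be finite and lie in [0, 1]")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("pixel_size must be a single positive number (nm/pixel)")
  }
  if (is.null(excluded)) {
    excluded <- matrix(FALSE, nrow(intensity), ncol(intensity))
  }
  stopifnot(is.logical(excluded), identical(dim(excluded), dim(intensity)))
  structure(
    list(intensity = intensity, pixel_size = pixel_size, excluded = excluded),
    class = "tem_image"
  )
}

#' @export
print.tem_image <- function(x, ...) {
  cat(sprintf(
    "<tem_image> %d x %d px, %.4g nm/px, %d excluded px\n",
    nrow(x$intensity), ncol(x$intensity), x$pixel_size, sum(x$excluded)
  ))
  invisible(x)
}

#' @export
dim.tem_image <- function(x) dim(x$intensity)

#' Read a grayscale micrograph and normalize it to [0, 1]
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG and scales intensities by the
#' bit-depth maximum so the result lies in `[0, 1]` (255 or 65535 map to 1).
#' Multi-channel images are rejected unless all channels are identical (a
#' common grayscale-in-RGB encoding), in which case the first channel is used.
#'
#' @param path Path to a TIFF or PNG file.
#' @param pixel_size Physical pixel size in nm/pixel.
#' @return A [tem_image()] with an all-`FALSE` exclusion grid.
#' @export
tem_read <- function(path, pixel_size) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext, " (expected TIFF or PNG)")
  )
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    same <- all(vapply(
      seq_len(ch)[-1],
      function(k) isTRUE(all.equal(img[, , 1], img[, , k])),
      logical(1)
    ))
    if (!same) {
      stop("multi-channel image without a grayscale reduction rule")
    }
    img <- img[, , 1]
  }
  # readTIFF/readPNG already scale integer data by the bit-depth maximum
  img <- pmin(pmax(img, 0), 1)
  tem_image(img, pixel_size = pixel_size)
}

#' Default smoothing bandwidth for a micrograph
#'
#' The Gaussian smoothing bandwidth (standard deviation, in pixels) is 0.3% of
#' the smallest image dimension.
#'
#' @param image A [tem_image()].
#' @param fraction Fraction of the smallest dimension; default 0.003.
#' @return Bandwidth in pixels.
#' @export
default_smoothing_bandwidth <- function(image, fraction = 0.003) {
  stopifnot(inherits(image, "tem_image"))
  fraction * min(dim(image$intensity))
}

#' Gaussian smoothing with reflective boundaries
#'
#' Convolves a 2-D field with an isotropic Gaussian kernel of standard
#' deviation `bandwidth` pixels, truncated at 4 standard deviations, with
#' reflective (symmetric) boundary handling. Output dimensions are unchanged.
#'
#' @param field Numeric matrix.
#' @param bandwidth Gaussian standard deviation in pixels; must be positive.
#' @return Smoothed matrix of the same dimensions.
#' @export
gaussian_smooth <- function(field, bandwidth) {
  stopifnot(is.matrix(field), is.numeric(field))
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0) {
    stop("bandwidth must be a single positive number of pixels")
  }
  r <- max(1L, as.integer(ceiling(4 * bandwidth)))
  k1 <- dnorm(seq(-r, r), sd = bandwidth)
  k1 <- k1 / sum(k1)
  kern <- outer(k1, k1)
  padded <- pad_reflect(field, r)
  sm <- EBImage::filter2(padded, kern, boundary = "circular")
  sm[(r + 1):(r + nrow(field)), (r + 1):(r + ncol(field)), drop = FALSE]
}

# symmetric (edge-repeating) reflective padding by r pixels on each side
pad_reflect <- function(m, r) {
  ri <- reflect_index(seq(1 - r, nrow(m) + r), nrow(m))
  ci <- reflect_index(seq(1 - r, ncol(m) + r), ncol(m))
  m[ri, ci, drop = FALSE]
}

# reflect 1-based indices into 1..n (symmetric: 0 -> 1, -1 -> 2, n+1 -> n)
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  j <- ((idx - 1L) %% period + period) %% period
  ifelse(j < n, j + 1L, period - j)
}

#' Otsu threshold over a fixed 256-bin histogram
#'
#' Finds the threshold maximizing the between-class variance of the masked
#' pixel intensities over a fixed 256-bin histogram on `[0, 1]`. Class means
#' use the actual pixel values accumulated per bin (not bin midpoints).
#' Candidate thresholds are the 255 interior bin edges `b/256`; ties are broken
#' toward the lowest qualifying edge. Pixels strictly below the returned
#' threshold are classified fibrillar (dark = fibril).
#'
#' @param field Numeric matrix (or `tem_image`) of intensities in `[0, 1]`.
#' @param mask Optional logical matrix; only `TRUE` pixels enter the histogram.
#'   For a `tem_image` the non-excluded pixels are used by default.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold, a value in `(0, 1)`.
#' @export
otsu_threshold <- function(field, mask = NULL, n_bins = 256L) {
  if (inherits(field, "tem_image")) {
    if (is.null(mask)) mask <- !field$excluded
    field <- field$intensity
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(field), ncol(field))
  stopifnot(identical(dim(mask), dim(field)))
  x <- field[mask]
  if (length(unique(x)) < 2L) {
    stop("degenerate histogram: fewer than 2 distinct intensity values")
  }
  bin <- pmin(floor(x * n_bins), n_bins - 1L)       # 0 .. n_bins-1
  cnt <- tabulate(bin + 1L, nbins = n_bins)
  sums <- vapply(
    split(x, factor(bin, levels = 0:(n_bins - 1L))),
    sum, numeric(1)
  )
  sums[is.na(sums)] <- 0
  n <- length(x)
  w0 <- cumsum(cnt)[-n_bins]       # class 0 = bins 0..b-1, b = 1..255
  s0 <- cumsum(sums)[-n_bins]
  w1 <- n - w0
  s1 <- sum(x) - s0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (w0[valid] / n) * (w1[valid] / n) *
    (s0[valid] / w0[valid] - s1[valid] / w1[valid])^2
  b <- which.max(bcv)              # which.max returns the first (lowest) max
  b / n_bins
}

#' Binarize an intensity field (dark pixels are fibrillar)
#'
#' Applies [otsu_threshold()] to the non-excluded pixels and returns a binary
#' mask in which pixels strictly below the threshold are fibrillar. Excluded
#' pixels are always non-fibrillar.
#'
#' @param field Numeric matrix of intensities in `[0, 1]`.
#' @param image The source [tem_image()] (supplies the exclusion grid).
#' @return A `binary_mask` object: list with `fibrillar` (logical matrix),
#'   `threshold`, and the exclusion grid.
#' @export
binarize <- function(field, image) {
  stopifnot(inherits(image, "tem_image"), identical(dim(field), dim(image$intensity)))
  thr <- otsu_threshold(field, mask = !image$excluded)
  fib <- field < thr & !image$excluded
  structure(
    list(fibrillar = fib, threshold = thr, excluded = image$excluded),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask> %d x %d px, %d fibrillar px, threshold %.4f\n",
    nrow(x$fibrillar), ncol(x$fibrillar), sum(x$fibrillar), x$threshold
  ))
  invisible(x)
}

#' Collagen area fraction
#'
#' Percentage of the analyzable (non-excluded) pixels that are fibrillar.
#'
#' @param mask A `binary_mask` (from [binarize()] or [rebinarize()]).
#' @param image The source [tem_image()].
#' @return Area fraction in percent.
#' @export
area_fraction <- function(mask, image) {
  stopifnot(
    inherits(mask, "binary_mask"), inherits(image, "tem_image"),
    identical(dim(mask$fibrillar), dim(image$intensity))
  )
  n_ok <- sum(!image$excluded)
  if (n_ok == 0L) stop("all pixels excluded: area fraction undefined")
  100 * sum(mask$fibrillar & !image$excluded) / n_ok
}

#' Apply polygonal exclusion regions
#'
#' Marks as excluded every pixel whose center lies inside any of the supplied
#' polygons. Polygons entirely outside the image raise a warning and are
#' skipped. Intensities are unchanged.
#'
#' @param image A [tem_image()].
#' @param polygons List of polygons; each is a two-column matrix (or a list
#'   with element `vertices`) of `(u, v)` coordinates, at least 3 vertices.
#' @return The image with an updated exclusion grid.
#' @export
apply_exclusions <- function(image, polygons) {
  stopifnot(inherits(image, "tem_image"))
  if (length(polygons) == 0L) return(image)
  h <- nrow(image$intensity); w <- ncol(image$intensity)
  uv <- pixel_centers(h, w)
  excl <- image$excluded
  for (p in polygons) {
    verts <- polygon_vertices(p)
    if (max(verts[, 1]) < -0.5 || min(verts[, 1]) > w - 0.5 ||
        max(verts[, 2]) < -0.5 || min(verts[, 2]) > h - 0.5) {
      warning("exclusion polygon lies fully outside the image; skipped")
      next
    }
    inside <- mgcv::in.out(rbind(verts, verts[1, ]), uv)
    excl <- excl | matrix(inside, h, w)
  }
  image$excluded <- excl
  image
}

polygon_vertices <- function(p) {
  if (is.list(p) && !is.null(p$vertices)) p <- p$vertices
  if (is.list(p) && !is.matrix(p)) p <- do.call(rbind, lapply(p, as.numeric))
  verts <- as.matrix(p)
  if (nrow(verts) < 3L || ncol(verts) != 2L) {
    stop("an exclusion polygon needs at least 3 (u, v) vertices")
  }
  storage.mode(verts) <- "double"
  verts
}

# (u, v) centers of all pixels, in column-major matrix order
pixel_centers <- function(h, w) {
  cbind(u = rep(0:(w - 1), each = h), v = rep(0:(h - 1), times = w))
}

#' Read exclusion polygons from JSON
#'
#' Expects a JSON array of objects `{"vertices": [[u, v], ...]}` in 0-based
#' pixel coordinates.
#'
#' @param path Path to a JSON file.
#' @return List of vertex matrices suitable for [apply_exclusions()].
#' @export
read_exclusions <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (is.data.frame(doc)) {
    lapply(doc$vertices, function(v) polygon_vertices(v))
  } else {
    lapply(doc, function(p) polygon_vertices(p$vertices))
  }
}

#' Export a binary mask as an 8-bit PNG
#'
#' Fibrillar pixels are written as 255, background as 0 and excluded pixels
#' as 128.
#'
#' @param mask A `binary_mask`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- matrix(0, nrow(mask$fibrillar), ncol(mask$fibrillar))
  img[mask$fibrillar] <- 255 / 255
  img[mask$excluded] <- 128 / 255
  png::writePNG(img, path)
  invisible(path)
}
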