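# Per-fibril morphometrics (area, moment ellipse, aspect ratio, orientation)
# and population distributions with strictly positive support.

#' Cross-sectional area of one fibril
#'
#' Sum of the areas of the fibril's pixels: `pixel_count * pixel_size^2`.
#'
#' @param pixel_set Two-column matrix of the fibril's pixel coordinates (or
#'   anything with a row count).
#' @param pixel_size Pixel size in nm/pixel.
#' @return Area in nm^2.
#' @export
fibril_area <- function(pixel_set, pixel_size) {
  n <- if (is.matrix(pixel_set) || is.data.frame(pixel_set)) nrow(pixel_set)
       else length(pixel_set)
  if (n == 0L) {
    warning("empty pixel set: fibril dropped")
    return(NA_real_)
  }
  n * pixel_size^2
}

#' Moment-based ellipse fit of a fibril's pixels
#'
#' Under the approximation that a fibril's pixels are uniformly distributed
#' inside an ellipse, the variance of the pixel coordinates along each
#' principal axis equals (radius/2)^2, so the radii are recovered as twice the
#' square roots of the eigenvalues of the pixel coordinate covariance matrix
#' (1/n normalization), scaled to nm. The orientation is the angle of the
#' leading eigenvector folded into `[0, pi)`; for equal eigenvalues it is 0
#' by convention.
#'
#' @param coords Two-column matrix of pixel `(u, v)` coordinates (px).
#' @param pixel_size Pixel size in nm/pixel.
#' @return List with `r_major`, `r_minor` (nm), `orientation` (radians in
#'   `[0, pi)`), and `degenerate` (TRUE when the pixels are collinear or
#'   fewer than 3).
#' @export
fit_ellipse <- function(coords, pixel_size = 1) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3L) {
    return(list(r_major = NA_real_, r_minor = NA_real_,
                orientation = NA_real_, degenerate = TRUE))
  }
  S <- pop_cov(coords)
  e <- eigen(S, symmetric = TRUE)
  if (e$values[2] <= 1e-12) {
    return(list(r_major = NA_real_, r_minor = NA_real_,
                orientation = NA_real_, degenerate = TRUE))
  }
  radii <- 2 * sqrt(e$values) * pixel_size
  if (abs(e$values[1] - e$values[2]) < 1e-12) {
    theta <- 0
  } else {
    vec <- e$vectors[, 1]
    theta <- atan2(vec[2], vec[1]) %% pi
  }
  list(r_major = radii[1], r_minor = radii[2], orientation = theta,
       degenerate = FALSE)
}

#' Aspect ratio of a fitted ellipse
#'
#' @param r_major,r_minor Ellipse radii.
#' @return `r_major / r_minor`, at least 1 for a valid ellipse.
#' @export
aspect_ratio <- function(r_major, r_minor) r_major / r_minor

#' Per-fibril record table
#'
#' Builds the morphometric table from a pixel assignment: one row per mixture
#' component with pixel count, area, moment-ellipse radii, orientation,
#' aspect ratio and flags. Boundary flags are carried over from the Voronoi
#' tessellation; components with degenerate pixel sets are flagged and
#' excluded from shape statistics.
#'
#' @param assignment A [assign_fibril_pixels()] result.
#' @param tess The flagged [tessellate()] result (supplies boundary flags).
#' @param pixel_size Pixel size in nm/pixel.
#' @return A tibble with columns `id`, `u`, `v`, `pixel_count`, `area_nm2`,
#'   `r_major_nm`, `r_minor_nm`, `orientation_rad`, `aspect_ratio`,
#'   `boundary_flag`, `degenerate`, `user_rejected`.
#' @export
fibril_records <- function(assignment, tess, pixel_size) {
  stopifnot(inherits(assignment, "fibril_assignment"),
            inherits(tess, "voronoi_tess"))
  n <- length(assignment$pixels)
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    px <- assignment$pixels[[i]]
    ell <- fit_ellipse(px, pixel_size)
    tibble(
      id = i,
      u = if (nrow(px) > 0) mean(px[, 1]) else tess$centroids[i, 1],
      v = if (nrow(px) > 0) mean(px[, 2]) else tess$centroids[i, 2],
      pixel_count = nrow(px),
      area_nm2 = if (nrow(px) > 0) nrow(px) * pixel_size^2 else NA_real_,
      r_major_nm = ell$r_major,
      r_minor_nm = ell$r_minor,
      orientation_rad = ell$orientation,
      aspect_ratio = aspect_ratio(ell$r_major, ell$r_minor),
      boundary_flag = isTRUE(tess$boundary[i]),
      degenerate = ell$degenerate,
      user_rejected = FALSE
    )
  })
  structure(rows, class = c("fibril_records", class(rows)))
}

#' Reject poorly fitted ellipses
#'
#' The programmatic equivalent of interactively discarding ellipses that fit
#' the actual fibril boundary poorly: flagged records stay in the table but
#' are excluded from population summaries. Invalid ids are reported and
#' skipped.
#'
#' @param records A [fibril_records()] tibble.
#' @param ids Fibril ids to reject.
#' @return The updated records.
#' @export
reject_ellipses <- function(records, ids) {
  stopifnot(inherits(records, "fibril_records"))
  ids <- unique(as.integer(ids))
  bad <- setdiff(ids, records$id)
  if (length(bad) > 0L) {
    warning("invalid fibril id(s) ignored: ", paste(bad, collapse = ", "))
  }
  records$user_rejected[records$id %in% ids] <- TRUE
  records
}

#' Kernel density estimate of fibril areas on positive support
#'
#' Gaussian KDE of log-transformed areas with Silverman's bandwidth, mapped
#' back to the area scale as `f_A(a) = f_L(log a) / a` on a log-spaced grid,
#' so all density mass lies at `a > 0` and the density integrates to one.
#'
#' @param areas Positive areas in nm^2, at least 2.
#' @param n_grid Number of grid points (default 512).
#' @return Tibble with columns `area_nm2`, `density`; attributes `bandwidth`
#'   (log scale) and `n`.
#' @export
log_area_kde <- function(areas, n_grid = 512L) {
  areas <- as.numeric(areas)
  if (any(!is.finite(areas)) || any(areas <= 0)) {
    stop("all areas must be positive and finite")
  }
  if (length(areas) < 2L) stop("need at least 2 areas")
  dl <- density(log(areas), bw = "nrd0", n = n_grid)
  grid <- exp(dl$x)
  out <- tibble(area_nm2 = grid, density = dl$y / grid)
  attr(out, "bandwidth") <- dl$bw
  attr(out, "n") <- length(areas)
  out
}

#' Kernel density estimate of aspect ratios on support > 1
#'
#' Aspect ratios are shifted by 1 and log-transformed before a Gaussian KDE
#' with Silverman's bandwidth; the back-transformed density
#' `f(ar) = f_L(log(ar - 1)) / (ar - 1)` is supported on `ar > 1`. Ratios
#' within `1e-9` of exactly 1 are nudged up by that amount so the logarithm is
#' defined.
#'
#' @param ratios Aspect ratios (all >= 1), at least 2.
#' @param n_grid Number of grid points (default 512).
#' @return Tibble with columns `aspect_ratio`, `density`; attributes
#'   `bandwidth` and `n`.
#' @export
aspect_ratio_kde <- function(ratios, n_grid = 512L) {
  ratios <- as.numeric(ratios)
  if (any(!is.finite(ratios)) || any(ratios < 1)) {
    stop("all aspect ratios must be finite and at least 1")
  }
  if (length(ratios) < 2L) stop("need at least 2 aspect ratios")
  x <- pmax(ratios - 1, 1e-9)
  dl <- density(log(x), bw = "nrd0", n = n_grid)
  grid <- exp(dl$x)
  out <- tibble(aspect_ratio = 1 + grid, density = dl$y / grid)
  attr(out, "bandwidth") <- dl$bw
  attr(out, "n") <- length(ratios)
  out
}

#' Population summary of the fibril records
#'
#' Aggregates the analyzable fibrils — boundary-flagged, user-rejected and
#' degenerate records are excluded — into positive-support density estimates
#' of area and aspect ratio plus raw histograms and bookkeeping counts.
#'
#' @param records A [fibril_records()] tibble.
#' @return A `population_summary` object.
#' @export
population_summary <- function(records) {
  stopifnot(inherits(records, "fibril_records"))
  keep <- !records$boundary_flag & !records$user_rejected &
    !records$degenerate & !is.na(records$area_nm2)
  used <- records[keep, , drop = FALSE]
  counts <- list(
    total = nrow(records),
    boundary_excluded = sum(records$boundary_flag),
    user_rejected = sum(records$user_rejected),
    degenerate = sum(records$degenerate),
    analyzed = nrow(used)
  )
  if (nrow(used) < 2L) {
    warning("fewer than 2 analyzable fibrils: empty population summary")
    return(structure(
      list(area_density = NULL, aspect_density = NULL,
           area_hist = NULL, aspect_hist = NULL, counts = counts),
      class = "population_summary"
    ))
  }
  area_hist <- graphics::hist(used$area_nm2, breaks = "Sturges", plot = FALSE)
  aspect_hist <- graphics::hist(used$aspect_ratio, breaks = "Sturges",
                                plot = FALSE)
  structure(
    list(
      area_density = log_area_kde(used$area_nm2),
      aspect_density = aspect_ratio_kde(used$aspect_ratio),
      area_hist = list(breaks = area_hist$breaks, counts = area_hist$counts),
      aspect_hist = list(breaks = aspect_hist$breaks,
                         counts = aspect_hist$counts),
      counts = counts
    ),
    class = "population_summary"
  )
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf(
    "<population_summary> %d fibrils analyzed (%d boundary, %d rejected, %d degenerate of %d)\n",
    x$counts$analyzed, x$counts$boundary_excluded, x$counts$user_rejected,
    x$counts$degenerate, x$counts$total
  ))
  invisible(x)
}

#' @export
tidy.population_summary <- function(x, ...) {
  if (is.null(x$area_density)) {
    return(tibble(metric = character(0), value = numeric(0),
                  density = numeric(0)))
  }
  dplyr::bind_rows(
    tibble(metric = "area_nm2", value = x$area_density$area_nm2,
           density = x$area_density$density),
    tibble(metric = "aspect_ratio", value = x$aspect_density$aspect_ratio,
           density = x$aspect_density$density)
  )
}

#' @export
glance.population_summary <- function(x, ...) {
  tibble(
    total = x$counts$total, analyzed = x$counts$analyzed,
    boundary_excluded = x$counts$boundary_excluded,
    user_rejected = x$counts$user_rejected, degenerate = x$counts$degenerate
  )
}
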