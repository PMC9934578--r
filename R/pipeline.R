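# End-to-end pipeline: exclusions -> smoothing -> robust trend + power
# adjustment -> Otsu binarization -> distance field -> bandwidth selection ->
# centroids -> (scripted corrections) -> Voronoi -> characteristic
# intensities -> natural-neighbour refinement -> re-binarization -> Gaussian
# mixture -> P = 0.5 assignment -> morphometrics -> (scripted rejections) ->
# population summary.

#' Pipeline configuration
#'
#' All defaults equal the method's defining constants: smoothing bandwidth
#' 0.3% of the smallest image dimension, bandwidth scan 0.5-10 px in 0.5 px
#' steps with a 5th-degree count polynomial, Cauchy tuning constant 2.3849
#' (95% asymptotic efficiency), 5th-percentile characteristic intensities,
#' and the 0.5 posterior boundary level. Numerical controls (tolerances,
#' iteration caps, covariance floor, peak-height guard) are package choices.
#'
#' @param smoothing_fraction Gaussian bandwidth as a fraction of the smallest
#'   image dimension.
#' @param sigma_range,sigma_step Bandwidth scan range and step (px).
#' @param poly_degree Degree of the count polynomial.
#' @param cauchy_k Cauchy tuning constant.
#' @param char_percentile Characteristic-intensity distance percentile.
#' @param boundary_level Posterior level defining neighborhood boundaries.
#' @param irls_tol,irls_max_iter IRLS controls.
#' @param em_tol,em_max_cycles EM controls.
#' @param cov_floor Minimum mixture covariance eigenvalue (px^2).
#' @param peak_min_height Minimum smoothed peak height (px).
#' @param otsu_bins Histogram bins for Otsu thresholding.
#' @return A `fibril_config` list.
#' @export
fibril_config <- function(smoothing_fraction = 0.003,
                          sigma_range = c(0.5, 10), sigma_step = 0.5,
                          poly_degree = 5L,
                          cauchy_k = 2.3849,
                          char_percentile = 5,
                          boundary_level = 0.5,
                          irls_tol = 1e-8, irls_max_iter = 50L,
                          em_tol = 1e-8, em_max_cycles = 200L,
                          cov_floor = 0.25,
                          peak_min_height = 0.5,
                          otsu_bins = 256L) {
  cfg <- as.list(environment())
  class(cfg) <- "fibril_config"
  cfg
}

#' Detection stage: preprocess through centroid extraction
#'
#' Runs the automatic half of the pipeline: Gaussian smoothing, robust
#' quadratic trend fit, power-law intensity adjustment, Otsu binarization,
#' Euclidean distance field, bandwidth scan with automatic selection, and
#' centroid extraction. Its output is the natural checkpoint at which
#' scripted centroid corrections are applied before segmentation.
#'
#' @param image A [tem_image()] (already carrying any exclusions).
#' @param config A [fibril_config()].
#' @return A `pipeline_detect` list of all stage outputs.
#' @export
pipeline_detect <- function(image, config = fibril_config()) {
  stopifnot(inherits(image, "tem_image"), inherits(config, "fibril_config"))
  bw <- default_smoothing_bandwidth(image, config$smoothing_fraction)
  smoothed <- gaussian_smooth(image$intensity, bw)
  trend <- irls_fit_quadratic(image, field = smoothed, k = config$cauchy_k,
                              tol = config$irls_tol,
                              max_iter = config$irls_max_iter)
  f1 <- predict(trend)
  adjusted <- power_adjust(smoothed, f1)
  mask1 <- binarize(adjusted, image)
  dfield <- distance_field(mask1)
  scan <- bandwidth_scan(
    dfield,
    sigmas = seq(config$sigma_range[1], config$sigma_range[2],
                 by = config$sigma_step),
    degree = config$poly_degree, min_height = config$peak_min_height
  )
  sigma_star <- optimal_bandwidth(scan)
  centroids <- extract_centroids(dfield, sigma_star, config$peak_min_height)
  structure(
    list(image = image, bandwidth = bw, smoothed = smoothed, trend = trend,
         adjusted = adjusted, mask_first = mask1, distance = dfield,
         scan = scan, sigma_star = sigma_star, centroids = centroids,
         config = config),
    class = "pipeline_detect"
  )
}

#' Segmentation stage: corrected centroids through population summary
#'
#' @param detect A [pipeline_detect()] result.
#' @param centroids The (possibly corrected) `centroid_set` to use.
#' @param reject_ids Fibril ids whose ellipses are rejected from the summary.
#' @return A `fibril_run` object.
#' @export
pipeline_segment <- function(detect, centroids = detect$centroids,
                             reject_ids = NULL) {
  stopifnot(inherits(detect, "pipeline_detect"))
  config <- detect$config
  image <- detect$image
  if (nrow(centroids) == 0L) stop("no centroids: cannot segment")

  tess <- tessellate(centroids, image)
  tess <- flag_boundary_fibrils(tess, image)
  char_int <- characteristic_intensities(tess, detect$adjusted,
                                         config$char_percentile)
  f2 <- natural_neighbor_field(centroids, clip_unit(char_int), image)
  mask_refined <- rebinarize(detect$adjusted, f2, image)
  af <- area_fraction(mask_refined, image)

  gmm <- init_from_voronoi(mask_refined, tess, config$cov_floor)
  gmm <- em_fit(mask_refined, gmm, tol = config$em_tol,
                max_cycles = config$em_max_cycles)
  assignment <- assign_fibril_pixels(mask_refined, gmm, config$boundary_level)
  records <- fibril_records(assignment, tess, image$pixel_size)
  if (!is.null(reject_ids) && length(reject_ids) > 0L) {
    records <- reject_ellipses(records, reject_ids)
  }
  summary <- population_summary(records)

  structure(
    list(
      image = image, detect = detect, centroids = centroids, tess = tess,
      characteristic_intensities = char_int, f2 = f2,
      mask_refined = mask_refined, area_fraction = af,
      mixture = gmm, assignment = assignment, records = records,
      summary = summary, config = config
    ),
    class = "fibril_run"
  )
}

#' Run the full segmentation pipeline
#'
#' Orchestrates the whole sequence with the interactive steps of the original
#' workflow replaced by optional, reproducible correction inputs: polygonal
#' exclusion regions, a centroid-correction session and a list of rejected
#' ellipses. With no correction inputs the run is fully automatic.
#'
#' @param image A [tem_image()] or a path to a TIFF/PNG micrograph.
#' @param pixel_size Pixel size in nm/pixel (required when `image` is a path).
#' @param config A [fibril_config()].
#' @param exclusions List of exclusion polygons, or a JSON path
#'   (see [read_exclusions()]).
#' @param corrections A corrections list (`add`/`remove`/`move`) or JSON path
#'   (see [read_corrections()]).
#' @param reject_ids Fibril ids to reject, or a JSON path holding an array.
#' @param out_dir Optional output directory; when given, the per-fibril CSV,
#'   population and diagnostics JSON, masks and the run manifest are written.
#' @return A `fibril_run` object (with a `manifest` element).
#' @export
run_pipeline <- function(image, pixel_size = NULL, config = fibril_config(),
                         exclusions = NULL, corrections = NULL,
                         reject_ids = NULL, out_dir = NULL) {
  t0 <- Sys.time()
  input_path <- NULL
  if (is.character(image)) {
    input_path <- image
    if (is.null(pixel_size)) stop("pixel_size is required when reading a file")
    image <- tem_read(image, pixel_size)
  }
  if (is.character(exclusions)) exclusions <- read_exclusions(exclusions)
  if (!is.null(exclusions)) image <- apply_exclusions(image, exclusions)

  detect <- pipeline_detect(image, config)

  centroids <- detect$centroids
  if (is.character(corrections)) corrections <- read_corrections(corrections)
  if (!is.null(corrections)) {
    centroids <- correct_centroids(
      centroids, image,
      add = corrections$add, remove = corrections$remove,
      move = corrections$move
    )
  }
  if (is.character(reject_ids)) {
    reject_ids <- unlist(jsonlite::read_json(reject_ids, simplifyVector = TRUE))
  }

  run <- pipeline_segment(detect, centroids, reject_ids)
  run$manifest <- list(
    package_version = as.character(utils::packageVersion("fibrilseg")),
    input = if (!is.null(input_path)) {
      list(path = input_path, md5 = unname(tools::md5sum(input_path)))
    },
    pixel_size = image$pixel_size,
    dims = dim(image$intensity),
    config = unclass(config),
    n_exclusion_polygons = length(exclusions %||% list()),
    corrections = corrections,
    reject_ids = reject_ids,
    sigma_star = detect$sigma_star,
    n_centroids = nrow(centroids),
    area_fraction = run$area_fraction,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.fibril_run <- function(x, ...) {
  cat(sprintf(
    "<fibril_run> %d fibrils (%d analyzed), area fraction %.1f%%, sigma* = %.2f px\n",
    nrow(x$records), x$summary$counts$analyzed, x$area_fraction,
    x$detect$sigma_star
  ))
  invisible(x)
}

#' @export
tidy.fibril_run <- function(x, ...) tibble::as_tibble(x$records)

#' @export
glance.fibril_run <- function(x, ...) {
  tibble(
    n_fibrils = nrow(x$records),
    n_analyzed = x$summary$counts$analyzed,
    n_boundary = x$summary$counts$boundary_excluded,
    n_rejected = x$summary$counts$user_rejected,
    area_fraction = x$area_fraction,
    sigma_star = x$detect$sigma_star,
    em_cycles = x$mixture$cycles,
    em_converged = x$mixture$converged
  )
}

#' Write the outputs of a pipeline run
#'
#' Writes `fibrils.csv` (per-fibril table), `population.json`,
#' `manifest.json`, `sigma_scan.json`, `mixture.json` and the first-pass and
#' refined masks as PNG into `out_dir`. Output is deterministic for identical
#' inputs, corrections and configuration (the manifest's timing entry aside).
#'
#' @param run A `fibril_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "fibril_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as.data.frame(run$records), file.path(out_dir, "fibrils.csv"))

  summ <- run$summary
  jsonlite::write_json(
    list(
      counts = summ$counts,
      area_density = summ$area_density,
      aspect_density = summ$aspect_density,
      area_hist = summ$area_hist,
      aspect_hist = summ$aspect_hist,
      area_fraction = run$area_fraction
    ),
    file.path(out_dir, "population.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  jsonlite::write_json(
    list(
      scan = run$detect$scan$scan,
      poly = run$detect$scan$poly,
      scaling = run$detect$scan$scaling,
      sigma_star = run$detect$sigma_star
    ),
    file.path(out_dir, "sigma_scan.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(
      means = run$mixture$means, covariances = run$mixture$covs,
      proportions = run$mixture$prop, loglik_trace = run$mixture$loglik,
      cycles = run$mixture$cycles, converged = run$mixture$converged
    ),
    file.path(out_dir, "mixture.json"), auto_unbox = TRUE, digits = NA
  )
  manifest <- run$manifest %||% list()
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_mask_png(run$detect$mask_first, file.path(out_dir, "mask_first.png"))
  write_mask_png(run$mask_refined, file.path(out_dir, "mask_refined.png"))
  write_labels_png(run$assignment, file.path(out_dir, "labels.png"))
  invisible(out_dir)
}

#' Export a field as 32-bit float TIFF
#'
#' For inspecting trend surfaces and interpolants outside R.
#'
#' @param field Numeric matrix.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  field <- pmin(pmax(field, 0), 1)   # writeTIFF stores [0,1] float samples
  tiff::writeTIFF(field, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
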