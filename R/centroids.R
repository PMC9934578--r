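# Fibril centroid detection from the smoothed Euclidean distance field, with
# automatic smoothing-bandwidth selection and scriptable user corrections.

#' Euclidean distance field of a binary mask
#'
#' For every fibrillar pixel, the exact Euclidean distance to the nearest
#' non-fibrillar pixel; zero on all non-fibrillar pixels. Image borders are
#' not implicitly treated as background: a fibril touching the border measures
#' its distance to in-image background only (border-cut fibrils are flagged as
#' boundary fibrils downstream regardless).
#'
#' @param mask A `binary_mask`.
#' @return A `distance_field` object (matrix of distances in pixels).
#' @export
distance_field <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (all(mask$fibrillar)) stop("all pixels fibrillar: distance field undefined")
  d <- EBImage::distmap(EBImage::Image(mask$fibrillar * 1), metric = "euclidean")
  structure(
    list(values = matrix(EBImage::imageData(d), nrow(mask$fibrillar)),
         excluded = mask$excluded),
    class = "distance_field"
  )
}

#' @export
print.distance_field <- function(x, ...) {
  cat(sprintf("<distance_field> %d x %d px, max %.2f px\n",
              nrow(x$values), ncol(x$values), max(x$values)))
  invisible(x)
}

# Strict local maxima of a smoothed field over 8-neighborhoods.
# A connected plateau of equal-valued maximal pixels counts as one peak,
# located at the centroid of the plateau's pixels; any plateau adjacent to a
# strictly greater pixel is not a peak. Peaks with value <= min_height are
# ignored (background noise guard).
find_peaks <- function(values, min_height = 0.5) {
  h <- nrow(values); w <- ncol(values)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- values
  nb_max <- matrix(-Inf, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb_max <- pmax(nb_max, pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)])
  }
  cand <- values > min_height & values >= nb_max
  if (!any(cand)) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("u", "v"))))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(cand * 1)))
  peaks <- matrix(numeric(0), 0, 2)
  for (k in seq_len(max(lab))) {
    comp <- which(lab == k, arr.ind = TRUE)
    v0 <- values[comp[1, 1], comp[1, 2]]
    plat <- flood_equal(values, comp, v0)
    if (is.null(plat)) next                     # shoulder of a higher region
    # plateau centroid in (u, v) = (col-1, row-1)
    peaks <- rbind(peaks, c(mean(plat[, 2]) - 1, mean(plat[, 1]) - 1))
  }
  colnames(peaks) <- c("u", "v")
  peaks
}

# Expand a candidate component over the full 8-connected equal-valued plateau.
# Returns the plateau's (row, col) pixels, or NULL if any neighbor of the
# plateau is strictly greater than the plateau value.
flood_equal <- function(values, seed_px, v0) {
  h <- nrow(values); w <- ncol(values)
  seen <- matrix(FALSE, h, w)
  seen[seed_px] <- TRUE
  queue <- seed_px
  out <- seed_px
  while (nrow(queue) > 0L) {
    nxt <- matrix(integer(0), 0, 2)
    for (i in seq_len(nrow(queue))) {
      r0 <- queue[i, 1]; c0 <- queue[i, 2]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- r0 + dr; c <- c0 + dc
        if (r < 1 || r > h || c < 1 || c > w || seen[r, c]) next
        val <- values[r, c]
        if (val > v0) return(NULL)
        if (val == v0) {
          seen[r, c] <- TRUE
          nxt <- rbind(nxt, c(r, c))
        }
      }
    }
    out <- rbind(out, nxt)
    queue <- nxt
  }
  out
}

#' Count detected fibrils at a given smoothing bandwidth
#'
#' Smooths the distance field with a Gaussian of standard deviation `sigma`
#' and counts the local peaks (see the peak rules in [extract_centroids()]).
#'
#' @param field A [distance_field()].
#' @param sigma Bandwidth in pixels, positive.
#' @param min_height Minimum smoothed peak height in pixels (default 0.5).
#' @return Integer peak count.
#' @export
count_peaks <- function(field, sigma, min_height = 0.5) {
  stopifnot(inherits(field, "distance_field"), sigma > 0)
  sm <- gaussian_smooth(field$values, sigma)
  nrow(find_peaks(sm, min_height))
}

#' Scan smoothing bandwidths and fit the count polynomial
#'
#' Counts detected fibrils for bandwidths 0.5 to 10 pixels in steps of 0.5
#' (20 scan points) and fits a 5th-degree polynomial `p(sigma)` to the
#' `(sigma_i, N_i)` pairs by least squares. The polynomial is fitted on
#' sigma rescaled to `[-1, 1]` for conditioning.
#'
#' @param field A [distance_field()].
#' @param sigmas Scan bandwidths (default `seq(0.5, 10, 0.5)`).
#' @param degree Polynomial degree (default 5).
#' @param min_height Peak-height guard passed to [count_peaks()].
#' @return A `bandwidth_scan` object; its `scan` element is a tibble with
#'   columns `sigma` and `n_peaks`.
#' @export
bandwidth_scan <- function(field, sigmas = seq(0.5, 10, by = 0.5),
                           degree = 5L, min_height = 0.5) {
  stopifnot(inherits(field, "distance_field"))
  counts <- vapply(sigmas, function(s) count_peaks(field, s, min_height), numeric(1))
  sc <- list(mid = mean(range(sigmas)), half = diff(range(sigmas)) / 2)
  x <- (sigmas - sc$mid) / sc$half
  X <- outer(x, 0:degree, `^`)
  beta <- qr.coef(qr(X), counts)
  structure(
    list(
      scan = tibble(sigma = sigmas, n_peaks = counts),
      poly = unname(beta), scaling = sc, degree = degree
    ),
    class = "bandwidth_scan"
  )
}

#' @export
print.bandwidth_scan <- function(x, ...) {
  cat(sprintf("<bandwidth_scan> %d points, counts %d..%d\n",
              nrow(x$scan), min(x$scan$n_peaks), max(x$scan$n_peaks)))
  invisible(x)
}

#' @export
tidy.bandwidth_scan <- function(x, ...) x$scan

# evaluate polynomial (coefficients in increasing powers) at x
poly_eval <- function(coefs, x) {
  out <- numeric(length(x))
  for (j in rev(seq_along(coefs))) out <- out * x + coefs[j]
  out
}

poly_deriv <- function(coefs) {
  if (length(coefs) <= 1L) return(0)
  coefs[-1] * seq_len(length(coefs) - 1L)
}

# real roots of a polynomial given increasing-power coefficients
poly_real_roots <- function(coefs) {
  nz <- which(abs(coefs) > 0)
  if (length(nz) <= 1L) return(numeric(0))
  coefs <- coefs[1:max(nz)]
  r <- polyroot(coefs)
  Re(r[abs(Im(r)) < 1e-8 * (1 + abs(Re(r)))])
}

#' Select the optimal smoothing bandwidth from a scan
#'
#' Forms `q(sigma) = p'(sigma)^2` and returns the lowest positive sigma in the
#' scanned range at which `q` attains a strict local minimum. The candidates
#' are the real roots of `q'(sigma) = 2 p'(sigma) p''(sigma)` — that is, the
#' roots of `p'` and of `p''` — computed analytically from the fitted
#' polynomial; no iterative minimization is needed. If no candidate in range
#' qualifies, the scanned sigma minimizing `|p'(sigma)|` is returned with a
#' warning.
#'
#' @param scan A [bandwidth_scan()].
#' @return `sigma_star` in pixels.
#' @export
optimal_bandwidth <- function(scan) {
  stopifnot(inherits(scan, "bandwidth_scan"))
  p <- scan$poly
  p1 <- poly_deriv(p)
  p2 <- poly_deriv(p1)
  sc <- scan$scaling
  lo <- (min(scan$scan$sigma) - sc$mid) / sc$half
  hi <- (max(scan$scan$sigma) - sc$mid) / sc$half
  q <- function(x) poly_eval(p1, x)^2

  fallback <- function(msg) {
    warning(msg)
    scan$scan$sigma[which.min(abs(poly_eval(p1, (scan$scan$sigma - sc$mid) / sc$half)))]
  }
  if (all(abs(p1) < 1e-12)) {
    return(fallback("degenerate polynomial (p' = 0); falling back to scan points"))
  }
  cand <- sort(unique(c(poly_real_roots(p1), poly_real_roots(p2))))
  cand <- cand[cand > lo - 1e-9 & cand <= hi + 1e-9]
  delta <- 1e-5
  ok <- vapply(cand, function(x) {
    q(x - delta) > q(x) && q(x + delta) > q(x)
  }, logical(1))
  cand <- cand[ok]
  cand <- cand[cand * sc$half + sc$mid > 0]
  if (length(cand) == 0L) {
    return(fallback("no strict local minimum of (p')^2 in range; using scan argmin |p'|"))
  }
  min(cand) * sc$half + sc$mid
}

#' Extract fibril centroids from the optimally smoothed distance field
#'
#' Smooths the distance field at `sigma_star` and returns the local-peak
#' locations as sub-pixel `(u, v)` coordinates. A connected equal-valued
#' plateau yields a single centroid at the centroid of its pixels. Peaks with
#' smoothed height at most `min_height` pixels are suppressed; peaks closer
#' than 1 px are merged (highest kept). Provenance is `"auto"`.
#'
#' @param field A [distance_field()].
#' @param sigma_star Smoothing bandwidth in pixels.
#' @param min_height Peak-height guard (default 0.5 px).
#' @return A `centroid_set`: tibble with columns `u`, `v`, `provenance`.
#' @export
extract_centroids <- function(field, sigma_star, min_height = 0.5) {
  stopifnot(inherits(field, "distance_field"), sigma_star > 0)
  sm <- gaussian_smooth(field$values, sigma_star)
  pk <- find_peaks(sm, min_height)
  if (nrow(pk) == 0L) {
    warning("no peaks detected: empty centroid set")
    return(new_centroid_set(tibble(u = numeric(0), v = numeric(0),
                                   provenance = character(0))))
  }
  hts <- sm[cbind(pmin(pmax(round(pk[, "v"]) + 1, 1), nrow(sm)),
                  pmin(pmax(round(pk[, "u"]) + 1, 1), ncol(sm)))]
  ord <- order(-hts)
  keep <- rep(TRUE, nrow(pk))
  for (i in seq_along(ord)) {
    if (!keep[ord[i]]) next
    if (i < length(ord)) for (j in ord[(i + 1):length(ord)]) {
      if (keep[j] &&
          sum((pk[ord[i], ] - pk[j, ])^2) < 1) keep[j] <- FALSE
    }
  }
  pk <- pk[keep, , drop = FALSE]
  # drop peaks in excluded regions (cannot arise from a valid mask, but the
  # invariant is enforced regardless)
  ri <- pmin(pmax(round(pk[, "v"]) + 1, 1), nrow(sm))
  ci <- pmin(pmax(round(pk[, "u"]) + 1, 1), ncol(sm))
  pk <- pk[!field$excluded[cbind(ri, ci)], , drop = FALSE]
  new_centroid_set(tibble(u = pk[, "u"], v = pk[, "v"],
                          provenance = rep("auto", nrow(pk))))
}

new_centroid_set <- function(tbl, removed = tibble(u = numeric(0), v = numeric(0)),
                             rejected_edits = character(0)) {
  structure(tbl, class = c("centroid_set", class(tbl)),
            removed = removed, rejected_edits = rejected_edits)
}

#' Apply scripted centroid corrections
#'
#' The programmatic equivalent of interactive centroid editing: removals,
#' moves, then additions, applied in that order. Invalid edits (out-of-bounds
#' or excluded targets, bad indices) are rejected individually, recorded in
#' the `rejected_edits` attribute, and the remaining edits proceed. Removed
#' points are retained in the `removed` attribute for audit.
#'
#' @param set A `centroid_set`.
#' @param image The [tem_image()] (bounds and exclusions for validation).
#' @param add Matrix/list of `(u, v)` points to add.
#' @param remove Integer indices (1-based rows of `set`) to remove.
#' @param move List of `list(index, c(u, v))` pairs (or an n x 3 matrix
#'   `(index, u, v)`) of points to relocate.
#' @return The corrected `centroid_set` with updated provenance.
#' @export
correct_centroids <- function(set, image, add = NULL, remove = NULL, move = NULL) {
  stopifnot(inherits(set, "centroid_set"), inherits(image, "tem_image"))
  h <- nrow(image$intensity); w <- ncol(image$intensity)
  tbl <- tibble(u = set$u, v = set$v, provenance = set$provenance)
  removed <- attr(set, "removed")
  rejected <- attr(set, "rejected_edits")

  valid_point <- function(u, v) {
    if (!is.finite(u) || !is.finite(v) ||
        u < -0.5 || u > w - 0.5 || v < -0.5 || v > h - 0.5) return(FALSE)
    !image$excluded[pmin(pmax(round(v) + 1, 1), h), pmin(pmax(round(u) + 1, 1), w)]
  }

  if (!is.null(remove) && length(remove) > 0L) {
    remove <- unique(as.integer(remove))
    bad <- remove[remove < 1L | remove > nrow(tbl)]
    if (length(bad) > 0L) {
      rejected <- c(rejected, sprintf("remove: invalid index %d", bad))
    }
    ok <- setdiff(remove, bad)
    if (length(ok) > 0L) {
      removed <- dplyr::bind_rows(removed, tbl[ok, c("u", "v")])
      tbl <- tbl[-ok, , drop = FALSE]
    }
  }

  if (!is.null(move) && length(move) > 0L) {
    if (is.matrix(move)) move <- lapply(seq_len(nrow(move)),
                                        function(i) list(move[i, 1], move[i, 2:3]))
    for (mv in move) {
      idx <- as.integer(mv[[1]]); pt <- as.numeric(mv[[2]])
      if (is.na(idx) || idx < 1L || idx > nrow(tbl)) {
        rejected <- c(rejected, sprintf("move: invalid index %s", mv[[1]]))
      } else if (!valid_point(pt[1], pt[2])) {
        rejected <- c(rejected,
                      sprintf("move: target (%.2f, %.2f) out of bounds or excluded",
                              pt[1], pt[2]))
      } else {
        tbl$u[idx] <- pt[1]; tbl$v[idx] <- pt[2]
        tbl$provenance[idx] <- "user_moved"
      }
    }
  }

  if (!is.null(add) && length(add) > 0L) {
    if (is.list(add) && !is.matrix(add)) add <- do.call(rbind, lapply(add, as.numeric))
    add <- matrix(as.numeric(add), ncol = 2)
    for (i in seq_len(nrow(add))) {
      if (!valid_point(add[i, 1], add[i, 2])) {
        rejected <- c(rejected,
                      sprintf("add: point (%.2f, %.2f) out of bounds or excluded",
                              add[i, 1], add[i, 2]))
      } else {
        tbl <- dplyr::bind_rows(tbl, tibble(u = add[i, 1], v = add[i, 2],
                                            provenance = "user_added"))
      }
    }
  }
  new_centroid_set(tbl, removed = removed, rejected_edits = rejected)
}

#' Read a centroid-correction session from JSON
#'
#' Expects `{"add": [[u, v], ...], "remove": [idx, ...],
#' "move": [[idx, [u, v]], ...]}` with 1-based indices and 0-based pixel
#' coordinates.
#'
#' @param path Path to a JSON file.
#' @return List with elements `add`, `remove`, `move` for [correct_centroids()].
#' @export
read_corrections <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  list(
    add = lapply(doc$add %||% list(), function(p) as.numeric(unlist(p))),
    remove = as.integer(unlist(doc$remove %||% list())),
    move = lapply(doc$move %||% list(), function(m) {
      list(as.integer(m[[1]]), as.numeric(unlist(m[[2]])))
    })
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
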