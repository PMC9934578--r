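# Gaussian mixture segmentation of fibrillar pixels: Voronoi-seeded
# initialization, sequential conditional EM (means/proportions conditional on
# covariances, then covariances/proportions conditional on means), posterior
# membership fields and the P = 0.5 neighborhood boundaries.

#' Initialize a Gaussian mixture from the Voronoi tessellation
#'
#' Component means are the (user-approved) centroid locations; each component
#' covariance is the covariance (1/n normalization) of the fibrillar pixels in
#' its Voronoi cell, floored so that no eigenvalue falls below `cov_floor`;
#' proportions are the cell fibrillar-pixel counts over the total (empty cells
#' count as one pixel so that no proportion starts at zero).
#'
#' @param mask A `binary_mask` (refined binarization).
#' @param tess A [tessellate()] result.
#' @param cov_floor Minimum covariance eigenvalue in px^2 (default 0.25).
#' @return A `fibril_gmm` object (unfitted).
#' @export
init_from_voronoi <- function(mask, tess, cov_floor = 0.25) {
  stopifnot(inherits(mask, "binary_mask"), inherits(tess, "voronoi_tess"))
  px <- fibrillar_coords(mask)
  n <- nrow(tess$centroids)
  lab <- tess$labels[cbind(round(px[, 2]) + 1, round(px[, 1]) + 1)]
  counts <- tabulate(lab, nbins = n)
  covs <- array(0, c(2, 2, n))
  for (i in seq_len(n)) {
    sel <- lab == i
    if (sum(sel) < 3L) {
      warning("component ", i, " has fewer than 3 fibrillar pixels; ",
              "using the floored isotropic covariance")
      covs[, , i] <- diag(cov_floor, 2)
    } else {
      covs[, , i] <- floor_cov(pop_cov(px[sel, , drop = FALSE]), cov_floor)
    }
  }
  prop <- pmax(counts, 1)
  prop <- prop / sum(prop)
  new_fibril_gmm(
    means = tess$centroids, covs = covs, prop = prop,
    cov_floor = cov_floor, loglik = numeric(0), converged = NA, cycles = 0L
  )
}

fibrillar_coords <- function(mask) {
  rc <- which(mask$fibrillar, arr.ind = TRUE)
  cbind(u = rc[, 2] - 1, v = rc[, 1] - 1)
}

pop_cov <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  unname(crossprod(xc) / nrow(x))
}

floor_cov <- function(S, floor_ev) {
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, floor_ev)
  S2 <- e$vectors %*% diag(ev) %*% t(e$vectors)
  (S2 + t(S2)) / 2
}

new_fibril_gmm <- function(means, covs, prop, cov_floor, loglik, converged,
                           cycles, frozen = NULL) {
  structure(
    list(means = means, covs = covs, prop = prop, cov_floor = cov_floor,
         loglik = loglik, converged = converged, cycles = cycles,
         frozen = frozen %||% rep(FALSE, nrow(means))),
    class = "fibril_gmm"
  )
}

#' @export
print.fibril_gmm <- function(x, ...) {
  cat(sprintf(
    "<fibril_gmm> %d components, %d ECM cycles (%s)\n",
    nrow(x$means), x$cycles,
    if (isTRUE(x$converged)) "converged" else if (is.na(x$converged)) "unfitted"
    else "not converged"
  ))
  invisible(x)
}

#' @export
tidy.fibril_gmm <- function(x, ...) {
  tibble(
    component = seq_len(nrow(x$means)),
    mu_u = x$means[, 1], mu_v = x$means[, 2],
    var_u = x$covs[1, 1, ], var_v = x$covs[2, 2, ], cov_uv = x$covs[1, 2, ],
    proportion = x$prop
  )
}

#' @export
glance.fibril_gmm <- function(x, ...) {
  tibble(
    n_components = nrow(x$means), cycles = x$cycles,
    converged = x$converged,
    loglik = if (length(x$loglik)) tail(x$loglik, 1) else NA_real_
  )
}

# log densities of all components at points x (m x 2): returns m x N matrix
# of log(phi_i) + log N(x | mu_i, Sigma_i)
log_weighted_dens <- function(x, means, covs, prop) {
  n <- nrow(means)
  out <- matrix(NA_real_, nrow(x), n)
  for (i in seq_len(n)) {
    S <- covs[, , i]
    det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
    inv <- matrix(c(S[2, 2], -S[1, 2], -S[1, 2], S[1, 1]), 2) / det_s
    dx <- x[, 1] - means[i, 1]
    dy <- x[, 2] - means[i, 2]
    maha <- inv[1, 1] * dx^2 + 2 * inv[1, 2] * dx * dy + inv[2, 2] * dy^2
    out[, i] <- log(prop[i]) - log(2 * pi) - 0.5 * log(det_s) - 0.5 * maha
  }
  out
}

# responsibilities + observed-data log-likelihood via log-sum-exp
e_step <- function(x, means, covs, prop) {
  lw <- log_weighted_dens(x, means, covs, prop)
  mx <- apply(lw, 1, max)
  lse <- mx + log(rowSums(exp(lw - mx)))
  list(gamma = exp(lw - lse), loglik = sum(lse))
}

#' Fit the mixture by sequential conditional EM
#'
#' Each cycle refreshes the posterior responsibilities and then performs two
#' conditional maximizations: first the component means and proportions are
#' updated holding the covariances fixed, then (after a second E-step) the
#' covariances and proportions are updated holding the means fixed. The
#' covariance floor is enforced after every covariance update. The
#' observed-data log-likelihood is non-decreasing across each half-update
#' (ECM property) and the cycle stops when its relative change falls below
#' `tol` or after `max_cycles` cycles. A component whose proportion collapses
#' below `1 / (10 n_pixels)` is frozen at its initial state with a warning.
#'
#' @param pixels Two-column matrix of fibrillar pixel `(u, v)` coordinates,
#'   or a `binary_mask`.
#' @param mixture An initialized `fibril_gmm` (see [init_from_voronoi()]).
#' @param tol Relative log-likelihood tolerance (default 1e-8).
#' @param max_cycles Cycle cap (default 200).
#' @return The fitted `fibril_gmm`; `$loglik` holds the log-likelihood trace
#'   recorded after every half-update.
#' @export
em_fit <- function(pixels, mixture, tol = 1e-8, max_cycles = 200L) {
  stopifnot(inherits(mixture, "fibril_gmm"))
  x <- if (inherits(pixels, "binary_mask")) fibrillar_coords(pixels) else
    as.matrix(pixels)
  storage.mode(x) <- "double"
  n_comp <- nrow(mixture$means)
  if (nrow(x) < 3L * n_comp) {
    stop("need at least 3 pixels per mixture component")
  }
  means <- mixture$means; covs <- mixture$covs; prop <- mixture$prop
  init <- list(means = means, covs = covs, prop = prop)
  frozen <- rep(FALSE, n_comp)
  floor_ev <- mixture$cov_floor
  collapse_at <- 1 / (10 * nrow(x))

  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  cyc <- 0L
  while (cyc < max_cycles) {
    cyc <- cyc + 1L

    # half-update 1: means and proportions conditional on covariances
    es <- e_step(x, means, covs, prop)
    g <- es$gamma
    nk <- colSums(g)
    upd <- !frozen & nk > 0
    means[upd, 1] <- (crossprod(g, x[, 1]) / nk)[upd]
    means[upd, 2] <- (crossprod(g, x[, 2]) / nk)[upd]
    prop_new <- nk / nrow(x)
    prop[!frozen] <- prop_new[!frozen]
    prop <- prop / sum(prop)
    # half-update 2: covariances and proportions conditional on means
    es <- e_step(x, means, covs, prop)
    trace <- c(trace, es$loglik)
    g <- es$gamma
    nk <- colSums(g)
    for (i in seq_len(n_comp)) {
      if (frozen[i] || nk[i] <= 0) next
      dx <- x[, 1] - means[i, 1]
      dy <- x[, 2] - means[i, 2]
      S <- matrix(c(
        sum(g[, i] * dx^2), sum(g[, i] * dx * dy),
        sum(g[, i] * dx * dy), sum(g[, i] * dy^2)
      ), 2) / nk[i]
      covs[, , i] <- floor_cov(S, floor_ev)
    }
    prop_new <- nk / nrow(x)
    prop[!frozen] <- prop_new[!frozen]
    prop <- prop / sum(prop)

    collapse <- !frozen & prop < collapse_at
    if (any(collapse)) {
      warning("component(s) ", paste(which(collapse), collapse = ", "),
              " collapsed; frozen at initial state")
      for (i in which(collapse)) {
        means[i, ] <- init$means[i, ]
        covs[, , i] <- init$covs[, , i]
        prop[i] <- init$prop[i]
      }
      prop <- prop / sum(prop)
      frozen <- frozen | collapse
    }

    ll <- e_step(x, means, covs, prop)$loglik
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  if (!converged) warning("EM did not converge in ", max_cycles, " cycles")
  new_fibril_gmm(means, covs, prop, floor_ev, trace, converged, cyc, frozen)
}

#' Posterior membership probabilities
#'
#' Evaluates, for each query location, the posterior probability that it
#' belongs to each mixture component (weighted normal densities normalized
#' across components, computed in log space). Rows sum to one. If every
#' component's density underflows at a query point, the point is assigned to
#' the component with the smallest Mahalanobis distance, with a warning.
#'
#' @param mixture A fitted `fibril_gmm`.
#' @param query Two-column matrix of `(u, v)` locations.
#' @return Matrix of posteriors, `nrow(query)` by `n_components`.
#' @export
posterior_field <- function(mixture, query) {
  stopifnot(inherits(mixture, "fibril_gmm"))
  x <- as.matrix(query)
  storage.mode(x) <- "double"
  lw <- log_weighted_dens(x, mixture$means, mixture$covs, mixture$prop)
  mx <- apply(lw, 1, max)
  bad <- !is.finite(mx)
  if (any(bad)) {
    warning(sum(bad), " query point(s) underflowed; assigned by nearest ",
            "Mahalanobis distance")
    for (r in which(bad)) {
      d <- vapply(seq_len(nrow(mixture$means)), function(i) {
        S <- mixture$covs[, , i]
        dv <- x[r, ] - mixture$means[i, ]
        c(dv %*% solve(S, dv))
      }, numeric(1))
      lw[r, ] <- ifelse(seq_along(d) == which.min(d), 0, -Inf)
      mx[r] <- 0
    }
  }
  p <- exp(lw - mx)
  p / rowSums(p)
}

#' Assign fibrillar pixels to fibrils by the P = 0.5 rule
#'
#' A fibrillar pixel belongs to component `i` iff its posterior `P_i` strictly
#' exceeds 0.5 at the pixel center (at most one component can). Fibrillar
#' pixels with maximum posterior at or below 0.5 remain unassigned (label 0)
#' and are reported.
#'
#' @param mask A `binary_mask` (refined binarization).
#' @param mixture A fitted `fibril_gmm`.
#' @param level Posterior boundary level (default 0.5).
#' @return A `fibril_assignment`: `labels` (integer matrix; 0 = background or
#'   unassigned), `n_unassigned`, and the pixel coordinates per component.
#' @export
assign_fibril_pixels <- function(mask, mixture, level = 0.5) {
  stopifnot(inherits(mask, "binary_mask"), inherits(mixture, "fibril_gmm"))
  px <- fibrillar_coords(mask)
  post <- posterior_field(mixture, px)
  pmax_i <- max.col(post, ties.method = "first")
  pmax_v <- post[cbind(seq_len(nrow(post)), pmax_i)]
  assigned <- ifelse(pmax_v > level, pmax_i, 0L)
  labels <- matrix(0L, nrow(mask$fibrillar), ncol(mask$fibrillar))
  labels[cbind(px[, 2] + 1, px[, 1] + 1)] <- assigned
  structure(
    list(
      labels = labels, n_unassigned = sum(assigned == 0L),
      pixels = lapply(seq_len(nrow(mixture$means)), function(i) {
        px[assigned == i, , drop = FALSE]
      })
    ),
    class = "fibril_assignment"
  )
}

#' @export
print.fibril_assignment <- function(x, ...) {
  cat(sprintf("<fibril_assignment> %d fibrils, %d unassigned fibrillar px\n",
              length(x$pixels), x$n_unassigned))
  invisible(x)
}

#' Export a per-pixel assignment map as a 16-bit label PNG
#'
#' Component ids (0 = background or unassigned fibrillar pixel) are stored
#' losslessly as a 16-bit value split across the red (high byte) and green
#' (low byte) channels of an RGBA PNG; [read_labels_png()] reverses the
#' encoding.
#'
#' @param assignment A [assign_fibril_pixels()] result (or an integer label
#'   matrix).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_labels_png <- function(assignment, path) {
  labels <- if (inherits(assignment, "fibril_assignment")) assignment$labels
            else assignment
  stopifnot(is.matrix(labels), max(labels) <= 65535L, min(labels) >= 0L)
  img <- array(0, c(nrow(labels), ncol(labels), 4))
  img[, , 1] <- (labels %/% 256L) / 255
  img[, , 2] <- (labels %% 256L) / 255
  img[, , 4] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' Read a label PNG written by [write_labels_png()]
#'
#' @param path Path to the label PNG.
#' @return Integer label matrix.
#' @export
read_labels_png <- function(path) {
  img <- png::readPNG(path)
  stopifnot(length(dim(img)) == 3L, dim(img)[3] >= 2L)
  matrix(as.integer(round(img[, , 1] * 255) * 256L +
                    round(img[, , 2] * 255)),
         dim(img)[1], dim(img)[2])
}

#' Extract fibril neighborhood boundary polylines
#'
#' The implicit neighborhood boundary of each fibril is the 0.5 level set of
#' its posterior field, extracted by marching squares on the 1-px pixel grid
#' (visualization only; pixel assignment uses pointwise evaluation).
#'
#' @param mixture A fitted `fibril_gmm`.
#' @param dims Image dimensions `c(height, width)`.
#' @param level Contour level (default 0.5).
#' @param components Which components to contour (default all).
#' @return Tibble with columns `component`, `piece`, `u`, `v`.
#' @export
neighborhood_boundaries <- function(mixture, dims, level = 0.5,
                                    components = NULL) {
  stopifnot(inherits(mixture, "fibril_gmm"))
  h <- dims[1]; w <- dims[2]
  uv <- pixel_centers(h, w)
  post <- posterior_field(mixture, uv)
  if (is.null(components)) components <- seq_len(nrow(mixture$means))
  out <- purrr::map_dfr(components, function(i) {
    z <- matrix(post[, i], h, w)
    cl <- grDevices::contourLines(x = 0:(h - 1), y = 0:(w - 1), z = z,
                                  levels = level)
    purrr::imap_dfr(cl, function(seg, k) {
      tibble(component = i, piece = k, u = seg$y, v = seg$x)
    })
  })
  out
}
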