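# Independent brute-force oracles and small fixture builders. Every oracle is
# a direct transcription of the quantity's definition, sharing no code with
# the implementation it checks.

# exact Euclidean distance transform by all-pairs nearest-background scan
brute_edt <- function(fib) {
  h <- nrow(fib); w <- ncol(fib)
  out <- matrix(0, h, w)
  bg <- which(!fib, arr.ind = TRUE)
  fg <- which(fib, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2
    out[fg[i, 1], fg[i, 2]] <- sqrt(min(d2))
  }
  out
}

# exhaustive Otsu: for every interior edge of a 256-bin histogram, split the
# actual pixel values and compute the between-class variance directly
brute_otsu <- function(x, n_bins = 256L) {
  best <- -Inf
  best_t <- NA_real_
  n <- length(x)
  bin <- pmin(floor(x * n_bins), n_bins - 1L)
  for (b in 1:(n_bins - 1L)) {
    lo <- x[bin < b]
    hi <- x[bin >= b]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / n
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best + 1e-15) {          # strict improvement: ties keep lowest b
      best <- v
      best_t <- b / n_bins
    }
  }
  best_t
}

# nearest-centroid labels with lowest-index tie rule
brute_nearest_labels <- function(pts, h, w) {
  out <- matrix(0L, h, w)
  for (r in 1:h) for (cc in 1:w) {
    d2 <- (cc - 1 - pts[, 1])^2 + (r - 1 - pts[, 2])^2
    out[r, cc] <- which(d2 == min(d2))[1]
  }
  out
}

# dense-grid minimizer of (p')^2 restricted to interior local minima,
# in the scaled polynomial coordinate; returns sigma on the raw scale
grid_sigma_star <- function(poly, scaling, lo = 0.5, hi = 10, step = 1e-4) {
  sig <- seq(lo, hi, by = step)
  x <- (sig - scaling$mid) / scaling$half
  p1 <- fibrilseg:::poly_deriv(poly)
  q <- fibrilseg:::poly_eval(p1, x)^2
  n <- length(q)
  is_min <- c(FALSE, q[2:(n - 1)] < q[1:(n - 2)] & q[2:(n - 1)] <= q[3:n], FALSE)
  if (!any(is_min)) return(NA_real_)
  sig[which(is_min)[1]]
}

# increasing-power coefficients of a monic polynomial with the given roots
poly_from_roots <- function(roots, lead = 1) {
  p <- lead                                   # decreasing-power coefficients
  for (r in roots) p <- c(p, 0) - r * c(0, p)
  rev(p)                                      # increasing powers
}

# filled disk / ellipse masks on an h x w canvas (0-based centers)
disk_mask <- function(h, w, cu, cv, radius) {
  u <- matrix(rep(0:(w - 1), each = h), h, w)
  v <- matrix(rep(0:(h - 1), times = w), h, w)
  (u - cu)^2 + (v - cv)^2 <= radius^2
}

make_mask <- function(fib, excluded = NULL) {
  if (is.null(excluded)) excluded <- matrix(FALSE, nrow(fib), ncol(fib))
  structure(list(fibrillar = fib & !excluded, threshold = NA_real_,
                 excluded = excluded), class = "binary_mask")
}

# uniform samples inside an ellipse (rejection sampling)
runif_ellipse <- function(n, a, b, theta = 0) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    x <- runif(2 * n, -a, a)
    y <- runif(2 * n, -b, b)
    keep <- (x / a)^2 + (y / b)^2 <= 1
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  cbind(out[, 1] * cos(theta) - out[, 2] * sin(theta),
        out[, 1] * sin(theta) + out[, 2] * cos(theta))
}
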