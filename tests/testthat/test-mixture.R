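make_blob_mask <- function(h, w, centers, radius) {
  fib <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(centers))) {
    fib <- fib | disk_mask(h, w, centers[i, 1], centers[i, 2], radius)
  }
  make_mask(fib)
}

test_that("Voronoi initialization uses cell covariances and counts", {
  mask <- make_blob_mask(40, 40, rbind(c(19.5, 19.5)), 10)
  img <- tem_image(matrix(0.5, 40, 40), 1)
  tess <- tessellate(rbind(c(19.5, 19.5)), img)
  gmm <- init_from_voronoi(mask, tess)
  px <- fibrilseg:::fibrillar_coords(mask)
  expect_equal(gmm$prop, 1)
  expect_equal(gmm$covs[, , 1], fibrilseg:::pop_cov(px), tolerance = 1e-12)
  expect_equal(gmm$means[1, ], c(19.5, 19.5), ignore_attr = TRUE)

  # two equal blobs -> equal proportions
  mask2 <- make_blob_mask(40, 80, rbind(c(20, 20), c(60, 20)), 8)
  img2 <- tem_image(matrix(0.5, 40, 80), 1)
  tess2 <- tessellate(rbind(c(20, 20), c(60, 20)), img2)
  gmm2 <- init_from_voronoi(mask2, tess2)
  expect_equal(gmm2$prop, c(0.5, 0.5))

  # empty cell -> floored isotropic covariance with a warning
  mask3 <- make_blob_mask(40, 80, rbind(c(20, 20)), 8)
  expect_warning(gmm3 <- init_from_voronoi(mask3, tess2), "fewer than 3")
  expect_equal(gmm3$covs[, , 2], diag(0.25, 2))
  expect_gt(gmm3$prop[2], 0)
})

test_that("a one-component fit lands on the sample moments", {
  mask <- make_blob_mask(30, 30, rbind(c(14, 15)), 9)
  img <- tem_image(matrix(0.5, 30, 30), 1)
  tess <- tessellate(rbind(c(12, 12)), img)  # deliberately offset start
  fit <- em_fit(mask, init_from_voronoi(mask, tess))
  px <- fibrilseg:::fibrillar_coords(mask)
  expect_equal(fit$means[1, ], colMeans(px), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fit$covs[, , 1], fibrilseg:::pop_cov(px), tolerance = 1e-4)
  expect_equal(fit$prop, 1)
})

test_that("sequential conditional EM recovers two separated Gaussians", {
  set.seed(42)
  n <- 500
  x1 <- cbind(rnorm(n, 30, 4), rnorm(n, 40, 3))
  x2 <- cbind(rnorm(n, 80, 3), rnorm(n, 40, 4))
  pts <- rbind(x1, x2)
  start <- fibrilseg:::new_fibril_gmm(
    means = rbind(c(32, 41), c(78, 39)),
    covs = array(rep(diag(9, 2), 2), c(2, 2, 2)),
    prop = c(0.5, 0.5), cov_floor = 0.25,
    loglik = numeric(0), converged = NA, cycles = 0L
  )
  fit <- em_fit(pts, start)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$means - rbind(c(30, 40), c(80, 40)))), 0.5)
  expect_lt(max(abs(fit$prop - 0.5)), 0.02)

  # log-likelihood trace is non-decreasing across every half-update
  expect_gte(min(diff(fit$loglik)), -1e-9)

  # independent EM cross-check: mclust on the same data, same model class
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  mc <- mclust::Mclust(pts, G = 2, modelNames = "VVV", verbose = FALSE)
  ord <- order(mc$parameters$mean[1, ])
  expect_lt(max(abs(t(mc$parameters$mean)[ord, ] - fit$means)), 0.5)
})

test_that("posterior fields normalize and respect symmetry", {
  gmm1 <- fibrilseg:::new_fibril_gmm(
    means = rbind(c(10, 10)), covs = array(diag(4, 2), c(2, 2, 1)),
    prop = 1, cov_floor = 0.25, loglik = numeric(0), converged = TRUE,
    cycles = 1L
  )
  q <- cbind(runif(50, 0, 20), runif(50, 0, 20))
  expect_true(all(posterior_field(gmm1, q) == 1))

  # mirrored identical components: P = 0.5 on the midline
  gmm2 <- fibrilseg:::new_fibril_gmm(
    means = rbind(c(10, 15), c(20, 15)),
    covs = array(rep(diag(6, 2), 2), c(2, 2, 2)),
    prop = c(0.5, 0.5), cov_floor = 0.25, loglik = numeric(0),
    converged = TRUE, cycles = 1L
  )
  mid <- cbind(rep(15, 21), seq(5, 25))
  pm <- posterior_field(gmm2, mid)
  expect_true(all(abs(pm - 0.5) < 1e-12))

  set.seed(7)
  q2 <- cbind(runif(1e4, -50, 80), runif(1e4, -50, 80))
  p2 <- posterior_field(gmm2, q2)
  expect_lt(max(abs(rowSums(p2) - 1)), 1e-12)

  # log-space stabilization keeps even extreme queries normalized
  pf <- posterior_field(gmm2, cbind(1e4, 1e4))
  expect_equal(rowSums(pf), 1)
})

test_that("pixels are assigned only where a posterior strictly exceeds 0.5", {
  mask <- make_blob_mask(31, 61, rbind(c(15, 15), c(45, 15)), 9)
  img <- tem_image(matrix(0.5, 31, 61), 1)
  tess <- tessellate(rbind(c(15, 15), c(45, 15)), img)
  fit <- em_fit(mask, init_from_voronoi(mask, tess))
  asg <- assign_fibril_pixels(mask, fit)
  # at most one component can exceed 0.5 anywhere: labels partition pixels
  expect_true(all(asg$labels %in% 0:2))
  expect_equal(sum(asg$labels > 0) + asg$n_unassigned, sum(mask$fibrillar))

  # an exactly mirrored mixture leaves the midline pixel unassigned
  gmm2 <- fibrilseg:::new_fibril_gmm(
    means = rbind(c(14, 10), c(16, 10)),
    covs = array(rep(diag(2, 2), 2), c(2, 2, 2)),
    prop = c(0.5, 0.5), cov_floor = 0.25, loglik = numeric(0),
    converged = TRUE, cycles = 1L
  )
  midmask <- make_mask({f <- matrix(FALSE, 21, 31); f[11, 16] <- TRUE; f})
  asg2 <- assign_fibril_pixels(midmask, gmm2)
  expect_equal(asg2$n_unassigned, 1)
})

test_that("isotropic equal mixtures reduce to nearest-centroid assignment", {
  set.seed(13)
  pts <- cbind(sample(0:59, 8), sample(0:39, 8))
  img <- tem_image(matrix(0.5, 40, 60), 1)
  fib <- matrix(TRUE, 40, 60)
  mask <- make_mask(fib)
  eps <- 1e-4
  gmm <- fibrilseg:::new_fibril_gmm(
    means = pts, covs = array(rep(diag(eps, 2), 8), c(2, 2, 8)),
    prop = rep(1 / 8, 8), cov_floor = eps, loglik = numeric(0),
    converged = TRUE, cycles = 1L
  )
  asg <- assign_fibril_pixels(mask, gmm)
  brute <- brute_nearest_labels(pts, 40, 60)
  # exactly equidistant pixels: brute breaks the tie, the mixture leaves the
  # pixel unassigned (both posteriors 0.5); compare where the nearest site
  # is unique
  u <- rep(0:59, each = 40); v <- rep(0:39, times = 60)
  d2 <- sapply(seq_len(nrow(pts)),
               function(i) (u - pts[i, 1])^2 + (v - pts[i, 2])^2)
  dmin <- do.call(pmin, as.data.frame(d2))
  tie <- matrix(rowSums(d2 == dmin) > 1, 40, 60)
  expect_identical(asg$labels[!tie], brute[!tie])
  expect_true(all(asg$labels[tie] == 0L))
})

test_that("fitted means stay near their user-approved initializations", {
  ph <- generate_phantom(phantom_spec(n_fibrils = 12, width = 170L,
                                      height = 170L, cores = FALSE), seed = 31)
  det <- pipeline_detect(ph$image)
  run <- pipeline_segment(det)
  drift <- sqrt(rowSums((run$mixture$means - run$tess$centroids)^2))
  expect_lt(max(drift), 3)
})

test_that("neighborhood boundary polylines trace the 0.5 level set", {
  gmm <- fibrilseg:::new_fibril_gmm(
    means = rbind(c(20, 20)), covs = array(diag(9, 2), c(2, 2, 1)),
    prop = 1, cov_floor = 0.25, loglik = numeric(0), converged = TRUE,
    cycles = 1L
  )
  # a single component has P = 1 everywhere: no 0.5 contour exists
  expect_equal(nrow(neighborhood_boundaries(gmm, c(41, 41))), 0)

  gmm2 <- fibrilseg:::new_fibril_gmm(
    means = rbind(c(15, 20), c(26, 20)),
    covs = array(rep(diag(4, 2), 2), c(2, 2, 2)),
    prop = c(0.5, 0.5), cov_floor = 0.25, loglik = numeric(0),
    converged = TRUE, cycles = 1L
  )
  nb <- neighborhood_boundaries(gmm2, c(41, 41))
  expect_gt(nrow(nb), 0)
  # the boundary between mirrored components is the vertical line u = 20.5
  expect_true(all(abs(nb$u - 20.5) < 1e-6))
})

test_that("label PNG export round-trips component ids losslessly", {
  d <- withr::local_tempdir()
  set.seed(2)
  labels <- matrix(sample(c(0L, 1L, 2L, 300L, 65535L), 120, replace = TRUE),
                   10, 12)
  p <- write_labels_png(labels, file.path(d, "lab.png"))
  expect_identical(read_labels_png(p), labels)
})
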