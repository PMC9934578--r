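test_that("tessellation labels equal brute-force nearest centroid with tie rule", {
  img <- tem_image(matrix(0.5, 20, 20), 1)

  t1 <- tessellate(rbind(c(7, 9)), img)
  expect_true(all(t1$labels == 1L))

  # two centroids: the label boundary is the rasterized perpendicular bisector
  t2 <- tessellate(rbind(c(4, 10), c(14, 10)), img)
  expect_true(all(t2$labels[, 1:9] == 1L))
  expect_true(all(t2$labels[, 11:20] == 2L))

  # 4 centroids at square corners: center pixel ties to the lowest index
  img9 <- tem_image(matrix(0.5, 9, 9), 1)
  t4 <- tessellate(rbind(c(0, 0), c(8, 0), c(0, 8), c(8, 8)), img9)
  expect_equal(t4$labels[5, 5], 1L)

  # oracle equivalence on random instances up to 128 x 128 (exact)
  for (seed in 1:3) {
    set.seed(seed)
    h <- sample(20:128, 1); w <- sample(20:128, 1)
    n <- sample(3:12, 1)
    pts <- cbind(runif(n, 0, w - 1), runif(n, 0, h - 1))
    tess <- tessellate(pts, tem_image(matrix(0.5, h, w), 1))
    expect_identical(tess$labels, brute_nearest_labels(pts, h, w))
  }

  expect_error(tessellate(matrix(numeric(0), 0, 2), img), "zero")
})

test_that("excluded pixels get label 0", {
  img <- tem_image(matrix(0.5, 10, 10), 1)
  img$excluded[1:3, ] <- TRUE
  tess <- tessellate(rbind(c(5, 6)), img)
  expect_true(all(tess$labels[1:3, ] == 0L))
  expect_true(all(tess$labels[4:10, ] == 1L))
})

test_that("boundary flags mark cells with vertices outside or excluded", {
  img <- tem_image(matrix(0.5, 100, 100), 1)
  # single centroid: cell clipped only by the frame -> flagged
  t1 <- flag_boundary_fibrils(tessellate(rbind(c(50, 50)), img), img)
  expect_true(t1$boundary[1])

  # dense 5 x 5 grid: the 9 interior cells are interior, the ring is not
  gg <- expand.grid(u = seq(10, 90, 20), v = seq(10, 90, 20))
  tess <- flag_boundary_fibrils(tessellate(cbind(gg$u, gg$v), img), img)
  interior <- gg$u > 10 & gg$u < 90 & gg$v > 10 & gg$v < 90
  expect_false(any(tess$boundary[interior]))
  expect_true(all(tess$boundary[!interior]))

  # a cell vertex inside an excluded region flags that fibril: the Voronoi
  # vertex shared by the cells of (30,30), (50,30), (30,50), (50,50) sits at
  # (40, 40); excluding a small square around it flags exactly those cells
  img2 <- apply_exclusions(
    img, list(rbind(c(38, 38), c(42, 38), c(42, 42), c(38, 42)))
  )
  tess2 <- flag_boundary_fibrils(tessellate(cbind(gg$u, gg$v), img2), img2)
  touching <- (gg$u %in% c(30, 50)) & (gg$v %in% c(30, 50))
  expect_true(all(tess2$boundary[touching]))
  expect_false(any(tess2$boundary[interior & !touching]))
})

test_that("characteristic intensity averages the near-centroid pixels", {
  # uniform cell -> the constant
  adj <- matrix(0.42, 30, 30)
  px <- fibrilseg:::pixel_centers(30, 30)
  expect_equal(characteristic_intensity(px, c(14.5, 14.5), adj), 0.42)

  # radial gradient, dark at the centroid -> below the cell mean
  u <- matrix(rep(0:29, each = 30), 30, 30)
  v <- matrix(rep(0:29, times = 30), 30, 30)
  grad <- 0.2 + 0.6 * sqrt((u - 14.5)^2 + (v - 14.5)^2) / 21
  ci <- characteristic_intensity(px, c(14.5, 14.5), grad)
  expect_lt(ci, mean(grad))

  # constructed 100-pixel cell: hand enumeration of the strict-5th-percentile set
  cell <- fibrilseg:::pixel_centers(10, 10)
  vals <- matrix(seq(0.01, 1, length.out = 100), 10, 10)
  cen <- c(0, 0)
  d <- sqrt(cell[, 1]^2 + cell[, 2]^2)
  thr <- quantile(d, 0.05, type = 7, names = FALSE)
  sel <- d < thr
  expected <- mean(vals[cbind(cell[sel, 2] + 1, cell[sel, 1] + 1)])
  expect_equal(characteristic_intensity(cell, cen, vals), expected)
  expect_gte(sum(sel), 1)

  # tiny cell: nearest pixel with a warning
  tiny <- cell[1:10, , drop = FALSE]
  expect_warning(got <- characteristic_intensity(tiny, c(0, 0), vals),
                 "fewer than 20")
  expect_equal(got, vals[1, 1])
})

test_that("natural-neighbour field is exact at sites, bounded, and linear-precise", {
  img <- tem_image(matrix(0.5, 100, 100), 1)
  set.seed(5)
  pts <- cbind(runif(20, 5, 95), runif(20, 5, 95))

  # constant reproduction
  f_const <- natural_neighbor_field(pts, rep(0.37, 20), img)
  expect_true(all(abs(f_const - 0.37) < 1e-12))

  # exact at (pixel-coincident) sites
  ipts <- cbind(round(pts[, 1]), round(pts[, 2]))
  vals <- runif(20, 0.1, 0.9)
  f <- natural_neighbor_field(ipts, vals, img)
  expect_equal(f[cbind(ipts[, 2] + 1, ipts[, 1] + 1)], vals, tolerance = 1e-9)

  # maximum principle
  expect_gte(min(f), min(vals) - 1e-9)
  expect_lte(max(f), max(vals) + 1e-9)

  # linear precision inside the convex hull (1 px margin from the hull edge)
  lin <- 0.2 + 0.003 * pts[, 1] + 0.002 * pts[, 2]
  fl <- natural_neighbor_field(pts, lin, img)
  hull <- grDevices::chull(pts)
  hp <- pts[c(hull, hull[1]), ]
  uv <- fibrilseg:::pixel_centers(100, 100)
  ctr <- colMeans(hp[-nrow(hp), ])
  shrunk <- t(ctr + 0.97 * (t(hp) - ctr))
  inside <- mgcv::in.out(shrunk, uv)
  expected <- 0.2 + 0.003 * uv[, 1] + 0.002 * uv[, 2]
  got <- fl[cbind(uv[, 2] + 1, uv[, 1] + 1)]
  expect_lt(max(abs(got - expected)[inside]), 1e-6)

  # collinear centroids fall back to nearest-centroid with a warning
  col_pts <- cbind(c(10, 50, 90), c(10, 50, 90))
  expect_warning(fc <- natural_neighbor_field(col_pts, c(0.1, 0.5, 0.9), img),
                 "collinear")
  expect_equal(fc[1, 1], 0.1)
})

test_that("rebinarization with f2 = 0.5 equals direct binarization", {
  ph <- generate_phantom(phantom_spec(n_fibrils = 8, width = 140L,
                                      height = 140L, cores = FALSE), seed = 6)
  sm <- gaussian_smooth(ph$image$intensity, 1)
  trend <- predict(irls_fit_quadratic(ph$image, field = sm))
  adj <- power_adjust(sm, trend)
  direct <- binarize(adj, ph$image)
  via <- rebinarize(adj, matrix(0.5, 140, 140), ph$image)
  expect_identical(via$fibrillar, direct$fibrillar)
  expect_equal(via$threshold, direct$threshold)
})

test_that("refinement is conservative on phantoms without cores", {
  ph <- generate_phantom(phantom_spec(n_fibrils = 15, width = 180L,
                                      height = 180L, cores = FALSE), seed = 8)
  det <- pipeline_detect(ph$image)
  run <- pipeline_segment(det)
  changed <- mean(det$mask_first$fibrillar != run$mask_refined$fibrillar)
  expect_lt(changed, 0.02)
  # pixelwise F1 does not degrade
  truth <- ph$truth$label_map > 0
  f1 <- function(pred) {
    tp <- sum(pred & truth)
    2 * tp / (2 * tp + sum(pred & !truth) + sum(!pred & truth))
  }
  expect_gte(f1(run$mask_refined$fibrillar) + 1e-3, f1(det$mask_first$fibrillar))
})
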