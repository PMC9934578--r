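test_that("distance field matches the brute-force all-pairs oracle", {
  # empty foreground
  m0 <- make_mask(matrix(FALSE, 8, 8))
  expect_true(all(distance_field(m0)$values == 0))

  # single fibrillar pixel surrounded by background
  m1 <- make_mask({f <- matrix(FALSE, 9, 9); f[5, 5] <- TRUE; f})
  expect_equal(distance_field(m1)$values[5, 5], 1)

  # filled disk of radius 20: maximum within 1 px of 20
  md <- make_mask(disk_mask(48, 48, 23.5, 23.5, 20))
  expect_lt(abs(max(distance_field(md)$values) - 20), 1)

  # oracle equivalence on random masks up to 64 x 64 (exact)
  for (seed in 1:4) {
    set.seed(seed)
    dims <- sample(8:64, 2)
    f <- matrix(runif(prod(dims)) < runif(1, 0.2, 0.7), dims[1], dims[2])
    if (all(f)) f[1, 1] <- FALSE
    if (!any(f)) f[2, 2] <- TRUE
    expect_equal(distance_field(make_mask(f))$values, brute_edt(f),
                 tolerance = 1e-12)
  }

  expect_error(distance_field(make_mask(matrix(TRUE, 4, 4))), "fibrillar")
})

test_that("peak counting merges plateaus and guards low peaks", {
  two <- disk_mask(60, 100, 25, 30, 9) | disk_mask(60, 100, 75, 30, 9)
  field <- distance_field(make_mask(two))
  expect_equal(count_peaks(field, 1), 2)
  # blobs merge under heavy smoothing (height guard off: the flattened field
  # drops below the default 0.5 px noise floor)
  expect_equal(count_peaks(field, 50, min_height = 0), 1)
  expect_equal(count_peaks(distance_field(make_mask(matrix(FALSE, 20, 20))), 1), 0)
})

test_that("an interior step plateau adjacent to a higher region is not a peak", {
  vals <- matrix(1, 12, 12)
  vals[, 7:12] <- 2
  vals[6, 9] <- 3
  pk <- fibrilseg:::find_peaks(vals, min_height = 0.5)
  expect_equal(nrow(pk), 1)        # only the true maximum
  expect_equal(unname(pk[1, ]), c(8, 5))
})

test_that("a symmetric plateau counts once, at its pixel centroid", {
  vals <- matrix(0, 11, 11)
  vals[5:7, 5:7] <- 2              # 3 x 3 flat top
  pk <- fibrilseg:::find_peaks(vals, min_height = 0.5)
  expect_equal(nrow(pk), 1)
  expect_equal(unname(pk[1, ]), c(5, 5))
})

test_that("bandwidth scan produces 20 points and nonincreasing phantom counts", {
  ph <- generate_phantom(phantom_spec(n_fibrils = 10, width = 160L,
                                      height = 160L, cores = FALSE), seed = 2)
  run_mask <- binarize(gaussian_smooth(ph$image$intensity, 1), ph$image)
  scan <- bandwidth_scan(distance_field(run_mask))
  expect_equal(nrow(scan$scan), 20)
  expect_equal(scan$scan$sigma, seq(0.5, 10, 0.5))
  expect_gte(scan$scan$n_peaks[1], scan$scan$n_peaks[20])
  expect_length(scan$poly, 6)
  expect_s3_class(tidy(scan), "tbl_df")
})

test_that("optimal bandwidth takes the lowest strict local minimum of (p')^2", {
  # constructed p with p'(x) = (x - x2)(x - x5)(x - x8)(x - x12) in scaled
  # coordinates, where xK is the image of sigma = K: sigma* = 2
  sc <- list(mid = 5.25, half = 4.75)
  xr <- (c(2, 5, 8, 12) - sc$mid) / sc$half
  p1 <- poly_from_roots(xr)
  p <- c(0, p1 / seq_along(p1))             # antiderivative
  scan <- structure(
    list(scan = tibble::tibble(sigma = seq(0.5, 10, 0.5),
                               n_peaks = rep(0, 20)),
         poly = p, scaling = sc, degree = 5L),
    class = "bandwidth_scan"
  )
  expect_equal(optimal_bandwidth(scan), 2, tolerance = 1e-8)

  # linear p: (p')^2 constant, no local minimum -> fallback with warning
  lin <- scan
  lin$poly <- c(0, 1, 0, 0, 0, 0)
  expect_warning(sstar <- optimal_bandwidth(lin), "no strict local minimum")
  expect_true(sstar %in% seq(0.5, 10, 0.5))

  # degenerate polynomial
  flat <- scan
  flat$poly <- c(3, 0, 0, 0, 0, 0)
  expect_warning(optimal_bandwidth(flat), "degenerate")
})

test_that("optimal bandwidth agrees with the dense-grid oracle on 100 quintics", {
  sc <- list(mid = 5.25, half = 4.75)
  set.seed(1234)
  n_checked <- 0
  for (i in 1:100) {
    roots_sigma <- sort(runif(4, 0.8, 9.7))
    xr <- (roots_sigma - sc$mid) / sc$half
    p1 <- poly_from_roots(xr, lead = sample(c(-2, -1, 1, 2), 1))
    p <- c(runif(1, -5, 5), p1 / seq_along(p1))
    scan <- structure(
      list(scan = tibble::tibble(sigma = seq(0.5, 10, 0.5),
                                 n_peaks = rep(0, 20)),
           poly = p, scaling = sc, degree = 5L),
      class = "bandwidth_scan"
    )
    oracle <- grid_sigma_star(p, sc)
    if (is.na(oracle)) next
    expect_equal(optimal_bandwidth(scan), oracle, tolerance = 1e-3)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 95)
})

test_that("centroid extraction locates disk centers", {
  one <- disk_mask(64, 64, 31, 33, 12)
  cs <- extract_centroids(distance_field(make_mask(one)), sigma_star = 2)
  expect_equal(nrow(cs), 1)
  expect_lt(sqrt((cs$u - 31)^2 + (cs$v - 33)^2), 1.5)
  expect_equal(cs$provenance, "auto")

  two <- disk_mask(70, 110, 30, 35, 10) | disk_mask(70, 110, 70, 35, 10)
  cs2 <- extract_centroids(distance_field(make_mask(two)), sigma_star = 2)
  expect_equal(nrow(cs2), 2)
  ds <- pmin(sqrt((cs2$u - 30)^2 + (cs2$v - 35)^2),
             sqrt((cs2$u - 70)^2 + (cs2$v - 35)^2))
  expect_true(all(ds < 1.5))

  expect_warning(
    empty <- extract_centroids(distance_field(make_mask(matrix(FALSE, 20, 20))), 1),
    "no peaks"
  )
  expect_equal(nrow(empty), 0)
})

test_that("centroid corrections apply remove, move, add in order with audit", {
  img <- tem_image(matrix(0.5, 50, 50), 1)
  img$excluded[41:50, 41:50] <- TRUE
  base <- fibrilseg:::new_centroid_set(
    tibble::tibble(u = seq(5, 35, length.out = 10),
                   v = seq(5, 35, length.out = 10),
                   provenance = rep("auto", 10))
  )
  expect_identical(
    correct_centroids(base, img)[, c("u", "v")], base[, c("u", "v")]
  )

  out <- correct_centroids(base, img, add = rbind(c(10, 40)), remove = 3,
                           move = list(list(1, c(20, 21))))
  expect_equal(nrow(out), 10)  # 10 - 1 + 1
  expect_equal(out$provenance[1], "user_moved")
  expect_equal(out$u[1], 20)
  expect_equal(sum(out$provenance == "user_added"), 1)
  expect_equal(nrow(attr(out, "removed")), 1)

  # move onto an excluded region rejected; other edits proceed
  out2 <- correct_centroids(base, img, move = list(list(2, c(45, 45))),
                            add = rbind(c(200, 5)))
  expect_equal(nrow(out2), 10)
  expect_equal(out2$provenance[2], "auto")
  expect_length(attr(out2, "rejected_edits"), 2)

  # bad remove index recorded, not fatal
  out3 <- correct_centroids(base, img, remove = c(99))
  expect_equal(nrow(out3), 10)
  expect_match(attr(out3, "rejected_edits"), "invalid index")
})

test_that("correction sessions round-trip through JSON", {
  d <- withr::local_tempdir()
  path <- file.path(d, "c.json")
  jsonlite::write_json(
    list(add = list(c(1, 2)), remove = list(4),
         move = list(list(2, c(7, 8)))),
    path, auto_unbox = TRUE
  )
  cor <- read_corrections(path)
  expect_equal(cor$add[[1]], c(1, 2))
  expect_equal(cor$remove, 4L)
  expect_equal(cor$move[[1]][[2]], c(7, 8))
})
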