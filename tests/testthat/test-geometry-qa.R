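test_that("the analysis grid is 1 mm isotropic and origin-aligned", {
  g <- analysis_grid(make_geometry(c(20, 20, 20), c(0.3, 1.7, -2.2), c(2, 2, 2)),
                     make_geometry(c(30, 30, 30), c(1.1, 0.4, 0), c(1.5, 1.5, 1.5)))
  expect_identical(g$spacing, c(1, 1, 1))
  expect_identical(g$origin, ceiling(c(1.1, 1.7, 0)))
  # grid stays inside both extents
  expect_true(all(g$origin + (g$dim - 1) * g$spacing <=
                    pmin(c(0.3, 1.7, -2.2) + 19 * 2, c(1.1, 0.4, 0) + 29 * 1.5)))
  expect_error(analysis_grid(make_geometry(c(8, 8, 8), c(0, 0, 0), c(1, 1, 1)),
                             make_geometry(c(8, 8, 8), c(100, 0, 0), c(1, 1, 1))),
               "extent")
})

test_that("field resampling is exact for aligned, constant and linear fields", {
  # no-op resample: already on the requested grid, bit-wise unchanged
  g1 <- make_geometry(c(12, 12, 12), c(3, 4, 5), c(1, 1, 1))
  set.seed(2)
  f1 <- vector_field(array(rnorm(12^3 * 3), c(12, 12, 12, 3)),
                     g1$origin, g1$spacing)
  expect_identical(resample_to_analysis_grid(f1, g1)$u, f1$u)

  # spatially constant field survives a 2 mm -> 1 mm resample exactly
  g2 <- make_geometry(c(10, 10, 10), c(0, 0, 0), c(2, 2, 2))
  fc <- translation_field(g2, c(1.5, -2.5, 3.5))
  rc <- resample_to_analysis_grid(fc, analysis_grid(g2))
  expect_identical(geometry(rc)$spacing, c(1, 1, 1))
  expect_true(all(rc$u[, , , 1] == 1.5 & rc$u[, , , 2] == -2.5 &
                    rc$u[, , , 3] == 3.5))

  # trilinear interpolation reproduces a componentwise-linear field
  zs <- g2$origin[3] + (seq_len(10) - 1) * 2
  u <- array(0, c(10, 10, 10, 3))
  u[, , , 3] <- rep(0.25 * zs, each = 100)
  fl <- vector_field(u, g2$origin, g2$spacing)
  rl <- resample_to_analysis_grid(fl, analysis_grid(g2))
  zn <- rl$origin[3] + (seq_len(geometry(rl)$dim[3]) - 1) * 1
  expected <- rep(0.25 * zn, each = prod(geometry(rl)$dim[1:2]))
  expect_equal(as.vector(rl$u[, , , 3]), expected, tolerance = 1e-12)
})

test_that("the magnitude-error map matches its definition and a brute-force
           oracle", {
  g <- make_geometry(c(5, 5, 5), c(0, 0, 0), c(1, 1, 1))
  set.seed(42)
  a <- vector_field(array(rnorm(5^3 * 3), c(5, 5, 5, 3)), g$origin, g$spacing)
  b <- vector_field(array(rnorm(5^3 * 3), c(5, 5, 5, 3)), g$origin, g$spacing)

  # independent per-voxel brute force
  oracle <- array(0, c(5, 5, 5))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    oracle[i, j, k] <- sqrt(sum((a$u[i, j, k, ] - b$u[i, j, k, ])^2))
  expect_equal(magnitude_error_map(a, b)$data, oracle, tolerance = 1e-12)

  # self-comparison, constant offset, zero-candidate reduction
  expect_true(all(magnitude_error_map(a, a)$data == 0))
  off <- a
  off$u[, , , 1] <- off$u[, , , 1] + 3
  off$u[, , , 2] <- off$u[, , , 2] + 4
  expect_equal(unique(as.vector(magnitude_error_map(off, a)$data)), 5)
  z <- zero_field(g)
  expect_identical(magnitude_error_map(z, a)$data, magnitude_map(a)$data)
})

test_that("the error metric is symmetric and obeys the triangle inequality", {
  g <- make_geometry(c(6, 6, 6), c(0, 0, 0), c(1, 1, 1))
  for (seed in 1:5) {
    set.seed(seed)
    fs <- lapply(1:3, function(i)
      vector_field(array(rnorm(6^3 * 3, sd = 4), c(6, 6, 6, 3)),
                   g$origin, g$spacing))
    ab <- magnitude_error_map(fs[[1]], fs[[2]])$data
    ba <- magnitude_error_map(fs[[2]], fs[[1]])$data
    expect_identical(ab, ba)
    ac <- magnitude_error_map(fs[[1]], fs[[3]])$data
    bc <- magnitude_error_map(fs[[2]], fs[[3]])$data
    expect_true(all(ac <= ab + bc + 1e-12))
  }
})

test_that("ROI error statistics match hand computations and conserve counts", {
  g <- make_geometry(c(10, 10, 10), c(0, 0, 0), c(1, 1, 1))
  err <- image_volume(array(2, g$dim), g$origin, g$spacing)
  roi <- array(FALSE, g$dim); roi[2:5, 2:5, 2:5] <- TRUE
  body <- array(TRUE, g$dim)
  masks <- list(body = body, lung = roi, spine = roi, gtv = roi,
                stomach_duodenum = roi, small_bowel = roi)
  ss <- structure_set(masks, g$origin, g$spacing)

  st <- roi_error_stats(err, ss, rois = "gtv")
  expect_equal(st$mean_mm, 2); expect_equal(st$p90_mm, 2)
  expect_equal(st$max_mm, 2); expect_equal(st$n_voxels, 64)

  # half the ROI at 0, half at 2
  e2 <- array(0, g$dim); e2[2:5, 2:5, 2:3] <- 2
  st2 <- roi_error_stats(image_volume(e2, g$origin, g$spacing), ss,
                         rois = "gtv")
  expect_equal(st2$mean_mm, 1); expect_equal(st2$max_mm, 2)

  # histogram counts sum to the ROI voxel count
  set.seed(9)
  e3 <- image_volume(array(abs(rnorm(1000)), g$dim), g$origin, g$spacing)
  st3 <- roi_error_stats(e3, ss, rois = c("gtv", "body"))
  h <- attr(st3, "histograms")
  expect_equal(sum(h$gtv$count), 64)
  expect_equal(sum(h$body$count), 1000)
  # p90 at least the median
  expect_gte(st3$p90_mm[1], median(e3$data[roi]))
})

test_that("magnitude maps behave for zero, digestive-only and combined fields", {
  ph <- small_phantom()
  geom <- geometry(ph$ct)
  expect_true(all(magnitude_map(zero_field(geom))$data == 0))
  m <- ph$structures$masks$stomach_duodenum
  dig <- digestive_shift(geom, m, 5, 5)
  mag <- magnitude_map(dig)$data
  expect_equal(unique(mag[m]), sqrt(50), tolerance = 1e-12)
  expect_true(all(mag[!m] == 0))
  resp <- respiratory_field(geom, respiratory_preset("high"), ph$structures)
  comb <- combine_fields(resp, dig)
  expect_gte(max(magnitude_map(comb)$data), max(magnitude_map(resp)$data))
})

test_that("exporting then importing the ground truth self-compares to zero", {
  ph <- small_phantom()
  geom <- geometry(ph$ct)
  m <- ph$structures$masks
  gt <- combine_fields(
    respiratory_field(geom, respiratory_preset("high"), ph$structures),
    digestive_shift(geom, m$stomach_duodenum, 5, 5),
    digestive_shift(geom, m$small_bowel, 5, 5))
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_dvf(gt, p)
  cand <- import_dvf(p)
  agrid <- analysis_grid(gt, cand)
  emap <- magnitude_error_map(resample_to_analysis_grid(cand, agrid),
                              resample_to_analysis_grid(gt, agrid))
  ss <- resample_structures(ph$structures, agrid)
  st <- roi_error_stats(emap, ss)
  expect_true(all(st$mean_mm < 1e-6))
})
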