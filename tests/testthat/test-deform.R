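test_that("respiratory presets carry the standard amplitudes", {
  expect_equal(respiratory_preset("low")$amplitude_mm, 10)
  expect_equal(respiratory_preset("medium")$amplitude_mm, 20)
  expect_equal(respiratory_preset("high")$amplitude_mm, 38)
})

test_that("respiratory field peaks at the diaphragm and spares the spine", {
  ph <- small_phantom()
  geom <- geometry(ph$ct)
  m <- ph$structures$masks
  for (preset in c("low", "high")) {
    pr <- respiratory_preset(preset)
    f <- respiratory_field(geom, pr, ph$structures)
    # SI-only component
    expect_equal(max(abs(field_component(f, "AP"))), 0)
    expect_equal(max(abs(field_component(f, "LR"))), 0)
    usi <- field_component(f, "SI")
    # peak amplitude within 1 % of the preset
    expect_lt(abs(max(abs(usi)) - pr$amplitude_mm) / pr$amplitude_mm, 0.01)
    # peak lies at the diaphragm plane (inferior lung extent)
    kz <- which(apply(m$lung, 3, any))
    peak_k <- which(abs(usi) == max(abs(usi)), arr.ind = TRUE)[1, 3]
    expect_lt(abs(peak_k - min(kz)) * geom$spacing[3], 2 * geom$spacing[3])
    # spine nearly static: mean |u| under 10 % of the peak
    mag <- magnitude_map(f)$data
    expect_lt(mean(mag[m$spine]), 0.10 * pr$amplitude_mm)
    # invertibility: all finite-difference gradients below 1
    expect_lt(dirqa:::max_field_gradient(f), 1)
  }
  # low preset, spec'd bound forms
  flow <- respiratory_field(geom, respiratory_preset("low"), ph$structures)
  expect_lt(mean(magnitude_map(flow)$data[m$spine]), 3.8)
})

test_that("zero amplitude yields the zero field and huge amplitudes fail", {
  ph <- small_phantom()
  geom <- geometry(ph$ct)
  f0 <- respiratory_field(geom, structures = ph$structures, amplitude_mm = 0)
  expect_equal(max(abs(f0$u)), 0)
  expect_error(
    respiratory_field(geom, structures = ph$structures, amplitude_mm = 80),
    "fold|gradient")
})

test_that("digestive shift is exact in-mask and exactly zero outside", {
  ph <- small_phantom()
  geom <- geometry(ph$ct)
  m <- ph$structures$masks$stomach_duodenum
  f <- digestive_shift(geom, m, shift_ap_mm = 5, shift_lr_mm = 5)
  expect_true(all(field_component(f, "AP")[m] == 5.0))
  expect_true(all(field_component(f, "LR")[m] == 5.0))
  expect_true(all(field_component(f, "SI") == 0))
  mag <- magnitude_map(f)$data
  expect_true(all(mag[!m] == 0))
  expect_equal(unique(mag[m]), sqrt(50), tolerance = 1e-12)

  fz <- digestive_shift(geom, m, 0, 0)
  expect_equal(max(abs(fz$u)), 0)
  empty <- array(FALSE, geom$dim)
  expect_warning(fe <- digestive_shift(geom, empty, 5, 5), "empty")
  expect_equal(max(abs(fe$u)), 0)
})

test_that("combining fields is additive, commutative, and matches the
           respiratory + digestive ground-truth construction", {
  ph <- small_phantom()
  geom <- geometry(ph$ct)
  m <- ph$structures$masks
  resp <- respiratory_field(geom, respiratory_preset("high"), ph$structures)
  dig <- digestive_shift(geom, m$stomach_duodenum, 5, 5)
  z <- zero_field(geom)
  expect_identical(combine_fields(resp, z)$u, resp$u)
  expect_identical(combine_fields(resp, dig)$u, combine_fields(dig, resp)$u)

  gt <- combine_fields(resp, dig, digestive_shift(geom, m$small_bowel, 5, 5))
  # at an in-stomach voxel: u = (5, 5, s) with s the respiratory SI value
  sel <- which(m$stomach_duodenum)[1]
  n <- prod(geom$dim)
  expect_equal(gt$u[sel], 5)                    # LR
  expect_equal(gt$u[sel + n], 5)                # AP
  expect_equal(gt$u[sel + 2 * n], resp$u[sel + 2 * n])  # SI
  off <- geometry(ph$ct)
  expect_error(combine_fields(resp, zero_field(
    make_geometry(off$dim, off$origin + 1, off$spacing))), "geometry")
})

test_that("field inversion is exact for translations and tight for smooth fields", {
  ph <- small_phantom()
  geom <- geometry(ph$ct)
  t_mm <- c(3, -2, 5)
  finv <- invert_dvf(translation_field(geom, t_mm))
  expect_true(all(finv$u[, , , 1] == -3))
  expect_true(all(finv$u[, , , 2] == 2))
  expect_true(all(finv$u[, , , 3] == -5))

  z <- invert_dvf(zero_field(geom))
  expect_equal(max(abs(z$u)), 0)

  f <- respiratory_field(geom, respiratory_preset("high"), ph$structures)
  inv <- invert_dvf(f, iters = 50L, tol = 0.01)
  # composition residual |u(p + v(p)) + v(p)| over the eroded body
  pts <- voxel_centers(geom)
  res <- dirqa:::sample_field(f$u, f$origin, f$spacing,
                              pts + matrix(inv$u, ncol = 3)) +
    matrix(inv$u, ncol = 3)
  rmag <- array(sqrt(rowSums(res^2)), geom$dim)
  core <- dirqa:::erode_mask(ph$structures$masks$body, 2L)
  expect_lt(max(rmag[core]), 0.1)
})

test_that("warping is exact for identity and whole-voxel translations", {
  ph <- small_phantom()
  geom <- geometry(ph$ct)
  w0 <- warp_image(ph$ct, zero_field(geom))
  expect_identical(w0$data, ph$ct$data)

  # translation by exactly one voxel along SI: interior is a bit-exact shift
  t_mm <- c(0, 0, geom$spacing[3])
  w1 <- warp_image(ph$ct, translation_field(geom, t_mm))
  d <- geom$dim
  expect_identical(w1$data[, , 2:d[3]], ph$ct$data[, , 1:(d[3] - 1)])
  expect_true(all(w1$data[, , 1] == -1000))
})

test_that("mask warping keeps the GTV volume within 15 % under the high preset", {
  ph <- small_phantom()
  geom <- geometry(ph$ct)
  f <- respiratory_field(geom, respiratory_preset("high"), ph$structures)
  gtv <- image_volume(ph$structures$masks$gtv * 1, geom$origin, geom$spacing)
  wg <- warp_image(gtv, f, mode = "mask")
  expect_true(all(wg$data %in% c(0, 1)))
  v0 <- sum(gtv$data); v1 <- sum(wg$data)
  expect_lt(abs(v1 - v0) / v0, 0.15)
})

test_that("warp then inverse-warp returns the image within twice the noise
           level over the eroded body for a smooth field", {
  ph <- small_phantom()
  geom <- geometry(ph$ct)
  f <- respiratory_field(geom, respiratory_preset("medium"), ph$structures)
  inv <- invert_dvf(f)
  fwd <- warp_image(ph$ct, f, inverse = inv)
  # undo: warp with the inverse displacement as a push-forward field
  back_field <- vector_field(inv$u, geom$origin, geom$spacing)
  back <- warp_image(fwd, back_field)
  core <- dirqa:::erode_mask(ph$structures$masks$body, 2L)
  expect_lt(mean(abs(back$data[core] - ph$ct$data[core])), 2 * 20)
})
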