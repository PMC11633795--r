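test_that("correspondence points follow the push-forward field", {
  g <- make_geometry(c(8, 8, 8), c(0, 0, 0), c(2, 2, 2))
  pts0 <- voxel_centers(g)
  expect_identical(unclass(correspondence_points(g, zero_field(g)))[, 1:3],
                   pts0)
  f <- translation_field(g, c(5, 5, 0))
  pts <- correspondence_points(g, f)
  expect_equal(pts[, 1], pts0[, 1] + 5)
  expect_equal(pts[, 2], pts0[, 2] + 5)
  expect_equal(pts[, 3], pts0[, 3])
  expect_true(any(attr(pts, "outside")))  # shifted past the lattice edge

  # forward correspondence then inverse correspondence returns to start
  ph <- small_phantom()
  geom <- geometry(ph$ct)
  smooth <- respiratory_field(geom, respiratory_preset("medium"), ph$structures)
  inv <- invert_dvf(smooth)
  fwd <- voxel_centers(geom) + matrix(smooth$u, ncol = 3)
  backdisp <- dirqa:::sample_field(inv$u, inv$origin, inv$spacing, fwd)
  res <- fwd + backdisp - voxel_centers(geom)
  core <- dirqa:::erode_mask(ph$structures$masks$body, 2L)
  # off-grid sampling of the inverse adds trilinear interpolation error on
  # top of the 0.01 mm fixed-point tolerance; 0.25 mm covers it at 4 mm voxels
  expect_lt(max(abs(res[as.vector(core), ])), 0.25)
})

test_that("dose-error maps vanish for perfect DIR and for flat dose, and
           match the linear-ramp closed form", {
  g <- make_geometry(c(12, 12, 12), c(0, 0, 0), c(2, 2, 2))
  body <- array(TRUE, g$dim)
  ph <- small_phantom()
  model <- build_dose_model(ph$structures, plan_prescription(c(4500, 7500)))

  f <- smooth_random_field(g, 4, seed = 3)
  e0 <- dose_error_map(model, f, f, body)
  expect_true(all(e0$data == 0))

  # flat dose hides any geometric error
  flat <- linear_dose_model(c(0, 0, 0), 500)
  e_flat <- dose_error_map(flat, zero_field(g),
                           digestive_shift(g, body, 5, 5), body)
  expect_true(all(e_flat$data == 0))

  # linear ramp with gradient grad, candidate offset t: error is -grad . t
  grad <- c(12, -7, 4)
  ramp <- linear_dose_model(grad, 5000)
  t_mm <- c(2, 1, -3)
  e_lin <- dose_error_map(ramp, zero_field(g), translation_field(g, t_mm), body)
  expect_equal(unique(round(as.vector(e_lin$data), 9)),
               round(-sum(grad * t_mm), 9))
})

test_that("DVH metrics match their definitions", {
  rx <- plan_prescription(c(4500, 7500))
  m1 <- dvh_metrics(rep(7500, 100), rx = rx)
  expect_equal(m1$V100, 100)
  expect_equal(m1$Dmax, 7500); expect_equal(m1$Dmin, 7500)
  expect_equal(m1$D95, 7500)

  # half the ROI at 0, half at twice the prescription
  m2 <- dvh_metrics(c(rep(0, 50), rep(15000, 50)), rx = rx)
  expect_equal(m2$V100, 50)
  expect_equal(m2$D95, 0)

  # order-statistics invariants on random fixtures
  for (seed in 1:5) {
    set.seed(seed)
    v <- runif(500, 0, 9000)
    m <- dvh_metrics(v, rx = rx)
    expect_lte(m$Dmin, m$mean); expect_lte(m$mean, m$Dmax)
    expect_lte(m$D95, m$Dmax); expect_gte(m$D95, m$Dmin)
    expect_gte(m$V100, 0); expect_lte(m$V100, 100)
  }
  expect_error(dvh_metrics(numeric(0), rx = rx), "empty")
})

test_that("the dose-error panel matches constant-field hand computations", {
  g <- make_geometry(c(12, 12, 12), c(0, 0, 0), c(2, 2, 2))
  rx <- plan_prescription(7500)
  roi <- array(TRUE, g$dim)
  zero_map <- structure(list(data = array(0, g$dim), origin = g$origin,
                             spacing = g$spacing),
                        class = c("dose_error_map", "image_volume"))
  same <- dvh_metrics(rep(4000, 10), rx = rx)
  p0 <- error_panel(zero_map, same, same, roi, rx)
  expect_true(all(p0 == 0))

  cmap <- zero_map; cmap$data[] <- 150
  pc <- error_panel(cmap, same, same, roi, rx)
  expect_equal(pc$mean_err_pct, 2)
  expect_equal(pc$max_err_pct, 2)
  expect_equal(pc$p95_err_pct, 2)
  expect_equal(pc$top1cc_err_pct, 2)

  # doubling all doses and the prescription leaves percentages unchanged
  rx2 <- plan_prescription(15000)
  c2 <- zero_map; c2$data[] <- 300
  mt2 <- dvh_metrics(rep(8000, 10), rx = rx2)
  pc2 <- error_panel(c2, mt2, mt2, roi, rx2)
  expect_equal(pc, pc2)

  # metric-level Dmax/Dmin differences are signed
  mt <- dvh_metrics(c(1000, 8000), rx = rx)
  mc <- dvh_metrics(c(1150, 7700), rx = rx)
  ps <- error_panel(zero_map, mt, mc, roi, rx)
  expect_equal(ps$Dmax_err_pct, 100 * (7700 - 8000) / 7500)
  expect_equal(ps$Dmin_err_pct, 100 * (1150 - 1000) / 7500)

  # an ROI smaller than 1 cc triggers the whole-ROI fallback with a warning
  tiny <- array(FALSE, g$dim); tiny[1:2, 1, 1] <- TRUE
  expect_warning(error_panel(cmap, same, same, tiny, rx), "1 cc")
})

test_that("dose error is bounded by the dose Lipschitz constant times the
           geometric error", {
  ph <- small_phantom()
  geom <- geometry(ph$ct)
  model <- build_dose_model(ph$structures, plan_prescription(c(4500, 7500)))
  # numerical Lipschitz constant of the dose cloud over the volume
  dvol <- evaluate_dose(model, geom)
  gr <- dirqa:::gradient3d(dvol$data, geom$spacing)
  L <- max(sqrt(gr[[1]]^2 + gr[[2]]^2 + gr[[3]]^2)) * 1.2
  truth <- respiratory_field(geom, respiratory_preset("medium"), ph$structures)
  cand <- smooth_random_field(geom, 6, seed = 5)
  e <- dose_error_map(model, truth, cand, ph$structures$masks$body)
  gerr <- magnitude_error_map(cand, truth)$data
  sel <- !is.na(e$data)
  expect_true(all(abs(e$data[sel]) <= L * gerr[sel] + 1e-6))
})

test_that("full dose QA is null for a perfect registration", {
  ph <- small_phantom()
  geom <- geometry(ph$ct)
  rx <- plan_prescription(c(4500, 7500))
  model <- build_dose_model(ph$structures, rx)
  gt <- combine_fields(
    respiratory_field(geom, respiratory_preset("high"), ph$structures),
    digestive_shift(geom, ph$structures$masks$stomach_duodenum, 5, 5))
  dq <- dose_qa(model, gt, gt, ph$structures, rx)
  num <- vapply(dq$panel[-1], function(x) max(abs(x)), numeric(1))
  expect_true(all(num < 1e-9))
  expect_true(all(abs(dq$dvh$Dmax_err_pct) < 1e-9))
  expect_true(all(abs(dq$dvh$V100_err_pct) < 1e-9))
})
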