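test_that("mtf10 matches the closed-form Gaussian oracle within 2%", {
  g <- psf_test_geometry()
  for (sigma in c(0.3, 0.5, 0.8, 1.1, 1.5)) {
    res <- mtf_from_bead(gaussian_psf_volume(sigma), origin_pose, g)
    expect_false(res$saturated)
    expect_equal(res$mtf10_lp_cm, gaussian_mtf10(sigma),
                 tolerance = 0.02, label = sprintf("sigma=%.1f", sigma))
  }
})

test_that("mtf scales inversely with PSF width and is normalized at DC", {
  g <- psf_test_geometry()
  r1 <- mtf_from_bead(gaussian_psf_volume(0.5), origin_pose, g)
  r2 <- mtf_from_bead(gaussian_psf_volume(1.0), origin_pose, g)
  expect_equal(r2$mtf10_lp_cm / r1$mtf10_lp_cm, 0.5, tolerance = 0.02)
  expect_equal(r1$curve$modulation[1], 1)
  expect_equal(r1$curve$freq_lp_cm[1], 0)
  expect_true(all(diff(r1$curve$freq_lp_cm) > 0))
})

test_that("modulation still above 0.10 at the cap reports Nyquist saturation", {
  # at 1 mm in-plane sampling the Gaussian f10 for sigma = 0.5 mm
  # (6.83 lp/cm) lies beyond the 5 lp/cm Nyquist limit
  g <- psf_test_geometry()
  vol <- gaussian_psf_volume(0.5, spacing_xy = 1)
  res <- mtf_from_bead(vol, origin_pose, g)
  expect_true(res$saturated)
  expect_equal(res$mtf10_lp_cm, 0.8 * 5, tolerance = 0.1)
})

test_that("sphere-aperture correction undoes the finite bead diameter", {
  # same blurred image attributed to a 1.5 mm bead must report a wider MTF
  # than a point bead, because part of the blur is explained by the bead
  vol <- gaussian_psf_volume(0.8)
  r_point <- mtf_from_bead(vol, origin_pose, psf_test_geometry(0.01))
  r_bead <- mtf_from_bead(vol, origin_pose, psf_test_geometry(1.5))
  expect_gt(r_bead$mtf10_lp_cm, r_point$mtf10_lp_cm)
})

test_that("geometric distortion is near zero on a true render and tracks scaling", {
  g <- small_geometry()
  v <- render_phantom(g, c(0, 0, 0), noiseless_acq())
  pose <- locate_phantom(v, g)
  expect_lt(geometric_distortion(v, pose, g), 0.25)

  # render markers scaled in-plane by 2%, analyze against nominal 16 mm
  # spacing: expect |16.32 - 16| = 0.32 mm
  g_scaled <- g
  g_scaled$modules[[2]]$markers$positions <- lapply(
    g$modules[[2]]$markers$positions,
    function(p) list(x_mm = 1.02 * p$x_mm, y_mm = 1.02 * p$y_mm,
                     z_mm = p$z_mm))
  v2 <- render_phantom(g_scaled, c(0, 0, 0), noiseless_acq())
  gd <- geometric_distortion(v2, locate_phantom(v2, g), g)
  expect_equal(as.numeric(gd), 0.32, tolerance = 0.3)
})

test_that("hu_constancy is near zero on a sharp render and shifts with a global offset", {
  g <- small_geometry()
  v <- render_phantom(g, c(0, 0, 0), sharp_acq())
  pose <- locate_phantom(v, g)
  hc <- hu_constancy(v, pose, g)
  expect_lt(as.numeric(hc), 2)
  tab <- attr(hc, "per_plug")
  expect_setequal(tab$plug_id, c("air", "ldpe", "acrylic"))

  v5 <- v
  v5$voxels <- v5$voxels + 5
  hc5 <- hu_constancy(v5, pose, g)
  expect_equal(as.numeric(hc5) - as.numeric(hc), 5, tolerance = 0.3)
})

test_that("uniformity reproduces an analytic in-plane shading ramp", {
  g <- small_geometry()
  v <- render_phantom(g, c(0, 0, 0), sharp_acq())
  pose <- locate_phantom(v, g)
  expect_lt(uniformity(v, pose, g), 0.1)

  # 5 HU per 100 mm ramp along X; peripheral ROIs sit at +/- 20 mm from the
  # module center, so the expected metric is 0.05 * 20 = 1 HU
  ramp <- v
  ramp$voxels <- ramp$voxels + 0.05 * axis_coords(v, 1)
  expect_equal(as.numeric(uniformity(ramp, pose, g)), 1.0, tolerance = 0.05)
})

test_that("noise measures the central-ROI standard deviation", {
  g <- small_geometry()
  v <- render_phantom(g, c(0, 0, 0), sharp_acq())
  pose <- locate_phantom(v, g)
  expect_equal(image_noise(v, pose, g), 0)

  # alternating +/-10 pattern has (population) sd 10
  chk <- v
  d <- dim(chk$voxels)
  parity <- (outer(outer(seq_len(d[1]), seq_len(d[2]), "+"), seq_len(d[3]),
                   "+")) %% 2
  chk$voxels <- chk$voxels + 20 * parity - 10
  expect_equal(image_noise(chk, pose, g), 10, tolerance = 0.001)

  # seeded Gaussian noise of scale 5 (small_sim) reads back within 10%
  sim <- small_sim()
  expect_equal(image_noise(sim$stationary,
                           locate_phantom(sim$stationary, g), g),
               5, tolerance = 0.1)
})

test_that("CNR follows the quadrature formula and its homogeneity", {
  g <- small_geometry()
  sim <- small_sim()  # noise sigma 5
  v <- sim$stationary
  pose <- locate_phantom(v, g)
  cnr <- cnr_low_contrast(v, pose, g)
  # polystyrene (-35) minus LDPE (-100) over sqrt(2) * 5
  expect_equal(as.numeric(cnr), 65 / sqrt(50), tolerance = 0.2)
  cnr_sum <- cnr_low_contrast(v, pose, g, denominator = "sum")
  expect_equal(cnr_sum / cnr, 1 / sqrt(2), tolerance = 0.05)

  # zero-noise degenerate case (ideal voxel-aligned plugs) flags undefined CNR
  gg <- tiny_cnr_geometry()
  vox <- array(-1000, dim = c(41, 41, 17))
  xs <- -20:20
  zs <- seq(-16, 16, by = 2)
  for (i in 1:41) for (j in 1:41) {
    r2 <- xs[i]^2 + xs[j]^2
    if (r2 <= 20^2) vox[i, j, abs(zs) <= 15] <- 100
    if ((xs[i] - 10)^2 + xs[j]^2 < 16) vox[i, j, abs(zs) < 5] <- -35
    if ((xs[i] + 10)^2 + xs[j]^2 < 16) vox[i, j, abs(zs) < 5] <- -100
  }
  ideal <- ct_volume(vox, c(1, 1, 2), c(-20, -20, -16))
  pose0 <- locate_phantom(ideal, gg)
  res <- cnr_low_contrast(ideal, pose0, gg)
  expect_true(is.infinite(res))
  expect_true(isTRUE(attr(res, "undefined")))
})

test_that("HU metrics are invariant under global offsets except hu_constancy", {
  g <- small_geometry()
  sim <- small_sim()
  v <- sim$stationary
  pose <- locate_phantom(v, g)
  v5 <- v
  v5$voxels <- v$voxels + 5
  expect_equal(uniformity(v5, pose, g), uniformity(v, pose, g),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(image_noise(v5, pose, g), image_noise(v, pose, g))
  expect_equal(as.numeric(cnr_low_contrast(v5, pose, g)),
               as.numeric(cnr_low_contrast(v, pose, g)), tolerance = 0.05)
})

test_that("noise and CNR are invariant under whole-voxel phantom translation", {
  g <- small_geometry()
  acq <- noiseless_acq()
  v0 <- render_phantom(g, c(0, 0, 0), acq)
  v1 <- render_phantom(g, c(1, 1, 2), acq)  # exactly one voxel per axis
  p0 <- locate_phantom(v0, g)
  p1 <- locate_phantom(v1, g)
  expect_equal(image_noise(v1, p1, g), image_noise(v0, p0, g),
               tolerance = 1e-6)
  expect_equal(as.numeric(cnr_low_contrast(v1, p1, g)),
               as.numeric(cnr_low_contrast(v0, p0, g)), tolerance = 1e-6)
})

test_that("low-contrast detectability finds ideal targets and fails in heavy noise", {
  g <- small_geometry()
  v <- render_phantom(g, c(0, 0, 0), noiseless_acq())
  pose <- locate_phantom(v, g)
  res <- low_contrast_detectability(v, pose, g)
  expect_equal(res$smallest_detectable_mm, 3)  # smallest configured target
  expect_true(all(res$table$detectable))

  noisy <- v
  noisy$voxels <- noisy$voxels +
    array(withr::with_seed(9, stats::rnorm(length(v$voxels), 0, 300)),
          dim = dim(v$voxels))
  res2 <- low_contrast_detectability(noisy, pose, g)
  expect_true(is.na(res2$smallest_detectable_mm))
  expect_equal(res2$largest_tested_mm, 8)
})

test_that("iq_suite aggregates all metrics and is bit-reproducible", {
  g <- small_geometry()
  sim <- small_sim()
  a <- iq_suite(sim$stationary, g)
  b <- iq_suite(sim$stationary, g)
  expect_identical(a, b)
  expect_length(a$errors, 0)
  expect_equal(a$bin_label, "stationary")
  df <- as.data.frame(a)
  expect_true(all(qa4dct:::iq_metric_names %in% names(df)))

  ser <- iq_suite_series(sim$series, g)
  expect_equal(nrow(ser$per_bin), 10)
  expect_equal(nrow(ser$summary), length(qa4dct:::iq_metric_names))

  # averaging lowers noise below the per-bin mean
  avg_iq <- iq_suite(average_ct(sim$series), g)
  mean_bin_noise <- ser$summary$mean[ser$summary$metric == "noise_hu"]
  expect_lt(avg_iq$noise_hu, mean_bin_noise)
})
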