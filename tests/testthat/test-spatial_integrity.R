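fake_measurement <- function(id, fwhm = c(12, 12, 25), centroid = c(0, 0, 0),
                             mean_hu = 990) {
  structure(list(plug_id = id, bin_label = "bin", centroid_mm = centroid,
                 fwhm_mm = fwhm, mean_hu = mean_hu, sd_hu = 1,
                 threshold_hu = 545, n_voxels = 100, boundary_flag = FALSE),
            class = "plug_measurement")
}

test_that("dimension_consistency averages bins against the stationary value", {
  stat <- fake_measurement("teflon", fwhm = c(12, 12, 25))
  bins <- lapply(c(24, 25, 26), function(z) {
    fake_measurement("teflon", fwhm = c(12, 12, z))
  })
  tab <- dimension_consistency(bins, stat)
  expect_equal(tab$delta_mm, c(0, 0, 0))
  expect_equal(tab$mean_fwhm_mm[3], 25)
  expect_equal(dim(attr(tab, "per_bin")), c(3, 3))

  same <- dimension_consistency(list(stat, stat), stat)
  expect_equal(same$delta_mm, c(0, 0, 0))

  expect_error(dimension_consistency(list(fake_measurement("air")), stat),
               class = "qa4dct_input_error")
  expect_error(dimension_consistency(list(), stat),
               class = "qa4dct_input_error")
})

test_that("motion_amplitude measures the centroid extent per axis", {
  trace <- sinusoid_trace(15, 6)
  bins <- lapply(0:9, function(k) {
    fake_measurement("teflon", centroid = c(0, 0, 7.5 * cos(2 * pi * k / 10)))
  })
  tab <- motion_amplitude(bins, trace)
  expect_equal(tab$measured_extent_mm[3], 15)
  expect_equal(tab$delta_mm[3], 0)
  expect_equal(tab$measured_extent_mm[1:2], c(0, 0))

  same <- motion_amplitude(list(fake_measurement("a"), fake_measurement("a")),
                           sinusoid_trace(0, 6))
  expect_equal(same$measured_extent_mm, c(0, 0, 0))

  expect_error(motion_amplitude(list(fake_measurement("a")), trace),
               class = "qa4dct_insufficient_bins_error")
})

test_that("average and projections are voxelwise with the documented labels", {
  mk <- function(hu, label, k) {
    ct_volume(array(hu, dim = c(4, 4, 3)), c(1, 1, 2),
              meta = list(bin_label = label, bin_index = k))
  }
  series <- phase4d_series(list(mk(0, "bin_00", 0L), mk(100, "bin_01", 1L)))
  avg <- average_ct(series)
  expect_true(all(avg$voxels == 50))
  expect_equal(avg$meta$bin_label, "average")
  expect_true(all(intensity_projection(series, "MIP")$voxels == 100))
  expect_true(all(intensity_projection(series, "MinIP")$voxels == 0))

  one <- phase4d_series(list(mk(42, "bin_00", 0L)))
  expect_true(all(intensity_projection(one, "MIP")$voxels == 42))

  # identical bins: average equals any bin
  twin <- phase4d_series(list(mk(7, "bin_00", 0L), mk(7, "bin_01", 1L)))
  expect_true(all(average_ct(twin)$voxels == 7))
})

test_that("MIP >= average CT >= MinIP voxelwise on simulated data", {
  sim <- small_sim()
  avg <- average_ct(sim$series)
  mip <- intensity_projection(sim$series, "MIP")
  minip <- intensity_projection(sim$series, "MinIP")
  expect_true(all(mip$voxels >= avg$voxels - 1e-9))
  expect_true(all(avg$voxels >= minip$voxels - 1e-9))
})

test_that("averaging 10 independent-noise bins reduces noise by about sqrt(10)", {
  sim <- small_sim()  # sigma = 5, 10 bins
  g <- small_geometry()
  avg <- average_ct(sim$series)
  pose <- locate_phantom(avg, g)
  noise_bins <- vapply(sim$series$volumes, function(v) {
    image_noise(v, locate_phantom(v, g), g)
  }, numeric(1))
  ratio <- image_noise(avg, pose, g) / mean(noise_bins)
  expect_equal(ratio, 1 / sqrt(10), tolerance = 0.15)
})

test_that("MIP widens the moving plug and the projection check uses the motion envelope", {
  sim <- small_sim()  # 10 mm p-p
  g <- small_geometry()
  trace <- sinusoid_trace(10, 6)
  pose_s <- locate_phantom(sim$stationary, g)
  stat <- measure_plug_dimensions(sim$stationary, pose_s,
                                  find_plug(g, "teflon"), g)
  mip <- intensity_projection(sim$series, "MIP")
  res <- projection_dimension_check(mip, stat, trace, find_plug(g, "teflon"),
                                    g)
  expect_equal(res$expected_z_mm, stat$fwhm_mm[3] + 10)
  expect_gt(res$measured_z_mm, stat$fwhm_mm[3] + 5)
  expect_lt(abs(res$delta_mm), 1)

  minip <- intensity_projection(sim$series, "MinIP")
  stat_air <- measure_plug_dimensions(sim$stationary, pose_s,
                                      find_plug(g, "air"), g)
  res_air <- projection_dimension_check(minip, stat_air, trace,
                                        find_plug(g, "air"), g)
  expect_lt(abs(res_air$delta_mm), 1)
})

test_that("zero-amplitude series leaves the projection at the stationary dimension", {
  g <- tiny_geometry()
  sim <- simulate_4dct(g, sinusoid_trace(0, 6), binning_spec("phase", 3, 1),
                       noiseless_acq(seed = 4))
  pose <- locate_phantom(sim$stationary, g)
  stat <- measure_plug_dimensions(sim$stationary, pose,
                                  find_plug(g, "teflon"), g)
  mip <- intensity_projection(sim$series, "MIP")
  res <- projection_dimension_check(mip, stat, sinusoid_trace(0, 6),
                                    find_plug(g, "teflon"), g)
  expect_equal(res$expected_z_mm, stat$fwhm_mm[3])
  expect_lt(abs(res$delta_mm), 0.2)
})
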