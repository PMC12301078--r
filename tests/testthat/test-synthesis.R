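test_that("phase-mode bins of a sinusoid hit the trace extremes at bin starts", {
  trace <- sinusoid_trace(15, 6)
  bins <- sample_trace_bins(trace, binning_spec("phase", 10, 1))
  expect_length(bins, 10)
  dz <- vapply(bins, function(b) b[1, "dz"], numeric(1))
  expect_equal(dz[1], 7.5)
  expect_equal(dz[6], -7.5)
  expect_equal(max(dz) - min(dz), 15)
  # motion is along Z only
  expect_true(all(vapply(bins, function(b) all(b[, c("dx", "dy")] == 0),
                         logical(1))))
})

test_that("amplitude-mode bins split the displacement range into equal intervals", {
  trace <- sinusoid_trace(15, 6)
  bins <- sample_trace_bins(trace, binning_spec("amplitude", 10, 3))
  expect_length(bins, 10)
  # each bin's dz values stay within its 1.5 mm interval
  for (k in seq_len(10)) {
    lo <- -7.5 + (k - 1) * 1.5
    expect_true(all(bins[[k]][, "dz"] >= lo - 1e-9 &
                      bins[[k]][, "dz"] <= lo + 1.5 + 1e-9))
  }
  expect_error(sample_trace_bins(sinusoid_trace(0, 6),
                                 binning_spec("amplitude", 10, 1)),
               class = "qa4dct_degenerate_trace_error")
})

test_that("a constant trace produces identical phase bins", {
  bins <- sample_trace_bins(sinusoid_trace(0, 6), binning_spec("phase", 5, 2))
  for (b in bins) expect_equal(unname(b), matrix(0, 2, 3))
})

test_that("sampled traces bin by phase and amplitude", {
  trace <- patient_like_trace()
  expect_equal(trace$period_s, 4.2)
  p2p <- trace_peak_to_peak(trace)
  expect_gt(p2p[3], p2p[1])  # Z is the principal axis
  for (mode in c("phase", "amplitude")) {
    bins <- sample_trace_bins(trace, binning_spec(mode, 10, 3))
    expect_length(bins, 10)
    expect_true(all(vapply(bins, nrow, integer(1)) == 3))
  }
})

test_that("rendered plug interiors carry the nominal HU and edges show partial volume", {
  g <- tiny_geometry()
  acq1 <- sharp_acq(supersampling = 1)
  acq8 <- sharp_acq(supersampling = 8)
  v1 <- render_phantom(g, c(0, 0, 0), acq1)
  v8 <- render_phantom(g, c(0, 0, 0), acq8)
  # voxel at the teflon plug center (plug at x=10, y=0, z=0)
  ix <- which.min(abs(axis_coords(v8, 1) - 10))
  iy <- which.min(abs(axis_coords(v8, 2) - 0))
  iz <- which.min(abs(axis_coords(v8, 3) - 0))
  expect_equal(v8$voxels[ix, iy, iz], 990)
  expect_equal(v1$voxels[ix, iy, iz], 990)
  # partial volume only affects boundaries: interiors agree across
  # supersampling, some rim voxel differs
  expect_false(isTRUE(all.equal(v1$voxels, v8$voxels)))
  interior <- v8$voxels[(ix - 1):(ix + 1), (iy - 1):(iy + 1), iz]
  expect_true(all(interior == 990))
})

test_that("rendering at a displacement shifts the plug centroid accordingly", {
  g <- tiny_geometry()
  acq <- noiseless_acq()
  v0 <- render_phantom(g, c(0, 0, 0), acq)
  v5 <- render_phantom(g, c(0, 0, 5), acq)
  p <- find_plug(g, "teflon")
  m0 <- detect_plug(v0, list(center_mm = c(0, 0, 0), rotation_deg = 0), p, g)
  m5 <- detect_plug(v5, list(center_mm = c(0, 0, 5), rotation_deg = 0), p, g)
  shift <- m5$centroid_mm - m0$centroid_mm
  expect_equal(shift[3], 5, tolerance = 0.5)  # within half a voxel (abs)
  expect_lt(max(abs(shift[1:2])), 0.5)
  expect_error(render_phantom(g, c(0, 0, 500), acq),
               class = "qa4dct_geometry_error")
})

test_that("simulation is bit-reproducible for a fixed seed", {
  g <- tiny_geometry()
  args <- list(g, sinusoid_trace(8, 6), binning_spec("phase", 4, 2),
               acquisition_spec(noise_sigma_hu = 10, seed = 7))
  s1 <- do.call(simulate_4dct, args)
  s2 <- do.call(simulate_4dct, args)
  expect_identical(s1$stationary$voxels, s2$stationary$voxels)
  for (k in seq_len(4)) {
    expect_identical(s1$series$volumes[[k]]$voxels,
                     s2$series$volumes[[k]]$voxels)
  }
  # different seed changes the noise
  s3 <- simulate_4dct(g, sinusoid_trace(8, 6), binning_spec("phase", 4, 2),
                      acquisition_spec(noise_sigma_hu = 10, seed = 8))
  expect_false(identical(s1$stationary$voxels, s3$stationary$voxels))
})

test_that("seeded additive noise has the configured scale", {
  sim <- small_sim()  # noise_sigma_hu = 5
  g <- small_geometry()
  pose <- locate_phantom(sim$stationary, g)
  expect_equal(image_noise(sim$stationary, pose, g), 5, tolerance = 0.1)
})

test_that("ground truth records the achievable peak-to-peak amplitude", {
  g <- tiny_geometry()
  sim <- simulate_4dct(g, sinusoid_trace(8, 6), binning_spec("phase", 10, 1),
                       sharp_acq(seed = 3))
  expect_equal(sim$ground_truth$achievable_p2p_mm[[3]], 8)
  expect_equal(sim$ground_truth$trace_p2p_mm[3], 8)
  expect_equal(nrow(sim$ground_truth$bin_displacements), 10)
  # with bins anchored at the extremes the per-bin displacements span p2p
  dz <- sim$ground_truth$bin_displacements[, 3]
  expect_equal(max(dz) - min(dz), 8)
})

test_that("intra-bin averaging never narrows the plug extent along the motion axis", {
  sim <- small_sim()
  g <- small_geometry()
  pose_s <- locate_phantom(sim$stationary, g)
  p <- find_plug(g, "teflon")
  stat_z <- measure_plug_dimensions(sim$stationary, pose_s, p, g)$fwhm_mm[3]
  for (v in sim$series$volumes[c(1, 3, 6)]) {
    m <- measure_plug_dimensions(v, locate_phantom(v, g), p, g)
    expect_gte(m$fwhm_mm[3], stat_z - 0.35)  # never below stationary minus
    # one z-interpolation quantum
  }
})
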