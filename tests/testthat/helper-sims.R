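# Memoised simulations shared across test files so each configuration is
# simulated and measured once per test run.

.sim_memo <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.sim_memo[[key]])) .sim_memo[[key]] <- force(expr)
  .sim_memo[[key]]
}

# Small-geometry simulation used by unit tests. Slice thickness is scaled
# down with the phantom so plugs span a similar number of slices as the
# full-size phantom does at 2 mm.
small_sim <- function() {
  memo("small_sim", {
    simulate_4dct(small_geometry(), sinusoid_trace(10, 6),
                  binning_spec("phase", 10, 2),
                  acquisition_spec(voxel_spacing_mm = c(1, 1, 1),
                                   noise_sigma_hu = 5, seed = 11))
  })
}

# Measure everything the acceptance criteria need from one simulation, then
# drop the volumes (memory). Full builtin geometry, default acquisition.
measure_sim <- function(sim, geom, trace, oracle = FALSE) {
  pose_s <- locate_phantom(sim$stationary, geom)
  surr <- find_plug(geom, role = "motion_surrogate")
  sens_ids <- vapply(qa4dct:::geometry_module(geom, "sensitometry")$plugs,
                     `[[`, "", "id")
  stat_dims <- lapply(surr, function(p) {
    measure_plug_dimensions(sim$stationary, pose_s, p, geom)
  })
  names(stat_dims) <- vapply(surr, `[[`, "", "id")
  stat_hu <- lapply(sens_ids, function(id) {
    detect_plug(sim$stationary, pose_s, find_plug(geom, id), geom)
  })
  names(stat_hu) <- sens_ids
  bin_dims <- lapply(stat_dims, function(x) list())
  bin_hu <- lapply(stat_hu, function(x) list())
  oracle_rows <- list()
  for (v in sim$series$volumes) {
    pose_k <- locate_phantom(v, geom)
    for (p in surr) {
      m <- measure_plug_dimensions(v, pose_k, p, geom)
      bin_dims[[p$id]] <- c(bin_dims[[p$id]], list(m))
      if (oracle) {
        o <- contour_plug_measure(v, pose_k, p, geom)
        oracle_rows <- c(oracle_rows, list(list(plug = p$id, meas = m,
                                                oracle = o)))
      }
    }
    for (id in sens_ids) {
      bin_hu[[id]] <- c(bin_hu[[id]],
                        list(detect_plug(v, pose_k, find_plug(geom, id),
                                         geom)))
    }
  }
  if (oracle) {
    for (p in surr) {
      m <- stat_dims[[p$id]]
      o <- contour_plug_measure(sim$stationary, pose_s, p, geom)
      oracle_rows <- c(oracle_rows, list(list(plug = p$id, meas = m,
                                              oracle = o)))
    }
  }
  dim_tabs <- lapply(names(stat_dims), function(id) {
    dimension_consistency(bin_dims[[id]], stat_dims[[id]])
  })
  names(dim_tabs) <- names(stat_dims)
  amp_tabs <- lapply(names(bin_dims), function(id) {
    motion_amplitude(bin_dims[[id]], trace)
  })
  names(amp_tabs) <- names(bin_dims)
  mip <- intensity_projection(sim$series, "MIP")
  minip <- intensity_projection(sim$series, "MinIP")
  proj <- rbind(
    projection_dimension_check(mip, stat_dims$teflon, trace,
                               find_plug(geom, "teflon"), geom),
    projection_dimension_check(minip, stat_dims$air, trace,
                               find_plug(geom, "air"), geom)
  )
  list(dim = dim_tabs, amp = amp_tabs, proj = proj,
       hu = hu_consistency(bin_hu, stat_hu),
       stat_dims = stat_dims, oracle = oracle_rows,
       ground_truth = sim$ground_truth)
}

# One noisy full-size simulation of the standard QA conditions:
# 15 mm peak-to-peak sinusoid, 10 phase bins, default blur/noise.
qa_sim_measured <- function(period_s, seed, model = 504, oracle = FALSE) {
  key <- sprintf("qa_%d_%d_%d_%d", period_s, seed, model, oracle)
  memo(key, {
    geom <- builtin_geometry(model)
    trace <- sinusoid_trace(15, period_s)
    sim <- simulate_4dct(geom, trace, binning_spec("phase", 10, 3),
                         acquisition_spec(seed = seed))
    out <- measure_sim(sim, geom, trace, oracle = oracle)
    rm(sim)
    gc(verbose = FALSE)
    out
  })
}

# Binning-mode comparison at full size for a given trace.
binning_mode_measured <- function(trace_kind, mode, seed = 5) {
  key <- sprintf("bm_%s_%s_%d", trace_kind, mode, seed)
  memo(key, {
    geom <- builtin_geometry(504)
    trace <- if (trace_kind == "patient") {
      patient_like_trace()
    } else {
      sinusoid_trace(15, 6)
    }
    sim <- simulate_4dct(geom, trace, binning_spec(mode, 10, 3),
                         acquisition_spec(seed = seed))
    out <- measure_sim(sim, geom, trace)
    rm(sim)
    gc(verbose = FALSE)
    out
  })
}
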