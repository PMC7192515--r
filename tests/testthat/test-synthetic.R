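test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_foci_total = 10, n_foci_axis_touching = 11),
               "n_foci_axis_touching")
  expect_error(simulation_config(nucleus_radius = 20), "does not contain")
  expect_error(simulation_config(background_level = 40000,
                                 focus_amplitude_range = c(20000, 30000)),
               "clip")
  expect_error(simulation_config(
    offaxis_distance_distribution = list(name = "cauchy")), "unknown")
})

test_that("zero tortuosity yields straight exact-length paths", {
  cfg <- simulation_config(grid_shape = c(128, 128, 128),
                           voxel_spacing = c(0.2, 0.2, 0.2),
                           nucleus_radius = 12, nucleolus_radius = 1,
                           nucleolus_center = c(0, 5, 0), n_axes = 1,
                           axis_total_length = 20, tortuosity = 0,
                           n_foci_total = 0, n_foci_axis_touching = 0,
                           seed = 2)
  set.seed(2)
  paths <- sample_axis_paths(cfg)
  expect_length(paths, 1)
  expect_equal(paths[[1]]$length, 20, tolerance = 1e-6)
  expect_lte(attr(fit_kappa(paths[[1]]$points, 7), "average_kappa"), 1.01e-6)
  # a straight axis longer than the nucleus diameter cannot fit
  cfg2 <- simulation_config(grid_shape = c(40, 96, 96),
                            voxel_spacing = c(0.2, 0.2, 0.2),
                            nucleus_radius = 3.5, nucleolus_radius = 0.5,
                            nucleolus_center = c(0, 1.5, 0), n_axes = 1,
                            axis_total_length = 20, tortuosity = 0,
                            n_foci_total = 0, n_foci_axis_touching = 0)
  set.seed(2)
  expect_error(sample_axis_paths(cfg2), "infeasible geometry")
})

test_that("total path length meets the 1% contract", {
  cfg <- simulation_config(n_axes = 2, axis_total_length = 60,
                           n_foci_total = 0, n_foci_axis_touching = 0,
                           seed = 4)
  set.seed(4)
  paths <- sample_axis_paths(cfg)
  total <- sum(vapply(paths, function(p) p$length, 0))
  expect_gte(total, 59.4)
  expect_lte(total, 60.6)
  # all points inside the nucleus sphere, outside the nucleolus
  ctr <- cfg$grid_shape * cfg$voxel_spacing / 2
  for (p in paths) {
    r <- sqrt(rowSums(sweep(p$points, 2, ctr)^2))
    expect_true(all(r <= cfg$nucleus_radius))
    rn <- sqrt(rowSums(sweep(p$points, 2, ctr + cfg$nucleolus_center)^2))
    expect_true(all(rn >= cfg$nucleolus_radius - 1e-9))
  }
})

test_that("path curvature increases with tortuosity", {
  mean_kappa <- function(tort) {
    cfg <- simulation_config(n_axes = 20, axis_total_length = 120,
                             tortuosity = tort, n_foci_total = 0,
                             n_foci_axis_touching = 0, seed = 9)
    set.seed(9)
    paths <- sample_axis_paths(cfg)
    mean(vapply(paths, function(p)
      attr(fit_kappa(p$points, 7), "average_kappa"), 0))
  }
  ks <- vapply(c(0, 0.5, 1, 2), mean_kappa, 0)
  expect_true(all(diff(ks) > 0))
  expect_gt(ks[4], ks[2])   # tortuosity 2 vs 0.5 clearly separated
})

test_that("focus placement respects counts and target distances", {
  cfg <- simulation_config(n_axes = 2, axis_total_length = 30,
                           tortuosity = 0.3, n_foci_total = 100,
                           n_foci_axis_touching = 30, seed = 6)
  set.seed(6)
  paths <- sample_axis_paths(cfg)
  foci <- place_foci(cfg, paths)
  expect_equal(nrow(foci), 100)
  expect_equal(sum(foci$is_axis_touching), 30)
  expect_true(all(foci$true_min_distance_um[foci$is_axis_touching] <=
                    cfg$axis_tube_sigma))
  expect_error(place_foci(cfg, list()), "no axis paths")

  # point-mass off-axis distribution lands within the rejection tolerance
  cfgp <- simulation_config(n_axes = 2, axis_total_length = 30,
                            tortuosity = 0.3, n_foci_total = 60,
                            n_foci_axis_touching = 0,
                            offaxis_distance_distribution =
                              list(name = "point", at = 1.0), seed = 6)
  set.seed(6)
  focp <- place_foci(cfgp, paths)
  expect_true(all(abs(focp$true_min_distance_um - 1.0) <= 0.05))
})

test_that("uniform off-axis distances reproduce the analytic CDF", {
  # an axis placed by hand through open nucleus volume, so rejection
  # plays no role and the realized distances follow the drawn CDF
  cfg <- simulation_config(n_foci_total = 2000, n_foci_axis_touching = 0,
                           offaxis_distance_distribution =
                             list(name = "uniform", min = 0, max = 1.2),
                           seed = 8)
  ctr <- cfg$grid_shape * cfg$voxel_spacing / 2
  xs <- seq(ctr[3] - 2, ctr[3] + 2, by = 0.1)
  pts <- cbind(ctr[1], ctr[2] - 2, xs)
  paths <- list(structure(list(path_id = 1L, points = pts,
                               length = axofoci:::polyline_length(pts)),
                          class = "axis_path"))
  set.seed(8)
  foci <- place_foci(cfg, paths)
  expect_lt(abs(mean(foci$true_min_distance_um <= 0.6) - 0.5), 0.05)
})

test_that("generator truth distances match an independent oracle", {
  nuc <- small_nucleus()
  tf <- nuc$truth$foci
  pick <- round(seq(1, nrow(tf), length.out = 15))
  pts <- as.matrix(tf[pick, c("z_um", "y_um", "x_um")])
  oracle <- r_min_dist_to_paths(pts, lapply(nuc$truth$axes,
                                            function(p) p$points))
  expect_true(all(abs(oracle - tf$true_min_distance_um[pick]) <= 0.02))
})

test_that("rendering is deterministic and respects the background model", {
  nuc1 <- small_nucleus()
  cfg <- nuc1$config
  nuc2 <- simulate_nucleus(cfg)
  expect_identical(nuc1$channels$focus$data, nuc2$channels$focus$data)
  expect_identical(nuc1$channels$axis$data, nuc2$channels$axis$data)

  # no foci: focus channel is the background model alone
  cfg0 <- simulation_config(grid_shape = c(16, 64, 64), nucleus_radius = 0.9,
                            nucleolus_radius = 0.25,
                            nucleolus_center = c(0, 0.4, 0), n_axes = 1,
                            axis_total_length = 4, n_foci_total = 0,
                            n_foci_axis_touching = 0, seed = 12)
  nuc0 <- simulate_nucleus(cfg0)
  expect_lt(abs(mean(nuc0$channels$focus$data) - cfg0$background_level), 2)

  # pre-noise render: the focus amplitude adds to the background
  cfg1 <- simulation_config(grid_shape = c(16, 64, 64), nucleus_radius = 0.9,
                            nucleolus_radius = 0.25,
                            nucleolus_center = c(0, 0.4, 0), n_axes = 1,
                            axis_total_length = 4, n_foci_total = 1,
                            n_foci_axis_touching = 1,
                            focus_amplitude_range = c(10000, 10000),
                            focus_sigma = 0.1,
                            background_sd = 0, photon_scale = 0, seed = 13)
  nuc1f <- simulate_nucleus(cfg1)
  f <- nuc1f$truth$foci
  sp <- cfg1$voxel_spacing
  at <- nuc1f$channels$focus$data[round(f$z_um / sp[1] + 0.5),
                                  round(f$y_um / sp[2] + 0.5),
                                  round(f$x_um / sp[3] + 0.5)]
  expect_gte(at, 12000)
})

test_that("the camera model measures clipping against the 16-bit range", {
  cam_cfg <- list(background_level = 100, background_sd = 0,
                  photon_scale = 0, voxel_spacing = c(0.1, 0.1, 0.1))
  cam <- axofoci:::apply_camera(array(70000, c(4, 8, 8)), cam_cfg)
  expect_equal(cam$clipped_fraction, 1)
  expect_true(all(cam$img <= 65535))
  cam2 <- axofoci:::apply_camera(array(1000, c(4, 8, 8)), cam_cfg)
  expect_equal(cam2$clipped_fraction, 0)
})
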