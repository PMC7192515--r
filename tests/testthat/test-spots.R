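test_that("auto threshold lands above the unimodal background peak", {
  set.seed(1)
  img <- vol_img(array(pmin(pmax(round(rnorm(24 * 48 * 48, 3200, 150)), 0),
                            65535), c(24, 48, 48)), c(0.125, 0.04, 0.04))
  thr <- select_threshold(img)                   # default k = 3
  expect_gte(thr, 3000)
  expect_lte(thr, 4000)
  expect_equal(select_threshold(img, threshold = 3500), 3500)
  # k = 0 returns the histogram mode
  half <- array(3000, c(8, 8, 8)); half[1:3, , ] <- 2000
  img2 <- vol_img(half, c(0.1, 0.1, 0.1))
  expect_equal(select_threshold(img2, k = 0), 3000)
  expect_error(select_threshold(vol_img(array(5, c(4, 4, 4)),
                                        c(0.1, 0.1, 0.1))),
               "degenerate histogram")
})

test_that("rolling-ball subtraction matches a brute-force opening oracle", {
  # constant image maps to zero
  cimg <- vol_img(array(700, c(3, 30, 30)), c(0.1, 0.1, 0.1))
  expect_true(all(subtract_background(cimg, 5)$data == 0))

  # single Gaussian spot on an offset
  d <- c(1, 41, 41)
  yy <- matrix(rep(1:41, 41), 41, 41)
  xx <- t(yy)
  A <- 1000
  sl <- 500 + A * exp(-((yy - 21)^2 + (xx - 21)^2) / (2 * 2^2))
  img <- vol_img(array(sl, d), c(0.1, 0.1, 0.1))
  out <- subtract_background(img, 10)
  # oracle: independent nonflat erosion/dilation in plain R
  el <- axofoci:::ball_element(10)
  erode <- matrix(NA_real_, 41, 41)
  for (y in 1:41) for (x in 1:41) {
    v <- Inf
    for (k in seq_len(nrow(el$offs))) {
      y2 <- y + el$offs[k, 1]; x2 <- x + el$offs[k, 2]
      if (y2 < 1 || y2 > 41 || x2 < 1 || x2 > 41) next
      v <- min(v, sl[y2, x2] - el$h[k])
    }
    erode[y, x] <- v
  }
  open <- matrix(NA_real_, 41, 41)
  for (y in 1:41) for (x in 1:41) {
    v <- -Inf
    for (k in seq_len(nrow(el$offs))) {
      y2 <- y + el$offs[k, 1]; x2 <- x + el$offs[k, 2]
      if (y2 < 1 || y2 > 41 || x2 < 1 || x2 > 41) next
      v <- max(v, erode[y2, x2] + el$h[k])
    }
    open[y, x] <- v
  }
  oracle <- pmax(sl - open, 0)
  expect_equal(out$data[1, , ], oracle, tolerance = 1e-9)
  expect_gte(out$data[1, 21, 21], 0.9 * A)
  expect_lte(max(out$data[1, 1:5, 1:5]), 2)

  # never negative on random input
  set.seed(2)
  rnd <- vol_img(array(runif(3 * 25 * 25, 0, 5000), c(3, 25, 25)),
                 c(0.1, 0.1, 0.1))
  expect_true(all(subtract_background(rnd, 6)$data >= 0))
})

test_that("3D median filter removes impulses and preserves plateaus", {
  cimg <- vol_img(array(42, c(6, 6, 6)), c(0.1, 0.1, 0.1))
  expect_equal(median_filter_3d(cimg, 1)$data, cimg$data)
  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 1000
  out <- median_filter_3d(vol_img(imp, c(0.1, 0.1, 0.1)), 1)
  expect_equal(out$data[5, 5, 5], 0)
  plat <- array(0, c(11, 11, 11)); plat[4:8, 4:8, 4:8] <- 77
  outp <- median_filter_3d(vol_img(plat, c(0.1, 0.1, 0.1)), 1)
  expect_true(all(outp$data[5:7, 5:7, 5:7] == 77))
})

test_that("seed detection finds separated maxima with plateau tie-breaks", {
  d <- c(5, 31, 31)
  arr <- array(0, d)
  for (y in 1:31) for (x in 1:31) {
    arr[3, y, x] <- 100 * exp(-((y - 10)^2 + (x - 10)^2) / 4) +
                    100 * exp(-((y - 10)^2 + (x - 20)^2) / 4)
  }
  img <- vol_img(arr, c(0.1, 0.1, 0.1))
  seeds <- detect_seeds(img, 50)
  expect_equal(nrow(seeds), 2)
  expect_setequal(seeds$x, c(10, 20))
  expect_equal(nrow(detect_seeds(img, max(arr) + 1)), 0)

  plat <- array(0, c(4, 8, 8)); plat[2, 3, 4] <- 10; plat[2, 3, 5] <- 10
  sp <- detect_seeds(vol_img(plat, c(0.1, 0.1, 0.1)), 5)
  expect_equal(nrow(sp), 1)
  expect_equal(unlist(sp[1, c("z", "y", "x")], use.names = FALSE),
               c(2, 3, 4))
})

test_that("seed count is non-increasing in the threshold", {
  set.seed(7)
  arr <- axofoci:::gaussian_smooth3d(array(rnorm(16 * 32 * 32), c(16, 32, 32)),
                                     c(0.1, 0.1, 0.1), 0.15)
  img <- vol_img(array(arr - min(arr), dim(arr)), c(0.1, 0.1, 0.1))
  thrs <- quantile(img$data, c(0.5, 0.7, 0.9, 0.97, 0.999))
  counts <- vapply(thrs, function(t) nrow(detect_seeds(img, t)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("seeded growth respects volume bounds and claim priority", {
  d <- c(5, 21, 41)
  arr <- array(0, d)
  for (y in 1:21) for (x in 1:41)
    arr[3, y, x] <- 1000 * exp(-((y - 11)^2 + (x - 15)^2) / 6)
  img <- vol_img(arr, c(0.1, 0.1, 0.1))
  seeds <- detect_seeds(img, 100)
  labs <- segment_spots(img, seeds, spot_params(min_volume = 4))
  expect_equal(labs$n_objects, 1)
  expect_gt(labs$labels[3, 11, 15], 0)

  # a 2-voxel speckle is removed by the volume filter
  spk <- array(0, c(5, 9, 9)); spk[3, 4, 4] <- 500; spk[3, 4, 5] <- 400
  imgs <- vol_img(spk, c(0.1, 0.1, 0.1))
  labs2 <- segment_spots(imgs, detect_seeds(imgs, 100),
                         spot_params(min_volume = 5))
  expect_equal(labs2$n_objects, 0)
  expect_equal(segment_spots(imgs, detect_seeds(imgs, 1e6),
                             spot_params())$n_objects, 0)

  # two equal spots whose basins meet at the growth cutoff: contested
  # voxels (here the whole bridged region) go to the lower-index seed
  arr2 <- array(0, d)
  for (y in 1:21) for (x in 1:41)
    arr2[3, y, x] <- 1000 * (exp(-((y - 11)^2 + (x - 12)^2) / 50) +
                             exp(-((y - 11)^2 + (x - 28)^2) / 50))
  img2 <- vol_img(arr2, c(0.1, 0.1, 0.1))
  seeds2 <- detect_seeds(img2, 100)
  expect_equal(nrow(seeds2), 2)
  labs3 <- segment_spots(img2, seeds2,
                         spot_params(local_contrast_fraction = 0.1,
                                     max_volume = 5000))
  first <- which.min(seeds2$x)   # equal peaks: lower index claims first
  lab_first <- labs3$labels[seeds2$z[first], seeds2$y[first],
                            seeds2$x[first]]
  expect_equal(labs3$labels[3, 11, 20], lab_first)
  # with a cutoff above the valley the basins separate into two objects
  labs4 <- segment_spots(img2, seeds2,
                         spot_params(local_contrast_fraction = 0.7,
                                     max_volume = 5000))
  expect_equal(labs4$n_objects, 2)
})

test_that("object measurements are exact on a known cube", {
  d <- c(12, 12, 12)
  lab <- array(0L, d); lab[4:6, 5:7, 6:8] <- 1L
  img <- array(100, d); img[4:6, 5:7, 6:8] <- 200
  m <- measure_objects(label_vol(lab, c(0.1, 0.1, 0.1)),
                       vol_img(img, c(0.1, 0.1, 0.1)))
  expect_equal(unname(m$Vol_voxels), 27L)
  expect_equal(m$Vol_um3, 0.027, ignore_attr = TRUE)
  expect_equal(m$CZ, (5 - 0.5) * 0.1, ignore_attr = TRUE)
  expect_equal(m$CY, (6 - 0.5) * 0.1, ignore_attr = TRUE)
  expect_equal(m$CX, (7 - 0.5) * 0.1, ignore_attr = TRUE)
  expect_equal(m$Mean, 200, ignore_attr = TRUE)
  expect_equal(m$IntDen, 200 * 27, ignore_attr = TRUE)
  expect_true(m$DC_min <= m$DC_max)
})

test_that("IntDen equals Mean times voxel count for arbitrary objects", {
  nuc <- small_nucleus()
  res <- segment_spot_channel(nuc$channels$focus)
  m <- res$objects
  expect_true(all(abs(m$IntDen - m$Mean * m$Vol_voxels) < 1e-6))
  expect_true(all(m$Min <= m$Mean + 1e-9))
  expect_true(all(m$Comp > 0 & m$Comp <= 1))
})

test_that("sphericity separates balls from plates", {
  ball <- make_ball_mask(6)
  d <- dim(ball)
  lab <- array(0L, d); lab[ball] <- 1L
  img <- vol_img(array(1, d), c(0.1, 0.1, 0.1))
  mb <- measure_objects(label_vol(lab, c(0.1, 0.1, 0.1)), img)
  expect_gte(mb$Comp, 0.9)
  # same-volume one-voxel-thick plate
  n <- mb$Vol_voxels
  side <- ceiling(sqrt(n))
  d2 <- c(5, side + 4, side + 4)
  lab2 <- array(0L, d2)
  filled <- 0
  for (y in 3:(side + 2)) for (x in 3:(side + 2)) {
    if (filled < n) { lab2[3, y, x] <- 1L; filled <- filled + 1 }
  }
  mp <- measure_objects(label_vol(lab2, c(0.1, 0.1, 0.1)),
                        vol_img(array(1, d2), c(0.1, 0.1, 0.1)))
  expect_lt(mp$Comp, 0.5)
})

test_that("noise-free separable spots are recovered exactly", {
  cfg <- simulation_config(grid_shape = c(32, 128, 128), nucleus_radius = 1.9,
                           nucleolus_radius = 0.3,
                           nucleolus_center = c(0, 0.8, 0), n_axes = 1,
                           axis_total_length = 6, n_foci_total = 0,
                           n_foci_axis_touching = 0, background_sd = 0,
                           photon_scale = 0, seed = 15)
  # lattice of foci with known sub-voxel offsets, >= 5 px separation
  centers <- expand.grid(z = c(1.2, 2.4), y = seq(1.0, 4.2, by = 0.45),
                         x = seq(1.0, 4.2, by = 0.45))
  set.seed(15)
  foci <- tibble::tibble(
    focus_id = seq_len(nrow(centers)),
    z_um = centers$z + runif(nrow(centers), -0.05, 0.05),
    y_um = centers$y + runif(nrow(centers), -0.015, 0.015),
    x_um = centers$x + runif(nrow(centers), -0.015, 0.015),
    amplitude = runif(nrow(centers), 12000, 28000),
    true_min_distance_um = Inf, is_axis_touching = FALSE)
  nuc <- render_nucleus(cfg, list(), foci)
  res <- segment_spot_channel(nuc$channels$focus)
  expect_equal(nrow(res$objects), nrow(foci))
  # match each truth focus to the nearest centroid; <= 0.5 voxel per axis
  for (i in seq_len(nrow(foci))) {
    dzv <- abs(res$objects$CZ - foci$z_um[i]) / 0.125
    dyv <- abs(res$objects$CY - foci$y_um[i]) / 0.04
    dxv <- abs(res$objects$CX - foci$x_um[i]) / 0.04
    j <- which.min(dzv^2 + dyv^2 + dxv^2)
    expect_lte(dzv[j], 0.5); expect_lte(dyv[j], 0.5); expect_lte(dxv[j], 0.5)
  }
})

test_that("focus counts are recovered within 10% at resolvable density", {
  run_uniform <- function(n, side) {
    cfg <- simulation_config(grid_shape = c(64, side, side),
                             nucleus_radius = 3.9, n_foci_total = 0,
                             n_foci_axis_touching = 0, n_axes = 1,
                             axis_total_length = 5, seed = 30 + n %% 97)
    set.seed(cfg$seed)
    ext <- side * 0.04 - 0.4
    foci <- tibble::tibble(
      focus_id = seq_len(n),
      z_um = runif(n, 0.4, 7.6), y_um = runif(n, 0.4, ext),
      x_um = runif(n, 0.4, ext),
      amplitude = runif(n, cfg$focus_amplitude_range[1],
                        cfg$focus_amplitude_range[2]),
      true_min_distance_um = Inf, is_axis_touching = FALSE)
    nuc <- render_nucleus(cfg, list(), foci)
    nrow(segment_spot_channel(nuc$channels$focus)$objects)
  }
  n1 <- run_uniform(600, 320)
  expect_gte(n1, 540); expect_lte(n1, 660)
  n2 <- run_uniform(3000, 384)
  expect_gte(n2, 2700); expect_lte(n2, 3300)
})
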