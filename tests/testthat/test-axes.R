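test_that("top-hat removes smooth background and preserves thin lines", {
  cimg <- vol_img(array(900, c(3, 40, 40)), c(0.1, 0.1, 0.1))
  expect_true(all(tophat_filter(cimg, 8)$data == 0))

  # thin bright line on a linear ramp
  d <- c(1, 60, 60)
  ramp <- outer(1:60, 1:60, function(y, x) 5 * x)
  sl <- ramp
  sl[, 30:31] <- sl[, 30:31] + 800
  img <- vol_img(array(sl, d), c(0.1, 0.1, 0.1))
  out <- tophat_filter(img, 15)
  mid <- out$data[1, 25:35, 30:31]
  expect_gte(min(mid), 0.9 * 800)
  expect_lt(max(out$data[1, 10:50, 5:20]), 5)
  expect_true(all(out$data <= img$data + 1e-9))
  expect_error(tophat_filter(img, 40), "radius")
})

test_that("the feature stack has the stated layout and annihilates constants", {
  img <- vol_img(array(7, c(8, 16, 16)), c(0.1, 0.05, 0.05))
  fs <- compute_feature_stack(img, scales = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(ncol(fs$features), 24)
  grad_cols <- grep("gradmag", fs$feature_names)
  expect_true(all(abs(fs$features[, grad_cols]) < 1e-8))
  dog_cols <- grep("dog", fs$feature_names)
  expect_true(all(abs(fs$features[, dog_cols]) < 1e-9))
})

# a clean rendered tube image plus truth mask, reused by classifier tests
tube_image <- function(seed = 17) {
  cached(sprintf("tube_image_%d", seed), function() {
    d <- c(16, 48, 48)
    sp <- c(0.1, 0.06, 0.06)
    xs <- seq(0.3, 2.6, by = 0.02)
    pts <- cbind(0.8, 1.44 + 0.5 * sin(xs * 2.5), xs)
    arr <- array(0, d)
    iz <- round(pts[, 1] / sp[1] + 0.5); iy <- round(pts[, 2] / sp[2] + 0.5)
    ix <- round(pts[, 3] / sp[3] + 0.5)
    lin <- iz + (iy - 1) * d[1] + (ix - 1) * d[1] * d[2]
    tb <- table(lin)
    arr[as.numeric(names(tb))] <- as.numeric(tb)
    arr <- axofoci:::gaussian_smooth3d(arr, sp, 0.12)
    arr <- arr * (8000 / max(arr))
    seedm <- array(0L, d); seedm[cbind(iz, iy, ix)] <- 1L
    dmap <- array(axofoci:::cpp_edt3d(as.integer(seedm), d, sp), d)
    list(img = vol_img(arr + 300, sp, "axis"), truth = dmap <= 0.14,
         dmap = dmap)
  })
}

test_that("the voxel classifier learns a separable tube and is seeded", {
  ti <- tube_image()
  fs <- compute_feature_stack(ti$img, scales = c(0.08, 0.12, 0.24))
  scrib <- array(0L, dim(ti$img$data))
  # scribbles bracket the tube boundary: on-axis strokes near the
  # medial line, background strokes just outside the tube
  on_idx <- which(ti$dmap <= 0.1)
  off_idx <- which(ti$dmap >= 0.2)
  set.seed(1)
  scrib[sample(on_idx, min(400, length(on_idx)))] <- 1L
  scrib[sample(off_idx, 800)] <- 2L
  clf <- train_voxel_classifier(fs, scrib, seed = 11)
  df <- as.data.frame(fs$features[which(scrib > 0L), ])
  pr <- predict(clf$model, df, num.threads = 1)$predictions[, "axis"]
  truth <- scrib[scrib > 0L] == 1L
  expect_gte(mean((pr >= 0.5) == truth), 0.99)

  clf2 <- train_voxel_classifier(fs, scrib, seed = 11)
  m1 <- classify_voxels(clf, fs)
  m2 <- classify_voxels(clf2, fs)
  expect_identical(m1$mask, m2$mask)

  # held-out tube voxels on the full image
  held <- which(ti$dmap <= 0.1)
  expect_gte(mean(m1$mask[held]), 0.95)
  # Dice against the truth tube mask
  dice <- 2 * sum(m1$mask & ti$truth) / (sum(m1$mask) + sum(ti$truth))
  expect_gte(dice, 0.9)

  expect_true(all(classify_voxels(clf, fs, prob_cutoff = 0)$mask))
  expect_false(any(classify_voxels(clf, fs, prob_cutoff = 1.01)$mask))
  fs2 <- compute_feature_stack(ti$img, scales = c(0.1))
  expect_error(classify_voxels(clf, fs2), "feature configuration")
  scrib1 <- scrib; scrib1[scrib1 == 2L] <- 0L
  expect_error(train_voxel_classifier(fs, scrib1, seed = 1), "both classes")
})

test_that("tubeness enhances tubes over blobs and vanishes on constants", {
  cimg <- vol_img(array(5, c(8, 16, 16)), c(0.1, 0.1, 0.1))
  expect_true(all(tubeness(cimg, 0.2)$data == 0))

  d <- c(17, 33, 61)
  sp <- c(0.1, 0.1, 0.1)
  sig_t <- 0.2
  tube <- array(0, d)
  blob <- array(0, d)
  for (z in 1:17) for (y in 1:33) for (x in 1:61) {
    r2 <- ((z - 9) * 0.1)^2 + ((y - 17) * 0.1)^2
    tube[z, y, x] <- 100 * exp(-r2 / (2 * sig_t^2))
    r3 <- r2 + ((x - 31) * 0.1)^2
    blob[z, y, x] <- 100 * exp(-r3 / (2 * sig_t^2))
  }
  tt <- tubeness(vol_img(tube, sp), sig_t)
  expect_gt(tt$data[9, 17, 31], 5 * tt$data[9, 17 + 6, 31])  # 3 sigma off
  tb <- tubeness(vol_img(blob, sp), sig_t)
  expect_gt(tt$data[9, 17, 31], tb$data[9, 17, 31])
})

test_that("thinning preserves topology on canonical shapes", {
  sp <- c(0.1, 0.1, 0.1)
  tube <- make_tube_mask(100, 3)
  sk <- skeletonize_3d(tube, spacing = sp)
  g <- glance(sk)
  expect_equal(length(sk$branches), 1)
  expect_gte(sk$total_length, 0.98 * 9.9)
  expect_lte(sk$total_length, 1.02 * 9.9)
  expect_equal(g$n_components, 1L)
  expect_equal(g$cycle_rank, 0L)
  # skeleton is a subset of the mask
  expect_true(all(tube[sk$voxels]))

  ball <- make_ball_mask(6)
  skb <- skeletonize_3d(ball, spacing = sp)
  expect_lte(nrow(skb$voxels), 5)

  torus <- make_torus_mask()
  skt <- skeletonize_3d(torus, spacing = sp)
  gt <- glance(skt)
  expect_equal(gt$n_components, 1L)
  expect_equal(gt$cycle_rank, 1L)
  expect_true(all(torus[skt$voxels]))

  # two disjoint tubes stay two components; lengths add
  t1 <- make_tube_mask(40, 2)
  d2 <- dim(t1)
  both <- array(FALSE, c(2 * d2[1] + 3, d2[2], d2[3]))
  both[1:d2[1], , ] <- t1
  both[(d2[1] + 4):(2 * d2[1] + 3), , ] <- t1
  sk2 <- skeletonize_3d(both, spacing = sp)
  g2 <- glance(sk2)
  expect_equal(g2$n_components, 2L)
  one_len <- skeletonize_3d(t1, spacing = sp)$total_length
  expect_equal(sk2$total_length, 2 * one_len, tolerance = 1e-9)

  expect_error(skeletonize_3d(array(FALSE, c(4, 4, 4)), spacing = sp),
               "empty mask")
})

test_that("pruning removes short spurs and is idempotent", {
  m <- make_tube_mask(100, 1)
  # add a 3-voxel spur off the middle
  m[5, 4, 52] <- TRUE; m[5, 3, 53] <- TRUE; m[5, 2, 54] <- TRUE
  sk <- skeletonize_3d(m, spacing = c(0.1, 0.1, 0.1))
  pr <- prune_skeleton(sk, 0.5)
  expect_equal(length(pr$branches), 1)
  expect_gte(pr$total_length, 0.95 * 9.9)
  expect_identical(prune_skeleton(sk, 0)$voxels, sk$voxels)
  pr2 <- prune_skeleton(pr, 0.5)
  expect_identical(pr2$voxels, pr$voxels)
})

test_that("branch tracing decomposes junctions, paths and cycles", {
  sp <- c(0.1, 0.1, 0.1)
  skY <- skeletonize_3d(make_y_mask(), spacing = sp)
  expect_equal(length(skY$branches), 3)
  junction <- skY$voxels[which(skY$degree >= 3), , drop = FALSE]
  expect_equal(nrow(junction), 1)
  tb <- trace_branches(skY)
  jrows <- tb[tb$z == junction[1] & tb$y == junction[2] & tb$x == junction[3], ]
  expect_equal(sort(unique(jrows$branch_id)), 1:3)

  # simple open path
  p <- array(FALSE, c(3, 3, 30)); p[2, 2, 3:28] <- TRUE
  skp <- skeletonize_3d(p, spacing = sp)
  expect_equal(length(skp$branches), 1)

  # 8-voxel ring: one cyclic branch of 8 steps
  ring <- array(FALSE, c(3, 5, 5))
  ring[2, 2:4, 2:4] <- TRUE; ring[2, 3, 3] <- FALSE
  skr <- skeleton <- axofoci:::skeleton_from_voxels(
    which(ring, arr.ind = TRUE)[, c(1, 2, 3)], dim(ring), sp)
  expect_equal(length(skr$branches), 1)
  expect_true(skr$cyclic[1])
  b <- skr$branches[[1]]
  expect_equal(length(b), 9)            # closed: first voxel repeated
  expect_equal(b[1], b[length(b)])
})

test_that("skeleton length tracks an analytic in-plane tube within 5%", {
  d <- c(24, 128, 256)
  sp <- c(0.125, 0.04, 0.04)
  xs <- seq(0.5, 9.7, by = 0.02)
  pts <- cbind(1.5, 2.56 + 0.4 * sin(xs), xs)
  path <- structure(list(path_id = 1L, points = pts,
                         length = axofoci:::polyline_length(pts)),
                    class = "axis_path")
  # a well-sampled tube (sigma 0.15 um spans >1 z-plane) so staircase
  # effects stay small for this in-plane trajectory
  cfg <- simulation_config(grid_shape = d, nucleus_radius = 1.4,
                           nucleolus_radius = 0.3,
                           nucleolus_center = c(0, 0, 0), n_axes = 1,
                           axis_total_length = 10, axis_tube_sigma = 0.15,
                           n_foci_total = 5,
                           n_foci_axis_touching = 0, seed = 2)
  arr <- axofoci:::render_tube_channel(list(path), cfg, 9000)
  set.seed(2)
  cam <- axofoci:::apply_camera(arr, cfg)
  ax <- segment_axis_channel(vol_img(cam$img, sp, "axis"),
                             axis_params(tubeness_sigma = 0.15))
  expect_lt(abs(ax$skeleton$total_length / path$length - 1), 0.05)
})

test_that("the axis mask overlaps the true tube at default noise", {
  nuc <- tortuosity_nucleus(0.3, seed = 11)
  ax <- cached("dice_axes", function()
    segment_axis_channel(nuc$channels$axis))
  tm <- truth_tube_mask(nuc, radius = 0.15)
  dice <- 2 * sum(ax$mask$mask & tm) / (sum(ax$mask$mask) + sum(tm))
  expect_gte(dice, 0.8)
})
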