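# Shared fixtures. Expensive synthetic nuclei are generated once per test
# run and cached here; everything is rebuilt from code (no stored data).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

# solid tube along x with circular cross-section, centred in a small grid
make_tube_mask <- function(len = 100, rad = 3, pad = 2) {
  side <- 2 * rad + 3
  d <- c(side, side, len + 2 * pad)
  m <- array(FALSE, d)
  c0 <- (side + 1) / 2
  for (x in (pad + 1):(pad + len)) for (y in 1:side) for (z in 1:side)
    if ((y - c0)^2 + (z - c0)^2 <= rad^2) m[z, y, x] <- TRUE
  m
}

make_torus_mask <- function() {
  d <- c(9, 33, 33)
  m <- array(FALSE, d)
  for (x in 1:33) for (y in 1:33) for (z in 1:9) {
    rr <- sqrt((x - 17)^2 + (y - 17)^2)
    if ((rr - 10)^2 + (z - 5)^2 <= 6.25) m[z, y, x] <- TRUE
  }
  m
}

make_y_mask <- function() {
  d <- c(5, 40, 40)
  m <- array(FALSE, d)
  for (i in 0:15) m[3, 20, 5 + i] <- TRUE
  for (i in 0:14) {
    m[3, 20 - i - 1, 21 + i] <- TRUE
    m[3, 20 + i + 1, 21 + i] <- TRUE
  }
  m[3, 20, 21] <- TRUE
  m
}

make_ball_mask <- function(rad = 6) {
  side <- 2 * rad + 5
  d <- rep(side, 3)
  m <- array(FALSE, d)
  c0 <- (side + 1) / 2
  for (x in 1:side) for (y in 1:side) for (z in 1:side)
    if ((x - c0)^2 + (y - c0)^2 + (z - c0)^2 <= rad^2) m[z, y, x] <- TRUE
  m
}

# small but complete nucleus used by several module tests
small_nucleus <- function() {
  cached("small_nucleus", function() {
    cfg <- simulation_config(grid_shape = c(24, 96, 96), nucleus_radius = 1.4,
                             nucleolus_radius = 0.35,
                             nucleolus_center = c(0, 0.6, 0), n_axes = 2,
                             axis_total_length = 20, n_foci_total = 60,
                             n_foci_axis_touching = 20, seed = 3)
    simulate_nucleus(cfg)
  })
}

# moderate-density nucleus for classification/distance recovery tests
sparse_nucleus <- function() {
  cached("sparse_nucleus", function() {
    cfg <- simulation_config(seed = 5, n_foci_total = 500,
                             n_foci_axis_touching = 120)
    simulate_nucleus(cfg)
  })
}

sparse_pipeline <- function() {
  cached("sparse_pipeline", function() {
    nuc <- sparse_nucleus()
    spots <- segment_spot_channel(nuc$channels$focus)
    axes <- segment_axis_channel(nuc$channels$axis)
    dmap <- distance_map_3d(axes$skeleton)
    records <- object_axis_distances(spots$labels, spots$objects, dmap)
    list(nuc = nuc, spots = spots, axes = axes, dmap = dmap,
         records = records)
  })
}

# low/medium/high tortuosity nuclei (axis channel only matters)
tortuosity_nucleus <- function(tort, seed = 21) {
  cached(sprintf("tort_%s_%d", tort, seed), function() {
    cfg <- simulation_config(seed = seed, n_axes = 2, axis_total_length = 40,
                             tortuosity = tort, n_foci_total = 20,
                             n_foci_axis_touching = 5)
    simulate_nucleus(cfg)
  })
}

tortuosity_axes <- function(tort, seed = 21) {
  cached(sprintf("tortax_%s_%d", tort, seed), function() {
    segment_axis_channel(tortuosity_nucleus(tort, seed)$channels$axis)
  })
}

# one full-pipeline acceptance-style nucleus (spec study conditions)
dense_run <- function(seed) {
  cached(sprintf("dense_run_%d", seed), function() {
    cfg <- pipeline_config(simulate = list(seed = seed), seed = seed)
    run_pipeline(cfg)
  })
}

# per-focus classification metrics against planted truth
association_metrics <- function(nuc, spots, records) {
  tf <- nuc$truth$foci
  sp <- nuc$config$voxel_spacing
  at_label <- function(df) {
    iz <- round(df$z_um / sp[1] + 0.5)
    iy <- round(df$y_um / sp[2] + 0.5)
    ix <- round(df$x_um / sp[3] + 0.5)
    spots$labels$labels[cbind(iz, iy, ix)]
  }
  tt <- tf[tf$is_axis_touching, ]
  lt <- at_label(tt)
  touch_assoc <- mean(records$is_axis_associated[match(lt[lt > 0],
                                                       records$object_id)])
  farf <- tf[!tf$is_axis_touching & tf$true_min_distance_um >= 0.3, ]
  lf <- at_label(farf)
  sel <- lf > 0
  far_assoc <- mean(records$is_axis_associated[match(lf[sel],
                                                     records$object_id)])
  mae_far <- mean(abs(records$dist_min_um[match(lf[sel], records$object_id)] -
                      farf$true_min_distance_um[sel]))
  list(touch_assoc = touch_assoc, far_assoc = far_assoc, mae_far = mae_far)
}

# independent point-to-polyline distance oracle (plain R, used to check
# the generator's truth table and measured distances)
r_min_dist_to_paths <- function(pts, paths) {
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    best <- Inf
    for (pm in paths) {
      for (s in seq_len(nrow(pm) - 1)) {
        a <- pm[s, ]; b <- pm[s + 1, ]
        v <- b - a; w <- p - a
        vv <- sum(v^2)
        t <- if (vv > 0) max(0, min(1, sum(w * v) / vv)) else 0
        best <- min(best, sqrt(sum((w - t * v)^2)))
      }
    }
    best
  }, 0)
}
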