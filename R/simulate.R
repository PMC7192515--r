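#' Simulation configuration for a synthetic nucleus
#'
#' Builds and validates the full parameter set of the synthetic-nucleus
#' generator. Defaults describe a desk-scale meiotic prophase nucleus:
#' tortuous tube-like chromosome axes inside a spherical nucleus with a
#' nucleolar exclusion zone, thousands of diffraction-limited foci whose
#' distances to the nearest axis follow a configurable "chromatin sleeve"
#' distribution, smooth background, shot and read noise, and 16-bit
#' quantization with background such that automatic thresholds land in
#' the 3000-4000 count range.
#'
#' @param grid_shape voxel counts `(z, y, x)`.
#' @param voxel_spacing um per voxel `(dz, dy, dx)`.
#' @param nucleus_radius nucleus sphere radius, um. Must fit in the grid.
#' @param nucleolus_radius nucleolus sphere radius, um.
#' @param nucleolus_center nucleolus centre offset from the nucleus
#'   centre, um `(z, y, x)`.
#' @param n_axes number of axis paths.
#' @param axis_total_length total axis length summed over paths, um.
#' @param tortuosity dimensionless >= 0; per-step turning-angle scale of
#'   the smoothed random walk. 0 gives straight segments.
#' @param axis_tube_sigma Gaussian cross-section sigma of rendered axis
#'   tubes, um.
#' @param axis_amplitude peak axis-channel intensity, counts.
#' @param n_foci_total total planted foci.
#' @param n_foci_axis_touching planted axis-touching subset (their true
#'   minimal distance to an axis medial line is at most
#'   `axis_tube_sigma`).
#' @param offaxis_distance_distribution named list describing the
#'   distance-from-axis distribution of the remaining foci:
#'   `list(name = "lognormal", meanlog, sdlog)`,
#'   `list(name = "uniform", min, max)`, `list(name = "gamma", shape,
#'   scale)` or `list(name = "point", at)`. The default lognormal places
#'   55% of its mass within 0.35 um and 90% within 0.6 um of an axis.
#' @param offaxis_tolerance rejection tolerance for realized off-axis
#'   distances, um.
#' @param focus_sigma lateral Gaussian sigma of a rendered focus, um.
#' @param focus_axial_ratio axial elongation factor; the axial sigma is
#'   `focus_sigma * focus_axial_ratio`.
#' @param focus_amplitude_range 16-bit count range for focus amplitudes.
#' @param background_level mean background, counts.
#' @param background_sd read-noise standard deviation, counts.
#' @param photon_scale counts per photon for shot noise; 0 disables it.
#' @param synapsis_fraction `NULL` for no synapsis channel, else the
#'   fraction (0-1) of each axis rendered into the ZYP1-like channel.
#' @param seed integer seed; config + seed fully determine all outputs.
#' @return A validated list of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(grid_shape = c(24, 64, 64), nucleus_radius = 1.1,
#'                          n_axes = 2, axis_total_length = 12,
#'                          n_foci_total = 40, n_foci_axis_touching = 10)
#' @export
simulation_config <- function(grid_shape = c(64, 256, 256),
                              voxel_spacing = c(0.125, 0.04, 0.04),
                              nucleus_radius = 3.8,
                              nucleolus_radius = 1.0,
                              nucleolus_center = c(0, 1.5, 0),
                              n_axes = 10,
                              axis_total_length = 300,
                              tortuosity = 1,
                              axis_tube_sigma = 0.1,
                              axis_amplitude = 9000,
                              n_foci_total = 2500,
                              n_foci_axis_touching = 350,
                              offaxis_distance_distribution = list(
                                name = "lognormal",
                                meanlog = -1.108424, sdlog = 0.466320),
                              offaxis_tolerance = 0.05,
                              focus_sigma = 0.05,
                              focus_axial_ratio = 2.5,
                              focus_amplitude_range = c(12000, 28000),
                              background_level = 3200,
                              background_sd = 150,
                              photon_scale = 2,
                              synapsis_fraction = NULL,
                              seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_spacing = as.numeric(voxel_spacing),
              nucleus_radius = nucleus_radius,
              nucleolus_radius = nucleolus_radius,
              nucleolus_center = as.numeric(nucleolus_center),
              n_axes = as.integer(n_axes),
              axis_total_length = axis_total_length,
              tortuosity = tortuosity,
              axis_tube_sigma = axis_tube_sigma,
              axis_amplitude = axis_amplitude,
              n_foci_total = as.integer(n_foci_total),
              n_foci_axis_touching = as.integer(n_foci_axis_touching),
              offaxis_distance_distribution = offaxis_distance_distribution,
              offaxis_tolerance = offaxis_tolerance,
              focus_sigma = focus_sigma,
              focus_axial_ratio = focus_axial_ratio,
              focus_amplitude_range = as.numeric(focus_amplitude_range),
              background_level = background_level,
              background_sd = background_sd,
              photon_scale = photon_scale,
              synapsis_fraction = synapsis_fraction,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(length(cfg$grid_shape) == 3, all(cfg$grid_shape >= 4),
            length(cfg$voxel_spacing) == 3, all(cfg$voxel_spacing > 0))
  if (cfg$n_foci_axis_touching > cfg$n_foci_total)
    stop("n_foci_axis_touching must not exceed n_foci_total", call. = FALSE)
  if (cfg$nucleus_radius <= 0 || cfg$nucleolus_radius <= 0 ||
      cfg$axis_tube_sigma <= 0 || cfg$focus_sigma <= 0)
    stop("all radii and sigmas must be positive", call. = FALSE)
  extent <- cfg$grid_shape * cfg$voxel_spacing
  if (any(cfg$nucleus_radius * 2 > extent))
    stop(sprintf(paste0("grid does not contain the nucleus sphere: ",
                        "diameter %.3g um vs extent (%.3g, %.3g, %.3g) um"),
                 2 * cfg$nucleus_radius, extent[1], extent[2], extent[3]),
         call. = FALSE)
  if (cfg$background_level + 3 * cfg$background_sd >=
      65536 - max(cfg$focus_amplitude_range))
    stop("background + 3 sd would systematically clip against 16-bit range",
         call. = FALSE)
  if (cfg$tortuosity < 0) stop("tortuosity must be >= 0", call. = FALSE)
  dist <- cfg$offaxis_distance_distribution
  if (is.null(dist$name) ||
      !dist$name %in% c("lognormal", "uniform", "gamma", "point"))
    stop("unknown off-axis distance distribution: ",
         if (is.null(dist$name)) "<missing name>" else dist$name, call. = FALSE)
  invisible(cfg)
}

# nucleus centre in world (um) coordinates = physical grid centre
nucleus_center_um <- function(cfg) cfg$grid_shape * cfg$voxel_spacing / 2

sample_offaxis_distances <- function(dist, n) {
  switch(dist$name,
    lognormal = rlnorm(n, dist$meanlog, dist$sdlog),
    uniform   = runif(n, dist$min, dist$max),
    gamma     = stats::rgamma(n, shape = dist$shape, scale = dist$scale),
    point     = rep(dist$at, n))
}

# random unit vectors, n x 3
runit <- function(n) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

#' Resample a polyline at uniform arc-length spacing
#'
#' @param points n x 3 matrix of ordered coordinates (um).
#' @param step spacing between resampled points (um).
#' @return Matrix of resampled points (first and last points preserved).
#' @export
resample_polyline <- function(points, step) {
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total == 0) return(points[1, , drop = FALSE])
  s <- unique(c(seq(0, total, by = step), total))
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(i, length(seg))
  t <- (s - cum[i]) / pmax(seg[i], .Machine$double.eps)
  points[i, , drop = FALSE] +
    (points[i + 1, , drop = FALSE] - points[i, , drop = FALSE]) * t
}

polyline_length <- function(points) {
  if (nrow(points) < 2) return(0)
  sum(sqrt(rowSums((points[-1, , drop = FALSE] -
                    points[-nrow(points), , drop = FALSE])^2)))
}

# trim a polyline to exact arc length L (interpolating the final point)
trim_polyline <- function(points, L) {
  if (L <= 0) return(points[1, , drop = FALSE])
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total < L) {
    if (total >= L - 1e-9) return(points)   # exact up to rounding
    return(NULL)
  }
  k <- which(cum >= L)[1]
  t <- (L - cum[k - 1]) / (cum[k] - cum[k - 1])
  last <- points[k - 1, ] + (points[k, ] - points[k - 1, ]) * t
  rbind(points[seq_len(k - 1), , drop = FALSE], last)
}

#' Sample ground-truth axis paths
#'
#' Draws `n_axes` smoothed 3D random walks inside the nucleus sphere and
#' outside the nucleolus. The per-step turning angle is proportional to
#' `tortuosity`; `tortuosity = 0` yields straight segments. Each path is
#' trimmed to exactly `axis_total_length / n_axes` um of arc length.
#'
#' Uses the current R random stream; wrap in [simulate_nucleus()] (or set
#' a seed) for reproducibility.
#'
#' @param config a [simulation_config()].
#' @return List of `axis_path` objects: `path_id`, `points` (n x 3 um,
#'   columns z, y, x), `length` (um).
#' @export
sample_axis_paths <- function(config) {
  cfg <- config
  ctr <- nucleus_center_um(cfg)
  margin <- 2 * cfg$axis_tube_sigma + 0.05
  r_max <- cfg$nucleus_radius - margin
  if (r_max <= 0)
    stop("infeasible geometry: nucleus radius smaller than the tube margin",
         call. = FALSE)
  L <- cfg$axis_total_length / cfg$n_axes
  nol_ctr <- ctr + cfg$nucleolus_center
  nol_r <- cfg$nucleolus_radius + 0.15
  ds <- 0.1
  inside_ok <- function(p) {
    sqrt(sum((p - ctr)^2)) <= r_max && sqrt(sum((p - nol_ctr)^2)) >= nol_r
  }
  paths <- vector("list", cfg$n_axes)
  for (a in seq_len(cfg$n_axes)) {
    if (cfg$tortuosity == 0) {
      if (L > 2 * r_max)
        stop(sprintf(paste0("infeasible geometry: straight axis of %.3g um ",
                            "cannot fit inside nucleus radius %.3g um ",
                            "(tube margin %.3g um)"), L, cfg$nucleus_radius,
                     margin), call. = FALSE)
      ok <- FALSE
      for (try in 1:500) {
        u <- runit(1)[1, ]
        pmaxoff <- sqrt(max(r_max^2 - (L / 2)^2, 0))
        perp <- runit(1)[1, ]
        perp <- perp - sum(perp * u) * u
        nrm <- sqrt(sum(perp^2))
        off <- if (nrm > 0) perp / nrm * runif(1, 0, pmaxoff) else c(0, 0, 0)
        p0 <- ctr + off - u * L / 2
        pts <- sweep(outer(seq(0, L, by = ds), u), 2, p0, "+")
        if (polyline_length(pts) < L) pts <- rbind(pts, p0 + u * L)
        pts <- trim_polyline(pts, L)
        if (all(apply(pts, 1, inside_ok))) { ok <- TRUE; break }
      }
      if (!ok)
        stop("infeasible geometry: straight axis cannot avoid the nucleolus",
             call. = FALSE)
      paths[[a]] <- structure(list(path_id = a, points = unname(pts),
                                   length = polyline_length(pts)),
                              class = "axis_path")
      next
    }
    # smoothed random walk: raw walk of 1.3 * L, moving-average smoothing,
    # uniform resampling, exact-length trim
    n_steps <- ceiling(1.3 * L / ds) + 10
    p <- ctr + runit(1)[1, ] * runif(1, 0, 0.6 * r_max)
    while (!inside_ok(p)) p <- ctr + runit(1)[1, ] * runif(1, 0, 0.6 * r_max)
    dirv <- runit(1)[1, ]
    pts <- matrix(NA_real_, n_steps + 1, 3)
    pts[1, ] <- p
    theta_sd <- 0.15 * cfg$tortuosity
    for (s in seq_len(n_steps)) {
      ang <- rnorm(1, 0, theta_sd)
      perp <- runit(1)[1, ]
      perp <- perp - sum(perp * dirv) * dirv
      nrm <- sqrt(sum(perp^2))
      if (nrm > 0) perp <- perp / nrm
      dirv <- dirv * cos(ang) + perp * sin(ang)
      dirv <- dirv / sqrt(sum(dirv^2))
      prop <- p + dirv * ds
      steer <- 0
      while (!inside_ok(prop) && steer < 60) {
        # steer away from the violated boundary
        to_ctr <- ctr - p
        to_ctr <- to_ctr / sqrt(sum(to_ctr^2))
        from_nol <- p - nol_ctr
        nn <- sqrt(sum(from_nol^2))
        pull <- if (nn < nol_r + 0.2) from_nol / nn else to_ctr
        dirv <- dirv + 0.35 * pull
        dirv <- dirv / sqrt(sum(dirv^2))
        prop <- p + dirv * ds
        steer <- steer + 1
      }
      p <- prop
      pts[s + 1, ] <- p
    }
    sm <- apply(pts, 2, function(v) {
      as.numeric(stats::filter(v, rep(1 / 5, 5), sides = 2))
    })
    sm <- sm[!is.na(sm[, 1]), , drop = FALSE]
    # clamp smoothed points back into the allowed shell
    rr <- sqrt(rowSums(sweep(sm, 2, ctr)^2))
    out <- rr > r_max
    if (any(out))
      sm[out, ] <- sweep(sweep(sm[out, , drop = FALSE], 2, ctr) *
                           (r_max / rr[out]), 2, ctr, "+")
    rn <- sqrt(rowSums(sweep(sm, 2, nol_ctr)^2))
    inn <- rn < cfg$nucleolus_radius + 0.02
    if (any(inn))
      sm[inn, ] <- matrix(nol_ctr, sum(inn), 3, byrow = TRUE) +
        sweep(sm[inn, , drop = FALSE], 2, nol_ctr) *
        ((cfg$nucleolus_radius + 0.02) / rn[inn])
    sm <- resample_polyline(sm, ds)
    pts2 <- trim_polyline(sm, L)
    if (is.null(pts2)) {
      # smoothing shortened the walk below target; extend along the last
      # direction (clamped) and retrim
      lastd <- sm[nrow(sm), ] - sm[nrow(sm) - 1, ]
      lastd <- lastd / sqrt(sum(lastd^2))
      extra <- sweep(outer(seq(ds, L, by = ds), lastd), 2, sm[nrow(sm), ], "+")
      rr <- sqrt(rowSums(sweep(extra, 2, ctr)^2))
      extra <- sweep(sweep(extra, 2, ctr) * pmin(1, r_max / rr), 2, ctr, "+")
      pts2 <- trim_polyline(rbind(sm, extra), L)
    }
    paths[[a]] <- structure(list(path_id = a, points = unname(pts2),
                                 length = polyline_length(pts2)),
                            class = "axis_path")
  }
  paths
}

#' Place ground-truth foci relative to axis paths
#'
#' Plants exactly `n_foci_total` foci: `n_foci_axis_touching` of them on
#' the axes (offset from the medial line by a half-normal draw with sd
#' `axis_tube_sigma / 5`, truncated at `axis_tube_sigma`, so they overlap
#' the rendered tube) and the rest at chromatin-sleeve distances drawn
#' from `offaxis_distance_distribution`, enforced by rejection inside the
#' nucleus. `true_min_distance_um` is always the exact recomputed
#' point-to-polyline distance, not the nominal draw.
#'
#' @param config a [simulation_config()].
#' @param paths axis paths from [sample_axis_paths()].
#' @return Tibble: `focus_id`, `z_um`, `y_um`, `x_um`, `amplitude`,
#'   `true_min_distance_um`, `is_axis_touching`.
#' @export
place_foci <- function(config, paths) {
  cfg <- config
  n_t <- cfg$n_foci_axis_touching
  n_o <- cfg$n_foci_total - n_t
  if (cfg$n_foci_total == 0)
    return(tibble::tibble(focus_id = integer(), z_um = numeric(),
                          y_um = numeric(), x_um = numeric(),
                          amplitude = numeric(),
                          true_min_distance_um = numeric(),
                          is_axis_touching = logical()))
  if (n_t > 0 && length(paths) == 0)
    stop("axis-touching foci requested but no axis paths supplied",
         call. = FALSE)
  ctr <- nucleus_center_um(cfg)
  nol_ctr <- ctr + cfg$nucleolus_center
  path_mats <- lapply(paths, function(p) p$points)
  # all path segments pooled, for length-weighted anchor sampling with
  # local tangents; displacement directions are drawn perpendicular to
  # the tangent so the realized minimal distance matches the draw
  seg_a <- do.call(rbind, lapply(path_mats, function(m)
    m[-nrow(m), , drop = FALSE]))
  seg_b <- do.call(rbind, lapply(path_mats, function(m)
    m[-1, , drop = FALSE]))
  seg_len <- sqrt(rowSums((seg_b - seg_a)^2))
  sample_anchors <- function(n) {
    if (n == 0) return(list(points = matrix(0, 0, 3),
                            tangents = matrix(0, 0, 3)))
    si <- sample.int(length(seg_len), n, replace = TRUE, prob = seg_len)
    t <- runif(n)
    pts <- seg_a[si, , drop = FALSE] +
      (seg_b[si, , drop = FALSE] - seg_a[si, , drop = FALSE]) * t
    tan <- (seg_b[si, , drop = FALSE] - seg_a[si, , drop = FALSE]) /
      pmax(seg_len[si], 1e-12)
    list(points = pts, tangents = tan)
  }
  perp_unit <- function(tangents) {
    n <- nrow(tangents)
    v <- runit(n)
    v <- v - tangents * rowSums(v * tangents)
    nv <- sqrt(rowSums(v^2))
    bad <- nv < 1e-8
    if (any(bad)) {
      v[bad, ] <- runit(sum(bad))
      nv <- sqrt(rowSums(v^2))
    }
    v / nv
  }
  out <- vector("list", 2)
  if (n_t > 0) {
    anc <- sample_anchors(n_t)
    off <- pmin(abs(rnorm(n_t, 0, cfg$axis_tube_sigma / 5)),
                cfg$axis_tube_sigma * 0.95)
    centers <- anc$points + perp_unit(anc$tangents) * off
    d_true <- as.numeric(cpp_min_dist_to_paths(centers, path_mats))
    out[[1]] <- tibble::tibble(z_um = centers[, 1], y_um = centers[, 2],
                               x_um = centers[, 3],
                               true_min_distance_um = d_true,
                               is_axis_touching = TRUE)
  } else out[[1]] <- NULL
  if (n_o > 0) {
    centers <- matrix(NA_real_, n_o, 3)
    d_true <- rep(NA_real_, n_o)
    unfilled <- seq_len(n_o)
    tol <- cfg$offaxis_tolerance
    r_lim <- cfg$nucleus_radius - 0.1
    for (wave in 1:200) {
      if (!length(unfilled)) break
      m <- length(unfilled)
      anc <- sample_anchors(m)
      d <- sample_offaxis_distances(cfg$offaxis_distance_distribution, m)
      cand <- anc$points + perp_unit(anc$tangents) * d
      act <- as.numeric(cpp_min_dist_to_paths(cand, path_mats))
      in_nuc <- sqrt(rowSums(sweep(cand, 2, ctr)^2)) <= r_lim
      out_nol <- sqrt(rowSums(sweep(cand, 2, nol_ctr)^2)) >= cfg$nucleolus_radius
      ok <- in_nuc & out_nol & act >= d - tol
      if (wave == 200) ok <- ok | (in_nuc & out_nol)  # last wave: keep valid geometry
      take <- unfilled[ok]
      centers[take, ] <- cand[ok, , drop = FALSE]
      d_true[take] <- act[ok]
      unfilled <- unfilled[!ok]
    }
    if (length(unfilled))
      stop("could not place all off-axis foci inside the nucleus", call. = FALSE)
    out[[2]] <- tibble::tibble(z_um = centers[, 1], y_um = centers[, 2],
                               x_um = centers[, 3],
                               true_min_distance_um = d_true,
                               is_axis_touching = FALSE)
  } else out[[2]] <- NULL
  foci <- dplyr::bind_rows(out)
  foci$amplitude <- runif(nrow(foci), cfg$focus_amplitude_range[1],
                          cfg$focus_amplitude_range[2])
  foci$focus_id <- seq_len(nrow(foci))
  dplyr::select(foci, "focus_id", "z_um", "y_um", "x_um", "amplitude",
                "true_min_distance_um", "is_axis_touching")
}

# splat polylines onto the grid and blur to a Gaussian-cross-section tube,
# rescaled to peak `amplitude`
render_tube_channel <- function(paths, cfg, amplitude) {
  d <- cfg$grid_shape
  sp <- cfg$voxel_spacing
  arr <- array(0, d)
  for (p in paths) {
    pts <- resample_polyline(p$points, 0.02)
    iz <- pmin(pmax(round(pts[, 1] / sp[1] + 0.5), 1), d[1])
    iy <- pmin(pmax(round(pts[, 2] / sp[2] + 0.5), 1), d[2])
    ix <- pmin(pmax(round(pts[, 3] / sp[3] + 0.5), 1), d[3])
    lin <- iz + (iy - 1) * d[1] + (ix - 1) * d[1] * d[2]
    tb <- table(lin)
    arr[as.numeric(names(tb))] <- arr[as.numeric(names(tb))] + as.numeric(tb)
  }
  if (max(arr) == 0) return(arr)
  arr <- gaussian_smooth3d(arr, sp, cfg$axis_tube_sigma)
  arr * (amplitude / max(arr))
}

# additive anisotropic Gaussian spots, peak = amplitude at the centre
render_focus_channel <- function(foci, cfg) {
  d <- cfg$grid_shape
  sp <- cfg$voxel_spacing
  sig <- c(cfg$focus_sigma * cfg$focus_axial_ratio, cfg$focus_sigma,
           cfg$focus_sigma)
  r_vox <- pmax(1L, ceiling(3.5 * sig / sp))
  arr <- array(0, d)
  for (i in seq_len(nrow(foci))) {
    cz <- foci$z_um[i]; cy <- foci$y_um[i]; cx <- foci$x_um[i]
    iz <- round(cz / sp[1] + 0.5); iy <- round(cy / sp[2] + 0.5)
    ix <- round(cx / sp[3] + 0.5)
    zr <- max(1, iz - r_vox[1]):min(d[1], iz + r_vox[1])
    yr <- max(1, iy - r_vox[2]):min(d[2], iy + r_vox[2])
    xr <- max(1, ix - r_vox[3]):min(d[3], ix + r_vox[3])
    gz <- exp(-((zr - 0.5) * sp[1] - cz)^2 / (2 * sig[1]^2))
    gy <- exp(-((yr - 0.5) * sp[2] - cy)^2 / (2 * sig[2]^2))
    gx <- exp(-((xr - 0.5) * sp[3] - cx)^2 / (2 * sig[3]^2))
    arr[zr, yr, xr] <- arr[zr, yr, xr] +
      foci$amplitude[i] * (gz %o% gy %o% gx)
  }
  arr
}

apply_camera <- function(signal, cfg) {
  d <- dim(signal)
  img <- signal + cfg$background_level
  if (cfg$background_sd > 0) {
    # smooth low-frequency background variation (correlation length ~1.5 um)
    f <- array(rnorm(prod(d)), d)
    f <- gaussian_smooth3d(f, cfg$voxel_spacing, 1.5)
    f <- f - mean(f)
    s <- stats::sd(as.numeric(f))
    if (s > 0) img <- img + f * (0.5 * cfg$background_sd / s)
  }
  if (cfg$photon_scale > 0)
    img <- array(rpois(length(img), pmax(img, 0) / cfg$photon_scale), d) *
      cfg$photon_scale
  if (cfg$background_sd > 0)
    img <- img + rnorm(length(img), 0, cfg$background_sd)
  q <- round(img)
  clipped <- mean(q < 0 | q > 65535)
  q <- pmin(pmax(q, 0), 65535)
  list(img = array(q, d), clipped_fraction = clipped)
}

#' Render a synthetic nucleus from ground truth
#'
#' Renders the axis channel (Gaussian-cross-section tubes along the
#' paths), the focus channel (anisotropic Gaussian spots) and optionally
#' a synapsis channel (the first `synapsis_fraction` of each path), then
#' applies smooth background, Poisson shot noise, Gaussian read noise and
#' 16-bit quantization. Deterministic given the R random state; truth is
#' attached unchanged.
#'
#' @param config a [simulation_config()].
#' @param paths from [sample_axis_paths()].
#' @param foci from [place_foci()].
#' @return A `synthetic_nucleus`: named `channels` (each a [vol_img()]),
#'   `truth` (foci table, paths, totals), `config`, and a generation
#'   `report` (clipped-voxel fractions; a warning is recorded when any
#'   channel clips more than 0.1% of voxels).
#' @export
render_nucleus <- function(config, paths, foci) {
  cfg <- config
  sp <- cfg$voxel_spacing
  channels <- list()
  report <- list(warnings = character())
  cam <- apply_camera(render_focus_channel(foci, cfg), cfg)
  channels$focus <- vol_img(cam$img, sp, "focus")
  report$clipped_fraction <- c(focus = cam$clipped_fraction)
  cam <- apply_camera(render_tube_channel(paths, cfg, cfg$axis_amplitude), cfg)
  channels$axis <- vol_img(cam$img, sp, "axis")
  report$clipped_fraction <- c(report$clipped_fraction,
                               axis = cam$clipped_fraction)
  if (!is.null(cfg$synapsis_fraction)) {
    part <- lapply(paths, function(p) {
      tp <- trim_polyline(p$points, max(p$length * cfg$synapsis_fraction, 1e-6))
      structure(list(path_id = p$path_id, points = tp,
                     length = polyline_length(tp)), class = "axis_path")
    })
    part <- part[vapply(part, function(p) p$length > 0.05, TRUE)]
    syn <- if (length(part))
      render_tube_channel(part, cfg, cfg$axis_amplitude) else array(0, cfg$grid_shape)
    cam <- apply_camera(syn, cfg)
    channels$synapsis <- vol_img(cam$img, sp, "synapsis")
    report$clipped_fraction <- c(report$clipped_fraction,
                                 synapsis = cam$clipped_fraction)
  }
  over <- report$clipped_fraction > 0.001
  if (any(over))
    report$warnings <- c(report$warnings,
                         sprintf("channel '%s' clipped %.3g%% of voxels",
                                 names(report$clipped_fraction)[over],
                                 100 * report$clipped_fraction[over]))
  truth <- list(foci = foci, axes = paths,
                true_total_axis_length = sum(vapply(paths,
                                                    function(p) p$length, 0)),
                path_mean_kappa = vapply(paths, function(p) {
                  # truth curvature at the analysis bandwidth (0.3 um
                  # resampling, window 7) so it is comparable with
                  # pipeline-measured branch curvature
                  pts <- resample_polyline(p$points, 0.3)
                  if (nrow(pts) >= 7)
                    attr(fit_kappa(pts, window = 7), "average_kappa")
                  else NA_real_
                }, 0))
  structure(list(channels = channels, truth = truth, config = cfg,
                 report = report),
            class = "synthetic_nucleus")
}

#' Simulate a complete ground-truthed nucleus
#'
#' Seeds the random stream from `config$seed`, then runs
#' [sample_axis_paths()], [place_foci()] and [render_nucleus()].
#' Regeneration from the same config and seed is voxel-identical.
#'
#' @param config a [simulation_config()].
#' @return A `synthetic_nucleus` object.
#' @examples
#' cfg <- simulation_config(grid_shape = c(16, 48, 48), nucleus_radius = 0.9,
#'                          nucleolus_radius = 0.25, n_axes = 1,
#'                          axis_total_length = 5, n_foci_total = 10,
#'                          n_foci_axis_touching = 5, seed = 7)
#' nuc <- simulate_nucleus(cfg)
#' nuc$truth$foci
#' @export
simulate_nucleus <- function(config) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  paths <- sample_axis_paths(config)
  foci <- place_foci(config, paths)
  render_nucleus(config, paths, foci)
}

#' @export
print.synthetic_nucleus <- function(x, ...) {
  cat(sprintf("<synthetic_nucleus> %s channel(s); %d foci (%d axis-touching); %d axes, %.1f um total\n",
              paste(names(x$channels), collapse = "/"),
              nrow(x$truth$foci), sum(x$truth$foci$is_axis_touching),
              length(x$truth$axes), x$truth$true_total_axis_length))
  if (length(x$report$warnings))
    cat("  generation warnings:", paste(x$report$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Ground-truth tube mask
#'
#' Binary mask of voxels within `radius` of any axis medial line, for
#' segmentation-fidelity (Dice) checks. By default the radius is the
#' half-maximum radius of the rendered Gaussian tube,
#' `sqrt(2 log 2) * axis_tube_sigma`.
#'
#' @param nucleus a `synthetic_nucleus`.
#' @param radius mask radius in um.
#' @return Logical 3D array.
#' @export
truth_tube_mask <- function(nucleus,
                            radius = sqrt(2 * log(2)) *
                              nucleus$config$axis_tube_sigma) {
  cfg <- nucleus$config
  d <- cfg$grid_shape
  sp <- cfg$voxel_spacing
  seed <- array(0L, d)
  for (p in nucleus$truth$axes) {
    pts <- resample_polyline(p$points, min(sp) / 2)
    iz <- pmin(pmax(round(pts[, 1] / sp[1] + 0.5), 1), d[1])
    iy <- pmin(pmax(round(pts[, 2] / sp[2] + 0.5), 1), d[2])
    ix <- pmin(pmax(round(pts[, 3] / sp[3] + 0.5), 1), d[3])
    seed[cbind(iz, iy, ix)] <- 1L
  }
  dmap <- array(cpp_edt3d(as.integer(seed), d, sp), d)
  dmap <= radius
}

#' Write a synthetic nucleus to disk
#'
#' One 16-bit multi-page TIFF per channel (plane order z), the focus
#' truth table and resampled axis points as CSV, and the resolved
#' configuration as YAML.
#'
#' @param nucleus a `synthetic_nucleus`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(nucleus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(nucleus$channels))
    write_stack(nucleus$channels[[ch]], file.path(dir, paste0(ch, ".tif")))
  readr::write_csv(nucleus$truth$foci, file.path(dir, "truth_foci.csv"))
  axpts <- dplyr::bind_rows(lapply(nucleus$truth$axes, function(p) {
    pts <- resample_polyline(p$points, 0.05)
    tibble::tibble(path_id = p$path_id, point_index = seq_len(nrow(pts)),
                   z_um = pts[, 1], y_um = pts[, 2], x_um = pts[, 3])
  }))
  readr::write_csv(axpts, file.path(dir, "truth_axis_points.csv"))
  cfg <- nucleus$config
  cfg$synapsis_fraction <- if (is.null(cfg$synapsis_fraction)) "none" else
    cfg$synapsis_fraction
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
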