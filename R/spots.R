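#' Histogram-based threshold selection
#'
#' Fluorescence z-stacks of punctate signals have a unimodal intensity
#' histogram whose peak is dominated by background; a usable spot
#' threshold sits a few robust standard deviations above that peak (for
#' typical 16-bit stacks of this kind, in the 3000-4000 count range). The
#' rule is `mode + k * spread`, where the spread is `1.4826 *
#' median(mode - x)` over the voxels at or below the mode (the reflected
#' lower tail, insensitive to the bright foreground).
#'
#' @param image a [vol_img()].
#' @param k number of robust standard deviations above the mode.
#' @param threshold optional manual threshold; when supplied it bypasses
#'   the computation and is returned unchanged.
#' @return Threshold in counts.
#' @examples
#' img <- vol_img(array(round(rnorm(16^3, 3200, 150)), c(16, 16, 16)),
#'                c(0.1, 0.1, 0.1))
#' select_threshold(img)
#' @export
select_threshold <- function(image, k = 3, threshold = NULL) {
  if (!is.null(threshold) && !identical(threshold, "auto"))
    return(as.numeric(threshold))
  x <- round(as.numeric(image$data))
  rng <- range(x)
  if (rng[1] == rng[2]) stop("degenerate histogram: constant image",
                             call. = FALSE)
  tb <- tabulate(x - rng[1] + 1L)
  mode_v <- rng[1] + which.max(tb) - 1L
  below <- x[x <= mode_v]
  spread <- 1.4826 * median(mode_v - below)
  mode_v + k * spread
}

# discrete ball (spherical-cap height profile) structuring element; the
# height is in count units with unit curvature per pixel, so for typical
# 16-bit intensities it behaves as a paraboloid-capped rolling ball
ball_element <- function(radius) {
  r <- ceiling(radius)
  dy <- rep(-r:r, times = 2 * r + 1)
  dx <- rep(-r:r, each = 2 * r + 1)
  keep <- dy^2 + dx^2 <= radius^2
  dy <- dy[keep]; dx <- dx[keep]
  h <- sqrt(radius^2 - dy^2 - dx^2) - radius  # <= 0, 0 at the centre
  list(offs = cbind(dy, dx), h = h)
}

#' Rolling-ball background subtraction
#'
#' Removes smooth background by subtracting the grayscale opening of each
#' z-plane with a ball-shaped (spherical-cap) structuring element of the
#' given pixel radius — the classical rolling-ball estimate. The output
#' is nonnegative everywhere and exactly zero on constant images.
#'
#' @param image a [vol_img()].
#' @param radius ball radius in pixels (lateral).
#' @return Background-subtracted [vol_img()].
#' @export
subtract_background <- function(image, radius = 10) {
  d <- dim(image$data)
  if (radius < 1) stop("radius must be >= 1 pixel", call. = FALSE)
  if (2 * radius + 1 > min(d[2], d[3]))
    stop("rolling-ball radius exceeds the slice extent", call. = FALSE)
  el <- ball_element(radius)
  er <- cpp_ball_morph2d(as.numeric(image$data), d, el$offs, el$h, 0L)
  op <- cpp_ball_morph2d(er, d, el$offs, el$h, 1L)
  out <- pmax(as.numeric(image$data) - op, 0)
  vol_img(array(out, d), image$spacing, image$channel)
}

#' 3D median filter
#'
#' Each voxel is replaced by the median of its `(2r+1)^3` cubic
#' neighbourhood (edges replicated); removes isolated hot voxels while
#' preserving multi-voxel spots.
#'
#' @param image a [vol_img()].
#' @param radius neighbourhood radius in voxels.
#' @return Filtered [vol_img()].
#' @export
median_filter_3d <- function(image, radius = 1) {
  if (radius < 1) stop("radius must be >= 1 voxel", call. = FALSE)
  d <- dim(image$data)
  out <- cpp_median_filter3d(as.numeric(image$data), d, as.integer(radius))
  vol_img(array(out, d), image$spacing, image$channel)
}

#' Detect spot seeds
#'
#' Seeds are strict 26-neighbourhood local maxima with intensity above
#' `threshold`; an equal-valued plateau that is a maximum yields one seed
#' at its lexicographically smallest `(z, y, x)` index.
#'
#' @param image a [vol_img()] (normally preprocessed).
#' @param threshold intensity threshold in counts.
#' @return Tibble of seed voxels: `z`, `y`, `x` (1-based indices),
#'   `intensity`.
#' @export
detect_seeds <- function(image, threshold) {
  m <- cpp_local_maxima(as.numeric(image$data), dim(image$data),
                        as.numeric(threshold))
  tibble::tibble(z = m[, 1], y = m[, 2], x = m[, 3],
                 intensity = image$data[m])
}

#' Spot-segmentation parameters
#'
#' @param threshold `"auto"` or a numeric count threshold.
#' @param k robust deviations for the auto threshold.
#' @param rolling_ball_radius pixels.
#' @param median_radius voxels.
#' @param min_volume,max_volume object volume bounds in voxels.
#' @param local_contrast_fraction region-growing cutoff as a fraction of
#'   the Gaussian-fitted peak, in (0, 1).
#' @param gaussian_fit_max_radius voxels used for the radial Gaussian fit.
#' @param growth_image which preprocessed image seeds grow on:
#'   `"subtracted"` (background-subtracted; default — at fine voxel
#'   sizes the 3D median fills the valleys between adjacent
#'   diffraction-limited foci and fuses their objects) or `"median"`
#'   (median-filtered; preferable when foci span many voxels).
#' @return List of class `spot_params`.
#' @export
spot_params <- function(threshold = "auto", k = 3, rolling_ball_radius = 10,
                        median_radius = 1, min_volume = 4, max_volume = 2000,
                        local_contrast_fraction = 0.5,
                        gaussian_fit_max_radius = 5,
                        growth_image = c("subtracted", "median")) {
  growth_image <- match.arg(growth_image)
  if (min_volume > max_volume) stop("min_volume must be <= max_volume",
                                    call. = FALSE)
  if (local_contrast_fraction <= 0 || local_contrast_fraction >= 1)
    stop("local_contrast_fraction must lie in (0, 1)", call. = FALSE)
  structure(list(threshold = threshold, k = k,
                 rolling_ball_radius = rolling_ball_radius,
                 median_radius = median_radius, min_volume = min_volume,
                 max_volume = max_volume,
                 local_contrast_fraction = local_contrast_fraction,
                 gaussian_fit_max_radius = gaussian_fit_max_radius,
                 growth_image = growth_image),
            class = "spot_params")
}

# radial Gaussian fit around one seed: peak (counts at the centre) and
# sigma (voxel units, lateral), by linear regression of log intensity on
# squared radius over the in-range samples
fit_radial_gaussian <- function(arr, d, seed, max_r) {
  zr <- max(1, seed[1] - max_r):min(d[1], seed[1] + max_r)
  yr <- max(1, seed[2] - max_r):min(d[2], seed[2] + max_r)
  xr <- max(1, seed[3] - max_r):min(d[3], seed[3] + max_r)
  patch <- arr[zr, yr, xr, drop = FALSE]
  r2 <- outer(outer((zr - seed[1])^2, (yr - seed[2])^2, "+"),
              (xr - seed[3])^2, "+")
  keep <- r2 <= max_r^2
  v <- patch[keep]; rr <- r2[keep]
  base <- min(v)
  pos <- v - base
  use <- pos > max(pos) * 0.05
  if (sum(use) < 3) return(list(peak = arr[seed[1], seed[2], seed[3]], sigma = 1))
  fit <- stats::lm.fit(cbind(1, rr[use]), log(pos[use]))
  slope <- fit$coefficients[2]
  sigma <- if (is.finite(slope) && slope < 0) sqrt(-1 / (2 * slope)) else max_r
  peak <- base + exp(fit$coefficients[1])
  list(peak = max(peak, arr[seed[1], seed[2], seed[3]]), sigma = sigma)
}

#' Seeded 3D spot segmentation
#'
#' For each seed, a radial Gaussian is fitted to the local intensity
#' profile; the object grows as the 26-connected set of voxels with
#' intensity at least `local_contrast_fraction` times the fitted peak,
#' highest-intensity-first, capped at `max_volume` voxels. Contested
#' voxels go to the seed with the higher peak intensity (ties: lower seed
#' index). Objects smaller than `min_volume` voxels are discarded and the
#' survivors relabelled contiguously.
#'
#' @param image a [vol_img()] (preprocessed).
#' @param seeds tibble from [detect_seeds()].
#' @param params a [spot_params()].
#' @return A [label_vol()]; zero objects when `seeds` is empty.
#' @export
segment_spots <- function(image, seeds, params = spot_params()) {
  d <- dim(image$data)
  if (nrow(seeds) == 0)
    return(label_vol(array(0L, d), image$spacing))
  arr <- image$data
  ord <- order(-seeds$intensity, seeds$z, seeds$y, seeds$x)
  seeds <- seeds[ord, ]
  fits <- lapply(seq_len(nrow(seeds)), function(i)
    fit_radial_gaussian(arr, d, c(seeds$z[i], seeds$y[i], seeds$x[i]),
                        params$gaussian_fit_max_radius))
  thr <- vapply(fits, function(f) f$peak, 0) * params$local_contrast_fraction
  lin0 <- (seeds$z - 1) + (seeds$y - 1) * d[1] + (seeds$x - 1) * d[1] * d[2]
  lab <- cpp_grow_spots(as.numeric(arr), d, as.numeric(lin0), thr,
                        as.integer(params$max_volume))
  # volume filter + contiguous relabel (in seed-priority order)
  counts <- tabulate(lab, nbins = nrow(seeds))
  keep <- which(counts >= params$min_volume)
  remap <- integer(nrow(seeds))
  remap[keep] <- seq_along(keep)
  out <- integer(length(lab))
  pos <- lab > 0L
  out[pos] <- remap[lab[pos]]
  label_vol(array(out, d), image$spacing)
}

#' Measure 3D objects
#'
#' Geometric and intensity measurements per labelled object. Centroids
#' are unweighted voxel-centre averages converted to um; `Comp` is the
#' sphericity `36 pi V^2 / S^3` (1 for a ball), with the surface area
#' estimated from exposed voxel faces with the stereological `2/3`
#' orientation correction and clamped to 1; `DC` is the centre-to-border
#' distance, reported as both `DC_min` and `DC_max`. Intensity statistics
#' (`AtCenter`, `IntDen`, `Min`, `Mean`) are taken from `image` (normally
#' the original grayscale stack).
#'
#' @param labels a [label_vol()].
#' @param image a [vol_img()] on the same grid.
#' @return Tibble with columns `object_id`, `CX`, `CY`, `CZ` (um),
#'   `Vol_voxels`, `Vol_um3`, `Comp`, `DC_min`, `DC_max` (um),
#'   `AtCenter`, `IntDen`, `Min`, `Mean`, plus centroid voxel indices
#'   `cz`, `cy`, `cx`.
#' @export
measure_objects <- function(labels, image) {
  if (!identical(dim(labels$labels), dim(image$data)))
    stop("labels and image grids differ", call. = FALSE)
  d <- dim(labels$labels)
  sp <- labels$spacing
  lab <- labels$labels
  idx <- which(lab > 0L)
  if (!length(idx))
    return(tibble::tibble(object_id = integer(), CX = numeric(),
                          CY = numeric(), CZ = numeric(),
                          Vol_voxels = integer(), Vol_um3 = numeric(),
                          Comp = numeric(), DC_min = numeric(),
                          DC_max = numeric(), AtCenter = numeric(),
                          IntDen = numeric(), Min = numeric(),
                          Mean = numeric(), cz = integer(), cy = integer(),
                          cx = integer()))
  li <- lab[idx]
  iz <- ((idx - 1L) %% d[1]) + 1L
  iy <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  ix <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  n <- labels$n_objects
  vol <- tabulate(li, n)
  cz_um <- rowsum(voxel_to_um(iz, sp[1]), li)[, 1] / vol
  cy_um <- rowsum(voxel_to_um(iy, sp[2]), li)[, 1] / vol
  cx_um <- rowsum(voxel_to_um(ix, sp[3]), li)[, 1] / vol
  # exposed faces per axis: neighbour along each direction has another label
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])  # z, y, x faces
  surf <- numeric(n)
  nbr_lab <- function(dz, dy, dx) {
    z2 <- iz + dz; y2 <- iy + dy; x2 <- ix + dx
    inb <- z2 >= 1L & z2 <= d[1] & y2 >= 1L & y2 <= d[2] & x2 >= 1L & x2 <= d[3]
    out <- integer(length(idx))
    out[inb] <- lab[cbind(z2[inb], y2[inb], x2[inb])]
    out
  }
  for (a in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- nbr_lab(if (a == 1) s else 0L, if (a == 2) s else 0L,
                    if (a == 3) s else 0L)
      exposed <- nb != li
      surf <- surf + face_area[a] *
        tabulate(li[exposed], n)
    }
  }
  surf <- surf / 1.5  # orientation-averaged correction of the face estimate
  vol_um3 <- vol * prod(sp)
  comp <- pmin(36 * pi * vol_um3^2 / surf^3, 1)
  # border voxels: any 6-neighbour outside the object
  border <- rep(FALSE, length(idx))
  for (a in 1:3) for (s in c(-1L, 1L)) {
    nb <- nbr_lab(if (a == 1) s else 0L, if (a == 2) s else 0L,
                  if (a == 3) s else 0L)
    border <- border | nb != li
  }
  dcen <- sqrt((voxel_to_um(iz, sp[1]) - cz_um[li])^2 +
               (voxel_to_um(iy, sp[2]) - cy_um[li])^2 +
               (voxel_to_um(ix, sp[3]) - cx_um[li])^2)
  dc_min <- rep(NA_real_, n); dc_max <- rep(NA_real_, n)
  bl <- li[border]; bd <- dcen[border]
  agg_min <- tapply(bd, bl, min); agg_max <- tapply(bd, bl, max)
  dc_min[as.integer(names(agg_min))] <- agg_min
  dc_max[as.integer(names(agg_max))] <- agg_max
  inten <- image$data[idx]
  int_den <- rowsum(inten, li)[, 1]
  int_min <- tapply(inten, li, min)
  int_mean <- int_den / vol
  czv <- pmin(pmax(round(cz_um / sp[1] + 0.5), 1), d[1])
  cyv <- pmin(pmax(round(cy_um / sp[2] + 0.5), 1), d[2])
  cxv <- pmin(pmax(round(cx_um / sp[3] + 0.5), 1), d[3])
  at_center <- image$data[cbind(czv, cyv, cxv)]
  tibble::tibble(object_id = seq_len(n), CX = cx_um, CY = cy_um, CZ = cz_um,
                 Vol_voxels = vol, Vol_um3 = vol_um3, Comp = comp,
                 DC_min = dc_min, DC_max = dc_max, AtCenter = at_center,
                 IntDen = int_den, Min = as.numeric(int_min),
                 Mean = int_mean, cz = as.integer(czv), cy = as.integer(cyv),
                 cx = as.integer(cxv))
}

#' Segment the focus channel end to end
#'
#' The standard spot workflow: rolling-ball background subtraction and 3D
#' median filtering for contrast, automatic threshold selection from the
#' raw-image histogram (the 3000-4000 band refers to raw 16-bit counts;
#' both histograms' modes are recorded), seed detection on the
#' preprocessed image, seeded growth and 3D measurement against the
#' original image.
#'
#' @param image raw focus-channel [vol_img()].
#' @param params a [spot_params()].
#' @param verbose print threshold, seed and object counts.
#' @return List: `objects` (measurement tibble), `labels`
#'   ([label_vol()]), `threshold`, `seeds`, `preprocessed`.
#' @export
segment_spot_channel <- function(image, params = spot_params(),
                                 verbose = FALSE) {
  thr <- select_threshold(image, k = params$k, threshold = params$threshold)
  rb <- subtract_background(image, params$rolling_ball_radius)
  pre <- median_filter_3d(rb, params$median_radius)
  # seeds come from the sharp (background-subtracted) image so that
  # close foci are not fused by the median before detection; the
  # raw-histogram threshold is applied unchanged, its background
  # pedestal acting as a conservative safety margin over the flattened
  # background. Duplicate near-peak seeds resolve during growth (the
  # brighter seed claims the region first).
  seeds <- detect_seeds(rb, thr)
  grow_on <- if (params$growth_image == "median") pre else rb
  labels <- segment_spots(grow_on, seeds, params)
  objects <- measure_objects(labels, image)
  if (verbose)
    message(sprintf("spots: threshold %.1f, %d seeds, %d objects",
                    thr, nrow(seeds), labels$n_objects))
  list(objects = objects, labels = labels, threshold = thr, seeds = seeds,
       preprocessed = pre)
}
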