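#' 3D distance map from a skeletonized axis model
#'
#' Exact Euclidean distance transform with anisotropic physical spacing;
#' every voxel stores the distance in um to the nearest skeleton voxel
#' (exactly 0 on skeleton voxels, and only there).
#'
#' @param skeleton an `axis_skeleton`.
#' @param grid_shape optional `(z, y, x)` voxel counts; defaults to the
#'   skeleton's grid.
#' @param spacing optional `(dz, dy, dx)` um; defaults to the skeleton's.
#' @return A `dist_map`: `data` (3D array, um) plus `spacing`.
#' @export
distance_map_3d <- function(skeleton, grid_shape = skeleton$dim,
                            spacing = skeleton$spacing) {
  if (is.null(skeleton) || nrow(skeleton$voxels) == 0)
    stop("empty skeleton: no seeds for the distance map", call. = FALSE)
  seed <- array(0L, grid_shape)
  seed[skeleton$voxels] <- 1L
  dm <- array(cpp_edt3d(as.integer(seed), grid_shape, spacing), grid_shape)
  structure(list(data = dm, spacing = as.numeric(spacing)),
            class = "dist_map")
}

#' @export
print.dist_map <- function(x, ...) {
  cat(sprintf("<dist_map> %s voxels, range [0, %.3f] um\n",
              paste(dim(x$data), collapse = " x "), max(x$data)))
  invisible(x)
}

#' Per-object distances to the nearest axis
#'
#' Reads the distance map at each object: `dist_at_center_um` at the
#' centroid voxel, `dist_min_um` as the minimum over the object's mask
#' voxels, `dist_mean_um` as the mask mean. An object is axis-associated
#' exactly when its minimal distance is zero, i.e. its mask overlaps a
#' skeleton voxel.
#'
#' @param labels a [label_vol()].
#' @param objects measurement tibble from [measure_objects()] (supplies
#'   centroid voxels).
#' @param dmap a [distance_map_3d()] result on the same grid.
#' @return `objects` with `dist_at_center_um`, `dist_min_um`,
#'   `dist_mean_um` and `is_axis_associated` appended.
#' @export
object_axis_distances <- function(labels, objects, dmap) {
  if (!identical(dim(labels$labels), dim(dmap$data)))
    stop("label volume and distance map grids differ", call. = FALSE)
  n <- labels$n_objects
  if (nrow(objects) != n || !identical(sort(objects$object_id), seq_len(n)))
    stop("objects table does not match the label volume", call. = FALSE)
  if (n == 0)
    return(dplyr::mutate(objects, dist_at_center_um = numeric(0),
                         dist_min_um = numeric(0), dist_mean_um = numeric(0),
                         is_axis_associated = logical(0)))
  idx <- which(labels$labels > 0L)
  li <- labels$labels[idx]
  dv <- dmap$data[idx]
  dmin <- rep(NA_real_, n); dmean <- rep(NA_real_, n)
  mn <- tapply(dv, li, min); me <- tapply(dv, li, mean)
  dmin[as.integer(names(mn))] <- mn
  dmean[as.integer(names(me))] <- me
  ord <- order(objects$object_id)
  objects <- objects[ord, ]
  at_center <- dmap$data[cbind(objects$cz, objects$cy, objects$cx)]
  dplyr::mutate(objects,
                dist_at_center_um = at_center,
                dist_min_um = dmin,
                dist_mean_um = dmean,
                is_axis_associated = classify_association(dmin))
}

#' Strict zero-distance axis association
#'
#' A focus is axis-associated exactly when the minimal distance from its
#' mask to the skeletonized axis equals zero — its voxel mask overlaps at
#' least one skeleton voxel. No tolerance is applied.
#'
#' @param dist_min numeric vector of minimal distances (um).
#' @return Logical vector.
#' @export
classify_association <- function(dist_min) dist_min == 0

#' Distance distribution summary
#'
#' Histogram of per-object minimal distances with half-open bins
#' `[k w, (k+1) w)`, the empirical fraction within any radius, and the
#' median.
#'
#' @param records tibble with `dist_min_um` (e.g. from
#'   [object_axis_distances()]).
#' @param bin_width um.
#' @return A `dist_distribution`: `bins` tibble (`bin_lo`, `bin_hi`,
#'   `count`), `fraction_within` (function of radius), `median_um`,
#'   `n_objects`.
#' @export
distance_distribution <- function(records, bin_width = 0.1) {
  d <- records$dist_min_um
  if (!length(d)) stop("no distance records", call. = FALSE)
  k <- floor(d / bin_width)
  counts <- table(k)
  lo <- as.integer(names(counts)) * bin_width
  bins <- tibble::tibble(bin_lo = lo, bin_hi = lo + bin_width,
                         count = as.integer(counts))
  structure(list(bins = bins,
                 fraction_within = function(r) mean(d <= r),
                 median_um = median(d),
                 n_objects = length(d)),
            class = "dist_distribution")
}

#' @export
print.dist_distribution <- function(x, ...) {
  cat(sprintf("<dist_distribution> n = %d, median %.3f um, %.1f%% within 0.6 um\n",
              x$n_objects, x$median_um, 100 * x$fraction_within(0.6)))
  invisible(x)
}
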