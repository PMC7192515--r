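#' Total skeleton length
#'
#' Sum over traced branches of the physical step lengths between
#' consecutive skeleton voxels (26-connected steps, spacing-aware).
#' Branches partition the skeleton's edges, so junction voxels shared by
#' several branches are not double-counted as steps.
#'
#' @param skeleton an `axis_skeleton`, or `NULL`/empty for a zero
#'   result (with a warning).
#' @return Tibble: `total_length_um`, `total_length_mm`, `n_branches`,
#'   plus per-branch lengths in the `branch_lengths_um` list-column.
#' @export
skeleton_total_length <- function(skeleton) {
  if (is.null(skeleton) || nrow(skeleton$voxels) == 0) {
    warning("empty skeleton: length 0")
    return(tibble::tibble(total_length_um = 0, total_length_mm = 0,
                          n_branches = 0L,
                          branch_lengths_um = list(numeric())))
  }
  tibble::tibble(total_length_um = skeleton$total_length,
                 total_length_mm = skeleton$total_length / 1000,
                 n_branches = length(skeleton$branches),
                 branch_lengths_um = list(skeleton$branch_lengths))
}

# algebraic least-squares circle fit on 2D points (exact on noise-free
# arcs); collinear/rank-deficient windows give an infinite radius
circle_fit_radius <- function(xy) {
  u <- xy[, 1] - mean(xy[, 1]); v <- xy[, 2] - mean(xy[, 2])
  # collinear (or numerically collinear) windows have no finite circle
  sv <- svd(cbind(u, v), nu = 0, nv = 0)$d
  if (sv[2] <= 1e-9 * max(sv[1], 1e-300)) return(Inf)
  z <- u^2 + v^2
  A <- cbind(2 * u, 2 * v, 1)
  qrA <- qr(A)
  if (qrA$rank < 3) return(Inf)
  sol <- qr.coef(qrA, z)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) return(Inf)
  sqrt(r2)
}

#' Per-point curvature by local circle fitting (kappa = 1/r)
#'
#' For each interior point, a circle is fitted by algebraic least squares
#' to the `window` points centred on it — in the
#' plane for 2D traces, in the best-fit local plane (principal-component
#' projection) for 3D — and kappa is the reciprocal of the fitted
#' radius. Radii are capped at 1e6 um, so straight runs give kappa
#' 1e-6 ~ 0 rather than undefined. Endpoints take the nearest computable
#' value.
#'
#' @param points n x 2 or n x 3 matrix of ordered coordinates (um).
#' @param window odd number of points per fit (>= 3).
#' @return A `curve_measure` tibble: `point_index`, `kappa` (um^-1),
#'   with attribute `average_kappa`; also accessible via
#'   `$average_kappa` of the returned object.
#' @export
fit_kappa <- function(points, window = 7) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3",
                                           call. = FALSE)
  if (n < window) stop(sprintf("need at least %d points, got %d", window, n),
                       call. = FALSE)
  half <- (window - 1) / 2
  cap <- 1e6
  kap <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) {
    w <- points[(i - half):(i + half), , drop = FALSE]
    if (ncol(w) == 2) {
      r <- circle_fit_radius(w)
    } else {
      cen <- colMeans(w)
      wc <- sweep(w, 2, cen)
      sv <- svd(wc, nu = 0, nv = 2)
      r <- circle_fit_radius(wc %*% sv$v)
    }
    r <- min(r, cap)
    kap[i] <- 1 / r
  }
  kap[seq_len(half)] <- kap[half + 1]
  kap[(n - half + 1):n] <- kap[n - half]
  out <- tibble::tibble(point_index = seq_len(n), kappa = kap)
  class(out) <- c("curve_measure", class(out))
  attr(out, "average_kappa") <- mean(kap)
  out
}

#' @export
`$.curve_measure` <- function(x, name) {
  if (identical(name, "average_kappa")) return(attr(x, "average_kappa"))
  NextMethod()
}

#' Curvature of skeleton branches
#'
#' Resamples each branch polyline at uniform spacing (smoothing the
#' voxel staircase with a short moving average first), then runs
#' [fit_kappa()]. Branches shorter than the fit window are excluded from
#' curvature (they still count toward length).
#'
#' @param skeleton an `axis_skeleton`.
#' @param window odd point count for the circle fit.
#' @param resample_um spacing of the resampled polyline.
#' @param smooth_points moving-average half-window (points) applied to
#'   the voxel polyline before resampling.
#' @return Tibble: `branch_id`, `length_um`, `average_kappa`, and the
#'   pooled per-point kappas as a list-column `kappas`.
#' @export
branch_curvatures <- function(skeleton, window = 7, resample_um = 0.3,
                              smooth_points = 5) {
  sp <- skeleton$spacing
  res <- lapply(seq_along(skeleton$branches), function(i) {
    b <- skeleton$branches[[i]]
    v <- skeleton$voxels[b, , drop = FALSE]
    pts <- cbind(voxel_to_um(v[, 1], sp[1]), voxel_to_um(v[, 2], sp[2]),
                 voxel_to_um(v[, 3], sp[3]))
    if (nrow(pts) >= 2 * smooth_points + 1 && smooth_points > 0) {
      k <- 2 * smooth_points + 1
      sm <- apply(pts, 2, function(cc)
        as.numeric(stats::filter(cc, rep(1 / k, k), sides = 2)))
      keep <- !is.na(sm[, 1])
      pts <- rbind(pts[1, ], sm[keep, , drop = FALSE], pts[nrow(pts), ])
    }
    pts <- resample_polyline(pts, resample_um)
    if (nrow(pts) < window) return(NULL)
    fk <- fit_kappa(pts, window)
    tibble::tibble(branch_id = i,
                   length_um = skeleton$branch_lengths[i],
                   average_kappa = attr(fk, "average_kappa"),
                   kappas = list(fk$kappa))
  })
  dplyr::bind_rows(res)
}

#' Pooled curvature distribution of a cell
#'
#' Pools per-point kappa values over all measured curves and reports the
#' median, quartiles and a histogram; two cells/cohorts can be compared
#' by binding the outputs.
#'
#' @param curves tibble from [branch_curvatures()] (or any table with a
#'   `kappas` list-column), or a list of [fit_kappa()] results.
#' @param bin_width histogram bin width (um^-1).
#' @return A `kappa_distribution`: `pooled` (numeric vector), `median`,
#'   `q1`, `q3`, `bins` tibble.
#' @export
cell_curvature_distribution <- function(curves, bin_width = 0.1) {
  pooled <- if (is.data.frame(curves)) unlist(curves$kappas)
            else unlist(lapply(curves, function(cm) cm$kappa))
  pooled <- pooled[is.finite(pooled)]
  if (!length(pooled)) stop("no curvature values", call. = FALSE)
  k <- floor(pooled / bin_width)
  counts <- table(k)
  lo <- as.integer(names(counts)) * bin_width
  structure(list(pooled = pooled,
                 median = median(pooled),
                 q1 = unname(quantile(pooled, 0.25)),
                 q3 = unname(quantile(pooled, 0.75)),
                 bins = tibble::tibble(bin_lo = lo, bin_hi = lo + bin_width,
                                       count = as.integer(counts))),
            class = "kappa_distribution")
}

#' @export
print.kappa_distribution <- function(x, ...) {
  cat(sprintf("<kappa_distribution> n = %d points, median %.3f [Q1 %.3f, Q3 %.3f] um^-1\n",
              length(x$pooled), x$median, x$q1, x$q3))
  invisible(x)
}

#' @export
glance.kappa_distribution <- function(x, ...) {
  tibble::tibble(n_points = length(x$pooled), median_kappa = x$median,
                 q1_kappa = x$q1, q3_kappa = x$q3)
}

#' Synapsis fraction from two skeletons
#'
#' Percentage of the axis (DSY2-like) skeleton length covered by the
#' transverse-filament (ZYP1-like) skeleton length. Values above 100%
#' are flagged, not clamped.
#'
#' @param zyp1_skeleton `axis_skeleton` of the synapsis channel, or
#'   `NULL` for none (0%).
#' @param dsy2_skeleton `axis_skeleton` of the axis channel (required,
#'   nonempty).
#' @return Tibble: `zyp1_length_um`, `dsy2_length_um`,
#'   `percent_synapsed`, `flag_over_100`.
#' @export
synapsis_fraction <- function(zyp1_skeleton, dsy2_skeleton) {
  if (is.null(dsy2_skeleton) || nrow(dsy2_skeleton$voxels) == 0)
    stop("empty DSY2 skeleton: synapsis fraction undefined", call. = FALSE)
  dsy2 <- dsy2_skeleton$total_length
  zyp1 <- if (is.null(zyp1_skeleton)) 0 else zyp1_skeleton$total_length
  pct <- 100 * zyp1 / dsy2
  tibble::tibble(zyp1_length_um = zyp1, dsy2_length_um = dsy2,
                 percent_synapsed = pct, flag_over_100 = pct > 100)
}
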