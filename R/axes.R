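#' White top-hat filter
#'
#' Removes smooth background from the axis channel by subtracting the
#' grayscale opening of each z-plane with a flat disk of the given pixel
#' radius. Output is nonnegative and pointwise no larger than the input.
#'
#' @param image a [vol_img()].
#' @param radius disk radius in pixels.
#' @return Filtered [vol_img()].
#' @export
tophat_filter <- function(image, radius = 15) {
  d <- dim(image$data)
  if (radius < 1 || 2 * radius + 1 > min(d[2], d[3]))
    stop("top-hat radius out of range for the slice extent", call. = FALSE)
  brush <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
  mx <- max(image$data)
  if (mx == 0) return(image)
  out <- array(0, d)
  for (z in seq_len(d[1])) {
    sl <- matrix(image$data[z, , ] / mx, d[2], d[3])
    out[z, , ] <- as.matrix(EBImage::opening(sl, brush)) * mx
  }
  res <- pmax(image$data - out, 0)
  vol_img(res, image$spacing, image$channel)
}

feature_kinds <- c("gaussian", "dog", "gradmag", "hess1", "hess2", "hess3")

# Hessian of a 3D array at physical scale sigma; returns the six distinct
# second derivatives (spacing-aware separable Gaussian derivatives)
hessian3d <- function(arr, spacing, sigma) {
  k0 <- lapply(1:3, function(a) gauss_kernel(sigma, spacing[a], 0))
  k1 <- lapply(1:3, function(a) gauss_kernel(sigma, spacing[a], 1))
  k2 <- lapply(1:3, function(a) gauss_kernel(sigma, spacing[a], 2))
  H <- list()
  H$zz <- conv3_sep(arr, list(k2[[1]], k0[[2]], k0[[3]]))
  H$yy <- conv3_sep(arr, list(k0[[1]], k2[[2]], k0[[3]]))
  H$xx <- conv3_sep(arr, list(k0[[1]], k0[[2]], k2[[3]]))
  H$zy <- conv3_sep(arr, list(k1[[1]], k1[[2]], k0[[3]]))
  H$zx <- conv3_sep(arr, list(k1[[1]], k0[[2]], k1[[3]]))
  H$yx <- conv3_sep(arr, list(k0[[1]], k1[[2]], k1[[3]]))
  H
}

#' Compute a per-voxel feature stack
#'
#' Multi-scale filter bank used by the trainable voxel classifier:
#' Gaussian smoothing, difference of Gaussians (sigma vs 2 sigma),
#' gradient magnitude and the three sorted Hessian eigenvalues, at each
#' scale — six features per scale. Derivatives are computed in physical
#' units, so anisotropic spacing is handled.
#'
#' @param image a [vol_img()].
#' @param scales Gaussian scales in um.
#' @return A `feature_stack`: `features` (voxels x features matrix),
#'   `dim`, `spacing`, `scales`, `feature_names`.
#' @export
compute_feature_stack <- function(image, scales = c(0.08, 0.15, 0.3, 0.6)) {
  stopifnot(length(scales) >= 1, all(scales > 0))
  arr <- image$data
  d <- dim(arr)
  sp <- image$spacing
  nf <- 6L * length(scales)
  fm <- matrix(NA_real_, length(arr), nf)
  nms <- character(nf)
  j <- 0L
  for (s in scales) {
    g1 <- gaussian_smooth3d(arr, sp, s)
    g2 <- gaussian_smooth3d(arr, sp, 2 * s)
    dz <- conv3_sep(arr, list(gauss_kernel(s, sp[1], 1),
                              gauss_kernel(s, sp[2], 0),
                              gauss_kernel(s, sp[3], 0)))
    dy <- conv3_sep(arr, list(gauss_kernel(s, sp[1], 0),
                              gauss_kernel(s, sp[2], 1),
                              gauss_kernel(s, sp[3], 0)))
    dx <- conv3_sep(arr, list(gauss_kernel(s, sp[1], 0),
                              gauss_kernel(s, sp[2], 0),
                              gauss_kernel(s, sp[3], 1)))
    H <- hessian3d(arr, sp, s)
    eig <- cpp_sym3_eigs(as.numeric(H$zz), as.numeric(H$yy),
                         as.numeric(H$xx), as.numeric(H$zy),
                         as.numeric(H$zx), as.numeric(H$yx))
    fm[, j + 1L] <- as.numeric(g1)
    fm[, j + 2L] <- as.numeric(g1) - as.numeric(g2)
    fm[, j + 3L] <- sqrt(as.numeric(dz)^2 + as.numeric(dy)^2 +
                         as.numeric(dx)^2)
    fm[, j + 4L] <- eig[, 1]
    fm[, j + 5L] <- eig[, 2]
    fm[, j + 6L] <- eig[, 3]
    nms[j + 1:6] <- paste0(feature_kinds, "_s", s)
    j <- j + 6L
  }
  colnames(fm) <- nms
  structure(list(features = fm, dim = d, spacing = sp, scales = scales,
                 feature_names = nms),
            class = "feature_stack")
}

#' Train a voxel classifier from sparse scribbles
#'
#' Fits a seeded random-forest probability classifier (axis vs
#' background) on the feature vectors at scribbled voxels, standing in
#' for interactive trainable-segmentation tools.
#'
#' @param features a [compute_feature_stack()] result.
#' @param scribbles integer 3D array on the same grid: 0 unlabelled,
#'   1 axis, 2 background.
#' @param seed integer; the classifier is deterministic given the seed.
#' @param num_trees forest size.
#' @return A `voxel_classifier` with training metadata.
#' @export
train_voxel_classifier <- function(features, scribbles, seed = 1,
                                   num_trees = 100) {
  if (!identical(dim(scribbles), features$dim))
    stop("scribbles grid does not match the feature stack", call. = FALSE)
  idx <- which(scribbles > 0L)
  cls <- factor(ifelse(scribbles[idx] == 1L, "axis", "background"),
                levels = c("axis", "background"))
  if (length(unique(cls)) < 2)
    stop("scribbles must contain both classes", call. = FALSE)
  df <- as.data.frame(features$features[idx, , drop = FALSE])
  df$.class <- cls
  fit <- ranger::ranger(dependent.variable.name = ".class", data = df,
                        probability = TRUE, seed = seed,
                        num.trees = num_trees, num.threads = 1)
  structure(list(model = fit,
                 feature_config = list(scales = features$scales,
                                       feature_names = features$feature_names),
                 class_counts = table(cls), seed = seed),
            class = "voxel_classifier")
}

#' Classify voxels into an axis mask
#'
#' Applies a trained [train_voxel_classifier()] model to a feature stack
#' and thresholds the axis probability. For classifier-free use, build
#' the mask directly with [threshold_mask()].
#'
#' @param classifier a `voxel_classifier`.
#' @param features a [compute_feature_stack()] result with the same
#'   feature configuration the classifier was trained on.
#' @param prob_cutoff probability cutoff (default 0.5).
#' @return An `axis_mask`: logical 3D array plus spacing.
#' @export
classify_voxels <- function(classifier, features, prob_cutoff = 0.5) {
  if (!identical(classifier$feature_config$feature_names,
                 features$feature_names))
    stop("feature configuration does not match the classifier", call. = FALSE)
  df <- as.data.frame(features$features)
  pr <- predict(classifier$model, df, num.threads = 1)$predictions[, "axis"]
  axis_mask(array(pr >= prob_cutoff, features$dim), features$spacing,
            probability = array(pr, features$dim))
}

#' Threshold fallback axis mask
#'
#' @param image a [vol_img()].
#' @param threshold counts; `"otsu"` picks the Otsu threshold of the
#'   image.
#' @return An `axis_mask`.
#' @export
threshold_mask <- function(image, threshold = "otsu") {
  thr <- if (identical(threshold, "otsu"))
    otsu_threshold(as.numeric(image$data)) else as.numeric(threshold)
  axis_mask(image$data >= thr, image$spacing)
}

#' @rdname classify_voxels
#' @param mask logical 3D array.
#' @param spacing voxel spacing (um).
#' @param probability optional probability array.
#' @export
axis_mask <- function(mask, spacing, probability = NULL) {
  structure(list(mask = mask, spacing = as.numeric(spacing),
                 probability = probability),
            class = "axis_mask")
}

#' Hessian tubeness enhancement
#'
#' Scores bright curvilinear (tube-like) structures: with Hessian
#' eigenvalues `l1 >= l2 >= l3` at physical scale `sigma`, the score is
#' `sigma^2 * sqrt(l2 * l3)` where both are negative, else 0. For
#' single-plane volumes the 2D analogue `sigma^2 * |l2|` (smaller
#' eigenvalue, where negative) is used.
#'
#' @param image a [vol_img()].
#' @param sigma scale in um, normally the expected tube radius.
#' @return Tubeness [vol_img()].
#' @export
tubeness <- function(image, sigma) {
  stopifnot(sigma > 0)
  d <- dim(image$data)
  sp <- image$spacing
  if (d[1] == 1L) {
    arr2 <- image$data
    k0y <- gauss_kernel(sigma, sp[2], 0); k2y <- gauss_kernel(sigma, sp[2], 2)
    k1y <- gauss_kernel(sigma, sp[2], 1)
    k0x <- gauss_kernel(sigma, sp[3], 0); k2x <- gauss_kernel(sigma, sp[3], 2)
    k1x <- gauss_kernel(sigma, sp[3], 1)
    hyy <- conv3_sep(arr2, list(NULL, k2y, k0x))
    hxx <- conv3_sep(arr2, list(NULL, k0y, k2x))
    hyx <- conv3_sep(arr2, list(NULL, k1y, k1x))
    tr <- hyy + hxx
    dt <- sqrt(pmax((hyy - hxx)^2 + 4 * hyx^2, 0))
    l2 <- (tr - dt) / 2
    sc <- ifelse(l2 < 0, sigma^2 * abs(l2), 0)
    return(vol_img(array(sc, d), sp, image$channel))
  }
  H <- hessian3d(image$data, sp, sigma)
  sc <- cpp_tubeness_score(as.numeric(H$zz), as.numeric(H$yy),
                           as.numeric(H$xx), as.numeric(H$zy),
                           as.numeric(H$zx), as.numeric(H$yx), sigma^2)
  vol_img(array(sc, d), sp, image$channel)
}

# Tip reconstruction: directional thinning retracts tube end caps by about
# one voxel; extend each free endpoint of a long branch along its terminal
# tangent while the continuation stays inside the original mask and does
# not touch other skeleton voxels. Short branches (blob remnants) are left
# alone so compact objects keep their point-like skeletons.
extend_skeleton_tips <- function(sk, mask, min_branch_pts = 10,
                                 ext_max = 20) {
  vox <- sk$voxels
  have <- array(FALSE, sk$dim)
  have[vox] <- TRUE
  add <- list()
  for (i in seq_along(sk$branches)) {
    b <- sk$branches[[i]]
    if (sk$cyclic[i] || length(b) < min_branch_pts) next
    for (side in 1:2) {
      tipi <- if (side == 1) b[1] else b[length(b)]
      if (sk$degree[tipi] != 1) next
      k <- min(5, length(b) - 1)
      backi <- if (side == 1) b[1 + k] else b[length(b) - k]
      tang <- vox[tipi, ] - vox[backi, ]
      nt <- sqrt(sum(tang^2))
      if (nt == 0) next
      tang <- tang / nt
      off <- round(tang)
      if (all(off == 0)) next
      cur <- vox[tipi, ]
      for (s in seq_len(ext_max)) {
        nxt <- cur + off
        if (any(nxt < 1) || any(nxt > sk$dim)) break
        if (!mask[nxt[1], nxt[2], nxt[3]]) break
        if (have[nxt[1], nxt[2], nxt[3]]) break
        # refuse continuations that would fuse into another branch
        zr <- max(1, nxt[1] - 1):min(sk$dim[1], nxt[1] + 1)
        yr <- max(1, nxt[2] - 1):min(sk$dim[2], nxt[2] + 1)
        xr <- max(1, nxt[3] - 1):min(sk$dim[3], nxt[3] + 1)
        if (sum(have[zr, yr, xr]) > 1) break
        add[[length(add) + 1]] <- nxt
        have[nxt[1], nxt[2], nxt[3]] <- TRUE
        cur <- nxt
      }
    }
  }
  if (!length(add)) return(sk)
  newvox <- rbind(vox, do.call(rbind, add))
  storage.mode(newvox) <- "integer"
  skeleton_from_voxels(newvox, sk$dim, sk$spacing)
}

# build an axis_skeleton object from a set of skeleton voxels
skeleton_from_voxels <- function(vox, dim, spacing) {
  if (!nrow(vox)) stop("empty skeleton", call. = FALSE)
  g <- cpp_skeleton_graph(vox, dim, spacing)
  branches <- g$branches
  step_len <- function(b) {
    if (length(b) < 2) return(0)
    p <- vox[b, , drop = FALSE]
    dif <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
    sum(sqrt((dif[, 1] * spacing[1])^2 + (dif[, 2] * spacing[2])^2 +
             (dif[, 3] * spacing[3])^2))
  }
  br_len <- vapply(branches, step_len, 0)
  structure(list(voxels = vox, dim = dim, spacing = spacing,
                 branches = branches, cyclic = g$cyclic, degree = g$degree,
                 n_edges = g$n_edges, branch_lengths = br_len,
                 total_length = sum(br_len)),
            class = "axis_skeleton")
}

#' 3D skeletonization
#'
#' Topology-preserving iterative thinning of a binary mask to unit-width
#' 26-connected medial lines (simple-point deletion with curve-endpoint
#' preservation, six directional subiterations). Connected components and
#' loops of the mask are preserved.
#'
#' @param mask an `axis_mask` or logical 3D array.
#' @param spacing required when `mask` is a bare array.
#' @param priority optional 3D intensity array; when supplied, thinning
#'   deletes dimmest border voxels first so the medial line tracks the
#'   intensity ridge (ordered thinning).
#' @return An `axis_skeleton`: skeleton voxels, traced branches, degrees
#'   and total physical length.
#' @export
skeletonize_3d <- function(mask, spacing = NULL, priority = NULL) {
  if (inherits(mask, "axis_mask")) {
    spacing <- mask$spacing
    mask <- mask$mask
  }
  if (is.null(spacing)) stop("spacing required", call. = FALSE)
  d <- dim(mask)
  if (!any(mask)) stop("empty mask: nothing to skeletonize", call. = FALSE)
  thin <- cpp_thin3d(as.integer(mask), d,
                     if (is.null(priority)) numeric(0) else
                       as.numeric(priority))
  idx <- which(thin == 1L)
  vox <- cbind(((idx - 1L) %% d[1]) + 1L,
               (((idx - 1L) %/% d[1]) %% d[2]) + 1L,
               ((idx - 1L) %/% (d[1] * d[2])) + 1L)
  storage.mode(vox) <- "integer"
  sk <- skeleton_from_voxels(vox, d, spacing)
  extend_skeleton_tips(sk, mask)
}

#' @export
print.axis_skeleton <- function(x, ...) {
  cat(sprintf("<axis_skeleton> %d voxels, %d branches, total length %.2f um\n",
              nrow(x$voxels), length(x$branches), x$total_length))
  invisible(x)
}

#' Prune short terminal branches
#'
#' Iteratively removes spur branches — branches with a free endpoint
#' (degree 1) attached to a junction — shorter than `min_branch_length`.
#' Isolated open paths are never removed. Idempotent.
#'
#' @param skeleton an `axis_skeleton`.
#' @param min_branch_length um.
#' @return Pruned `axis_skeleton`.
#' @export
prune_skeleton <- function(skeleton, min_branch_length = 0.5) {
  if (min_branch_length <= 0) return(skeleton)
  sk <- skeleton
  repeat {
    deg <- sk$degree
    drop_vox <- integer()
    for (i in seq_along(sk$branches)) {
      b <- sk$branches[[i]]
      if (sk$cyclic[i] || length(b) < 2) next
      d1 <- deg[b[1]]; d2 <- deg[b[length(b)]]
      spur <- (d1 == 1 && d2 >= 3) || (d2 == 1 && d1 >= 3)
      if (spur && sk$branch_lengths[i] < min_branch_length) {
        keep_end <- if (d1 >= 3) b[1] else b[length(b)]
        drop_vox <- c(drop_vox, setdiff(b, keep_end))
      }
    }
    drop_vox <- unique(drop_vox)
    if (!length(drop_vox)) break
    vox <- sk$voxels[-drop_vox, , drop = FALSE]
    if (!nrow(vox)) break
    sk <- skeleton_from_voxels(vox, sk$dim, sk$spacing)
  }
  sk
}

#' Trace skeleton branches
#'
#' Decomposes the skeleton at junction voxels (degree >= 3). Each branch
#' runs endpoint-to-junction, junction-to-junction or
#' endpoint-to-endpoint; an isolated cycle yields one cyclic branch
#' starting (and ending) at its lexicographically smallest voxel.
#'
#' @param skeleton an `axis_skeleton`.
#' @return Tibble: `branch_id`, `point_index`, `z`, `y`, `x` (voxel
#'   indices), `z_um`, `y_um`, `x_um`, `cyclic`.
#' @export
trace_branches <- function(skeleton) {
  sp <- skeleton$spacing
  dplyr::bind_rows(lapply(seq_along(skeleton$branches), function(i) {
    b <- skeleton$branches[[i]]
    v <- skeleton$voxels[b, , drop = FALSE]
    tibble::tibble(branch_id = i, point_index = seq_along(b),
                   z = v[, 1], y = v[, 2], x = v[, 3],
                   z_um = voxel_to_um(v[, 1], sp[1]),
                   y_um = voxel_to_um(v[, 2], sp[2]),
                   x_um = voxel_to_um(v[, 3], sp[3]),
                   cyclic = skeleton$cyclic[i])
  }))
}

#' @export
tidy.axis_skeleton <- function(x, ...) {
  tibble::tibble(branch_id = seq_along(x$branches),
                 n_points = lengths(x$branches),
                 length_um = x$branch_lengths,
                 cyclic = x$cyclic)
}

#' @export
glance.axis_skeleton <- function(x, ...) {
  msk <- array(0L, x$dim)
  msk[x$voxels] <- 1L
  comp <- max(cpp_label26(as.integer(msk), x$dim))
  tibble::tibble(n_voxels = nrow(x$voxels),
                 n_branches = length(x$branches),
                 n_edges = x$n_edges,
                 n_components = comp,
                 cycle_rank = as.integer(x$n_edges - nrow(x$voxels) + comp),
                 total_length_um = x$total_length)
}

#' Axis-channel parameters
#'
#' @param tophat_radius pixels.
#' @param threshold `"otsu"` or counts (used when no classifier is
#'   given).
#' @param tubeness_sigma um; default is a typical axial-element tube
#'   radius.
#' @param prob_cutoff classifier probability cutoff.
#' @param prune_length um; spurs shorter than this are removed.
#' @param min_component_voxels connected components of the binarized
#'   tubeness smaller than this are dropped before skeletonization.
#' @return List of class `axis_params`.
#' @export
axis_params <- function(tophat_radius = 15, threshold = "otsu",
                        tubeness_sigma = 0.1, prob_cutoff = 0.5,
                        prune_length = 0.5, min_component_voxels = 27) {
  structure(list(tophat_radius = tophat_radius, threshold = threshold,
                 tubeness_sigma = tubeness_sigma, prob_cutoff = prob_cutoff,
                 prune_length = prune_length,
                 min_component_voxels = min_component_voxels),
            class = "axis_params")
}

#' Segment the axis channel end to end
#'
#' Fixed processing order: top-hat background removal, voxel
#' classification (or intensity threshold fallback), tubeness on the
#' masked intensity, binarization at the Otsu threshold of the in-mask
#' tubeness, small-component removal, 3D skeletonization and spur
#' pruning.
#'
#' @param image raw axis-channel [vol_img()].
#' @param params an [axis_params()].
#' @param classifier optional `voxel_classifier`; when supplied, the mask
#'   comes from [classify_voxels()] on [compute_feature_stack()] of the
#'   top-hat image.
#' @param verbose print mask and skeleton summaries.
#' @return List: `skeleton` (pruned `axis_skeleton`), `mask`
#'   (`axis_mask`), `tubeness` ([vol_img()]), `tophat`.
#' @export
segment_axis_channel <- function(image, params = axis_params(),
                                 classifier = NULL, verbose = FALSE) {
  th <- tophat_filter(image, params$tophat_radius)
  mask <- if (!is.null(classifier)) {
    fs <- compute_feature_stack(th)
    classify_voxels(classifier, fs, params$prob_cutoff)
  } else {
    threshold_mask(th, params$threshold)
  }
  masked <- th$data * mask$mask
  tb <- tubeness(vol_img(masked, image$spacing, image$channel),
                 params$tubeness_sigma)
  vals <- tb$data[mask$mask & tb$data > 0]
  if (!length(vals)) stop("no tubular signal found in the axis mask",
                          call. = FALSE)
  bin <- (tb$data >= otsu_threshold(vals)) & mask$mask
  lab <- cpp_label26(as.integer(bin), dim(bin))
  cnt <- tabulate(lab)
  keep <- which(cnt >= params$min_component_voxels)
  bin <- array(lab %in% keep & lab > 0, dim(bin))
  sk <- skeletonize_3d(axis_mask(bin, image$spacing), priority = tb$data)
  sk <- prune_skeleton(sk, params$prune_length)
  if (verbose)
    message(sprintf("axes: mask %d voxels, skeleton %d voxels, %.1f um",
                    sum(mask$mask), nrow(sk$voxels), sk$total_length))
  list(skeleton = sk, mask = mask, tubeness = tb, tophat = th)
}
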