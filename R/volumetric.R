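#' Volumetric image container
#'
#' A `vol_img` wraps a 3D numeric array of voxel intensities together with
#' its physical voxel spacing. Arrays are stored with dimensions
#' `(z, y, x)`, so `img$data[z, y, x]` addresses one voxel; spacing is
#' `(dz, dy, dx)` in micrometres. Intensities are kept real-valued
#' internally; 16-bit quantization happens only at simulation/file
#' boundaries.
#'
#' @param data numeric 3D array, dimensions `(z, y, x)`, intensities >= 0.
#' @param spacing numeric length-3, voxel pitch `(dz, dy, dx)` in um.
#' @param channel optional channel label (e.g. `"focus"`, `"axis"`).
#' @return An object of class `vol_img`.
#' @examples
#' img <- vol_img(array(0, c(4, 8, 8)), spacing = c(0.125, 0.04, 0.04))
#' dim(img)
#' @export
vol_img <- function(data, spacing, channel = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values (dz, dy, dx) in um",
         call. = FALSE)
  if (any(data < 0)) stop("intensities must be nonnegative", call. = FALSE)
  structure(list(data = data, spacing = spacing, channel = as.character(channel)),
            class = "vol_img")
}

#' @export
dim.vol_img <- function(x) dim(x$data)

#' @export
print.vol_img <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol_img%s> %d x %d x %d voxels (z, y, x)\n",
              if (nzchar(x$channel)) paste0(" ", x$channel) else "",
              d[1], d[2], d[3]))
  cat(sprintf("  spacing: %.4g x %.4g x %.4g um; extent %.3g x %.3g x %.3g um\n",
              x$spacing[1], x$spacing[2], x$spacing[3],
              d[1] * x$spacing[1], d[2] * x$spacing[2], d[3] * x$spacing[3]))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Label volume container
#'
#' Integer labels on the same grid as a [vol_img()]; 0 is background and
#' labels form the contiguous set `1..n_objects`. Objects are
#' 26-connected.
#'
#' @param labels integer 3D array `(z, y, x)`.
#' @param spacing voxel spacing `(dz, dy, dx)` in um.
#' @return An object of class `label_vol`.
#' @export
label_vol <- function(labels, spacing) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  storage.mode(labels) <- "integer"
  n <- max(labels, 0L)
  present <- sort(unique(as.integer(labels[labels > 0L])))
  if (length(present) && !identical(present, seq_len(n)))
    stop("labels must form a contiguous set 1..n_objects", call. = FALSE)
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 n_objects = as.integer(n)),
            class = "label_vol")
}

#' @export
print.label_vol <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_vol> %d objects on %d x %d x %d grid\n",
              x$n_objects, d[1], d[2], d[3]))
  invisible(x)
}

# world coordinate of voxel centre along one axis: (i - 0.5) * spacing
voxel_to_um <- function(i, spacing) (i - 0.5) * spacing
um_to_voxel <- function(u, spacing) pmin(pmax(round(u / spacing + 0.5), 1), Inf)

#' Read a multi-page grayscale TIFF z-stack
#'
#' Pages are stacked along z. 16-bit integer stacks are rescaled back to
#' raw counts (the `tiff` package normalizes samples to `[0, 1]`).
#'
#' @param path TIFF file.
#' @param spacing voxel spacing `(dz, dy, dx)` in um.
#' @param channel channel label.
#' @param scale multiplier applied to the normalized samples
#'   (default 65535, i.e. 16-bit counts).
#' @return A [vol_img()].
#' @export
read_stack <- function(path, spacing, channel = "", scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!length(pages)) stop("empty TIFF: ", path, call. = FALSE)
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]] * scale
  vol_img(arr, spacing, channel)
}

#' Write a 3D volume as a multi-page TIFF
#'
#' Integer images are written as 16-bit; distance maps and other
#' real-valued volumes are written as 32-bit float after division by
#' `scale` (float TIFF samples must lie in `[0, 1]`; with the default
#' `scale = 1000` a distance-map TIFF stores millimetres).
#'
#' @param x a [vol_img()], [label_vol()] or 3D array.
#' @param path output file.
#' @param bits 16 (integer counts) or 32 (float).
#' @param scale divisor used for 32-bit output (default 1000).
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, bits = 16, scale = 1000) {
  arr <- if (inherits(x, "vol_img")) x$data else if (inherits(x, "label_vol")) x$labels else x
  nz <- dim(arr)[1]
  pages <- vector("list", nz)
  if (bits == 16) {
    arr <- pmin(pmax(arr, 0), 65535) / 65535
    for (z in seq_len(nz)) pages[[z]] <- matrix(arr[z, , ], dim(arr)[2], dim(arr)[3])
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  } else {
    arr <- arr / scale
    if (any(arr > 1 | arr < 0))
      stop("32-bit output must lie in [0, scale]", call. = FALSE)
    for (z in seq_len(nz)) pages[[z]] <- matrix(arr[z, , ], dim(arr)[2], dim(arr)[3])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(path)
}

# separable spacing-aware Gaussian smoothing of a 3D array (sigma in um,
# scalar or per-axis); kernels truncated at 4 sigma and normalized to sum 1.
gaussian_smooth3d <- function(arr, spacing, sigma) {
  sigma <- rep(sigma, length.out = 3)
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    h <- spacing[ax]
    r <- max(1L, ceiling(4 * sigma[ax] / h))
    k <- exp(-((-r:r) * h)^2 / (2 * sigma[ax]^2))
    k <- k / sum(k)
    out <- array(cpp_conv_axis(as.numeric(out), d, k, ax - 1L), d)
  }
  out
}

# Gaussian derivative kernel along one axis; order 0, 1 or 2; exact
# annihilation of constants enforced for orders 1 and 2.
gauss_kernel <- function(sigma, h, order = 0) {
  r <- max(1L, ceiling(4 * sigma / h))
  xs <- (-r:r) * h
  g <- exp(-xs^2 / (2 * sigma^2))
  s <- sum(g)
  k <- switch(as.character(order),
    "0" = g / s,
    "1" = (-xs / sigma^2) * g / s,
    "2" = ((xs^2 / sigma^4) - 1 / sigma^2) * g / s,
    stop("order must be 0, 1 or 2"))
  if (order > 0) k <- k - mean(k)
  k
}

# convolution of a 3D array with per-axis kernels (list of 3, NULL = skip)
conv3_sep <- function(arr, kernels) {
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    if (is.null(kernels[[ax]])) next
    out <- array(cpp_conv_axis(as.numeric(out), d, kernels[[ax]], ax - 1L), d)
  }
  out
}

#' Otsu threshold of a numeric vector
#'
#' Maximizes between-class variance on a 256-bin histogram. Used to
#' binarize tubeness maps and as the automatic fallback threshold for the
#' axis channel.
#'
#' @param x numeric values.
#' @param n_bins histogram bins.
#' @return Threshold on the scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) stop("degenerate input: constant values", call. = FALSE)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE),
                           n_bins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[n_bins]; mt <- m[n_bins]
  w1 <- w[-n_bins]; m1 <- m[-n_bins]
  valid <- w1 > 0 & w1 < n
  bcv <- rep(-Inf, n_bins - 1)
  bcv[valid] <- (mt * w1[valid] - n * m1[valid])^2 /
    (w1[valid] * (n - w1[valid]))
  mids[which.max(bcv)]
}
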