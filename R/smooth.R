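# Separable Gaussian filtering with reflect (default) or nearest boundary
# padding, used for image pyramids, displacement-field regularization and
# transform-series smoothing.

gauss_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

.pad_cache <- new.env(parent = emptyenv())

pad_indices <- function(n, r, boundary = "reflect") {
  key <- paste0(n, ":", r, ":", boundary)
  hit <- .pad_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (boundary == "reflect") {
    # true multi-bounce reflection (period 2n - 2), without repeating the
    # edge sample: ..., 3, 2 | 1, 2, ..., n | n-1, n-2, ...
    reflect <- function(k) {
      if (n == 1) return(rep(1L, length(k)))
      m <- (k - 1) %% (2 * n - 2)
      ifelse(m < n, m + 1, 2 * n - 1 - m)
    }
    left <- reflect(seq(1 - r, 0))
    right <- reflect(seq(n + 1, n + r))
  } else if (boundary == "nearest") {
    left <- rep(1L, r); right <- rep(n, r)
  } else stop("pad_indices: unknown boundary")
  out <- c(left, seq_len(n), right)
  .pad_cache[[key]] <- out
  out
}

# convolve the rows of a padded matrix by shift-and-add (much faster than
# stats::filter, which pays time-series dispatch per call)
conv_cols <- function(mm, k, r, boundary) {
  n <- nrow(mm)
  mp <- mm[pad_indices(n, r, boundary), , drop = FALSE]
  out <- 0
  for (t in seq_along(k))
    out <- out + k[t] * mp[t:(t + n - 1), , drop = FALSE]
  out
}

# smooth a numeric vector along its length
gauss_smooth_vec <- function(x, sigma, boundary = "reflect") {
  if (sigma <= 0) return(x)
  k <- gauss_kernel1d(sigma)
  r <- (length(k) - 1) / 2
  as.numeric(conv_cols(matrix(x, ncol = 1), k, r, boundary))
}

# separable 2D Gaussian smoothing of a matrix, sigma in pixels per axis
gauss_smooth_mat <- function(m, sigma, boundary = "reflect") {
  sigma <- rep(sigma, length.out = 2)
  smooth_cols <- function(mm, s) {
    if (s <= 0) return(mm)
    k <- gauss_kernel1d(s)
    r <- (length(k) - 1) / 2
    conv_cols(mm, k, r, boundary)
  }
  t(smooth_cols(t(smooth_cols(m, sigma[1])), sigma[2]))
}

#' Gaussian-smooth a planar image
#'
#' @param image A [planar_image].
#' @param sigma_mm Physical standard deviation of the kernel, mm (scalar or
#'   per-axis).
#' @param boundary `"reflect"` (default) or `"nearest"` padding.
#' @return A smoothed [planar_image].
#' @export
smooth_planar <- function(image, sigma_mm, boundary = "reflect") {
  sig_px <- rep(sigma_mm, length.out = 2) / image$spacing
  new_planar(gauss_smooth_mat(image$pixels, sig_px, boundary),
             spacing = image$spacing, origin = image$origin)
}

# smooth both components of a displacement field (sigma in mm)
smooth_field <- function(field, sigma_mm) {
  if (all(sigma_mm <= 0)) return(field)
  sig_px <- rep(sigma_mm, length.out = 2) / field$spacing
  new_dispfield(gauss_smooth_mat(field$u1, sig_px),
                gauss_smooth_mat(field$u2, sig_px),
                spacing = field$spacing, origin = field$origin)
}

# 3D separable smoothing, sigma in voxels per axis
gauss_smooth_arr3 <- function(a, sigma) {
  sigma <- rep(sigma, length.out = 3)
  d <- dim(a)
  smooth_axis <- function(arr, axis, s) {
    if (s <= 0) return(arr)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    ap <- aperm(arr, perm)
    dp <- dim(ap)
    m <- matrix(ap, dp[1], dp[2] * dp[3])
    k <- gauss_kernel1d(s)
    r <- (length(k) - 1) / 2
    m <- conv_cols(m, k, r, "reflect")
    aperm(array(m, dp), order(perm))
  }
  for (ax in 1:3) a <- smooth_axis(a, ax, sigma[ax])
  a
}

# dyadic downsampling with anti-alias pre-blur
downsample_planar <- function(image, factor = 2L) {
  if (factor <= 1L) return(image)
  sm <- gauss_smooth_mat(image$pixels, rep(0.5 * factor, 2))
  ix <- seq(1, nrow(sm), by = factor); iy <- seq(1, ncol(sm), by = factor)
  planar_image(sm[ix, iy, drop = FALSE], spacing = image$spacing * factor,
               origin = image$origin)
}

downsample_volume <- function(vol, factor = 2L) {
  if (factor <= 1L) return(vol)
  sm <- gauss_smooth_arr3(vol$voxels, rep(0.5 * factor, 3))
  ix <- seq(1, dim(sm)[1], by = factor)
  iy <- seq(1, dim(sm)[2], by = factor)
  iz <- seq(1, dim(sm)[3], by = factor)
  volume_image(sm[ix, iy, iz, drop = FALSE], spacing = vol$spacing * factor,
               origin = vol$origin, slice_axis = vol$slice_axis)
}

# central-difference gradient of a planar image, per mm; one-sided at edges
planar_gradient <- function(image) {
  m <- image$pixels
  nx <- nrow(m); ny <- ncol(m)
  gx <- (m[c(2:nx, nx), ] - m[c(1, 1:(nx - 1)), ]) /
    (image$spacing[1] * c(1, rep(2, nx - 2), 1))
  gy <- (m[, c(2:ny, ny)] - m[, c(1, 1:(ny - 1))]) /
    (image$spacing[2] * rep(c(1, rep(2, ny - 2), 1), each = nx))
  list(gx = matrix(gx, nx, ny), gy = matrix(gy, nx, ny))
}
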