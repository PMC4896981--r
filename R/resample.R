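# Vectorized interpolation kernels.  Index arguments are fractional 1-based
# matrix indices; anything outside the grid takes `background`.

sample_bilinear <- function(mat, xi, yi, background = 0) {
  nx <- nrow(mat); ny <- ncol(mat)
  inside <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
  out <- rep(background, length(xi))
  if (!any(inside)) return(out)
  xi <- xi[inside]; yi <- yi[inside]
  i0 <- pmin(floor(xi), nx - 1); j0 <- pmin(floor(yi), ny - 1)
  fx <- xi - i0; fy <- yi - j0
  idx <- function(i, j) (j - 1) * nx + i
  v <- (1 - fx) * (1 - fy) * mat[idx(i0, j0)] +
       fx       * (1 - fy) * mat[idx(i0 + 1, j0)] +
       (1 - fx) * fy       * mat[idx(i0, j0 + 1)] +
       fx       * fy       * mat[idx(i0 + 1, j0 + 1)]
  out[inside] <- v
  out
}

sample_nearest <- function(mat, xi, yi, background = 0) {
  nx <- nrow(mat); ny <- ncol(mat)
  i <- round(xi); j <- round(yi)
  inside <- i >= 1 & i <= nx & j >= 1 & j <= ny
  out <- rep(background, length(xi))
  out[inside] <- mat[(j[inside] - 1) * nx + i[inside]]
  out
}

# Catmull-Rom cubic sampling; falls back to bilinear within one pixel of
# the border.  Used by the registration engine, where linear interpolation's
# spatially varying smoothing visibly biases smooth-image optima.
sample_cubic <- function(mat, xi, yi, background = 0) {
  nx <- nrow(mat); ny <- ncol(mat)
  inside <- xi >= 2 & xi <= nx - 1 & yi >= 2 & yi <= ny - 1
  out <- sample_bilinear(mat, xi, yi, background)
  if (!any(inside)) return(out)
  x <- xi[inside]; y <- yi[inside]
  i0 <- pmin(pmax(floor(x), 2), nx - 2); j0 <- pmin(pmax(floor(y), 2), ny - 2)
  fx <- x - i0; fy <- y - j0
  wcr <- function(f) {
    f2 <- f * f; f3 <- f2 * f
    cbind(-0.5 * f3 + f2 - 0.5 * f,
          1.5 * f3 - 2.5 * f2 + 1,
          -1.5 * f3 + 2 * f2 + 0.5 * f,
          0.5 * f3 - 0.5 * f2)
  }
  wx <- wcr(fx); wy <- wcr(fy)
  acc <- 0
  for (a in 1:4) for (b in 1:4)
    acc <- acc + wx[, a] * wy[, b] * mat[(j0 + b - 3L) * nx + i0 + a - 2L]
  out[inside] <- acc
  out
}

sample_tricubic <- function(arr, xi, yi, zi, background = 0) {
  d <- dim(arr); nx <- d[1]; ny <- d[2]; nz <- d[3]
  inside <- xi >= 2 & xi <= nx - 1 & yi >= 2 & yi <= ny - 1 &
            zi >= 2 & zi <= nz - 1
  out <- sample_trilinear(arr, xi, yi, zi, background)
  if (!any(inside)) return(out)
  x <- xi[inside]; y <- yi[inside]; z <- zi[inside]
  i0 <- pmin(pmax(floor(x), 2), nx - 2)
  j0 <- pmin(pmax(floor(y), 2), ny - 2)
  k0 <- pmin(pmax(floor(z), 2), nz - 2)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  wcr <- function(f) {
    f2 <- f * f; f3 <- f2 * f
    cbind(-0.5 * f3 + f2 - 0.5 * f,
          1.5 * f3 - 2.5 * f2 + 1,
          -1.5 * f3 + 2 * f2 + 0.5 * f,
          0.5 * f3 - 0.5 * f2)
  }
  wx <- wcr(fx); wy <- wcr(fy); wz <- wcr(fz)
  acc <- 0
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) {
    idx <- ((k0 + cc - 3L) * ny + (j0 + b - 3L)) * nx + i0 + a - 2L
    acc <- acc + wx[, a] * wy[, b] * wz[, cc] * arr[idx]
  }
  out[inside] <- acc
  out
}

sample_trilinear <- function(arr, xi, yi, zi, background = 0) {
  d <- dim(arr); nx <- d[1]; ny <- d[2]; nz <- d[3]
  inside <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny & zi >= 1 & zi <= nz
  out <- rep(background, length(xi))
  if (!any(inside)) return(out)
  xi <- xi[inside]; yi <- yi[inside]; zi <- zi[inside]
  i0 <- pmin(floor(xi), nx - 1); j0 <- pmin(floor(yi), ny - 1)
  k0 <- pmin(floor(zi), nz - 1)
  fx <- xi - i0; fy <- yi - j0; fz <- zi - k0
  idx <- function(i, j, k) ((k - 1) * ny + (j - 1)) * nx + i
  v <-
    (1 - fx) * (1 - fy) * (1 - fz) * arr[idx(i0,     j0,     k0)] +
    fx       * (1 - fy) * (1 - fz) * arr[idx(i0 + 1, j0,     k0)] +
    (1 - fx) * fy       * (1 - fz) * arr[idx(i0,     j0 + 1, k0)] +
    fx       * fy       * (1 - fz) * arr[idx(i0 + 1, j0 + 1, k0)] +
    (1 - fx) * (1 - fy) * fz       * arr[idx(i0,     j0,     k0 + 1)] +
    fx       * (1 - fy) * fz       * arr[idx(i0 + 1, j0,     k0 + 1)] +
    (1 - fx) * fy       * fz       * arr[idx(i0,     j0 + 1, k0 + 1)] +
    fx       * fy       * fz       * arr[idx(i0 + 1, j0 + 1, k0 + 1)]
  out[inside] <- v
  out
}

#' Resample a planar image through a transform
#'
#' Pull-back resampling: for every node `p` of the output grid the value is
#' the (interpolated) input intensity at `t(p)`.  The transform therefore
#' maps output physical coordinates to input physical coordinates.
#'
#' @param image A [planar_image].
#' @param t A 2D transform (`rigid2d`, `affine2d`, `dispfield2d` or
#'   `transform_seq`).
#' @param out_grid Output geometry: a [planar_image] (or [dispfield2d])
#'   whose grid is reused; default the input's own grid.
#' @param interpolation `"linear"` (default), `"cubic"` (Catmull-Rom) or
#'   `"nearest"`.
#' @param background Value for samples falling outside the input, default 0.
#' @return A [planar_image] on `out_grid`.
#' @export
resample_planar <- function(image, t, out_grid = NULL,
                            interpolation = c("linear", "cubic", "nearest"),
                            background = 0) {
  interpolation <- match.arg(interpolation)
  if (is.null(out_grid)) out_grid <- image
  dims <- if (inherits(out_grid, "dispfield2d")) dim(out_grid$u1)
          else dim(out_grid$pixels)
  g <- list(x = out_grid$origin[1] + (seq_len(dims[1]) - 1) * out_grid$spacing[1],
            y = out_grid$origin[2] + (seq_len(dims[2]) - 1) * out_grid$spacing[2])
  pts <- cbind(rep(g$x, times = dims[2]), rep(g$y, each = dims[1]))
  src <- map_points(t, pts)
  xi <- (src[, 1] - image$origin[1]) / image$spacing[1] + 1
  yi <- (src[, 2] - image$origin[2]) / image$spacing[2] + 1
  vals <- switch(interpolation,
                 linear = sample_bilinear(image$pixels, xi, yi, background),
                 cubic = sample_cubic(image$pixels, xi, yi, background),
                 nearest = sample_nearest(image$pixels, xi, yi, background))
  new_planar(matrix(vals, dims[1], dims[2]),
             spacing = out_grid$spacing, origin = out_grid$origin)
}

#' Resample a volume through a 3D transform
#'
#' Same pull-back convention as [resample_planar()].
#'
#' @param volume A [volume_image].
#' @param t An [affine3d].
#' @param out_grid A [volume_image] whose grid is reused; default the
#'   input's own grid.
#' @param interpolation `"linear"` (default), `"cubic"` or `"nearest"`.
#' @param background Fill value.
#' @return A [volume_image].
#' @export
resample_volume <- function(volume, t, out_grid = NULL,
                            interpolation = c("linear", "cubic", "nearest"),
                            background = 0) {
  interpolation <- match.arg(interpolation)
  if (is.null(out_grid)) out_grid <- volume
  d <- dim(out_grid$voxels)
  gx <- out_grid$origin[1] + (seq_len(d[1]) - 1) * out_grid$spacing[1]
  gy <- out_grid$origin[2] + (seq_len(d[2]) - 1) * out_grid$spacing[2]
  gz <- out_grid$origin[3] + (seq_len(d[3]) - 1) * out_grid$spacing[3]
  pts <- cbind(rep(gx, times = d[2] * d[3]),
               rep(rep(gy, each = d[1]), times = d[3]),
               rep(gz, each = d[1] * d[2]))
  src <- map_points(t, pts)
  xi <- (src[, 1] - volume$origin[1]) / volume$spacing[1] + 1
  yi <- (src[, 2] - volume$origin[2]) / volume$spacing[2] + 1
  zi <- (src[, 3] - volume$origin[3]) / volume$spacing[3] + 1
  vals <- if (interpolation == "linear")
    sample_trilinear(volume$voxels, xi, yi, zi, background)
  else if (interpolation == "cubic")
    sample_tricubic(volume$voxels, xi, yi, zi, background)
  else {
    i <- round(xi); j <- round(yi); k <- round(zi)
    inside <- i >= 1 & i <= dim(volume$voxels)[1] &
              j >= 1 & j <= dim(volume$voxels)[2] &
              k >= 1 & k <= dim(volume$voxels)[3]
    out <- rep(background, length(xi))
    out[inside] <- volume$voxels[cbind(i[inside], j[inside], k[inside])]
    out
  }
  volume_image(array(vals, d), spacing = out_grid$spacing,
               origin = out_grid$origin, slice_axis = out_grid$slice_axis)
}

#' Compose a new displacement update into a total field
#'
#' Both fields live on the same grid and act in the pull-back convention.
#' Warping first by `total` and then applying the update `new` in the fixed
#' frame is the single warp
#' \eqn{u(p) = u_{new}(p) + u_{total}(p + u_{new}(p))}.
#'
#' @param new,total [dispfield2d] objects on the same grid.
#' @return A [dispfield2d].
#' @export
compose_fields <- function(new, total) {
  stopifnot(identical(dim(new$u1), dim(total$u1)))
  d <- dim(new$u1)
  xi0 <- matrix(rep(seq_len(d[1]), times = d[2]), d[1], d[2])
  yi0 <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
  xi <- xi0 + new$u1 / new$spacing[1]
  yi <- yi0 + new$u2 / new$spacing[2]
  u1 <- new$u1 + matrix(sample_bilinear(total$u1, as.numeric(xi),
                                        as.numeric(yi), 0), d[1], d[2])
  u2 <- new$u2 + matrix(sample_bilinear(total$u2, as.numeric(xi),
                                        as.numeric(yi), 0), d[1], d[2])
  new_dispfield(u1, u2, spacing = new$spacing, origin = new$origin)
}

#' Zero displacement field on an image grid
#' @param image A [planar_image] supplying the grid.
#' @return A [dispfield2d] of zeros.
#' @export
zero_field <- function(image) {
  d <- dim(image$pixels)
  new_dispfield(matrix(0, d[1], d[2]), matrix(0, d[1], d[2]),
                spacing = image$spacing, origin = image$origin)
}
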