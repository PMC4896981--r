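# Parametric spatial transforms.  All transforms are point maps in physical
# coordinates (mm) used in the pull-back convention: resampling an image
# through transform t computes out(p) = in(t(p)).

#' Wrap angles into the (-180, 180] convention
#' @param theta Angles, degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(theta) {
  th <- (theta + 180) %% 360 - 180
  ifelse(th == -180, 180, th)
}

rot2 <- function(theta_deg) {
  a <- theta_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Rigid 2D transform (rotation + translation)
#'
#' The map is \eqn{p \mapsto R(\theta)(p - c) + c + t} with rotation angle
#' theta in degrees (wrapped to (-180, 180]), translation `t` and pivot `c`
#' in mm.
#'
#' @param theta Rotation, degrees.
#' @param tx,ty Translation, mm.
#' @param center Rotation center, mm (default the physical origin).
#' @return An object of class `rigid2d`.
#' @export
rigid2d <- function(theta = 0, tx = 0, ty = 0, center = c(0, 0)) {
  structure(list(theta = wrap_angle(as.numeric(theta)),
                 t = c(as.numeric(tx), as.numeric(ty)),
                 center = as.numeric(center)),
            class = "rigid2d")
}

#' Affine 2D transform
#'
#' The map is \eqn{p \mapsto M(p - c) + c + o}.
#'
#' @param matrix 2x2 linear part (must be invertible).
#' @param offset Length-2 offset, mm.
#' @param center Length-2 center, mm.
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(matrix = diag(2), offset = c(0, 0), center = c(0, 0)) {
  m <- base::matrix(as.numeric(matrix), 2, 2)
  if (abs(det(m)) < 1e-12) stop("affine2d: matrix is singular")
  structure(list(matrix = m, offset = as.numeric(offset),
                 center = as.numeric(center)),
            class = "affine2d")
}

#' Affine 3D transform
#'
#' @param matrix 3x3 linear part (invertible).
#' @param offset,center Length-3, mm.
#' @return An object of class `affine3d`.
#' @export
affine3d <- function(matrix = diag(3), offset = c(0, 0, 0),
                     center = c(0, 0, 0)) {
  m <- base::matrix(as.numeric(matrix), 3, 3)
  if (abs(det(m)) < 1e-12) stop("affine3d: matrix is singular")
  structure(list(matrix = m, offset = as.numeric(offset),
                 center = as.numeric(center)),
            class = "affine3d")
}

#' Dense 2D displacement field
#'
#' Encodes the warp \eqn{p \mapsto p + u(p)} on a regular grid; `u1`/`u2`
#' hold the displacement components (mm) at the grid nodes.  Outside the
#' grid the displacement is taken as zero.
#'
#' @param u1,u2 Matrices of displacement components, mm (same shape).
#' @param spacing Length-2 grid spacing, mm.
#' @param origin Length-2 physical coordinate of node (1,1), mm; defaults
#'   to a grid centered on the physical origin.
#' @return An object of class `dispfield2d`.
#' @export
dispfield2d <- function(u1, u2, spacing = c(1, 1), origin = NULL) {
  u1 <- as.matrix(u1); u2 <- as.matrix(u2)
  if (!identical(dim(u1), dim(u2)))
    stop("dispfield2d: components must share shape")
  if (!all(is.finite(u1)) || !all(is.finite(u2)))
    stop("dispfield2d: displacements must be finite")
  spacing <- as.numeric(spacing)
  if (is.null(origin)) origin <- default_origin(dim(u1), spacing)
  structure(list(u1 = u1, u2 = u2, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "dispfield2d")
}

#' Magnitudes of a displacement field
#' @param field A [dispfield2d].
#' @return Matrix of per-node Euclidean magnitudes, mm.
#' @export
field_magnitude <- function(field) sqrt(field$u1^2 + field$u2^2)

# ---- generic point mapping -------------------------------------------------

#' Map physical points through a transform
#'
#' @param t A transform (`rigid2d`, `affine2d`, `affine3d`, `dispfield2d`,
#'   or `transform_seq`).
#' @param pts n x d matrix of physical coordinates.
#' @return n x d matrix of mapped coordinates.
#' @export
map_points <- function(t, pts) UseMethod("map_points")

#' @export
map_points.rigid2d <- function(t, pts) map_points(as_affine(t), pts)

affine_apply <- function(M, off, center, pts) {
  pts <- base::matrix(pts, ncol = length(off))
  sweep(sweep(pts, 2, center) %*% t(M), 2, center + off, `+`)
}

#' @export
map_points.affine2d <- function(t, pts)
  affine_apply(t$matrix, t$offset, t$center, pts)

#' @export
map_points.affine3d <- function(t, pts)
  affine_apply(t$matrix, t$offset, t$center, pts)

#' @export
map_points.dispfield2d <- function(t, pts) {
  pts <- base::matrix(pts, ncol = 2)
  xi <- (pts[, 1] - t$origin[1]) / t$spacing[1] + 1
  yi <- (pts[, 2] - t$origin[2]) / t$spacing[2] + 1
  pts + cbind(sample_bilinear(t$u1, xi, yi, background = 0),
              sample_bilinear(t$u2, xi, yi, background = 0))
}

#' Sequence of transforms applied in order
#'
#' `map_points()` applies the member transforms left to right:
#' `p -> t1(p) -> t2(t1(p)) -> ...`.
#'
#' @param ... Transforms, or a single list of transforms.
#' @return An object of class `transform_seq`.
#' @export
transform_seq <- function(...) {
  ts <- list(...)
  if (length(ts) == 1L && is.list(ts[[1]]) && !inherits(ts[[1]], c(
    "rigid2d", "affine2d", "affine3d", "dispfield2d"))) ts <- ts[[1]]
  structure(list(transforms = ts), class = "transform_seq")
}

#' @export
map_points.transform_seq <- function(t, pts) {
  for (tt in t$transforms) pts <- map_points(tt, pts)
  pts
}

# ---- conversions and algebra ----------------------------------------------

#' Convert a transform to its affine representation
#' @param t A `rigid2d`, `affine2d` or `affine3d`.
#' @return An `affine2d`/`affine3d` realizing the same map.
#' @export
as_affine <- function(t) UseMethod("as_affine")

#' @export
as_affine.rigid2d <- function(t)
  affine2d(rot2(t$theta), offset = t$t, center = t$center)

#' @export
as_affine.affine2d <- function(t) t

#' @export
as_affine.affine3d <- function(t) t

# matrix/absolute-offset form: p -> M p + b
affine_mb <- function(t) {
  t <- as_affine(t)
  list(M = t$matrix, b = t$center + t$offset - t$matrix %*% t$center)
}

#' Extract a rigid transform from a rigid-valued affine
#'
#' @param t An `affine2d` whose linear part is a pure rotation, or a
#'   `rigid2d` (returned unchanged).
#' @param center Desired pivot for the result, mm.
#' @param tol Orthonormality tolerance.
#' @return A [rigid2d] realizing the same map, expressed about `center`.
#' @export
as_rigid <- function(t, center = c(0, 0), tol = 1e-6) {
  if (inherits(t, "rigid2d")) return(rigid_recenter(t, center))
  M <- as_affine(t)$matrix
  if (max(abs(crossprod(M) - diag(2))) > tol || det(M) < 0)
    stop("as_rigid: linear part is not a rotation")
  theta <- atan2(M[2, 1], M[1, 1]) * 180 / pi
  mb <- affine_mb(t)
  # solve R(p - c) + c + t' = M p + b  =>  t' = b + (M - I) c
  tv <- as.numeric(mb$b + (mb$M - diag(2)) %*% center)
  rigid2d(theta, tv[1], tv[2], center = center)
}

#' Re-express a rigid transform about a different pivot
#'
#' The map is unchanged; only the (center, translation) parameterization
#' moves.  Required before parameter-space algebra on transform series.
#'
#' @param t A [rigid2d].
#' @param center New pivot, mm.
#' @return A [rigid2d].
#' @export
rigid_recenter <- function(t, center) {
  center <- as.numeric(center)
  R <- rot2(t$theta)
  tv <- t$t + as.numeric((diag(2) - R) %*% (t$center - center))
  rigid2d(t$theta, tv[1], tv[2], center = center)
}

#' Compose two transforms
#'
#' `t_compose(a, b)` returns the transform realizing `p -> a(b(p))`
#' (matrix-product order: `b` is applied first).  Composing two rigid 2D
#' transforms yields a rigid transform; otherwise an affine of the common
#' dimensionality.
#'
#' @param a,b Transforms of matching dimensionality.
#' @return A `rigid2d`, `affine2d` or `affine3d`.
#' @export
t_compose <- function(a, b) {
  rigid_in <- inherits(a, "rigid2d") && inherits(b, "rigid2d")
  ma <- affine_mb(a); mb_ <- affine_mb(b)
  M <- ma$M %*% mb_$M
  off <- as.numeric(ma$M %*% mb_$b + ma$b)
  d <- nrow(M)
  out <- if (d == 2) affine2d(M, off) else affine3d(M, off)
  if (rigid_in) as_rigid(out) else out
}

#' Invert a transform
#'
#' @param t A `rigid2d`, `affine2d` or `affine3d`.
#' @return The inverse transform (same class).
#' @export
t_invert <- function(t) UseMethod("t_invert")

#' @export
t_invert.rigid2d <- function(t) as_rigid(t_invert(as_affine(t)), center = t$center)

#' @export
t_invert.affine2d <- function(t) {
  mb <- affine_mb(t)
  Mi <- solve(mb$M)
  affine2d(Mi, offset = as.numeric(-Mi %*% mb$b), center = c(0, 0))
}

#' @export
t_invert.affine3d <- function(t) {
  mb <- affine_mb(t)
  Mi <- solve(mb$M)
  affine3d(Mi, offset = as.numeric(-Mi %*% mb$b), center = c(0, 0, 0))
}

#' Identity transforms
#' @return A [rigid2d], [affine2d] or [affine3d] identity.
#' @export
identity2d <- function() rigid2d(0, 0, 0)

#' @rdname identity2d
#' @export
identity_affine2d <- function() affine2d()

#' @rdname identity2d
#' @export
identity_affine3d <- function() affine3d()

#' @export
print.rigid2d <- function(x, ...) {
  cat(sprintf("<rigid2d> theta %.4g deg, t (%.4g, %.4g) mm, center (%.4g, %.4g)\n",
              x$theta, x$t[1], x$t[2], x$center[1], x$center[2]))
  invisible(x)
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("<affine2d> matrix [%.4g %.4g; %.4g %.4g], offset (%.4g, %.4g)\n",
              x$matrix[1, 1], x$matrix[1, 2], x$matrix[2, 1], x$matrix[2, 2],
              x$offset[1], x$offset[2]))
  invisible(x)
}

#' @export
print.affine3d <- function(x, ...) {
  cat("<affine3d>\n"); print(cbind(x$matrix, offset = x$offset)); invisible(x)
}

#' @export
print.dispfield2d <- function(x, ...) {
  cat(sprintf("<dispfield2d> %d x %d nodes, median |u| = %.4g mm\n",
              nrow(x$u1), ncol(x$u1), stats::median(field_magnitude(x))))
  invisible(x)
}

# ---- transform text files --------------------------------------------------

transform_line <- function(t) {
  if (inherits(t, "rigid2d"))
    paste("rigid2d", paste(format(c(t$theta, t$t, t$center), digits = 17),
                           collapse = " "))
  else if (inherits(t, "affine2d"))
    paste("affine2d", paste(format(c(as.numeric(t$matrix), t$offset, t$center),
                                   digits = 17), collapse = " "))
  else if (inherits(t, "affine3d"))
    paste("affine3d", paste(format(c(as.numeric(t$matrix), t$offset, t$center),
                                   digits = 17), collapse = " "))
  else stop("unsupported transform kind for text serialization")
}

#' Write transforms to a plain-text file
#'
#' One transform per line: kind followed by its parameters (full double
#' precision); the shared format of all workflow outputs.
#'
#' @param transforms A transform or list of transforms.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_transforms <- function(transforms, path) {
  if (!is.list(transforms) || inherits(transforms, c("rigid2d", "affine2d", "affine3d")))
    transforms <- list(transforms)
  writeLines(vapply(transforms, transform_line, ""), path)
  invisible(path)
}

#' Read transforms from a plain-text file
#'
#' @param path File written by [write_transforms()].
#' @return List of transforms.
#' @export
read_transforms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    vals <- as.numeric(parts[-1])
    switch(parts[1],
           rigid2d = rigid2d(vals[1], vals[2], vals[3], center = vals[4:5]),
           affine2d = affine2d(matrix(vals[1:4], 2, 2), vals[5:6], vals[7:8]),
           affine3d = affine3d(matrix(vals[1:9], 3, 3), vals[10:12], vals[13:15]),
           stop("unknown transform kind: ", parts[1]))
  })
}
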