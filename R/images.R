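# Physical-coordinate convention used throughout:
#   pixel/voxel (i, j[, k]) (1-based) sits at
#     x_d = origin[d] + (i_d - 1) * spacing[d]
# The default origin centers the grid on (0, 0[, 0]) so that rotations about
# the physical origin are rotations about the image center.

default_origin <- function(dim, spacing) -(dim - 1) / 2 * spacing

# validation-free constructors for internal hot paths (inputs already known
# to be well-formed)
new_planar <- function(pixels, spacing, origin)
  structure(list(pixels = pixels, spacing = spacing, origin = origin),
            class = "planar_image")

new_dispfield <- function(u1, u2, spacing, origin)
  structure(list(u1 = u1, u2 = u2, spacing = spacing, origin = origin),
            class = "dispfield2d")

#' Create a 2D section image with physical geometry
#'
#' A planar image is a matrix of intensities together with the physical size
#' of a pixel (mm) and the physical coordinate of the first pixel (mm).  All
#' registration and resampling operations in the package address pixels by
#' their physical coordinates.
#'
#' @param pixels Numeric matrix of intensities (at least 2x2, all finite).
#' @param spacing Numeric length-2, physical size of one pixel along each
#'   matrix dimension, mm.  Must be positive.
#' @param origin Numeric length-2, physical coordinate of pixel (1,1), mm.
#'   Defaults to placing the image center at (0, 0).
#' @return An object of class `planar_image`.
#' @export
planar_image <- function(pixels, spacing = c(1, 1), origin = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (any(dim(pixels) < 2L))
    stop("planar_image: dimensions must be at least 2x2")
  if (!all(is.finite(pixels)))
    stop("planar_image: all intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(spacing <= 0))
    stop("planar_image: spacing must be two positive numbers")
  if (is.null(origin)) origin <- default_origin(dim(pixels), spacing)
  origin <- as.numeric(origin)
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("planar_image: origin must be two finite numbers")
  structure(list(pixels = pixels, spacing = spacing, origin = origin),
            class = "planar_image")
}

#' Create a 3D volume image
#'
#' @param voxels Numeric 3D array of intensities (all finite).
#' @param spacing Numeric length-3 voxel size, mm (positive).
#' @param origin Numeric length-3 physical coordinate of voxel (1,1,1), mm;
#'   defaults to centering the volume on the physical origin.
#' @param slice_axis Which array axis corresponds to the sectioning
#'   direction (1, 2 or 3; default 3).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, spacing = c(1, 1, 1), origin = NULL,
                         slice_axis = 3L) {
  voxels <- as.array(voxels)
  storage.mode(voxels) <- "double"
  if (length(dim(voxels)) != 3L)
    stop("volume_image: voxels must be a 3D array")
  if (!all(is.finite(voxels)))
    stop("volume_image: all intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("volume_image: spacing must be three positive numbers")
  if (is.null(origin)) origin <- default_origin(dim(voxels), spacing)
  origin <- as.numeric(origin)
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3) stop("volume_image: slice_axis must be 1, 2 or 3")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 slice_axis = slice_axis),
            class = "volume_image")
}

#' Create an ordered stack of serial sections
#'
#' All sections must share the same dimensions and pixel spacing; the stack
#' carries the (constant) section thickness.  Section index `i` (1-based)
#' sits at physical z = z_origin + (i-1) * thickness, with the stack
#' centered on z = 0 by default.
#'
#' @param sections List of [planar_image] objects (at least 2), or a 3D
#'   array sliced along its third axis.
#' @param thickness Section thickness, mm (positive).
#' @param spacing,origin Used only when `sections` is an array.
#' @param z_origin Physical z of the first section; default centers the
#'   stack on z = 0.
#' @return An object of class `section_stack`.
#' @export
section_stack <- function(sections, thickness, spacing = c(1, 1),
                          origin = NULL, z_origin = NULL) {
  if (is.array(sections) && length(dim(sections)) == 3L) {
    sections <- lapply(seq_len(dim(sections)[3]), function(k)
      planar_image(sections[, , k], spacing = spacing, origin = origin))
  }
  if (!is.list(sections) || length(sections) < 2L)
    stop("section_stack: need at least 2 sections")
  if (!all(vapply(sections, inherits, TRUE, "planar_image")))
    stop("section_stack: sections must be planar_image objects")
  d1 <- dim(sections[[1]]$pixels)
  sp1 <- sections[[1]]$spacing
  for (s in sections) {
    if (!identical(dim(s$pixels), d1) || !isTRUE(all.equal(s$spacing, sp1)))
      stop("section_stack: all sections must share shape and spacing")
  }
  thickness <- as.numeric(thickness)
  if (length(thickness) != 1L || thickness <= 0)
    stop("section_stack: thickness must be a positive scalar")
  if (is.null(z_origin))
    z_origin <- -(length(sections) - 1) / 2 * thickness
  structure(list(sections = sections, thickness = thickness,
                 z_origin = as.numeric(z_origin)),
            class = "section_stack")
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("<planar_image> %d x %d px, spacing %.4g x %.4g mm, origin (%.4g, %.4g) mm\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_image> %d x %d x %d vx, spacing %.4g x %.4g x %.4g mm, slice axis %d\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$slice_axis))
  invisible(x)
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$sections[[1]]$pixels)
  cat(sprintf("<section_stack> %d sections of %d x %d px, thickness %.4g mm\n",
              length(x$sections), d[1], d[2], x$thickness))
  invisible(x)
}

#' Number of sections in a stack
#' @param stack A [section_stack].
#' @return Integer count.
#' @export
n_sections <- function(stack) length(stack$sections)

# physical coordinates of the grid nodes of a planar image
grid_coords <- function(image) {
  d <- dim(image$pixels)
  list(x = image$origin[1] + (seq_len(d[1]) - 1) * image$spacing[1],
       y = image$origin[2] + (seq_len(d[2]) - 1) * image$spacing[2])
}

#' Physical center of an image grid
#'
#' The default rotation pivot of the registration engine.
#' @param image A [planar_image].
#' @return Length-2 physical coordinate, mm.
#' @export
grid_center <- function(image) {
  d <- dim(image$pixels)
  image$origin + (d - 1) / 2 * image$spacing
}

section_z <- function(stack, i) stack$z_origin + (i - 1) * stack$thickness

#' Stack sections into a 3D volume
#'
#' The third array axis is the sectioning direction; its spacing equals the
#' section thickness.  `volume_to_stack()` inverts this bit-exactly.
#'
#' @param stack A [section_stack].
#' @return A [volume_image] with `slice_axis = 3`.
#' @export
stack_to_volume <- function(stack) {
  stopifnot(inherits(stack, "section_stack"))
  d <- dim(stack$sections[[1]]$pixels)
  n <- n_sections(stack)
  vox <- array(0, c(d, n))
  for (i in seq_len(n)) vox[, , i] <- stack$sections[[i]]$pixels
  volume_image(vox,
               spacing = c(stack$sections[[1]]$spacing, stack$thickness),
               origin = c(stack$sections[[1]]$origin, stack$z_origin),
               slice_axis = 3L)
}

#' Slice a volume into a stack of sections
#'
#' @param v A [volume_image].
#' @param slice_axis Axis along which to slice (default: the volume's
#'   declared slice axis).
#' @return A [section_stack]; slicing along a non-third axis permutes the
#'   remaining axes into the in-plane dimensions in order.
#' @export
volume_to_stack <- function(v, slice_axis = v$slice_axis) {
  stopifnot(inherits(v, "volume_image"))
  perm <- switch(slice_axis, `1` = c(2, 3, 1), `2` = c(1, 3, 2), `3` = c(1, 2, 3))
  vox <- aperm(v$voxels, perm)
  sp <- v$spacing[perm]
  or <- v$origin[perm]
  sections <- lapply(seq_len(dim(vox)[3]), function(k)
    planar_image(vox[, , k], spacing = sp[1:2], origin = or[1:2]))
  section_stack(sections, thickness = sp[3], z_origin = or[3])
}

dynamic_range <- function(x) {
  px <- if (inherits(x, "planar_image")) x$pixels else x$voxels
  diff(range(px))
}

#' Write an image to a NIfTI-1 file
#'
#' Planar images are stored as degenerate 3D volumes (one slice); spacing
#' and origin are carried in the NIfTI header.
#'
#' @param image A [planar_image], [volume_image] or [section_stack]
#'   (stacked before writing).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_image <- function(image, path) {
  if (inherits(image, "section_stack")) image <- stack_to_volume(image)
  if (inherits(image, "planar_image")) {
    arr <- array(image$pixels, c(dim(image$pixels), 1L))
    spacing <- c(image$spacing, 1)
    origin <- c(image$origin, 0)
  } else if (inherits(image, "volume_image")) {
    arr <- image$voxels
    spacing <- image$spacing
    origin <- image$origin
  } else stop("write_nifti_image: unsupported object")
  hdr <- RNifti::niftiHeader(arr)
  hdr$dim <- c(3L, dim(arr), 1L, 1L, 1L, 1L)   # keep degenerate 3D (nz = 1)
  hdr$pixdim <- c(-1, spacing, 0, 0, 0, 0)
  img <- RNifti::asNifti(arr, reference = hdr)
  # origin and spacing via qform: diagonal spacing matrix, translation = origin
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an image from a NIfTI-1 file
#'
#' @param path NIfTI file path.
#' @return A [planar_image] if the stored volume is a single slice,
#'   otherwise a [volume_image].
#' @export
read_nifti_image <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim(arr))   # drop niftiImage attributes
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  q <- RNifti::xform(img)
  spacing <- abs(diag(q)[1:3])
  if (any(spacing == 0)) spacing <- RNifti::pixdim(img)[1:3]
  origin <- q[1:3, 4]
  if (dim(arr)[3] == 1L)
    planar_image(arr[, , 1], spacing = spacing[1:2], origin = origin[1:2])
  else
    volume_image(arr, spacing = spacing, origin = origin)
}

#' Write a section stack as numbered per-section NIfTI files
#'
#' Files are named `section_%04d.nii.gz` within `dir`.
#'
#' @param stack A [section_stack].
#' @param dir Output directory (created if missing).
#' @return Character vector of paths, invisibly.
#' @export
write_stack_sections <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("section_%04d.nii.gz",
                                  seq_len(n_sections(stack))))
  for (i in seq_along(paths)) write_nifti_image(stack$sections[[i]], paths[i])
  invisible(paths)
}

#' Read numbered per-section NIfTI files into a stack
#'
#' @param dir Directory holding `section_%04d.nii.gz` files.
#' @param thickness Section thickness, mm.
#' @return A [section_stack].
#' @export
read_stack_sections <- function(dir, thickness) {
  paths <- sort(list.files(dir, pattern = "^section_[0-9]{4}\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (length(paths) < 2L) stop("read_stack_sections: need at least 2 sections")
  section_stack(lapply(paths, read_nifti_image), thickness = thickness)
}
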