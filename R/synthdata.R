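# Phantom and distortion generators.  Every generator is seeded and returns
# full ground-truth provenance so that distortion experiments can be
# regenerated bit-exactly and recovered transforms can be scored against
# the truth.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Smooth seeded texture as a sum of random-frequency cosines evaluated in
# physical space: grid-independent, so resampling the same object at a
# different section thickness samples the same underlying function.
fourier_texture <- function(seed, n_waves, freq_range, amplitude) {
  pars <- with_seed(seed, list(
    dir = {
      v <- matrix(stats::rnorm(3 * n_waves), n_waves, 3)
      v / sqrt(rowSums(v^2))
    },
    freq = stats::runif(n_waves, freq_range[1], freq_range[2]),
    phase = stats::runif(n_waves, 0, 2 * pi),
    amp = stats::runif(n_waves, 0.5, 1)))
  function(x, y, z) {
    out <- 0
    for (k in seq_len(n_waves)) {
      f <- 2 * pi / pars$freq[k]
      out <- out + pars$amp[k] *
        cos(f * (pars$dir[k, 1] * x + pars$dir[k, 2] * y +
                 pars$dir[k, 3] * z) + pars$phase[k])
    }
    amplitude * out / sum(pars$amp)
  }
}

#' Curved-tube ("banana") phantom volume
#'
#' An MR-like phantom: an elliptical tube bent along an arc in the x-z
#' plane, with a smooth internal intensity gradient and seeded
#' low-frequency texture so that registration has features to lock onto.
#' Sliced along the third (z) axis.
#'
#' @param n_slices Number of sections along the slicing axis (default 200).
#' @param radius In-plane tube radius, mm.
#' @param arc_curvature Bend strength: the centroid path's sagitta equals
#'   `arc_curvature * length / 2`; 0 gives a straight tube.
#' @param texture_seed Seed for the internal texture.
#' @param inplane_dim,inplane_spacing In-plane grid size (pixels) and
#'   spacing (mm).
#' @param thickness Slice thickness, mm.
#' @return A [volume_image] (slice axis 3) with generator parameters in
#'   attribute `"record"`.
#' @export
make_banana_phantom <- function(n_slices = 200L, radius = 15,
                                arc_curvature = 0.4, texture_seed = 1L,
                                inplane_dim = c(80L, 80L),
                                inplane_spacing = c(2, 2), thickness = 1) {
  if (n_slices < 10L) stop("make_banana_phantom: need at least 10 slices")
  if (radius <= 0 || inplane_spacing[1] <= 0)
    stop("make_banana_phantom: degenerate geometry")
  L <- n_slices * thickness
  sagitta <- arc_curvature * L / 2
  xs <- (seq_len(inplane_dim[1]) - (inplane_dim[1] + 1) / 2) * inplane_spacing[1]
  ys <- (seq_len(inplane_dim[2]) - (inplane_dim[2] + 1) / 2) * inplane_spacing[2]
  tex <- fourier_texture(texture_seed, n_waves = 14L,
                         freq_range = c(radius / 2, radius * 1.5),
                         amplitude = 25)
  X <- matrix(xs, length(xs), length(ys))
  Y <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  vox <- array(0, c(inplane_dim, n_slices))
  for (k in seq_len(n_slices)) {
    tk <- (k - 0.5) / n_slices
    xc <- sagitta * (1 - (2 * tk - 1)^2)
    taper <- 0.55 + 0.45 * sin(pi * tk)
    a <- radius * taper
    b <- 0.75 * radius * taper
    rho2 <- ((X - xc) / a)^2 + (Y / b)^2
    # band-limited (MR-like) rim: smooth falloff over ~2-3 pixels instead of
    # a hard cutoff, so subvoxel boundary shifts decorrelate quadratically
    rim <- stats::plogis((1 - sqrt(rho2)) / 0.12)
    z <- (k - 0.5) * thickness - L / 2
    slice <- (100 + 60 * pmax(1 - rho2, 0) + 30 * (Y / b) + tex(X, Y, z)) * rim
    vox[, , k] <- slice
  }
  v <- volume_image(vox, spacing = c(inplane_spacing, thickness),
                    origin = c(xs[1], ys[1], -L / 2 + thickness / 2),
                    slice_axis = 3L)
  attr(v, "record") <- list(generator = "banana", n_slices = n_slices,
                            radius = radius, arc_curvature = arc_curvature,
                            texture_seed = texture_seed,
                            inplane_dim = inplane_dim,
                            inplane_spacing = inplane_spacing,
                            thickness = thickness)
  v
}

#' Layered ellipsoid phantom for deformable benchmarks
#'
#' Nested smooth ellipsoidal shells of distinct intensities plus a curved
#' internal rod, defined as a function of physical space and sampled at
#' the requested section positions: slicing the same object at different
#' thicknesses samples the same anatomy.
#'
#' @param n_sections Number of sections (default 40).
#' @param thickness Section thickness, mm (default 0.05, i.e. 50 um).
#' @param seed Texture seed.
#' @param inplane_dim,inplane_spacing In-plane geometry (default 48x48 at
#'   50 um).
#' @param z0 Physical z of the first section center; default 0 so that
#'   doubling the thickness keeps every second section position.
#' @return A [volume_image] with a `"record"` attribute.
#' @export
make_layered_phantom <- function(n_sections = 40L, thickness = 0.05,
                                 seed = 1L, inplane_dim = c(48L, 48L),
                                 inplane_spacing = c(0.05, 0.05), z0 = 0) {
  if (n_sections < 10L) stop("make_layered_phantom: need at least 10 sections")
  L <- n_sections * thickness
  W <- inplane_dim[1] * inplane_spacing[1]
  zc <- z0 + L / 2   # fixed in physical space, independent of thickness
  xs <- (seq_len(inplane_dim[1]) - (inplane_dim[1] + 1) / 2) * inplane_spacing[1]
  ys <- (seq_len(inplane_dim[2]) - (inplane_dim[2] + 1) / 2) * inplane_spacing[2]
  X <- matrix(xs, length(xs), length(ys))
  Y <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  ax <- 0.42 * W; ay <- 0.36 * W; az <- 0.48 * L
  tex <- fourier_texture(seed, n_waves = 12L,
                         freq_range = c(W / 8, W / 3), amplitude = 12)
  vox <- array(0, c(inplane_dim, n_sections))
  for (k in seq_len(n_sections)) {
    z <- z0 + (k - 1) * thickness
    rho <- sqrt((X / ax)^2 + (Y / ay)^2 + ((z - zc) / az)^2)
    slice <- ifelse(rho < 1, 60, 0)
    slice[rho < 0.72] <- 120
    slice[rho < 0.42] <- 200
    # curved rod threading the object
    xr <- 0.16 * W * sin(2 * pi * (z - z0) / L)
    yr <- 0.12 * W * cos(2 * pi * (z - z0) / L)
    rod <- ((X - xr)^2 + (Y - yr)^2) < (0.07 * W)^2 & rho < 0.95
    slice[rod] <- 255
    slice <- slice + tex(X, Y, z) * (rho < 1)
    vox[, , k] <- slice
  }
  v <- volume_image(vox, spacing = c(inplane_spacing, thickness),
                    origin = c(xs[1], ys[1], z0), slice_axis = 3L)
  attr(v, "record") <- list(generator = "layered", n_sections = n_sections,
                            thickness = thickness, seed = seed,
                            inplane_dim = inplane_dim,
                            inplane_spacing = inplane_spacing, z0 = z0)
  v
}

#' Apply random per-section rigid distortions
#'
#' Each section is independently translated and rotated by zero-mean
#' Gaussian draws (defaults: sigma 10 mm per translation axis, 10 degrees
#' rotation), applied about the section grid center in the pull-back
#' convention: `distorted(p) = clean(g_i(p))`.
#'
#' @param stack A [section_stack].
#' @param sigma_t Translation standard deviation, mm.
#' @param sigma_theta Rotation standard deviation, degrees.
#' @param seed Integer seed (draws are bit-reproducible).
#' @return List with elements `stack` (distorted) and `record` (per-section
#'   ground-truth [rigid2d] transforms plus parameters and seed).
#' @export
distort_rigid <- function(stack, sigma_t = 10, sigma_theta = 10, seed = 1L) {
  n <- n_sections(stack)
  draws <- with_seed(seed, list(theta = stats::rnorm(n, 0, sigma_theta),
                                tx = stats::rnorm(n, 0, sigma_t),
                                ty = stats::rnorm(n, 0, sigma_t)))
  ctr <- grid_center(stack$sections[[1]])
  transforms <- lapply(seq_len(n), function(i)
    rigid2d(draws$theta[i], draws$tx[i], draws$ty[i], center = ctr))
  sections <- lapply(seq_len(n), function(i) {
    if (sigma_t == 0 && sigma_theta == 0) stack$sections[[i]]
    else resample_planar(stack$sections[[i]], transforms[[i]],
                         interpolation = "cubic")
  })
  list(stack = section_stack(sections, thickness = stack$thickness,
                             z_origin = stack$z_origin),
       record = list(transforms = transforms, sigma_t = sigma_t,
                     sigma_theta = sigma_theta, seed = seed))
}

#' Remove part of the content of selected sections
#'
#' Emulates severely damaged sections: for each listed index a seeded
#' random half-plane through the section's intensity centroid is chosen
#' and the given fraction of foreground pixels on one side is set to
#' background (the cut offset is the exact projection quantile, so the
#' removed foreground fraction is exact up to pixel discreteness).
#'
#' @param stack A [section_stack].
#' @param indices 1-based section indices to ablate.
#' @param fraction Fraction of foreground removed, in (0, 1); default 0.5.
#' @param seed Seed for the per-section cut orientations.
#' @return List with `stack` and `record` (indices, angles, fraction, seed).
#' @export
ablate_sections <- function(stack, indices, fraction = 0.5, seed = 1L) {
  n <- n_sections(stack)
  indices <- as.integer(indices)
  if (any(indices < 1L | indices > n))
    stop("ablate_sections: index out of range")
  if (fraction <= 0 || fraction >= 1)
    stop("ablate_sections: fraction must be in (0, 1)")
  angles <- with_seed(seed, stats::runif(length(indices), 0, 2 * pi))
  sections <- stack$sections
  for (k in seq_along(indices)) {
    i <- indices[k]
    img <- sections[[i]]
    g <- grid_coords(img)
    X <- matrix(g$x, length(g$x), length(g$y))
    Y <- matrix(g$y, length(g$x), length(g$y), byrow = TRUE)
    fg <- img$pixels > 0.05 * max(img$pixels)
    if (!any(fg)) next
    w <- img$pixels * fg
    cx <- sum(X * w) / sum(w); cy <- sum(Y * w) / sum(w)
    nx <- cos(angles[k]); ny <- sin(angles[k])
    proj <- (X - cx) * nx + (Y - cy) * ny
    cut <- stats::quantile(proj[fg], 1 - fraction, names = FALSE)
    px <- img$pixels
    px[proj > cut & fg] <- 0
    sections[[i]] <- planar_image(px, img$spacing, img$origin)
  }
  list(stack = section_stack(sections, thickness = stack$thickness,
                             z_origin = stack$z_origin),
       record = list(indices = indices, angles = angles,
                     fraction = fraction, seed = seed))
}

#' Smooth random displacement field calibrated to a target median
#'
#' Each component is seeded white noise smoothed with a Gaussian kernel of
#' physical width `kernel_sigma` and linearly rescaled to \[-r, r\], with
#' the amplitude `r` set by [calibrate_amplitude()] so that the median
#' displacement-vector magnitude equals `target_median` exactly (up to
#' floating point).
#'
#' @param shape Grid size, pixels (length 2).
#' @param spacing Pixel spacing, mm (length 1 or 2).
#' @param kernel_sigma Gaussian kernel sigma, mm (default 0.3 mm = 300 um).
#' @param target_median Target median displacement magnitude, mm (default
#'   0.05 mm = 50 um).
#' @param seed Integer seed.
#' @return A [dispfield2d] with a `"record"` attribute carrying the
#'   parameters, the calibrated amplitude `r` and the seed.
#' @export
make_displacement_distortion <- function(shape, spacing = c(0.05, 0.05),
                                         kernel_sigma = 0.3,
                                         target_median = 0.05, seed = 1L) {
  if (kernel_sigma <= 0 || target_median <= 0)
    stop("make_displacement_distortion: kernel_sigma and target_median must be > 0")
  spacing <- rep(as.numeric(spacing), length.out = 2)
  shape <- as.integer(shape)
  noise <- with_seed(seed, list(
    n1 = matrix(stats::rnorm(prod(shape)), shape[1], shape[2]),
    n2 = matrix(stats::rnorm(prod(shape)), shape[1], shape[2])))
  sig_px <- kernel_sigma / spacing
  u1 <- gauss_smooth_mat(noise$n1, sig_px)
  u2 <- gauss_smooth_mat(noise$n2, sig_px)
  m1 <- max(abs(u1)); m2 <- max(abs(u2))
  if (m1 == 0 || m2 == 0)
    stop("make_displacement_distortion: degenerate (zero-variance) noise")
  unit <- dispfield2d(u1 / m1, u2 / m2, spacing = spacing)
  r <- calibrate_amplitude(unit, target_median)
  out <- dispfield2d(unit$u1 * r, unit$u2 * r, spacing = spacing)
  attr(out, "record") <- list(shape = shape, spacing = spacing,
                              kernel_sigma = kernel_sigma,
                              target_median = target_median,
                              amplitude_r = r, seed = seed)
  out
}

#' Calibrate the amplitude of a unit displacement field
#'
#' Uniform scaling is exact: the scale is
#' `target_median / median(|u_unit|)`, so the scaled field's median
#' magnitude equals the target to floating-point accuracy.
#'
#' @param field_unit A [dispfield2d] with nonzero median magnitude.
#' @param target_median Desired median displacement magnitude, mm.
#' @return The scalar amplitude `r`.
#' @export
calibrate_amplitude <- function(field_unit, target_median) {
  med <- stats::median(field_magnitude(field_unit))
  if (med == 0) stop("calibrate_amplitude: field has zero median magnitude")
  target_median / med
}

#' Apply independent smooth nonlinear distortions to every section
#'
#' Convenience wrapper: one calibrated displacement field per section
#' (seeds `seed`, `seed + 1`, ...), applied in the pull-back convention.
#'
#' @inheritParams make_displacement_distortion
#' @param stack A [section_stack].
#' @return List with `stack` (distorted) and `record` (per-section fields,
#'   parameters, seed).
#' @export
distort_displacement <- function(stack, kernel_sigma = 0.3,
                                 target_median = 0.05, seed = 1L) {
  n <- n_sections(stack)
  tmpl <- stack$sections[[1]]
  fields <- lapply(seq_len(n), function(i) {
    f <- make_displacement_distortion(dim(tmpl$pixels), tmpl$spacing,
                                      kernel_sigma, target_median,
                                      seed = seed + i - 1L)
    dispfield2d(f$u1, f$u2, spacing = tmpl$spacing, origin = tmpl$origin)
  })
  sections <- lapply(seq_len(n), function(i)
    resample_planar(stack$sections[[i]], fields[[i]]))
  list(stack = section_stack(sections, thickness = stack$thickness,
                             z_origin = stack$z_origin),
       record = list(fields = fields, kernel_sigma = kernel_sigma,
                     target_median = target_median, seed = seed))
}
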