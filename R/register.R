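# Intensity-based registration engine: multi-resolution derivative-free
# optimization (Nelder-Mead on normalized parameters) for rigid/affine
# models, and a Gaussian-regularized demons-style scheme for dense 2D
# deformable registration.

#' Registration settings
#'
#' @param metric Similarity metric driving the optimization: `"NCC"`
#'   (default; rescaled to \[-1,0\]), `"MSQ"` or `"MI"` (negated
#'   Mattes-style 32-bin histogram MI).
#' @param levels Multi-resolution depth (>= 1). Each level halves the
#'   resolution; levels that would shrink an axis below `min_dim` pixels
#'   are dropped.
#' @param iterations Optimizer iteration budget per level (for the
#'   deformable engine: demons iterations per level; may be a vector, one
#'   entry per level, coarsest first).
#' @param gradient_step Deformable update scale (unitless multiplier of
#'   the normalized demons force).
#' @param sigma_update Gaussian sigma, mm, applied to each demons update
#'   field (fluid-like regularization).
#' @param sigma_total Gaussian sigma, mm, applied to the accumulated total
#'   field after composition (elastic-like regularization).
#' @param multistart_angles Initial rotations, degrees, tried at the
#'   coarsest level of rigid 2D registration to escape local minima.
#' @param angle_grid Per-axis rotation offsets, degrees, searched
#'   exhaustively (outer product over the three axes) at the coarsest level
#'   of 3D registration when no explicit initialization is given.
#' @param smooth_px Gaussian pre-smoothing, in pixels, applied to both
#'   images at every pyramid level before metric evaluation (default 1.5).
#'   Equalizes frequency content so that interpolation smoothing cannot
#'   bias the optimum toward grid-aligned transforms.
#' @param bins Histogram bins for MI.
#' @param min_dim Smallest allowed image extent in the pyramid, pixels.
#' @param seed Optional integer recorded for provenance (the engine itself
#'   is deterministic).
#' @return An object of class `reg_settings`.
#' @export
reg_settings <- function(metric = "NCC", levels = 3L, iterations = 150L,
                         gradient_step = 1, sigma_update = NULL,
                         sigma_total = NULL,
                         multistart_angles = c(0, -10, 10),
                         angle_grid = c(-10, 0, 10),
                         smooth_px = 1.5, bins = 32L, min_dim = 12L,
                         seed = NULL) {
  metric <- match.arg(metric, c("NCC", "MSQ", "MI"))
  levels <- as.integer(levels)
  if (levels < 1L) stop("reg_settings: levels must be >= 1")
  if (!is.null(sigma_update) && any(sigma_update < 0))
    stop("reg_settings: sigma_update must be >= 0")
  if (!is.null(sigma_total) && any(sigma_total < 0))
    stop("reg_settings: sigma_total must be >= 0")
  structure(list(metric = metric, levels = levels,
                 iterations = as.integer(iterations),
                 gradient_step = gradient_step,
                 sigma_update = sigma_update, sigma_total = sigma_total,
                 multistart_angles = multistart_angles,
                 angle_grid = angle_grid,
                 smooth_px = smooth_px,
                 bins = as.integer(bins), min_dim = as.integer(min_dim),
                 seed = seed),
            class = "reg_settings")
}

planar_pyramid <- function(image, levels, min_dim) {
  out <- list(image)
  for (l in seq_len(levels - 1)) {
    nxt <- downsample_planar(out[[1]], 2L)
    if (min(dim(nxt$pixels)) < min_dim) break
    out <- c(list(nxt), out)
  }
  out   # coarsest first
}

volume_pyramid <- function(vol, levels, min_dim) {
  out <- list(vol)
  for (l in seq_len(levels - 1)) {
    nxt <- downsample_volume(out[[1]], 2L)
    if (min(dim(nxt$voxels)) < min_dim) break
    out <- c(list(nxt), out)
  }
  out
}

iter_budget <- function(settings, n_levels, level) {
  it <- rep(settings$iterations, length.out = n_levels)
  it[level]
}

# generic multi-level Nelder-Mead over a parametric 2D transform
optimize_params2d <- function(fixed, moving, settings, par0, make_transform,
                              parscale_of, starts = NULL) {
  fp <- planar_pyramid(fixed, settings$levels, settings$min_dim)
  mp <- planar_pyramid(moving, settings$levels, settings$min_dim)
  nl <- min(length(fp), length(mp))
  fp <- fp[(length(fp) - nl + 1):length(fp)]
  mp <- mp[(length(mp) - nl + 1):length(mp)]
  if (settings$smooth_px > 0) {
    fp <- lapply(fp, function(im) smooth_planar(im, settings$smooth_px * im$spacing))
    mp <- lapply(mp, function(im) smooth_planar(im, settings$smooth_px * im$spacing))
  }
  par <- par0
  for (l in seq_len(nl)) {
    fl <- fp[[l]]; ml <- mp[[l]]
    obj <- function(p) {
      w <- resample_planar(ml, make_transform(p), out_grid = fl,
                           interpolation = "cubic")
      metric_value(fl, w, settings$metric, settings$bins)
    }
    maxit <- iter_budget(settings, nl, l)
    ps <- parscale_of(fl)
    if (l == 1L && !is.null(starts)) {
      cands <- lapply(starts, function(s) {
        p <- par; p[seq_along(s)] <- p[seq_along(s)] + s
        stats::optim(p, obj, method = "Nelder-Mead",
                     control = list(parscale = ps, maxit = maxit,
                                    reltol = 1e-8))
      })
      best <- which.min(vapply(cands, `[[`, 0, "value"))
      par <- cands[[best]]$par
    } else {
      m0 <- obj(par)
      res <- stats::optim(par, obj, method = "Nelder-Mead",
                          control = list(parscale = ps, maxit = maxit,
                                         reltol = 1e-9))
      if (res$value <= m0 + 1e-12) par <- res$par
      else {
        cond <- simpleError("registration failed to improve over a full level")
        cond$best_par <- par
        stop(cond)
      }
    }
  }
  par
}

#' Rigid 2D registration
#'
#' Finds the rigid transform (rotation about the fixed image's grid center
#' plus translation) that, applied in the pull-back convention to the
#' moving image, minimizes the chosen metric against the fixed image.
#' Multi-resolution, with multi-start over initial rotations at the
#' coarsest level.
#'
#' @param fixed,moving [planar_image] objects on comparable grids.
#' @param settings A [reg_settings].
#' @param init Optional initializing [rigid2d].
#' @return A [rigid2d] with center at the fixed image's grid center.
#' @export
register_rigid2d <- function(fixed, moving, settings = reg_settings(),
                             init = NULL) {
  ctr <- grid_center(fixed)
  par0 <- c(0, 0, 0)
  if (!is.null(init)) {
    ri <- rigid_recenter(init, ctr)
    par0 <- c(ri$theta, ri$t)
  }
  starts <- lapply(settings$multistart_angles, function(a) a)
  par <- optimize_params2d(
    fixed, moving, settings, par0,
    make_transform = function(p) rigid2d(p[1], p[2], p[3], center = ctr),
    parscale_of = function(im) c(1, im$spacing),
    starts = starts)
  rigid2d(par[1], par[2], par[3], center = ctr)
}

#' Affine 2D registration
#'
#' Six-parameter model (rotation, translation, anisotropic log-scales,
#' shear), initialized from a rigid registration unless `init` is given.
#'
#' @inheritParams register_rigid2d
#' @param init Optional initializing `rigid2d` or `affine2d`.
#' @return An [affine2d] with center at the fixed image's grid center.
#' @export
register_affine2d <- function(fixed, moving, settings = reg_settings(),
                              init = NULL) {
  ctr <- grid_center(fixed)
  if (is.null(init)) init <- register_rigid2d(fixed, moving, settings)
  par0 <- affine_params_from(init, ctr)
  make_t <- function(p) affine2d(affine_matrix_of(p), offset = p[2:3],
                                 center = ctr)
  par <- optimize_params2d(
    fixed, moving, settings, par0, make_t,
    parscale_of = function(im) c(1, im$spacing, 0.05, 0.05, 0.05),
    starts = NULL)
  make_t(par)
}

# p = (theta, tx, ty, log_sx, log_sy, shear); M = R(theta) %*% [[sx, sh], [0, sy]]
affine_matrix_of <- function(p) {
  rot2(p[1]) %*% matrix(c(exp(p[4]), 0, p[6], exp(p[5])), 2, 2)
}

affine_params_from <- function(t, center) {
  if (inherits(t, "rigid2d")) {
    r <- rigid_recenter(t, center)
    return(c(r$theta, r$t, 0, 0, 0))
  }
  # re-center, then RQ-style decomposition M = R S (S upper triangular)
  mb <- affine_mb(t)
  off <- as.numeric(mb$b + (mb$M - diag(2)) %*% center)
  M <- mb$M
  theta <- atan2(M[2, 1], M[1, 1])
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  S <- t(R) %*% M
  c(theta * 180 / pi, off, log(abs(S[1, 1])), log(abs(S[2, 2])), S[1, 2])
}

#' Affine 3D registration
#'
#' Twelve-parameter model (Euler rotations, translation, log-scales,
#' shears) optimized coarse-to-fine; a six-parameter rigid stage
#' initializes the full affine stage.
#'
#' @param fixed,moving [volume_image] objects.
#' @param settings A [reg_settings].
#' @param init Optional initializing [affine3d].
#' @param dof 6 (rigid) or 12 (full affine).
#' @return An [affine3d] with center at the fixed volume's grid center.
#' @export
register_affine3d <- function(fixed, moving, settings = reg_settings(levels = 3L, min_dim = 20L),
                              init = NULL, dof = 12L) {
  ctr <- fixed$origin + (dim(fixed$voxels) - 1) / 2 * fixed$spacing
  fp <- volume_pyramid(fixed, settings$levels, settings$min_dim)
  mp <- volume_pyramid(moving, settings$levels, settings$min_dim)
  nl <- min(length(fp), length(mp))
  fp <- fp[(length(fp) - nl + 1):length(fp)]
  mp <- mp[(length(mp) - nl + 1):length(mp)]
  if (settings$smooth_px > 0) {
    smv <- function(v) volume_image(gauss_smooth_arr3(v$voxels,
                                                      rep(settings$smooth_px, 3)),
                                    v$spacing, v$origin, v$slice_axis)
    fp <- lapply(fp, smv)
    mp <- lapply(mp, smv)
  }

  make_t <- function(p) make_t_affine3d(p, ctr)
  par <- rep(0, 12)
  if (!is.null(init)) par <- affine3d_params_from(init, ctr)
  else {
    # centroid translation init + coarse rotation grid search at the
    # lowest resolution (escapes local minima near identity)
    fl <- fp[[1]]; ml <- mp[[1]]
    par[4:6] <- vol_centroid(ml) - vol_centroid(fl)
    grid <- settings$angle_grid
    if (length(grid) > 1L) {
      best <- Inf; best_a <- c(0, 0, 0)
      for (ax in grid) for (ay in grid) for (az in grid) {
        p <- par; p[1:3] <- c(ax, ay, az)
        w <- resample_volume(ml, make_t_affine3d(p, ctr), out_grid = fl)
        m <- metric_value(fl, w, settings$metric, settings$bins)
        if (m < best) { best <- m; best_a <- c(ax, ay, az) }
      }
      par[1:3] <- best_a
    }
    rm(fl, ml)
  }

  # Metric is sampled on a half-voxel-offset grid so the fixed volume is
  # interpolated exactly like the moving one: otherwise grid-aligned
  # transforms enjoy an interpolation-blur advantage that walls off the
  # optimizer ("cliff" at integer z-sampling).
  half_grid <- function(vol) {
    volume_image(array(0, pmax(dim(vol$voxels) - 1L, 2L)),
                 spacing = vol$spacing,
                 origin = vol$origin + vol$spacing / 2,
                 slice_axis = vol$slice_axis)
  }
  run_stage <- function(par, active) {
    for (l in seq_len(nl)) {
      fl <- fp[[l]]; ml <- mp[[l]]
      hg <- half_grid(fl)
      fh <- resample_volume(fl, identity_affine3d(), out_grid = hg)
      obj <- function(pa) {
        p <- par; p[active] <- pa
        w <- resample_volume(ml, make_t(p), out_grid = hg)
        metric_value(fh, w, settings$metric, settings$bins)
      }
      ps <- c(3, 3, 3, 2 * fl$spacing, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05)[active]
      res <- stats::optim(par[active], obj, method = "Nelder-Mead",
                          control = list(parscale = ps,
                                         maxit = iter_budget(settings, nl, l),
                                         reltol = 1e-9))
      if (res$value <= obj(par[active]) + 1e-12) par[active] <- res$par
    }
    par
  }
  par <- run_stage(par, 1:6)
  if (dof >= 12L) par <- run_stage(par, 1:12)
  make_t(par)
}

# p: angles (deg) 1:3, translation 4:6, log-scales 7:9, shears 10:12
make_t_affine3d <- function(p, ctr) {
  R <- rot3(p[1], p[2], p[3])
  S <- diag(exp(p[7:9]))
  S[1, 2] <- p[10]; S[1, 3] <- p[11]; S[2, 3] <- p[12]
  affine3d(R %*% S, offset = p[4:6], center = ctr)
}

vol_centroid <- function(v) {
  vox <- pmax(v$voxels, 0)
  tot <- sum(vox)
  if (tot == 0) return(v$origin + (dim(v$voxels) - 1) / 2 * v$spacing)
  d <- dim(v$voxels)
  ix <- rep(seq_len(d[1]), times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]), each = d[1] * d[2])
  w <- as.numeric(vox) / tot
  v$origin + (c(sum(ix * w), sum(iy * w), sum(iz * w)) - 1) * v$spacing
}

rot3 <- function(ax, ay, az) {
  a <- c(ax, ay, az) * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3, 3)
  Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3, 3)
  Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

affine3d_params_from <- function(t, center) {
  mb <- affine_mb(t)
  off <- as.numeric(mb$b + (mb$M - diag(3)) %*% center)
  M <- mb$M
  # polar-like decomposition via QR of M: M = R S
  qr_ <- qr(M)
  R <- qr.Q(qr_); S <- qr.R(qr_)
  sgn <- sign(diag(S)); sgn[sgn == 0] <- 1
  R <- R %*% diag(sgn); S <- diag(sgn) %*% S
  ay <- asin(-R[3, 1])
  ax <- atan2(R[3, 2], R[3, 3])
  az <- atan2(R[2, 1], R[1, 1])
  c(ax, ay, az) * 180 / pi -> ang
  c(ang, off, log(diag(S)), S[1, 2], S[1, 3], S[2, 3])
}

resample_field_to <- function(field, grid_image) {
  u1 <- resample_planar(new_planar(field$u1, field$spacing, field$origin),
                        identity2d(), out_grid = grid_image)
  u2 <- resample_planar(new_planar(field$u2, field$spacing, field$origin),
                        identity2d(), out_grid = grid_image)
  new_dispfield(u1$pixels, u2$pixels, spacing = grid_image$spacing,
                origin = grid_image$origin)
}

#' Deformable 2D registration (Gaussian-regularized demons)
#'
#' Iterative scheme: at each step the normalized intensity-difference force
#' (demons force) times `gradient_step` forms an update field, which is
#' smoothed with `sigma_update`, composed into the running total field, and
#' the total is smoothed with `sigma_total`.  Multi-resolution; the
#' returned total field never scores worse than the identity warp under
#' the settings metric.
#'
#' @param fixed,moving [planar_image] objects on the same grid.
#' @param settings A [reg_settings]; `sigma_update`/`sigma_total` default
#'   to one pixel.
#' @return A [dispfield2d] on the fixed image's grid.
#' @export
register_deformable2d <- function(fixed, moving,
                                  settings = reg_settings(levels = 2L,
                                                          iterations = 20L)) {
  stopifnot(identical(dim(fixed$pixels), dim(moving$pixels)))
  sig_u <- if (is.null(settings$sigma_update)) mean(fixed$spacing)
           else settings$sigma_update
  sig_t <- if (is.null(settings$sigma_total)) mean(fixed$spacing)
           else settings$sigma_total
  rng <- max(diff(range(fixed$pixels)), diff(range(moving$pixels)))
  if (rng == 0) {
    warning("register_deformable2d: flat images, returning zero field")
    return(zero_field(fixed))
  }
  fp <- planar_pyramid(fixed, settings$levels, settings$min_dim)
  mp <- planar_pyramid(moving, settings$levels, settings$min_dim)
  nl <- min(length(fp), length(mp))
  fp <- fp[(length(fp) - nl + 1):length(fp)]
  mp <- mp[(length(mp) - nl + 1):length(mp)]

  u <- NULL
  for (l in seq_len(nl)) {
    fl <- fp[[l]]; ml <- mp[[l]]
    u <- if (is.null(u)) zero_field(fl) else resample_field_to(u, fl)
    kinv2 <- mean(fl$spacing)^2   # converts diff^2 to 1/mm^2 scale parity
    f_n <- fl$pixels / rng
    best <- u
    wim <- resample_planar(ml, u, out_grid = fl)
    best_m <- metric_value(fl, wim, settings$metric, settings$bins)
    n_it <- iter_budget(settings, nl, l)
    for (it in seq_len(n_it)) {
      w_n <- wim$pixels / rng
      g <- planar_gradient(planar_image(w_n, fl$spacing, fl$origin))
      diffv <- f_n - w_n
      denom <- g$gx^2 + g$gy^2 + diffv^2 / kinv2
      denom[denom < 1e-12] <- Inf
      step1 <- settings$gradient_step * diffv * g$gx / denom
      step2 <- settings$gradient_step * diffv * g$gy / denom
      upd <- new_dispfield(gauss_smooth_mat(step1, sig_u / fl$spacing),
                           gauss_smooth_mat(step2, sig_u / fl$spacing),
                           spacing = fl$spacing, origin = fl$origin)
      u <- smooth_field(compose_fields(upd, u), sig_t)
      wim <- resample_planar(ml, u, out_grid = fl)
      m <- metric_value(fl, wim, settings$metric, settings$bins)
      if (m < best_m) { best_m <- m; best <- u }
    }
    u <- best
  }
  if (!identical(dim(u$u1), dim(fixed$pixels))) u <- resample_field_to(u, fixed)
  u
}
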