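# Iterative pairwise alignment to a 3D reference (shape prior): alternate
# a global 3D affine registration of the reference to the current
# reconstruction with per-section 2D registrations to the matching virtual
# cuts of the reference.

#' Virtual reference cuts on a stack grid
#'
#' Reslices the reference volume through the 3D transform onto the stack's
#' grid, producing one virtual section per stack index.  Pure function of
#' (reference, t3d, grid).
#'
#' @param reference A [volume_image].
#' @param t3d [affine3d] pull-back map: stack physical coordinates ->
#'   reference physical coordinates.
#' @param stack_grid A [section_stack] supplying the output geometry.
#' @param interpolation Sampling kernel.
#' @return A [section_stack] of virtual cuts.
#' @export
virtual_sections <- function(reference, t3d, stack_grid,
                             interpolation = "linear") {
  tmpl <- stack_grid$sections[[1]]
  d <- dim(tmpl$pixels)
  n <- n_sections(stack_grid)
  gx <- tmpl$origin[1] + (seq_len(d[1]) - 1) * tmpl$spacing[1]
  gy <- tmpl$origin[2] + (seq_len(d[2]) - 1) * tmpl$spacing[2]
  base <- cbind(rep(gx, times = d[2]), rep(gy, each = d[1]))
  sections <- lapply(seq_len(n), function(i) {
    pts <- cbind(base, section_z(stack_grid, i))
    src <- map_points(t3d, pts)
    xi <- (src[, 1] - reference$origin[1]) / reference$spacing[1] + 1
    yi <- (src[, 2] - reference$origin[2]) / reference$spacing[2] + 1
    zi <- (src[, 3] - reference$origin[3]) / reference$spacing[3] + 1
    vals <- switch(interpolation,
                   linear = sample_trilinear(reference$voxels, xi, yi, zi, 0),
                   cubic = sample_tricubic(reference$voxels, xi, yi, zi, 0),
                   nearest = {
                     i0 <- round(xi); j0 <- round(yi); k0 <- round(zi)
                     dd <- dim(reference$voxels)
                     ok <- i0 >= 1 & i0 <= dd[1] & j0 >= 1 & j0 <= dd[2] &
                           k0 >= 1 & k0 <= dd[3]
                     out <- numeric(length(xi))
                     out[ok] <- reference$voxels[cbind(i0[ok], j0[ok], k0[ok])]
                     out
                   })
    planar_image(matrix(vals, d[1], d[2]), tmpl$spacing, tmpl$origin)
  })
  vs <- section_stack(sections, stack_grid$thickness,
                      z_origin = stack_grid$z_origin)
  if (all(vapply(sections, function(s) all(s$pixels == 0), TRUE)))
    stop("virtual_sections: reference does not overlap the stack grid")
  vs
}

#' Iterative pairwise alignment of a stack to a reference volume
#'
#' Per iteration: (1) stack the current sections into a volume; (2)
#' register the reference (moving) to that volume (fixed), refining the
#' cumulative 3D affine; (3) reslice the reference into virtual cuts; (4)
#' re-register every ORIGINAL section to its virtual cut, replacing (not
#' chaining) the per-section 2D transforms.  Converges to a reconstruction
#' affinely aligned with the reference in which neighboring sections are
#' mutually consistent.
#'
#' @param stack A [section_stack] (the original experimental sections).
#' @param reference A [volume_image] shape prior.
#' @param n_iter Number of iterations (default 10).
#' @param model Per-section 2D model, `"rigid"` (default) or `"affine"`.
#' @param settings2d 2D registration settings (default CC-driven).
#' @param settings3d 3D registration settings (default MI-driven).
#' @param tol_px Optional early stop: mean per-section parameter change,
#'   in pixels, below which iteration halts (default 0.05; set to 0 to
#'   disable).
#' @return List with `stack` (aligned sections), `state` (class
#'   `pairwise_state`: per-section transforms, cumulative [affine3d],
#'   per-iteration mean metric and mean parameter change).
#' @export
iterative_pairwise <- function(stack, reference, n_iter = 10L,
                               model = c("rigid", "affine"),
                               settings2d = reg_settings(metric = "NCC"),
                               settings3d = reg_settings(metric = "MI",
                                                         levels = 3L,
                                                         min_dim = 20L),
                               tol_px = 0.05) {
  model <- match.arg(model)
  if (n_iter < 1L) stop("iterative_pairwise: n_iter must be >= 1")
  n <- n_sections(stack)
  sp <- mean(stack$sections[[1]]$spacing)
  transforms <- replicate(n, identity2d(), simplify = FALSE)
  current <- stack
  t3d <- NULL
  metric_hist <- numeric(0); change_hist <- numeric(0)
  for (it in seq_len(n_iter)) {
    vol <- stack_to_volume(current)
    t3d <- tryCatch(
      register_affine3d(vol, reference, settings3d, init = t3d),
      error = function(e) {
        warning("iterative_pairwise: 3D registration failed at iteration ",
                it, " (", conditionMessage(e), "); state preserved")
        NULL
      })
    if (is.null(t3d)) break
    vcuts <- virtual_sections(reference, t3d, stack)
    new_transforms <- vector("list", n)
    mvals <- numeric(n)
    for (i in seq_len(n)) {
      fixed <- vcuts$sections[[i]]
      moving <- stack$sections[[i]]
      res <- tryCatch({
        if (model == "rigid") register_rigid2d(fixed, moving, settings2d)
        else register_affine2d(fixed, moving, settings2d)
      }, error = function(e) transforms[[i]])
      new_transforms[[i]] <- res
      w <- resample_planar(moving, res, out_grid = fixed)
      mvals[i] <- metric_value(fixed, w, settings2d$metric, settings2d$bins)
    }
    # mean parameter change in pixels (translation at grid center + angle arc)
    chg <- mean(vapply(seq_len(n), function(i) {
      ctr <- grid_center(stack$sections[[i]])
      d <- map_points(new_transforms[[i]], matrix(ctr, 1)) -
           map_points(transforms[[i]], matrix(ctr, 1))
      sqrt(sum(d^2)) / sp
    }, 0))
    transforms <- new_transforms
    current <- section_stack(
      lapply(seq_len(n), function(i)
        resample_planar(stack$sections[[i]], transforms[[i]],
                        out_grid = stack$sections[[i]])),
      stack$thickness, z_origin = stack$z_origin)
    metric_hist <- c(metric_hist, mean(mvals))
    change_hist <- c(change_hist, chg)
    if (tol_px > 0 && chg < tol_px) break
  }
  state <- structure(list(transforms = transforms, t3d = t3d,
                          iterations = length(metric_hist),
                          mean_metric = metric_hist,
                          mean_change_px = change_hist, model = model),
                     class = "pairwise_state")
  list(stack = current, state = state)
}

#' @export
print.pairwise_state <- function(x, ...) {
  cat(sprintf("<pairwise_state> %d iterations, model %s\n", x$iterations,
              x$model))
  if (x$iterations > 0)
    cat("  mean parameter change (px):",
        paste(signif(x$mean_change_px, 3), collapse = ", "), "\n")
  invisible(x)
}
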