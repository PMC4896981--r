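# Coarse-to-fine alignment: combine the global shape of a reference-aligned
# (coarse) rigid series with the high-frequency component of a sequential
# (fine) rigid series.  Parameter-space algebra requires every transform to
# share a rotation pivot; the series are normalized to the image-center
# pivot before smoothing and merging.

#' Rigid series utilities
#'
#' A rigid series is a list of [rigid2d], one per section, with a common
#' pivot and angles unwrapped along the series (no neighbor jump exceeds
#' 180 degrees).
#'
#' @param transforms List of [rigid2d].
#' @param center Common pivot, mm.
#' @return Object of class `rigid_series` (list of recentered transforms).
#' @export
rigid_series <- function(transforms, center = c(0, 0)) {
  ts <- lapply(transforms, rigid_recenter, center = center)
  th <- vapply(ts, `[[`, 0, "theta")
  # unwrap: remove +-360 jumps accumulated by the (-180, 180] convention
  for (k in seq_along(th)[-1]) {
    d <- th[k] - th[k - 1]
    th[k] <- th[k - 1] + wrap_angle(d)
  }
  ts <- lapply(seq_along(ts), function(k) {
    t <- ts[[k]]; t$theta <- th[k]; t
  })
  structure(ts, class = "rigid_series", center = center)
}

#' Parameter matrix of a rigid series
#' @param series A [rigid_series()].
#' @return Matrix with columns theta (deg), tx, ty (mm), one row per section.
#' @export
series_params <- function(series) {
  cbind(theta = vapply(series, `[[`, 0, "theta"),
        tx = vapply(series, function(t) t$t[1], 0),
        ty = vapply(series, function(t) t$t[2], 0))
}

series_from_params <- function(par, center) {
  structure(lapply(seq_len(nrow(par)), function(k)
    rigid2d(par[k, 1], par[k, 2], par[k, 3], center = center)),
    class = "rigid_series", center = center)
}

#' Coarse-scale series: per-section registration to reference cuts
#'
#' Each section is rigidly registered, independently, to the corresponding
#' section of the reference stack.  Failed registrations are replaced by
#' the identity and flagged.
#'
#' @param stack,reference_sections [section_stack]s of equal length.
#' @param settings A [reg_settings].
#' @return List with `series` (a [rigid_series()]) and `failed` indices.
#' @export
coarse_series <- function(stack, reference_sections,
                          settings = reg_settings(metric = "MI")) {
  n <- n_sections(stack)
  if (n != n_sections(reference_sections))
    stop("coarse_series: section counts differ")
  ctr <- grid_center(stack$sections[[1]])
  failed <- integer(0)
  ts <- lapply(seq_len(n), function(i) {
    tryCatch(
      register_rigid2d(reference_sections$sections[[i]], stack$sections[[i]],
                       settings),
      error = function(e) { failed <<- c(failed, i); identity2d() })
  })
  list(series = rigid_series(ts, center = ctr), failed = failed)
}

#' Gaussian smoothing of a rigid series along the stack dimension
#'
#' Each parameter channel (theta, tx, ty) is convolved along the section
#' index with a normalized Gaussian; `sigma_z = 0` returns the input.
#'
#' @param series A [rigid_series()].
#' @param sigma_z Standard deviation, in sections.
#' @param boundary `"reflect"` (default) or `"nearest"` padding.
#' @return A [rigid_series()].
#' @export
smooth_series <- function(series, sigma_z, boundary = "reflect") {
  if (sigma_z < 0) stop("smooth_series: sigma_z must be >= 0")
  if (sigma_z == 0) return(series)
  par <- series_params(series)
  sm <- apply(par, 2, gauss_smooth_vec, sigma = sigma_z, boundary = boundary)
  series_from_params(sm, attr(series, "center"))
}

#' Merge coarse and fine rigid series
#'
#' Parameter-wise: `merged_i = coarse_i + (fine_i - smooth(fine)_i)` — the
#' low-frequency trend (including any z-shift / banana-effect drift) comes
#' from the coarse series, the high-frequency section-to-section detail
#' from the fine series.
#'
#' @param coarse,fine [rigid_series()]s of equal length and common pivot.
#' @param sigma_z Smoothing, in sections, defining the split (default 5).
#' @param boundary Padding rule passed to [smooth_series()].
#' @return A [rigid_series()].
#' @export
merge_series <- function(coarse, fine, sigma_z = 5, boundary = "reflect") {
  if (length(coarse) != length(fine))
    stop("merge_series: series lengths differ")
  if (max(abs(attr(coarse, "center") - attr(fine, "center"))) > 1e-9)
    stop("merge_series: series pivots differ")
  pc <- series_params(coarse)
  pf <- series_params(fine)
  ps <- series_params(smooth_series(fine, sigma_z, boundary))
  series_from_params(pc + (pf - ps), attr(coarse, "center"))
}

#' Coarse-to-fine reconstruction
#'
#' Computes the coarse series (per-section registration to reference
#' cuts), then the fine series (naive or graph-based sequential alignment
#' run on the coarse-aligned stack, so its high-frequency component is the
#' residual section-to-section correction), merges the two with
#' [merge_series()], and resamples each original section exactly once
#' through its merged transform.  The fine series must be computed on the
#' coarse-aligned sections: both series estimate the same per-section
#' distortions, so adding the high-frequency component of an independent
#' sequential alignment would apply that correction twice.
#'
#' @param stack A [section_stack] to reconstruct.
#' @param reference_sections Corresponding reference cuts
#'   ([section_stack]).
#' @param fine_method `"naive"` (sequential, epsilon = 1) or `"graphseq"`.
#' @param r Reference section for the fine series; default middle.
#' @param sigma_z Merge smoothing, sections (default 5).
#' @param settings_coarse,settings_fine Registration settings.  The
#'   defaults encode the workflow's division of labor: the coarse stage is
#'   a quick single-start MI alignment whose job is the global trend (its
#'   per-section jitter is exactly what the merge removes), while the fine
#'   stage, registering nearly identical neighbors, runs at full
#'   precision.
#' @param epsilon,lam Graph parameters when `fine_method = "graphseq"`.
#' @param truth Optional ground-truth [section_stack]; when supplied the
#'   report carries MSQ of coarse-only, fine-only and merged
#'   reconstructions against it.
#' @return List with `stack`, `series` (coarse/fine/merged), `transforms`
#'   and `report`.
#' @export
coarse_to_fine <- function(stack, reference_sections,
                           fine_method = c("naive", "graphseq"), r = NULL,
                           sigma_z = 5,
                           settings_coarse = reg_settings(
                             metric = "MI", levels = 3L,
                             iterations = c(60L, 40L, 20L),
                             multistart_angles = 0),
                           settings_fine = reg_settings(
                             metric = "MI", levels = 3L,
                             iterations = c(80L, 80L, 160L)),
                           epsilon = 3, lam = 0, truth = NULL) {
  fine_method <- match.arg(fine_method)
  n <- n_sections(stack)
  if (is.null(r)) r <- (n + 1L) %/% 2L
  ctr <- grid_center(stack$sections[[1]])

  co <- coarse_series(stack, reference_sections, settings_coarse)

  apply_series <- function(series)
    section_stack(lapply(seq_len(n), function(i)
      resample_planar(stack$sections[[i]], series[[i]],
                      out_grid = stack$sections[[i]])),
      stack$thickness, z_origin = stack$z_origin)

  eps_fine <- if (fine_method == "naive") 1 else epsilon
  coarse_aligned <- apply_series(co$series)
  gs <- reconstruct_graphseq(coarse_aligned, epsilon = eps_fine, lam = lam,
                             r = r, model = "rigid",
                             settings = settings_fine)
  fine <- rigid_series(lapply(gs$transforms, as_rigid, center = ctr),
                       center = ctr)

  merged <- merge_series(co$series, fine, sigma_z)
  out <- apply_series(merged)
  report <- list(workflow = "coarse_to_fine", n_sections = n,
                 sigma_z = sigma_z, fine_method = fine_method,
                 reference = r, coarse_failed = co$failed)
  if (!is.null(truth)) {
    # fine-only benchmark: an independent sequential alignment of the
    # original (uncorrected) stack, which exhibits the z-shift drift the
    # merge is meant to remove
    gs0 <- reconstruct_graphseq(stack, epsilon = eps_fine, lam = lam, r = r,
                                model = "rigid", settings = settings_fine)
    fine_only <- rigid_series(lapply(gs0$transforms, as_rigid, center = ctr),
                              center = ctr)
    tv <- stack_to_volume(truth)
    report$msq_coarse <- msq(tv, stack_to_volume(apply_series(co$series)))
    report$msq_fine <- msq(tv, stack_to_volume(apply_series(fine_only)))
    report$msq_merged <- msq(tv, stack_to_volume(out))
    report$fine_only_series <- fine_only
  }
  class(report) <- "recon_report"
  list(stack = out,
       series = list(coarse = co$series, fine = fine, merged = merged),
       transforms = merged, report = report)
}
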