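# Iterative deformable refinement: register every section to the average
# of its epsilon-neighborhood and repeat.  Removes section-specific
# nonlinear distortions by pulling each section toward the local anatomy
# consensus; with unlimited iterations the stack over-smooths and drifts
# from the true anatomy, so the per-iteration history is kept to locate
# the optimal stop point.

#' Average of a section's neighborhood
#'
#' Pixel-wise mean of the sections within distance `epsilon` of section
#' `i` (section `i` itself excluded), truncated at the stack boundaries;
#' the divisor is the actual neighbor count.
#'
#' @param stack A [section_stack].
#' @param i Section index (1-based).
#' @param epsilon Neighborhood radius (>= 1), sections.
#' @return A [planar_image].
#' @export
neighborhood_average <- function(stack, i, epsilon) {
  n <- n_sections(stack)
  if (epsilon < 1) stop("neighborhood_average: epsilon must be >= 1")
  idx <- setdiff(max(1, i - epsilon):min(n, i + epsilon), i)
  acc <- 0
  for (j in idx) acc <- acc + stack$sections[[j]]$pixels
  tmpl <- stack$sections[[1]]
  planar_image(acc / length(idx), tmpl$spacing, tmpl$origin)
}

#' One Jacobi iteration of deformable refinement
#'
#' All fixed targets (neighborhood averages) are computed from the current
#' stack before any section is updated; each current section is then
#' deformably registered to its target, the update composed into the
#' section's accumulated total field, and the output produced by warping
#' the ORIGINAL section once through the accumulated field (no repeated
#' interpolation).
#'
#' @param current Current [section_stack] (originals warped by `totals`).
#' @param original The original [section_stack].
#' @param totals List of accumulated [dispfield2d], one per section.
#' @param epsilon Neighborhood radius.
#' @param settings A [reg_settings] for the deformable engine.
#' @return List with `stack` (updated), `totals`, `updates`, and `failed`
#'   (indices whose registration failed; they receive zero updates).
#' @export
deformable_iteration <- function(current, original, totals, epsilon,
                                 settings = reg_settings(levels = 2L,
                                                         iterations = 20L,
                                                         metric = "MSQ")) {
  n <- n_sections(current)
  targets <- lapply(seq_len(n), function(i)
    neighborhood_average(current, i, epsilon))
  failed <- integer(0)
  updates <- lapply(seq_len(n), function(i) {
    tryCatch(
      register_deformable2d(targets[[i]], current$sections[[i]], settings),
      error = function(e) { failed <<- c(failed, i)
                            zero_field(current$sections[[i]]) })
  })
  new_totals <- lapply(seq_len(n), function(i)
    compose_fields(updates[[i]], totals[[i]]))
  sections <- lapply(seq_len(n), function(i)
    resample_planar(original$sections[[i]], new_totals[[i]],
                    out_grid = original$sections[[i]]))
  list(stack = section_stack(sections, original$thickness,
                             z_origin = original$z_origin),
       totals = new_totals, updates = updates, failed = failed)
}

#' Iterative deformable reconstruction
#'
#' Repeats [deformable_iteration()], recording the mean MSQ between
#' consecutive reconstructions.  Stop modes: `"fixed"` runs all
#' `n_iter` iterations; `"delta_tol"` stops once the consecutive-difference
#' MSQ falls below `tol`; `"first_local_min"` stops at the first increase
#' of the consecutive-difference curve.  The full history (including the
#' per-iteration stacks' MSQ against an optional reference) is retained in
#' the report so the optimal iteration can be identified afterwards.
#'
#' @param stack A [section_stack].
#' @param epsilon Neighborhood radius (default 1).
#' @param n_iter Maximum iterations (>= 1).
#' @param settings A [reg_settings], or a list of them (one per iteration,
#'   recycled) since deformable parameters may vary across iterations.
#' @param stop Stop mode.
#' @param tol Threshold for `"delta_tol"`.
#' @param reference Optional ground-truth [section_stack]; when given, the
#'   report records per-iteration MSQ to it.
#' @param keep_stacks Keep every intermediate stack in the result (memory
#'   heavy; default FALSE keeps only the final and the best-so-far ones).
#' @return List with `stack` (after the last iteration run), `stacks`
#'   (per-iteration, if kept), `totals` (final fields), `report`
#'   (class `recon_report`) with `consec_msq`, optional `msq_to_ref`,
#'   `iterations`, `failed`.
#' @export
deformable_reconstruct <- function(stack, epsilon = 1, n_iter = 10L,
                                   settings = reg_settings(levels = 2L,
                                                           iterations = 20L,
                                                           metric = "MSQ"),
                                   stop = c("fixed", "delta_tol",
                                            "first_local_min"),
                                   tol = 1e-3, reference = NULL,
                                   keep_stacks = FALSE) {
  stop <- match.arg(stop)
  if (n_iter < 1L) stop("deformable_reconstruct: n_iter must be >= 1")
  sched <- if (inherits(settings, "reg_settings")) list(settings) else settings
  n <- n_sections(stack)
  totals <- lapply(stack$sections, zero_field)
  current <- stack
  consec <- numeric(0); to_ref <- numeric(0); failed_all <- list()
  stacks <- list()
  for (it in seq_len(n_iter)) {
    s_it <- sched[[(it - 1L) %% length(sched) + 1L]]
    res <- deformable_iteration(current, stack, totals, epsilon, s_it)
    d <- mean(vapply(seq_len(n), function(i)
      msq(res$stack$sections[[i]], current$sections[[i]]), 0))
    consec <- c(consec, d)
    if (!is.null(reference))
      to_ref <- c(to_ref, msq(stack_to_volume(reference),
                              stack_to_volume(res$stack)))
    failed_all[[it]] <- res$failed
    current <- res$stack; totals <- res$totals
    if (keep_stacks) stacks[[it]] <- current
    if (stop == "delta_tol" && d < tol) break
    if (stop == "first_local_min" && it >= 2 &&
        consec[it] > consec[it - 1]) break
  }
  report <- structure(list(
    workflow = "deformable", n_sections = n, epsilon = epsilon,
    iterations = length(consec), stop = stop, tol = tol,
    consec_msq = consec,
    msq_to_ref = if (length(to_ref)) to_ref else NULL,
    failed = failed_all), class = "recon_report")
  list(stack = current, stacks = if (keep_stacks) stacks else NULL,
       totals = totals, report = report)
}
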