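# Multi-stage reconstruction pipelines.  Every stage consumes the current
# reconstruction and contributes per-section transforms; affine
# contributions are composed analytically and any deformable fields are
# applied last, so each original section is interpolated exactly once for
# the final product.

#' Run a multi-stage reconstruction pipeline
#'
#' Stages (in order, from `"pairwise"`, `"graphseq"`, `"c2f"`,
#' `"deformable"`) are applied to the evolving reconstruction; each
#' stage's per-section transforms are merged into a running per-section
#' bundle (affine parts composed analytically, deformable fields composed
#' last), and the final sections are the ORIGINAL sections resampled once
#' through their merged maps.  Masks, when provided, are resliced with
#' nearest-neighbor interpolation through the same maps.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{stack}{A [section_stack], or a list(dir=, thickness=) pointing
#'       at `section_%04d.nii.gz` files.}
#'     \item{reference}{Optional [volume_image] (or NIfTI path) required by
#'       the `pairwise` and `c2f` stages.}
#'     \item{stages}{Ordered list; each element is a list with `workflow`
#'       (stage name) and optional `params` passed to the stage function.}
#'     \item{masks}{Optional [section_stack] of masks.}
#'     \item{seed}{Optional integer recorded in the provenance log.}
#'   }
#' @return List with `stack` (final reconstruction), `transforms`
#'   (per-section affine part), `fields` (per-section deformable part or
#'   NULL), `masks` (resliced masks or NULL), `stage_reports`, and
#'   `provenance` (stage list, parameters, seeds, timings).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stack <- config$stack
  if (is.list(stack) && !inherits(stack, "section_stack"))
    stack <- read_stack_sections(stack$dir, stack$thickness)
  reference <- config$reference
  if (is.character(reference)) reference <- read_nifti_image(reference)
  stages <- config$stages
  if (length(stages) == 0) stop("run_pipeline: no stages configured")
  stage_names <- vapply(stages, `[[`, "", "workflow")
  bad <- !stage_names %in% c("pairwise", "graphseq", "c2f", "deformable")
  if (any(bad))
    stop("run_pipeline: unknown stage(s): ",
         paste(stage_names[bad], collapse = ", "))
  first_def <- match("deformable", stage_names)
  if (!is.na(first_def)) {
    if (first_def == 1L)
      stop("run_pipeline: a deformable stage cannot come first - it can ",
           "only refine an affinely reconstructed stack; put an affine ",
           "stage (pairwise, graphseq or c2f) before it")
    if (any(stage_names[first_def:length(stage_names)] != "deformable"))
      stop("run_pipeline: affine stages cannot follow a deformable stage ",
           "(fields are composed last); reorder the pipeline")
  }

  n <- n_sections(stack)
  affines <- replicate(n, identity2d(), simplify = FALSE)
  fields <- NULL
  current <- stack
  reports <- list()
  timings <- numeric(0)

  apply_bundle <- function(i, image, interpolation = "linear") {
    tr <- if (is.null(fields)) affines[[i]]
          else transform_seq(fields[[i]], affines[[i]])
    resample_planar(image, tr, out_grid = image,
                    interpolation = interpolation)
  }
  rebuild_current <- function() {
    section_stack(lapply(seq_len(n), function(i)
      apply_bundle(i, stack$sections[[i]])),
      stack$thickness, z_origin = stack$z_origin)
  }

  for (k in seq_along(stages)) {
    st <- stages[[k]]
    params <- st$params %||% list()
    t0 <- Sys.time()
    if (st$workflow == "pairwise") {
      res <- do.call(iterative_pairwise,
                     c(list(stack = current, reference = reference), params))
      new_t <- res$state$transforms
      reports[[k]] <- res$state
    } else if (st$workflow == "graphseq") {
      res <- do.call(reconstruct_graphseq, c(list(stack = current), params))
      new_t <- res$transforms
      reports[[k]] <- res$report
    } else if (st$workflow == "c2f") {
      ref_sections <- params$reference_sections
      params$reference_sections <- NULL
      if (is.null(ref_sections)) {
        if (is.null(reference))
          stop("run_pipeline: c2f stage needs a reference")
        ref_sections <- virtual_sections(reference, identity_affine3d(),
                                         current)
      }
      res <- do.call(coarse_to_fine,
                     c(list(stack = current,
                            reference_sections = ref_sections), params))
      new_t <- res$transforms
      reports[[k]] <- res$report
    } else {  # deformable
      res <- do.call(deformable_reconstruct,
                     c(list(stack = current), params))
      new_f <- res$totals
      fields <- if (is.null(fields)) new_f
                else lapply(seq_len(n), function(i)
                  compose_fields(new_f[[i]], fields[[i]]))
      new_t <- NULL
      reports[[k]] <- res$report
    }
    if (!is.null(new_t))
      affines <- lapply(seq_len(n), function(i)
        t_compose(affines[[i]], new_t[[i]]))
    current <- rebuild_current()
    timings <- c(timings, as.numeric(Sys.time() - t0, units = "secs"))
  }

  masks <- config$masks
  if (!is.null(masks))
    masks <- section_stack(lapply(seq_len(n), function(i)
      apply_bundle(i, masks$sections[[i]], interpolation = "nearest")),
      masks$thickness, z_origin = masks$z_origin)

  provenance <- list(
    stages = stage_names,
    params = lapply(stages, `[[`, "params"),
    seed = config$seed,
    timings_sec = stats::setNames(round(timings, 3), stage_names),
    n_sections = n,
    run_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  list(stack = current, transforms = affines, fields = fields,
       masks = masks, stage_reports = reports, provenance = provenance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Order-preserving (optionally parallel) map over independent tasks
#'
#' Results are identical to serial execution regardless of the worker
#' count: tasks are self-contained closures and results are returned in
#' input order.  A failing task surfaces its own error annotated with the
#' task index.
#'
#' @param tasks List of zero-argument functions.
#' @param workers Number of worker processes (default 1 = serial;
#'   forked workers via the parallel package otherwise).
#' @return List of task results in input order.
#' @export
parallel_map <- function(tasks, workers = 1L) {
  if (length(tasks) == 0) return(list())
  run_one <- function(k) {
    tryCatch(list(ok = TRUE, value = tasks[[k]]()),
             error = function(e) list(ok = FALSE, error = e))
  }
  res <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(tasks), run_one, mc.cores = workers)
  } else {
    lapply(seq_along(tasks), run_one)
  }
  for (k in seq_along(res)) {
    if (!isTRUE(res[[k]]$ok))
      stop("parallel_map: task ", k, " failed: ",
           conditionMessage(res[[k]]$error))
  }
  lapply(res, `[[`, "value")
}

#' Write a reconstruction report as JSON
#'
#' @param report A `recon_report`, `pairwise_state` or `benchmark_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  clean <- rapply(unclass(report), function(x) x, how = "replace")
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
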