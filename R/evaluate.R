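# Quantitative evaluation: the relative-similarity measure, optimal
# parameter selection, and the benchmark sweep harness.

#' Relative similarity of a reconstruction
#'
#' `MSQ(R, B) / MSQ(R, D)` for reference `R`, reconstruction `B` and
#' distorted input `D`: values below 1 mean the reconstruction improved on
#' the distorted input; 0 means perfect recovery; 1 means no change.
#' Invariant under common intensity rescaling of all three images.
#'
#' @param R,B,D Images or [section_stack]s of identical shape.
#' @return Non-negative scalar.
#' @export
relative_similarity <- function(R, B, D) {
  if (inherits(R, "section_stack")) R <- stack_to_volume(R)
  if (inherits(B, "section_stack")) B <- stack_to_volume(B)
  if (inherits(D, "section_stack")) D <- stack_to_volume(D)
  den <- msq(R, D)
  if (den == 0)
    stop("relative_similarity: MSQ(reference, distorted) is zero - nothing to reconstruct")
  msq(R, B) / den
}

#' Select the optimal parameter from a mean relative-similarity map
#'
#' Returns the parameter value with the minimal mean relative similarity;
#' ties are resolved toward the smaller parameter.
#'
#' @param series Named numeric vector: names are parameter values, values
#'   are mean relative similarities.
#' @return The optimal parameter (numeric).
#' @export
select_optimal <- function(series) {
  if (length(series) == 0) stop("select_optimal: empty series")
  par <- as.numeric(names(series))
  ord <- order(series, par)
  par[ord[1]]
}

#' Deformable-reconstruction benchmark sweep
#'
#' Generates a distorted phantom per trial seed, runs the deformable
#' reconstruction for every neighborhood radius in the sweep, and
#' aggregates relative-similarity curves (iteration 0 is the distorted
#' input, S = 1 by definition).  Deterministic given the seeds.
#'
#' @param config List with elements:
#'   \describe{
#'     \item{phantom}{list(n_sections, thickness, seed) for
#'       [make_layered_phantom()] (plus optional inplane_dim /
#'       inplane_spacing).}
#'     \item{distortion}{list(kernel_sigma, target_median) for
#'       [distort_displacement()].}
#'     \item{epsilons}{Neighborhood radii to sweep.}
#'     \item{n_iter}{Iterations per reconstruction.}
#'     \item{seeds}{One distortion seed per trial.}
#'     \item{settings}{Optional [reg_settings] for the deformable engine.}
#'   }
#'   May also be a path to a YAML file with the same structure.
#' @return Object of class `benchmark_result`: `curves` (long data frame:
#'   epsilon, seed, iteration, S), `means` (epsilon x iteration matrix of
#'   means over trials), `eps_star` (optimal epsilon per seed and
#'   overall), `i_star` (optimal iteration at the overall optimal
#'   epsilon), and the config.
#' @export
run_benchmark <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  ph <- config$phantom
  phantom_args <- ph[intersect(names(ph), c("n_sections", "thickness",
                                            "seed", "inplane_dim",
                                            "inplane_spacing", "z0"))]
  truth <- volume_to_stack(do.call(make_layered_phantom, phantom_args))
  sett <- if (!is.null(config$settings)) config$settings
          else reg_settings(levels = 2L, iterations = 20L, metric = "MSQ")
  rows <- list()
  for (seed in config$seeds) {
    dist <- distort_displacement(truth,
                                 kernel_sigma = config$distortion$kernel_sigma,
                                 target_median = config$distortion$target_median,
                                 seed = seed)
    den <- msq(stack_to_volume(truth), stack_to_volume(dist$stack))
    for (eps in config$epsilons) {
      rec <- tryCatch(
        deformable_reconstruct(dist$stack, epsilon = eps,
                               n_iter = config$n_iter, settings = sett,
                               stop = "fixed", reference = truth),
        error = function(e) NULL)
      if (is.null(rec)) {
        rows[[length(rows) + 1]] <- data.frame(
          epsilon = eps, seed = seed, iteration = NA_integer_, S = NA_real_,
          failed = TRUE)
        next
      }
      S <- c(1, rec$report$msq_to_ref / den)
      rows[[length(rows) + 1]] <- data.frame(
        epsilon = eps, seed = seed,
        iteration = seq_along(S) - 1L, S = S, failed = FALSE)
    }
  }
  curves <- do.call(rbind, rows)
  ok <- curves[!curves$failed, ]
  means <- tapply(ok$S, list(ok$epsilon, ok$iteration), mean)
  # optimal epsilon: per seed the argmin over (epsilon, iteration >= 1)
  eps_star_seed <- vapply(unique(ok$seed), function(sd) {
    sub <- ok[ok$seed == sd & ok$iteration >= 1, ]
    best <- tapply(sub$S, sub$epsilon, min)
    select_optimal(best)
  }, 0)
  names(eps_star_seed) <- unique(ok$seed)
  overall <- apply(means[, -1, drop = FALSE], 1, min)
  eps_star <- select_optimal(overall)
  mrow <- means[as.character(eps_star), -1]
  i_star <- select_optimal(stats::setNames(mrow, seq_along(mrow)))
  structure(list(curves = curves, means = means,
                 eps_star_per_seed = eps_star_seed, eps_star = eps_star,
                 i_star = i_star, config = config),
            class = "benchmark_result")
}

#' Write benchmark curves to CSV
#' @param bench A `benchmark_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_benchmark_csv <- function(bench, path) {
  utils::write.csv(bench$curves, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> eps* = %g, i* = %g (%d curve rows)\n",
              x$eps_star, x$i_star, nrow(x$curves)))
  invisible(x)
}
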