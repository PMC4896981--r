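# Graph-based sequential alignment: register every section to its
# epsilon-neighborhood, build a weighted similarity graph, and compose the
# transform chain along the least-cost path from a reference section.
# Badly distorted sections attract high-weight edges and get bypassed.

#' Register all section pairs within a neighborhood radius
#'
#' For every pair (i, j) with `1 <= j - i <= epsilon` the section `j`
#' (moving) is registered to section `i` (fixed) and the rescaled
#' cross-correlation of the aligned pair is recorded as the edge
#' similarity in \[-1, 0\] (lower = more similar), regardless of the
#' metric driving the registration itself.
#'
#' @param stack A [section_stack].
#' @param epsilon Neighborhood radius (>= 1), sections.
#' @param model `"rigid"` or `"affine"` pair registration model.
#' @param settings A [reg_settings].
#' @return A data-frame-like list of edges; each edge holds `i`, `j`, the
#'   pull-back transform `t_ij` (section i frame -> section j frame), the
#'   similarity `s_ij` and a `failed` flag (failed registrations receive
#'   identity transforms and worst similarity 0).
#' @export
pairwise_register_neighborhood <- function(stack, epsilon, model = c("affine", "rigid"),
                                           settings = reg_settings()) {
  model <- match.arg(model)
  if (epsilon < 1) stop("pairwise_register_neighborhood: epsilon must be >= 1")
  n <- n_sections(stack)
  pairs <- do.call(rbind, lapply(seq_len(n - 1), function(i) {
    j <- seq(i + 1, min(i + epsilon, n))
    cbind(i = i, j = j)
  }))
  edges <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    fixed <- stack$sections[[i]]; moving <- stack$sections[[j]]
    res <- tryCatch({
      t_ij <- if (model == "rigid") register_rigid2d(fixed, moving, settings)
              else register_affine2d(fixed, moving, settings)
      warped <- resample_planar(moving, t_ij, out_grid = fixed,
                                interpolation = "cubic")
      s_ij <- tryCatch(rescale_cc(ncc(fixed, warped)), error = function(e) 0)
      list(t = t_ij, s = s_ij, failed = FALSE)
    }, error = function(e) list(t = identity2d(), s = 0, failed = TRUE))
    list(i = i, j = j, t_ij = res$t, s_ij = res$s, failed = res$failed)
  })
  edges
}

#' Edge weight from similarity, section distance and skip modulation
#'
#' `w = (1 + s) * distance^lambda + eta` with a small floor
#' `eta = 1e-6`.  Perfectly similar pairs (s = -1) cost only the floor;
#' `lambda = 0` makes the weight independent of the jump length, while
#' larger `lambda` penalizes long jumps and so preserves sections from
#' being skipped.
#'
#' @param s_ij Similarity in \[-1, 0\].
#' @param distance Section index distance (>= 1).
#' @param lam Skip-modulation exponent (>= 0).
#' @return Non-negative weight.
#' @export
edge_weight <- function(s_ij, distance, lam) {
  if (any(distance < 1)) stop("edge_weight: distance must be >= 1")
  if (any(lam < 0)) stop("edge_weight: lambda must be >= 0")
  (1 + s_ij) * distance^lam + 1e-6
}

#' Build the similarity graph from registered edges
#'
#' @param edges Result of [pairwise_register_neighborhood()].
#' @param n_sections Number of sections.
#' @param epsilon Neighborhood radius the graph should use (must not
#'   exceed the radius the edges were computed with; smaller values
#'   subset the edges).
#' @param lam Skip-modulation lambda.
#' @return An object of class `similarity_graph`.
#' @export
similarity_graph <- function(edges, n_sections, epsilon, lam) {
  keep <- vapply(edges, function(e) (e$j - e$i) <= epsilon, TRUE)
  edges <- edges[keep]
  w <- vapply(edges, function(e) edge_weight(e$s_ij, e$j - e$i, lam), 0)
  structure(list(n = n_sections, epsilon = epsilon, lam = lam,
                 edges = edges, weights = w),
            class = "similarity_graph")
}

# Dijkstra with deterministic tie-breaking: minimal cost, then fewer hops,
# then lexicographically smallest path.  Hand-rolled because the
# tie-breaking order is part of the contract; graphs are small (n * eps
# edges) so the simple O(n^2) scan is ample.
#' Least-cost transform chains from a reference section
#'
#' @param graph A [similarity_graph()].
#' @param r Reference section index (1-based).
#' @return List of chains, one per section: each has `path` (indices from
#'   `r` to the section), `cost`, and `edges` (list of (from, to, t, s)).
#'   The chain for `r` itself is empty.  Errors if any section is
#'   unreachable.
#' @export
least_cost_chains <- function(graph, r) {
  n <- graph$n
  adj <- vector("list", n)
  for (k in seq_along(graph$edges)) {
    e <- graph$edges[[k]]; w <- graph$weights[k]
    adj[[e$i]] <- c(adj[[e$i]], list(list(to = e$j, w = w, edge = e, fwd = TRUE)))
    adj[[e$j]] <- c(adj[[e$j]], list(list(to = e$i, w = w, edge = e, fwd = FALSE)))
  }
  dist <- rep(Inf, n); hops <- rep(Inf, n)
  paths <- vector("list", n)
  dist[r] <- 0; hops[r] <- 0; paths[[r]] <- r
  done <- rep(FALSE, n)
  lex_less <- function(a, b) {
    k <- min(length(a), length(b))
    for (t in seq_len(k)) {
      if (a[t] < b[t]) return(TRUE)
      if (a[t] > b[t]) return(FALSE)
    }
    length(a) < length(b)
  }
  better <- function(d1, h1, p1, d2, h2, p2) {
    if (d1 < d2 - 1e-15) return(TRUE)
    if (d1 > d2 + 1e-15) return(FALSE)
    if (h1 != h2) return(h1 < h2)
    lex_less(p1, p2)
  }
  for (step in seq_len(n)) {
    u <- NA_integer_
    for (v in seq_len(n))
      if (!done[v] && is.finite(dist[v]) &&
          (is.na(u) || better(dist[v], hops[v], paths[[v]],
                              dist[u], hops[u], paths[[u]]))) u <- v
    if (is.na(u)) break
    done[u] <- TRUE
    for (a in adj[[u]]) {
      v <- a$to
      nd <- dist[u] + a$w; nh <- hops[u] + 1; np <- c(paths[[u]], v)
      if (!is.finite(dist[v]) ||
          better(nd, nh, np, dist[v], hops[v], paths[[v]])) {
        dist[v] <- nd; hops[v] <- nh; paths[[v]] <- np
      }
    }
  }
  if (any(!is.finite(dist)))
    stop("least_cost_chains: unreachable sections: ",
         paste(which(!is.finite(dist)), collapse = ", "))
  edge_lookup <- new.env()
  for (k in seq_along(graph$edges)) {
    e <- graph$edges[[k]]
    assign(paste(e$i, e$j), list(e = e, w = graph$weights[k]), envir = edge_lookup)
  }
  lapply(seq_len(n), function(i) {
    p <- as.integer(paths[[i]])
    eds <- list()
    if (length(p) > 1) {
      for (t in seq_len(length(p) - 1)) {
        a <- p[t]; b <- p[t + 1]
        key <- if (a < b) paste(a, b) else paste(b, a)
        rec <- get(key, envir = edge_lookup)
        eds[[t]] <- list(from = a, to = b, t_ij = rec$e$t_ij,
                         s_ij = rec$e$s_ij, w = rec$w,
                         forward = a < b)
      }
    }
    structure(list(path = p, cost = dist[i], edges = eds),
              class = "transform_chain")
  })
}

#' Compose the transforms along a chain
#'
#' Edge transforms are pull-back maps from the lower-index frame to the
#' higher-index frame; traversing an edge downward uses its inverse.  The
#' composition maps reference-frame coordinates to the terminal section's
#' frame, i.e. resampling the terminal section through it renders it in
#' the reference frame.  An empty chain gives the identity.
#'
#' @param chain A chain from [least_cost_chains()].
#' @return A transform (`rigid2d` or `affine2d`; identity for the
#'   reference itself).
#' @export
compose_chain <- function(chain) {
  tt <- identity2d()
  for (e in chain$edges) {
    step <- if (e$forward) e$t_ij else t_invert(e$t_ij)
    tt <- t_compose(step, tt)
  }
  tt
}

#' Graph-based sequential reconstruction
#'
#' Runs the neighborhood pair registrations (unless precomputed edges are
#' supplied), builds the weighted graph, extracts least-cost chains from
#' the reference section, composes them, and resamples every original
#' section exactly once through its composed transform.
#'
#' A section is flagged as "standing out" iff it serves as an intermediate
#' vertex in no chain; the reference section and the two stack-end
#' sections are excluded (they can never be intermediates).
#'
#' @param stack A [section_stack].
#' @param epsilon Neighborhood radius.
#' @param lam Skip-modulation lambda (default 0).
#' @param r Reference section index; default the middle section.
#' @param model `"rigid"` or `"affine"`.
#' @param settings A [reg_settings].
#' @param edges Optional precomputed edges from
#'   [pairwise_register_neighborhood()] (with radius >= `epsilon`).
#' @param interpolation Final resampling kernel.
#' @return List with `stack` (aligned), `transforms` (per-section composed
#'   maps), `report` (class `recon_report`: flags, chain costs, paths,
#'   settings).
#' @export
reconstruct_graphseq <- function(stack, epsilon, lam = 0, r = NULL,
                                 model = c("affine", "rigid"),
                                 settings = reg_settings(), edges = NULL,
                                 interpolation = "linear") {
  model <- match.arg(model)
  n <- n_sections(stack)
  if (is.null(r)) r <- (n + 1L) %/% 2L
  if (is.null(edges))
    edges <- pairwise_register_neighborhood(stack, epsilon, model, settings)
  graph <- similarity_graph(edges, n, epsilon, lam)
  chains <- least_cost_chains(graph, r)
  transforms <- lapply(chains, compose_chain)
  sections <- lapply(seq_len(n), function(i)
    resample_planar(stack$sections[[i]], transforms[[i]],
                    out_grid = stack$sections[[i]],
                    interpolation = interpolation))
  # intermediate-vertex bookkeeping for outlier flags
  used <- rep(FALSE, n)
  for (ch in chains) {
    p <- ch$path
    if (length(p) > 2) used[p[2:(length(p) - 1)]] <- TRUE
  }
  eligible <- setdiff(seq_len(n), c(r, 1L, n))
  flagged <- sort(eligible[!used[eligible]])
  report <- structure(list(
    workflow = "graphseq", n_sections = n, epsilon = epsilon, lam = lam,
    reference = r, model = model,
    flagged = flagged,
    costs = vapply(chains, `[[`, 0, "cost"),
    paths = lapply(chains, `[[`, "path"),
    failed_edges = sum(vapply(edges, `[[`, TRUE, "failed"))),
    class = "recon_report")
  list(stack = section_stack(sections, stack$thickness,
                             z_origin = stack$z_origin),
       transforms = transforms, chains = chains, report = report)
}

#' @export
print.recon_report <- function(x, ...) {
  cat(sprintf("<recon_report> workflow %s, %d sections\n", x$workflow,
              x$n_sections))
  if (!is.null(x$flagged))
    cat("  flagged sections:",
        if (length(x$flagged)) paste(x$flagged, collapse = ", ") else "none",
        "\n")
  if (!is.null(x$iterations))
    cat("  iterations run:", x$iterations, "\n")
  invisible(x)
}
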