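# Shared fixtures, built once per test run.  Everything is generated in
# code from fixed seeds; sizes are kept small so the whole suite stays
# fast.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

# a small straight textured tube stack (registration-friendly)
tube_stack <- function(n = 20, dim = 48, spacing = 2, thickness = 2,
                       curvature = 0) {
  fixture(paste("tube", n, dim, spacing, thickness, curvature, sep = "_"),
          function() {
    volume_to_stack(make_banana_phantom(
      n_slices = n, thickness = thickness, arc_curvature = curvature,
      inplane_dim = c(dim, dim), inplane_spacing = c(spacing, spacing)))
  })
}

# one well-featured slice of it
tube_slice <- function(...) {
  st <- tube_stack(...)
  st$sections[[n_sections(st) %/% 2]]
}

# a full-frame textured image (features everywhere; no background)
textured_image <- function(n = 48, seed = 5) {
  fixture(paste("tex", n, seed, sep = "_"), function() {
    set.seed(seed)
    px <- matrix(stats::rnorm(n * n), n, n)
    px <- serialrecon:::gauss_smooth_mat(px, c(2, 2))
    px <- (px - min(px)) / diff(range(px)) * 100
    planar_image(px, spacing = c(1, 1))
  })
}

layered_stack <- function(n = 20) {
  fixture(paste("layered", n, sep = "_"), function()
    volume_to_stack(make_layered_phantom(n_sections = n, thickness = 0.05,
                                         seed = 1)))
}

# random rigid/affine transforms for property tests
random_rigid <- function() rigid2d(stats::runif(1, -170, 170),
                                   stats::rnorm(1, 0, 5),
                                   stats::rnorm(1, 0, 5),
                                   center = stats::rnorm(2, 0, 3))

random_affine2d <- function() {
  repeat {
    m <- diag(2) + matrix(stats::rnorm(4, 0, 0.2), 2, 2)
    if (abs(det(m)) > 0.1) break
  }
  affine2d(m, offset = stats::rnorm(2, 0, 5), center = stats::rnorm(2, 0, 3))
}

random_affine3d <- function() {
  repeat {
    m <- diag(3) + matrix(stats::rnorm(9, 0, 0.15), 3, 3)
    if (abs(det(m)) > 0.1) break
  }
  affine3d(m, offset = stats::rnorm(3, 0, 5), center = stats::rnorm(3, 0, 2))
}

# exhaustive least-cost-path oracle over all simple paths (small graphs)
brute_force_chains <- function(graph, r) {
  n <- graph$n
  wmat <- matrix(Inf, n, n)
  for (k in seq_along(graph$edges)) {
    e <- graph$edges[[k]]
    wmat[e$i, e$j] <- wmat[e$j, e$i] <- graph$weights[k]
  }
  best <- vector("list", n)
  rec <- function(path, cost) {
    v <- path[length(path)]
    cur <- best[[v]]
    take <- is.null(cur) || cost < cur$cost - 1e-15 ||
      (abs(cost - cur$cost) <= 1e-15 &&
         (length(path) < length(cur$path) ||
            (length(path) == length(cur$path) &&
               paste(path, collapse = ",") < paste(cur$path, collapse = ","))))
    if (take) best[[v]] <<- list(cost = cost, path = path)
    for (u in seq_len(n))
      if (is.finite(wmat[v, u]) && !(u %in% path)) rec(c(path, u), cost + wmat[v, u])
  }
  rec(r, 0)
  best
}

random_similarity_graph <- function(n, eps) {
  edges <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):min(i + eps, n))
    edges[[length(edges) + 1]] <- list(i = i, j = j, t_ij = identity2d(),
                                       s_ij = stats::runif(1, -1, 0),
                                       failed = FALSE)
  similarity_graph(edges, n, eps, lam = stats::runif(1, 0, 1))
}

expect_transform_equal <- function(a, b, tol = 1e-9) {
  pts <- matrix(c(0, 0, 7, -3, -4, 5), ncol = 2, byrow = TRUE)
  if (inherits(a, "affine3d") || inherits(b, "affine3d"))
    pts <- cbind(pts, c(1, -2, 3))
  expect_lt(max(abs(map_points(a, pts) - map_points(b, pts))), tol)
}
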