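test_that("series smoothing is a normalized Gaussian convolution", {
  ctr <- c(0, 0)
  const <- rigid_series(lapply(1:10, function(i) rigid2d(3, 1, -2)), ctr)
  expect_equal(series_params(smooth_series(const, 4)), series_params(const),
               tolerance = 1e-12)
  s <- rigid_series(lapply(1:15, function(i) rigid2d(runif(1), runif(1), 0)),
                    ctr)
  expect_identical(series_params(smooth_series(s, 0)), series_params(s))
  # unit impulse reproduces the kernel
  imp <- rigid_series(lapply(1:21, function(i)
    rigid2d(0, as.numeric(i == 11), 0)), ctr)
  sm <- series_params(smooth_series(imp, 2))[, "tx"]
  k <- serialrecon:::gauss_kernel1d(2)
  r <- (length(k) - 1) / 2
  expect_equal(sm[(11 - r):(11 + r)], unname(k), tolerance = 1e-12)
})

test_that("merge is exact parameter algebra with the stated limits", {
  ctr <- c(0, 0)
  set.seed(41)
  co <- rigid_series(lapply(1:20, function(i)
    rigid2d(rnorm(1, 0, 5), rnorm(1, 0, 3), rnorm(1, 0, 3))), ctr)
  fi <- rigid_series(lapply(1:20, function(i)
    rigid2d(rnorm(1, 0, 5), rnorm(1, 0, 3), rnorm(1, 0, 3))), ctr)
  m <- merge_series(co, fi, 3)
  resid <- series_params(m) - series_params(co) - series_params(fi) +
    series_params(smooth_series(fi, 3))
  expect_lt(max(abs(resid)), 1e-12)
  # spatially constant fine series: merged == coarse
  fc <- rigid_series(lapply(1:20, function(i) rigid2d(2, 1, 1)), ctr)
  expect_equal(series_params(merge_series(co, fc, 3)), series_params(co),
               tolerance = 1e-12)
  # sigma_z -> 0: highpass vanishes, merged == coarse
  expect_equal(series_params(merge_series(co, fi, 0)), series_params(co),
               tolerance = 1e-12)
  # huge sigma_z on a zero-mean fine series: merged ~ coarse + fine.
  # The infinite-smoothing limit under reflect padding is the mean over the
  # reflection period (interior samples counted twice), so center on that.
  pf <- series_params(fi)
  w <- c(1, rep(2, nrow(pf) - 2), 1); w <- w / sum(w)
  pf0 <- sweep(pf, 2, colSums(pf * w))
  fi0 <- serialrecon:::series_from_params(pf0, ctr)
  m2 <- merge_series(co, fi0, 1e4)
  expect_equal(series_params(m2), series_params(co) + pf0, tolerance = 1e-6)
  expect_error(merge_series(co, rigid_series(list(rigid2d()), ctr), 3),
               "lengths")
})

test_that("coarse series is per-section independent and near-identity on aligned input", {
  st <- tube_stack(n = 12, dim = 32)
  sett <- reg_settings(levels = 2, iterations = c(40, 80))
  cs <- coarse_series(st, st, sett)
  par <- series_params(cs$series)
  expect_lt(max(abs(par[, "theta"])), 0.1)
  expect_lt(max(abs(par[, c("tx", "ty")])), 0.1)
  # permuting two input sections permutes the two results
  st2 <- st
  st2$sections[c(3, 6)] <- st$sections[c(6, 3)]
  ref2 <- st
  ref2$sections[c(3, 6)] <- st$sections[c(6, 3)]
  cs2 <- coarse_series(st2, ref2, sett)
  expect_equal(series_params(cs2$series)[c(3, 6), ],
               series_params(cs$series)[c(6, 3), ], tolerance = 1e-9)
})

test_that("coarse-to-fine on an undistorted stack is near-identity", {
  st <- tube_stack(n = 10, dim = 32, curvature = 0.3)
  sett <- reg_settings(levels = 2, iterations = c(40, 80))
  cf <- coarse_to_fine(st, st, fine_method = "naive", sigma_z = 2,
                       settings_coarse = sett, settings_fine = sett,
                       truth = st)
  rng2 <- diff(range(stack_to_volume(st)$voxels))^2
  expect_lt(cf$report$msq_merged, 0.01 * rng2)
  par <- series_params(cf$series$merged)
  expect_lt(max(abs(par[, c("tx", "ty")])), 2)  # < 1 px at 2 mm
})

test_that("the merge suppresses z-shift: merged follows the coarse trend", {
  # 200-section synthetic series: the coarse series carries the true global
  # trend plus per-section jitter; the fine series carries the detail plus a
  # linear drift (the z-shift sequential alignment accumulates)
  set.seed(42)
  n <- 200; idx <- seq_len(n); ctr <- c(0, 0)
  detail <- cbind(rnorm(n, 0, 0.5), rnorm(n, 0, 2), rnorm(n, 0, 2))
  coarse_par <- cbind(0.02 * idx, 0.1 * idx, -0.08 * idx) + detail +
    cbind(rnorm(n, 0, 0.2), rnorm(n, 0, 0.8), rnorm(n, 0, 0.8))
  fine_par <- cbind(0.01 * idx, 0.05 * idx, 0.06 * idx) + detail
  co <- serialrecon:::series_from_params(coarse_par, ctr)
  fi <- serialrecon:::series_from_params(fine_par, ctr)
  m <- merge_series(co, fi, 5)
  slope <- function(p, ch) unname(coef(stats::lm(p[, ch] ~ idx))[2])
  for (ch in c("theta", "tx", "ty")) {
    sc <- slope(series_params(co), ch)
    sm <- slope(series_params(m), ch)
    expect_lt(abs(sm - sc), 0.05 * abs(sc))
  }
})
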