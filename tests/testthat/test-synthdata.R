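test_that("banana phantom geometry follows its parameters", {
  v <- make_banana_phantom(n_slices = 24, thickness = 2,
                           inplane_dim = c(40, 40), inplane_spacing = c(2, 2))
  st <- volume_to_stack(v)
  # every slice is a single bright blob with nonzero content
  fracs <- vapply(st$sections, function(s) mean(s$pixels > 10), 0)
  expect_true(all(fracs > 0.02 & fracs < 0.8))
  # curved: centroid path deviates from its chord by > 10% of length
  centroid_x <- vapply(st$sections, function(s) {
    g <- grid_coords(s)
    w <- pmax(s$pixels, 0)
    sum(matrix(g$x, length(g$x), length(g$y)) * w) / sum(w)
  }, 0)
  n <- length(centroid_x)
  chord <- seq(centroid_x[1], centroid_x[n], length.out = n)
  sagitta <- max(abs(centroid_x - chord))
  expect_gt(sagitta, 0.1 * (n * 2))
  # curvature 0: collinear centroids
  v0 <- make_banana_phantom(n_slices = 24, thickness = 2, arc_curvature = 0,
                            inplane_dim = c(40, 40), inplane_spacing = c(2, 2))
  st0 <- volume_to_stack(v0)
  cx0 <- vapply(st0$sections, function(s) {
    g <- grid_coords(s); w <- pmax(s$pixels, 0)
    sum(matrix(g$x, length(g$x), length(g$y)) * w) / sum(w)
  }, 0)
  expect_lt(diff(range(cx0)), 0.5)
  expect_error(make_banana_phantom(n_slices = 5), "at least 10")
})

test_that("rigid distortion draws are seeded, zero-preserving, and have the stated spread", {
  st <- tube_stack(n = 12, dim = 24)
  d0 <- distort_rigid(st, sigma_t = 0, sigma_theta = 0, seed = 1)
  expect_identical(lapply(d0$stack$sections, `[[`, "pixels"),
                   lapply(st$sections, `[[`, "pixels"))
  expect_true(all(vapply(d0$record$transforms,
                         function(t) t$theta == 0 && all(t$t == 0), TRUE)))
  d1 <- distort_rigid(st, seed = 42)
  d2 <- distort_rigid(st, seed = 42)
  expect_identical(lapply(d1$stack$sections, `[[`, "pixels"),
                   lapply(d2$stack$sections, `[[`, "pixels"))
  # n = 200 draws at sigma 10: sample SD within the 99% chi-square interval
  big <- section_stack(replicate(200, planar_image(matrix(runif(16), 4, 4)),
                                 simplify = FALSE), thickness = 1)
  dd <- distort_rigid(big, sigma_t = 10, sigma_theta = 10, seed = 7)
  tx <- vapply(dd$record$transforms, function(t) t$t[1], 0)
  expect_gt(sd(tx), 8.2)
  expect_lt(sd(tx), 11.8)
})

test_that("applying the inverse ground-truth transforms undoes the distortion", {
  st <- tube_stack(n = 12, dim = 48)
  dd <- distort_rigid(st, sigma_t = 5, sigma_theta = 5, seed = 3)
  rng <- diff(range(stack_to_volume(st)$voxels))
  interior <- 10:38
  for (i in c(2, 7)) {
    undone <- resample_planar(dd$stack$sections[[i]],
                              t_invert(dd$record$transforms[[i]]),
                              out_grid = st$sections[[i]],
                              interpolation = "cubic")
    err <- max(abs(undone$pixels[interior, interior] -
                   st$sections[[i]]$pixels[interior, interior]))
    expect_lt(err, 0.02 * rng)
  }
})

test_that("ablation removes the requested foreground fraction on listed sections only", {
  st <- tube_stack(n = 12, dim = 48)
  ab <- ablate_sections(st, indices = c(3, 7), fraction = 0.5, seed = 9)
  for (i in c(3, 7)) {
    before <- st$sections[[i]]$pixels
    after <- ab$stack$sections[[i]]$pixels
    fg <- before > 0.05 * max(before)
    removed <- sum(fg & after == 0 & before != 0) / sum(fg)
    expect_gt(removed, 0.4); expect_lt(removed, 0.6)
  }
  for (i in setdiff(1:12, c(3, 7)))
    expect_identical(ab$stack$sections[[i]]$pixels, st$sections[[i]]$pixels)
  # an ablated section correlates worse with its neighbor than clean pairs do
  s_clean <- vapply(c(1, 4, 8), function(i)
    ncc(st$sections[[i]], st$sections[[i + 1]]), 0)
  s_abl <- ncc(ab$stack$sections[[3]], ab$stack$sections[[4]])
  expect_lt(s_abl, median(s_clean))
  expect_error(ablate_sections(st, 99), "out of range")
  expect_error(ablate_sections(st, 1, fraction = 1.5), "fraction")
})

test_that("displacement distortion is calibrated exactly to the target median", {
  f <- make_displacement_distortion(c(60, 60), spacing = c(0.05, 0.05),
                                    kernel_sigma = 0.3, target_median = 0.05,
                                    seed = 5)
  expect_equal(median(field_magnitude(f)), 0.05, tolerance = 1e-9)
  f2 <- make_displacement_distortion(c(60, 60), spacing = c(0.05, 0.05),
                                     kernel_sigma = 0.3, target_median = 0.05,
                                     seed = 5)
  expect_identical(f$u1, f2$u1)
  # enormous kernel: the field approaches spatial constancy
  fbig <- make_displacement_distortion(c(40, 40), spacing = c(0.05, 0.05),
                                       kernel_sigma = 50, target_median = 0.05,
                                       seed = 5)
  expect_lt(sd(field_magnitude(fbig)), 0.1 * sd(field_magnitude(f)))
})

test_that("amplitude calibration is exact linear scaling", {
  f <- make_displacement_distortion(c(40, 40), spacing = c(0.05, 0.05),
                                    kernel_sigma = 0.3, target_median = 0.02,
                                    seed = 2)
  unit <- dispfield2d(f$u1 / max(abs(f$u1)), f$u2 / max(abs(f$u2)),
                      spacing = c(0.05, 0.05))
  r1 <- calibrate_amplitude(unit, 0.05)
  r2 <- calibrate_amplitude(unit, 0.10)
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
  scaled <- dispfield2d(unit$u1 * r1, unit$u2 * r1, spacing = c(0.05, 0.05))
  expect_equal(median(field_magnitude(scaled)), 0.05, tolerance = 1e-9)
  unit1 <- dispfield2d(matrix(1, 4, 4), matrix(0, 4, 4), spacing = c(1, 1))
  expect_equal(calibrate_amplitude(unit1, 0.3), 0.3)
})

test_that("field correlation length grows with the smoothing kernel", {
  corr_len <- function(kernel_sigma) {
    f <- make_displacement_distortion(c(80, 80), spacing = c(0.05, 0.05),
                                      kernel_sigma = kernel_sigma,
                                      target_median = 0.05, seed = 8)
    u <- f$u1 - mean(f$u1)
    ac <- vapply(0:30, function(lag) {
      if (lag == 0) return(1)
      a <- u[1:(80 - lag), ]; b <- u[(1 + lag):80, ]
      sum(a * b) / sum(u^2)
    }, 0)
    which(ac < exp(-1))[1]
  }
  ls <- vapply(c(0.1, 0.3, 1.0), corr_len, 0)
  expect_true(all(diff(ls) > 0))
})

test_that("layered phantom slices consistently across thicknesses", {
  v1 <- make_layered_phantom(n_sections = 20, thickness = 0.05, seed = 4)
  # >= 3 separated intensity modes (background, shells)
  h <- hist(v1$voxels, breaks = 60, plot = FALSE)
  peaks <- sum(diff(sign(diff(h$counts))) == -2)
  expect_gte(peaks, 3)
  # doubling the thickness samples every second section position
  v2 <- make_layered_phantom(n_sections = 10, thickness = 0.10, seed = 4)
  expect_equal(v2$voxels[, , 3], v1$voxels[, , 5])
  expect_equal(v2$voxels[, , 7], v1$voxels[, , 13])
  # seeded reproducibility
  v1b <- make_layered_phantom(n_sections = 20, thickness = 0.05, seed = 4)
  expect_identical(v1$voxels, v1b$voxels)
})
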