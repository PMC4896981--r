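test_that("rigid registration recovers known in-plane perturbations", {
  sl <- tube_slice(n = 20, dim = 48)
  ctr <- grid_center(sl)
  sett <- reg_settings(levels = 3, iterations = c(60, 60, 120))
  # identity optimum
  r0 <- register_rigid2d(sl, sl, sett)
  expect_lt(abs(r0$theta), 0.05)
  expect_lt(max(abs(r0$t)), 0.05 * 2)   # 0.05 px at 2 mm spacing
  # pure translation
  g <- rigid2d(0, 3, -2, center = ctr)
  mov <- resample_planar(sl, g, interpolation = "cubic")
  r <- register_rigid2d(sl, mov, sett)
  gi <- rigid_recenter(t_invert(g), ctr)
  expect_lt(max(abs(r$t - gi$t)), 0.2)
  # rotation about the center
  g2 <- rigid2d(5, 0, 0, center = ctr)
  mov2 <- resample_planar(sl, g2, interpolation = "cubic")
  r2 <- register_rigid2d(sl, mov2, sett)
  expect_lt(abs(r2$theta + 5), 0.3)
})

test_that("affine registration recovers anisotropic scaling, degrading gracefully with noise", {
  sl <- tube_slice(n = 20, dim = 48)
  ctr <- grid_center(sl)
  sett <- reg_settings(levels = 3, iterations = c(60, 60, 150))
  r0 <- register_affine2d(sl, sl, sett)
  expect_lt(max(abs(r0$matrix - diag(2))), 1e-3)
  g <- affine2d(matrix(c(1.1, 0, 0, 0.9), 2, 2), offset = c(1, -1),
                center = ctr)
  mov <- resample_planar(sl, g, interpolation = "cubic")
  r <- register_affine2d(sl, mov, sett)
  truthM <- serialrecon:::affine_mb(t_invert(g))$M
  err_clean <- max(abs(serialrecon:::affine_mb(r)$M - truthM))
  expect_lt(err_clean, 0.02)
  # additive noise at 2% of the dynamic range: error below 2x the noise-free
  # error plus the noise scale itself
  set.seed(51)
  noisy <- mov
  noisy$pixels <- noisy$pixels +
    matrix(rnorm(length(mov$pixels), 0, 0.02 * diff(range(sl$pixels))),
           nrow(mov$pixels))
  rn <- register_affine2d(sl, noisy, sett)
  err_noisy <- max(abs(serialrecon:::affine_mb(rn)$M - truthM))
  expect_lt(err_noisy, 2 * max(err_clean, 0.01))
})

test_that("3D affine registration recovers oblique rotations", {
  v <- make_banana_phantom(n_slices = 40, thickness = 2.5,
                           inplane_dim = c(48, 48),
                           inplane_spacing = c(2.5, 2.5))
  ctr3 <- v$origin + (dim(v$voxels) - 1) / 2 * v$spacing
  sett <- reg_settings(levels = 3, iterations = c(500, 250, 120),
                       smooth_px = 1, min_dim = 20)
  r0 <- register_affine3d(v, v, sett, dof = 6)
  expect_lt(max(abs(serialrecon:::affine_mb(r0)$M - diag(3))), 1e-3)
  # oblique rotation about the slice axis
  g <- affine3d(serialrecon:::rot3(0, 0, 15), offset = c(0, 0, 0),
                center = ctr3)
  mov <- resample_volume(v, g, interpolation = "cubic")
  r <- register_affine3d(v, mov, sett, dof = 6)
  Rrel <- serialrecon:::affine_mb(r)$M %*%
    solve(serialrecon:::affine_mb(t_invert(g))$M)
  ang <- acos(min(1, (sum(diag(Rrel)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 1)
})

test_that("deformable registration recovers smooth warps and respects regularization", {
  fx <- textured_image()
  # identity: essentially zero field
  sett <- reg_settings(levels = 2, iterations = c(15, 15), metric = "MSQ")
  u0 <- register_deformable2d(fx, fx, sett)
  expect_lt(median(field_magnitude(u0)), 0.05)
  # known smooth warp of median 1.5 px: recovered field (which estimates the
  # inverse warp) has median residual < 30% of the applied median
  f <- make_displacement_distortion(dim(fx$pixels), fx$spacing,
                                    kernel_sigma = 8, target_median = 1.5,
                                    seed = 11)
  f <- dispfield2d(f$u1, f$u2, spacing = fx$spacing, origin = fx$origin)
  mov <- resample_planar(fx, f)
  sett2 <- reg_settings(levels = 2, iterations = c(40, 40), metric = "MSQ")
  u <- register_deformable2d(fx, mov, sett2)
  resid <- sqrt((u$u1 + f$u1)^2 + (u$u2 + f$u2)^2)
  expect_lt(median(resid), 0.3 * median(field_magnitude(f)))
  # the warp improves the metric
  expect_lt(msq(fx, resample_planar(mov, u, out_grid = fx)), msq(fx, mov))
  # doubling sigma_total does not increase the recovered fields' total
  # variation, checked as the aggregate over three seeded warps (the
  # best-iterate selection makes the per-case comparison only approximately
  # monotone)
  tv <- function(uu) sum(abs(diff(uu$u1))) + sum(abs(diff(t(uu$u1)))) +
    sum(abs(diff(uu$u2))) + sum(abs(diff(t(uu$u2))))
  tv1s <- tv2s <- numeric(3)
  for (seed in 1:3) {
    fs <- make_displacement_distortion(dim(fx$pixels), fx$spacing,
                                       kernel_sigma = 6, target_median = 1,
                                       seed = seed)
    fs <- dispfield2d(fs$u1, fs$u2, spacing = fx$spacing, origin = fx$origin)
    ms <- resample_planar(fx, fs)
    u1 <- register_deformable2d(fx, ms, reg_settings(levels = 2,
                                                     iterations = c(20, 20),
                                                     metric = "MSQ",
                                                     sigma_total = 1))
    u2 <- register_deformable2d(fx, ms, reg_settings(levels = 2,
                                                     iterations = c(20, 20),
                                                     metric = "MSQ",
                                                     sigma_total = 2))
    tv1s[seed] <- tv(u1); tv2s[seed] <- tv(u2)
  }
  expect_lte(mean(tv2s), mean(tv1s))
  # flat images: zero field with a warning
  flat <- planar_image(matrix(1, 16, 16))
  expect_warning(uf <- register_deformable2d(flat, flat, sett), "flat")
  expect_equal(max(field_magnitude(uf)), 0)
})

test_that("registration never returns a transform scoring worse than its initialization", {
  sl <- tube_slice(n = 20, dim = 48)
  dd <- distort_rigid(section_stack(rep(list(sl), 2), 1), 6, 6, seed = 61)
  mov <- dd$stack$sections[[1]]
  for (metric in c("NCC", "MSQ", "MI")) {
    sett <- reg_settings(metric = metric, levels = 2, iterations = c(40, 60))
    r <- register_rigid2d(sl, mov, sett)
    m_id <- metric_value(sl, resample_planar(mov, identity2d(), out_grid = sl),
                         metric)
    m_opt <- metric_value(sl, resample_planar(mov, r, out_grid = sl), metric)
    expect_lte(m_opt, m_id + 1e-9)
  }
})
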