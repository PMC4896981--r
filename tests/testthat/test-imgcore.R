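test_that("msq matches its definition and a brute-force loop oracle", {
  expect_equal(msq(matrix(c(0, 0), 1), matrix(c(3, 4), 1)), 12.5)
  A <- planar_image(matrix(runif(64), 8, 8))
  expect_identical(msq(A, A), 0)
  set.seed(1)
  a <- matrix(rnorm(64), 8, 8); b <- matrix(rnorm(64), 8, 8)
  acc <- 0
  for (i in 1:8) for (j in 1:8) acc <- acc + (a[i, j] - b[i, j])^2
  expect_equal(msq(a, b), acc / 64)
  expect_equal(msq(a, b), msq(b, a))
  expect_error(msq(a, matrix(0, 4, 4)), "shape")
})

test_that("ncc is the Pearson correlation, with its degenerate cases", {
  set.seed(2)
  a <- matrix(rnorm(256), 16, 16); b <- matrix(rnorm(256), 16, 16)
  av <- as.numeric(a); bv <- as.numeric(b)
  # textbook direct-sum formula
  num <- sum((av - mean(av)) * (bv - mean(bv)))
  den <- sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  expect_equal(ncc(a, b), num / den)
  expect_equal(ncc(a, b), ncc(b, a))
  expect_equal(ncc(a, a), 1)
  a0 <- a - mean(a)
  expect_equal(ncc(a0, -a0 + 3), -1)
  expect_error(ncc(a, matrix(5, 16, 16)), "variance")
})

test_that("rescale_cc maps [-1, 1] onto the [-1, 0] similarity scale", {
  expect_equal(rescale_cc(1), -1)
  expect_equal(rescale_cc(-1), 0)
  expect_equal(rescale_cc(0), -0.5)
  expect_error(rescale_cc(1.2), "\\[-1, 1\\]")
})

test_that("mutual information agrees with a histogram-loop oracle", {
  x <- matrix(rep(1:4, 4), 4, 4)
  expect_equal(mutual_information(x, x, bins = 4), log(4))
  set.seed(3)
  a <- matrix(runif(400), 20, 20); b <- matrix(runif(400), 20, 20)
  bins <- 8
  bin_of <- function(v) pmin(floor((v - min(v)) / diff(range(v)) * bins) + 1, bins)
  ba <- bin_of(as.numeric(a)); bb <- bin_of(as.numeric(b))
  joint <- matrix(0, bins, bins)
  for (k in seq_along(ba)) joint[ba[k], bb[k]] <- joint[ba[k], bb[k]] + 1
  p <- joint / sum(joint); pa <- rowSums(p); pb <- colSums(p)
  mi <- 0
  for (i in 1:bins) for (j in 1:bins)
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
  expect_equal(mutual_information(a, b, bins = bins), mi)
  # independent images: MI tends to zero within sampling error
  set.seed(4)
  big_a <- matrix(rep(c(0, 1), length.out = 128 * 128), 128, 128)
  big_b <- matrix(runif(128 * 128), 128, 128)
  expect_lt(mutual_information(big_a, big_b, bins = 32), 0.02)
  expect_warning(mutual_information(matrix(1, 4, 4), x), "constant")
})

test_that("stack/volume conversions round-trip bit-exactly and permute axes", {
  set.seed(5)
  st <- section_stack(array(runif(4 * 5 * 3), c(4, 5, 3)), thickness = 0.2)
  v <- stack_to_volume(st)
  expect_equal(dim(v$voxels), c(4, 5, 3))
  expect_equal(v$spacing[3], 0.2)
  st2 <- volume_to_stack(v)
  expect_identical(lapply(st2$sections, `[[`, "pixels"),
                   lapply(st$sections, `[[`, "pixels"))
  # slicing along each axis then restacking recovers the array modulo a
  # known permutation
  arr <- array(runif(4 * 5 * 6), c(4, 5, 6))
  vol <- volume_image(arr, spacing = c(1, 2, 3))
  for (ax in 1:3) {
    stx <- volume_to_stack(vol, slice_axis = ax)
    perm <- switch(ax, c(2, 3, 1), c(1, 3, 2), c(1, 2, 3))
    back <- stack_to_volume(stx)
    expect_identical(back$voxels, aperm(arr, perm))
    expect_equal(back$spacing, vol$spacing[perm])
  }
  expect_error(section_stack(list(planar_image(matrix(0, 3, 3), c(1, 1)),
                                  planar_image(matrix(0, 4, 4), c(1, 1))),
                             thickness = 1), "share")
})

test_that("NIfTI write/read round trip preserves pixels and geometry", {
  set.seed(6)
  img <- planar_image(matrix(runif(12 * 9), 12, 9), spacing = c(0.5, 0.25))
  tf <- tempfile(fileext = ".nii.gz")
  write_nifti_image(img, tf)
  back <- read_nifti_image(tf)
  expect_identical(back$pixels, img$pixels)
  expect_lt(max(abs(back$spacing - img$spacing)), 1e-6)
  expect_lt(max(abs(back$origin - img$origin)), 1e-6)
  v <- volume_image(array(runif(5 * 6 * 7), c(5, 6, 7)),
                    spacing = c(0.5, 1, 2))
  tfv <- tempfile(fileext = ".nii.gz")
  write_nifti_image(v, tfv)
  bv <- read_nifti_image(tfv)
  expect_identical(bv$voxels, v$voxels)
  expect_lt(max(abs(bv$spacing - v$spacing)), 1e-6)
  expect_lt(max(abs(bv$origin - v$origin)), 1e-6)
  # per-section files
  st <- section_stack(array(runif(6 * 5 * 4), c(6, 5, 4)), thickness = 0.1)
  d <- tempfile(); write_stack_sections(st, d)
  expect_identical(lapply(read_stack_sections(d, 0.1)$sections, `[[`, "pixels"),
                   lapply(st$sections, `[[`, "pixels"))
})

test_that("resampling honors the pull-back convention", {
  set.seed(7)
  img <- planar_image(matrix(runif(40 * 30), 40, 30), spacing = c(0.5, 0.5))
  # identity: bit-exact at grid nodes
  expect_identical(resample_planar(img, identity2d())$pixels, img$pixels)
  # integer-pixel translation with nearest neighbor shifts content
  shifted <- resample_planar(img, rigid2d(0, 2 * 0.5, 0),
                             interpolation = "nearest")
  expect_equal(shifted$pixels[1:38, ], img$pixels[3:40, ])
  # half-pixel shift of a linear ramp is exact under linear interpolation
  ramp <- planar_image(matrix(rep(1:32, 24), 32, 24), spacing = c(1, 1))
  half <- resample_planar(ramp, rigid2d(0, 0.5, 0))
  expect_equal(half$pixels[2:31, ], ramp$pixels[2:31, ] + 0.5)
  # out-of-domain samples take the background value
  bg <- resample_planar(img, rigid2d(0, 1e4, 0), background = -7)
  expect_true(all(bg$pixels == -7))
})

test_that("warping through t then its inverse restores a smooth image", {
  # band-limit the slice to ~1 px so the error measures resampling
  # fidelity, not aliasing of sub-pixel structure
  sl <- smooth_planar(tube_slice(), 4)
  t1 <- rigid2d(12, 1.3, -0.8, center = grid_center(sl))
  for (ip in c("linear", "cubic")) {
    wb <- resample_planar(resample_planar(sl, t1, interpolation = ip),
                          t_invert(t1), interpolation = ip)
    interior <- 8:(nrow(sl$pixels) - 8)
    err <- max(abs(wb$pixels[interior, interior] -
                   sl$pixels[interior, interior]))
    expect_lt(err, 0.02 * diff(range(sl$pixels)))
  }
})
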