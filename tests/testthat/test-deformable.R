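test_that("neighborhood averages follow the truncated-window definition", {
  st <- layered_stack(n = 20)
  na <- neighborhood_average(st, 8, 1)
  expect_equal(na$pixels,
               (st$sections[[7]]$pixels + st$sections[[9]]$pixels) / 2)
  # boundary truncation
  expect_equal(neighborhood_average(st, 1, 1)$pixels, st$sections[[2]]$pixels)
  # epsilon = 2 interior: brute-force accumulation over the 4 neighbors
  acc <- 0
  for (j in c(6, 7, 9, 10)) acc <- acc + st$sections[[j]]$pixels
  expect_equal(neighborhood_average(st, 8, 2)$pixels, acc / 4)
  expect_error(neighborhood_average(st, 3, 0), "epsilon")
})

test_that("a stack of identical sections is a fixed point", {
  st <- layered_stack(n = 20)
  same <- section_stack(rep(st$sections[10], 6), thickness = 0.05)
  totals <- lapply(same$sections, zero_field)
  sett <- reg_settings(levels = 2, iterations = c(8, 8), metric = "MSQ")
  res <- deformable_iteration(same, same, totals, 1, sett)
  meds <- vapply(res$updates, function(u)
    median(field_magnitude(u)) / mean(same$sections[[1]]$spacing), 0)
  expect_lt(max(meds), 0.05)
})

test_that("one iteration improves a single warped section between clean neighbors", {
  st <- layered_stack(n = 20)
  sub <- section_stack(st$sections[8:12], thickness = st$thickness)
  truth_mid <- sub$sections[[3]]
  f <- make_displacement_distortion(dim(truth_mid$pixels), truth_mid$spacing,
                                    kernel_sigma = 0.3, target_median = 0.05,
                                    seed = 71)
  f <- dispfield2d(f$u1, f$u2, spacing = truth_mid$spacing,
                   origin = truth_mid$origin)
  distorted <- sub
  distorted$sections[[3]] <- resample_planar(truth_mid, f)
  before <- msq(distorted$sections[[3]], truth_mid)
  sett <- reg_settings(levels = 2, iterations = c(12, 10), metric = "MSQ")
  res <- deformable_iteration(distorted, distorted,
                              lapply(distorted$sections, zero_field), 1, sett)
  after <- msq(res$stack$sections[[3]], truth_mid)
  expect_lt(after, before)
})

test_that("reconstruction history exposes convergence and respects stop modes", {
  st <- layered_stack(n = 14)
  dist <- distort_displacement(st, kernel_sigma = 0.3, target_median = 0.05,
                               seed = 72)
  sett <- reg_settings(levels = 2, iterations = c(10, 8), metric = "MSQ")
  rec <- deformable_reconstruct(dist$stack, epsilon = 1, n_iter = 4,
                                settings = sett, stop = "fixed",
                                reference = st)
  expect_length(rec$report$consec_msq, 4)
  expect_length(rec$report$msq_to_ref, 4)
  # consecutive-change decreases over the first iterations (smoothing effect)
  expect_lt(rec$report$consec_msq[2], rec$report$consec_msq[1])
  # delta_tol: a threshold between the 2nd and 3rd consecutive differences
  # stops the run right there
  tol <- mean(rec$report$consec_msq[2:3])
  rec0 <- deformable_reconstruct(dist$stack, epsilon = 1, n_iter = 4,
                                 settings = sett, stop = "delta_tol",
                                 tol = tol)
  expect_equal(rec0$report$iterations, 3)
  # adjacent-section MSQ is non-increasing over the first iterations
  adj_msq <- function(stk) mean(vapply(seq_len(n_sections(stk) - 1),
    function(i) msq(stk$sections[[i]], stk$sections[[i + 1]]), 0))
  rec2 <- deformable_reconstruct(dist$stack, epsilon = 1, n_iter = 3,
                                 settings = sett, stop = "fixed",
                                 keep_stacks = TRUE)
  vals <- c(adj_msq(dist$stack), vapply(rec2$stacks, adj_msq, 0))
  expect_true(all(diff(vals[1:3]) <= 0))
  # total foreground mass changes by < 2% per iteration
  mass <- c(sum(stack_to_volume(dist$stack)$voxels),
            vapply(rec2$stacks, function(s) sum(stack_to_volume(s)$voxels), 0))
  expect_true(all(abs(diff(mass)) / mass[-length(mass)] < 0.02))
})

test_that("mirroring the stack mirrors the update assignment", {
  st <- layered_stack(n = 14)
  dist <- distort_displacement(st, kernel_sigma = 0.3, target_median = 0.05,
                               seed = 73)
  sett <- reg_settings(levels = 2, iterations = c(8, 6), metric = "MSQ")
  fwd <- deformable_iteration(dist$stack, dist$stack,
                              lapply(dist$stack$sections, zero_field), 1, sett)
  rev_stack <- section_stack(rev(dist$stack$sections),
                             thickness = dist$stack$thickness)
  bwd <- deformable_iteration(rev_stack, rev_stack,
                              lapply(rev_stack$sections, zero_field), 1, sett)
  n <- n_sections(dist$stack)
  for (i in c(1, 7, n))
    expect_equal(bwd$updates[[n + 1 - i]]$u1, fwd$updates[[i]]$u1,
                 tolerance = 1e-12)
})
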