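test_that("mask construction applies per-subject activity and grey-matter rules", {
  dims <- c(3, 3, 3)
  uniform <- array(5, dims)
  gm1 <- array(1, dims)
  expect_true(all(build_mask(list(uniform), gm1)))

  # a zero-activity voxel in one subject excludes that voxel for everyone
  a2 <- array(5, dims); a2[2, 2, 2] <- 0
  m <- build_mask(list(uniform, a2), gm1)
  expect_false(m[2, 2, 2])
  expect_equal(sum(m), 26)

  # hand-evaluated toy grid against a naive voxel loop
  set.seed(1)
  act <- list(array(runif(27, 0, 2), dims), array(runif(27, 0, 2), dims))
  gm <- array(runif(27), dims)
  got <- build_mask(act, gm, activity_frac = 0.7, gm_thresh = 0.2)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    keep <- all(sapply(act, function(a) a[i, j, k] >= 0.7 * mean(a))) &&
      gm[i, j, k] > 0.2
    expect_identical(got[i, j, k], keep)
  }

  # monotonicity: stricter thresholds never add voxels
  m_loose <- build_mask(act, gm, activity_frac = 0.5, gm_thresh = 0.1)
  expect_true(all(m_loose | !got))
  expect_error(build_mask(act, gm, activity_frac = 10), "empty")
})

test_that("searchlight geometry matches the lattice-ball count of 123 at radius 3", {
  mask <- array(TRUE, c(10, 10, 10))
  sl <- define_searchlights(mask, radius = 3, step = 2, min_size = 15)
  # interior centres (>= 4 voxels from every face) hold a full radius-3 ball
  interior <- sl$cx >= 4 & sl$cx <= 7 & sl$cy >= 4 & sl$cy <= 7 &
    sl$cz >= 4 & sl$cz <= 7
  expect_true(any(interior))
  expect_true(all(sl$n_members[interior] == 123))
  expect_true(all(sl$n_members >= 15))

  # a 14-voxel mask cannot host a 15-voxel searchlight
  small <- array(FALSE, c(6, 6, 6)); small[seq_len(14)] <- TRUE
  expect_error(define_searchlights(small, 3, 2, 15), "minimum size")

  # refining the lattice never yields fewer searchlights
  set.seed(2)
  rmask <- array(runif(12^3) < 0.6, c(12, 12, 12))
  n2 <- nrow(define_searchlights(rmask, 3, 2, 15))
  n1 <- nrow(define_searchlights(rmask, 3, 1, 15))
  expect_gte(n1, n2)
})

test_that("Procrustes alignment recovers orthogonal transforms and never hurts", {
  set.seed(3)
  ref <- scale(matrix(rnorm(40 * 12), 40, 12))
  expect_equal(procrustes_align(ref, ref), diag(12), tolerance = 1e-9)

  Q <- random_orthogonal(12, seed = 4)
  sub <- ref %*% Q
  R <- procrustes_align(ref, sub)
  expect_equal(R, t(Q), tolerance = 1e-6)
  expect_equal(crossprod(R), diag(12), tolerance = 1e-9)

  for (i in 1:5) {
    noisy <- sub + matrix(rnorm(40 * 12, 0, 0.5), 40, 12)
    R2 <- procrustes_align(ref, noisy)
    expect_lte(norm(ref - noisy %*% R2, "F"), norm(ref - noisy, "F") + 1e-9)
  }
})

test_that("hyperalignment restores a shared space from rotated copies", {
  set.seed(5)
  # long series: column z-scoring then barely perturbs the rotated copies
  sig <- scale(matrix(rnorm(200 * 12), 200, 12))  # full column rank
  # identical subjects pass through unchanged
  same <- lapply(1:3, function(i) sig)
  out <- hyperalign_group(same)
  expect_equal(out[[1]], sig, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(out[[3]], sig, ignore_attr = TRUE, tolerance = 1e-9)

  # rotated copies, no noise: pairwise synchrony ~ 1 after alignment
  subs <- lapply(1:4, function(i) sig %*% random_orthogonal(12, seed = 10 + i))
  al <- hyperalign_group(subs)
  expect_gt(iss(al[[1]], al[-1]), 1 - 1e-3)
  expect_gt(iss(al[[3]], al[-3]), 1 - 1e-3)

  # orthogonality preserves row norms
  expect_equal(rowSums(al[[2]]^2), rowSums(zscore_cols_oracle(subs[[2]])^2),
               tolerance = 1e-9)

  expect_warning(single <- hyperalign_group(list(sig)), "Single subject")
  expect_length(single, 1)
})

test_that("aligning noisy rotated subjects sharpens the planted state structure", {
  st <- c(7L, 14L, 22L)
  wins <- 0
  for (s in 1:11) {
    sig <- planted_states_matrix(30, 20, st, 1, 0, seed = s)
    subs <- lapply(1:5, function(i) {
      set.seed(s * 100 + i)
      sig %*% random_orthogonal(20, seed = s * 100 + i) +
        matrix(rnorm(30 * 20, 0, 0.8), 30, 20)
    })
    t_un <- tdistance(group_average(subs), st)
    t_al <- tdistance(group_average(hyperalign_group(subs)), st)
    wins <- wins + (t_al > t_un)
  }
  expect_gt(wins, 5.5)  # majority of seeds
})

test_that("group averaging is the mean followed by row z-scoring", {
  a <- matrix(rnorm(20 * 6), 20, 6)
  expect_equal(group_average(list(a)), zscore_rows(a))
  b <- matrix(rnorm(20 * 6), 20, 6)
  expect_equal(group_average(list(a, b)), zscore_rows((a + b) / 2))
  expect_error(group_average(list(a, -a)), "constant")
})

test_that("searchlight values project back to voxels as membership means", {
  mask <- array(TRUE, c(8, 8, 8))
  sl <- define_searchlights(mask, radius = 2, step = 3, min_size = 5)
  vals <- seq_len(nrow(sl))
  map <- project_to_voxels(vals, sl, c(8, 8, 8))
  # single-membership voxels carry that searchlight's value
  one <- sl$members[[1]][!(sl$members[[1]] %in% unlist(sl$members[-1]))]
  expect_true(all(map[one] == vals[1]))
  # brute-force oracle over every voxel
  for (v in sample(512, 40)) {
    holders <- which(sapply(sl$members, function(m) v %in% m))
    if (length(holders) == 0) {
      expect_true(is.na(map[v]))
    } else {
      expect_equal(map[v], mean(vals[holders]))
    }
  }
  expect_error(project_to_voxels(vals[-1], sl, c(8, 8, 8)), "one value per")
})
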