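test_that("consensus clustering keeps only boundaries endorsed by enough observers", {
  all16 <- tibble::tibble(observer = 1:16, time_s = rep(10, 16))
  got <- consensus_events(all16, cluster_window_s = 2.47, min_agree = 5)
  expect_equal(got$onset_s, 10)
  expect_equal(got$n_observers, 16L)

  few <- tibble::tibble(observer = 1:4, time_s = c(9.8, 10, 10.1, 10.3))
  expect_equal(nrow(consensus_events(few, min_agree = 5)), 0)

  # planted clusters: recovered onsets are the cluster medians
  set.seed(1)
  centres <- c(12, 40, 77)
  presses <- do.call(rbind, lapply(centres, function(ct) {
    tibble::tibble(observer = 1:8, time_s = ct + seq(-0.8, 0.8, length.out = 8))
  }))
  got2 <- consensus_events(presses, cluster_window_s = 2.47, min_agree = 5)
  expect_equal(got2$onset_s, centres)
  expect_equal(got2$n_presses, rep(8L, 3))
})

test_that("event windows map to TRs by interval overlap", {
  # onset 100 s, shift 5, window 1: [104.5, 105.5] s; TR 43 spans [103.74, 106.21) s
  tl <- event_timeline(100, TR = 2.47, hrf_shift_s = 5, window_s = 1)
  expect_identical(event_tr_set(tl, 193), 43L)

  # shifted onset exactly on a TR edge: the 1-s window straddles, both TRs in
  edge <- 10 * 2.47 - 5
  tl2 <- event_timeline(edge, TR = 2.47)
  expect_identical(event_tr_set(tl2, 50), c(10L, 11L))

  # zero-width window: the single TR containing the shifted onset
  tl3 <- event_timeline(100, TR = 2.47, window_s = 0)
  got <- event_tr_set(tl3, 193)
  expect_length(got, 1)
  expect_identical(got, 43L)

  # events shifted past the stimulus end are dropped with a warning
  tl4 <- event_timeline(c(10, 1000), TR = 2.47)
  expect_warning(ev <- event_tr_set(tl4, 193), "dropped")
  expect_true(all(ev <= 193))
})

test_that("median state duration converts TRs to seconds at the scanner TR", {
  # three 2-TR states: 2 * 2.47 = 4.94 s (prints as 4.9)
  expect_equal(median_duration_s(c(3L, 5L), 6L, 2.47), 4.94)
  expect_equal(round(median_duration_s(c(3L, 5L), 6L, 2.47), 1), 4.9)
  # one 18-TR state: 44.46 s (prints as 44.5)
  expect_equal(median_duration_s(integer(0), 18L, 2.47), 44.46)
  expect_equal(round(median_duration_s(integer(0), 18L, 2.47), 1), 44.5)
  # durations 2, 3, 10 -> median 3 TRs
  expect_equal(median_duration_s(c(3L, 6L), 15L, 2.47), 3 * 2.47)
})

test_that("the duration CV is IQR over median and scale-invariant", {
  # equal durations
  expect_equal(duration_cv(c(5L, 9L), 12L), 0)
  # durations 2, 4, 6, 8: quartiles 3 and 7 under the averaging convention
  expect_equal(duration_cv(c(3L, 7L, 13L), 20L), 4 / 5)
  # doubling every duration leaves the CV unchanged
  expect_equal(duration_cv(c(5L, 13L, 25L), 40L), 4 / 5)
})

test_that("boundary strength reflects flanking-pattern similarity", {
  pat_same <- rbind(c(1, 2, 0, -1), c(1, 2, 0, -1) * 2)  # same shape, scaled
  m1 <- planted_states_matrix(10, 4, 6L, noise_sd = 0, seed = 1,
                              patterns = pat_same)
  expect_equal(boundary_strength(m1, 6L)$strength, 0, tolerance = 1e-9)

  pat_anti <- rbind(c(1, 2, 0, -1), -c(1, 2, 0, -1))
  m2 <- planted_states_matrix(10, 4, 6L, noise_sd = 0, seed = 1,
                              patterns = pat_anti)
  expect_equal(boundary_strength(m2, 6L)$strength, 2, tolerance = 1e-9)

  # hand 6 x 3 case: direct correlation of the two state-mean patterns
  h <- matrix(c(1, 5, 2, 2, 6, 1, 0, 4, 3, 7, 1, 2, 8, 0, 1, 6, 2, 3), 6, 3,
              byrow = TRUE)
  zh <- zscore_rows(h)
  expected <- 1 - cor(colMeans(zh[1:4, ]), colMeans(zh[5:6, ]))
  expect_equal(boundary_strength(h, 5L)$strength, expected)
  expect_error(boundary_strength(h, integer(0)), "2 states")
})

test_that("negating the second state's voxels mirrors boundary strength around 1", {
  m <- planted_states_matrix(14, 8, 8L, noise_sd = 0.1, seed = 2)
  flipped <- m
  flipped[8:14, ] <- -flipped[8:14, ]
  s1 <- boundary_strength(m, 8L)$strength
  s2 <- boundary_strength(flipped, 8L)$strength
  expect_equal(s1 + s2, 2, tolerance = 1e-9)
})

test_that("within-state correlation matches naive pair enumeration", {
  m <- planted_states_matrix(15, 6, c(6L, 11L), noise_sd = 0, seed = 3)
  expect_equal(within_state_correlation(m, c(6L, 11L)), 1, tolerance = 1e-9)
  set.seed(4)
  noise <- matrix(rnorm(20 * 100), 20, 100)
  expect_lt(abs(within_state_correlation(noise, c(8L, 15L))), 0.1)
  mr <- matrix(rnorm(12 * 5), 12, 5)
  b <- c(4L, 9L)
  expect_equal(within_state_correlation(mr, b), oracle_within_cor(mr, b),
               tolerance = 1e-10)
  expect_error(within_state_correlation(mr, 2:12), "single TR")
})

test_that("inter-subject synchrony behaves at its anchors", {
  set.seed(5)
  a <- matrix(rnorm(30 * 8), 30, 8)
  b <- matrix(rnorm(30 * 8), 30, 8)
  # subject equal to the mean of the others
  expect_equal(iss((a + b) / 2, list(a, b)), 1, tolerance = 1e-12)
  # independent noise: near zero
  expect_lt(abs(iss(matrix(rnorm(200 * 30), 200, 30),
                    list(matrix(rnorm(200 * 30), 200, 30)))), 0.1)
  # group ISS is the mean of the leave-one-out values
  subs <- list(a, b, (a + b) / 2)
  direct <- mean(c(iss(subs[[1]], subs[-1]), iss(subs[[2]], subs[-2]),
                   iss(subs[[3]], subs[-3])))
  expect_equal(group_iss(subs), direct)
  # constant voxels are skipped with a warning
  a2 <- a; a2[, 3] <- 7
  expect_warning(v <- iss(a2, list(b)), "skipped")
  expect_true(is.finite(v))
})

test_that("absolute overlap rescales between chance (0) and total overlap (1)", {
  # the worked configuration: 20 state boundaries, 10 event TRs, 100 TRs, 8 hits
  got <- overlap_stat(20, 10, 100, 8)
  expect_equal(got$expected, 2)
  expect_equal(got$absolute, 6 / 18)
  expect_lt(abs(got$absolute - 0.334), 1e-3)
  # chance-level observation maps to zero
  expect_equal(overlap_stat(20, 10, 100, 2)$absolute, 0)
  # via boundary/event vectors
  st <- as.integer(seq(2, 97, 5))          # 20 boundaries
  ev <- c(st[1:8], 98L, 99L)               # 8 hits among 10 event TRs
  ov <- absolute_overlap(st, ev, 100)
  expect_equal(ov$observed, 8L)
  expect_equal(ov$absolute, 6 / 18)
  expect_error(absolute_overlap(integer(0), ev, 100), "at least one")
})

test_that("absolute overlap depends only on the hit fraction at fixed events and length", {
  # 20 boundaries / 10 hits vs 30 boundaries / 15 hits
  expect_equal(overlap_stat(20, 10, 100, 10)$absolute,
               overlap_stat(30, 10, 100, 15)$absolute)
  set.seed(6)
  for (i in 1:25) {
    n_e <- sample(5:20, 1); n_tr <- sample(80:200, 1)
    r <- runif(1, 0.2, 0.9)
    ns1 <- sample(seq(10, 40, 2), 1); ns2 <- ns1 * 2
    o1 <- round(r * ns1); o2 <- 2 * o1
    expect_equal(overlap_stat(ns1, n_e, n_tr, o1)$absolute,
                 overlap_stat(ns2, n_e, n_tr, o2)$absolute,
                 tolerance = 1e-12)
  }
})

test_that("boundary occurrence splits on- and off-event TRs correctly", {
  ev <- c(5L, 10L, 15L)
  # every TR from 2..20 a boundary: occurrence 1 on-event; off-event misses TR 1
  full <- list(2:20)
  got <- boundary_occurrence_split(full, ev, 20L)
  expect_equal(got$on_event, 1)
  expect_equal(got$off_event, 16 / 17)
  # no boundaries
  none <- boundary_occurrence_split(list(integer(0)), ev, 20L)
  expect_equal(c(none$on_event, none$off_event), c(0, 0))
  # hand case: boundaries {5, 8}; events {5, 10}; T = 10
  h <- boundary_occurrence_split(list(c(5L, 8L)), c(5L, 10L), 10L)
  expect_equal(h$on_event, 1 / 2)
  expect_equal(h$off_event, 1 / 8)
  expect_error(boundary_occurrence_split(full, integer(0), 20L), "Empty")
})
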