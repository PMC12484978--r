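test_that("a 10-TR series with mean = min duration 5 forces the single feasible partition", {
  # only one way to cut 10 TRs into states of exactly 5: second state starts at TR 6
  expect_identical(make_state_sequence(10, mean_dur = 5, min_dur = 5, seed = 1), 6L)
  expect_identical(make_state_sequence(10, mean_dur = 5, min_dur = 5, seed = 99), 6L)
})

test_that("drawn state durations respect the minimum and hit the target mean", {
  durs <- unlist(lapply(1:100, function(s) {
    st <- make_state_sequence(193, mean_dur = 5, min_dur = 2, seed = s)
    state_durations(st, 193)
  }))
  expect_true(all(durs >= 2))
  expect_lt(abs(mean(durs) - 5) / 5, 0.20)
})

test_that("degenerate duration parameters are rejected", {
  expect_error(make_state_sequence(20, mean_dur = 5, min_dur = 0), "min")
  expect_error(make_state_sequence(20, mean_dur = 25, min_dur = 2), "state change")
  expect_error(make_state_sequence(20, mean_dur = 1, min_dur = 2), "min_dur")
})

test_that("subject simulation plants patterns, jitter, and calibrated noise", {
  st <- c(21L, 41L, 61L, 81L)
  # noiseless, jitter-free: correlation 1 within states, < 1 across boundaries
  sub <- make_subject(st, 100, 20, pattern_sd = 1, noise_sd = 0, jitter_sd = 0,
                      seed = 3)
  expect_identical(sub$starts, st)
  Z <- zscore_rows(sub$data)
  rr <- function(i, j) cor(Z[i, ], Z[j, ])
  expect_equal(rr(5, 6), 1, tolerance = 1e-12)
  for (b in st) expect_lt(rr(b - 1L, b), 1 - 1e-6)

  # noise amplitude: empirical residual SD within 5% of noise_sd at T*V >= 1e4
  sub2 <- make_subject(st, 200, 50, pattern_sd = 1, noise_sd = 0.7,
                       jitter_sd = 0, seed = 4)
  g <- findInterval(seq_len(200), c(1, st))
  resid <- sub2$data - sub2$patterns[g, ]
  expect_lt(abs(sd(resid) - 0.7) / 0.7, 0.05)

  # jitter keeps boundaries ordered and valid
  sub3 <- make_subject(st, 100, 20, noise_sd = 0.1, jitter_sd = 2, seed = 5)
  expect_true(all(diff(sub3$starts) > 0))
  expect_true(all(sub3$starts >= 2 & sub3$starts <= 100))

  # one voxel: pattern correlations undefined, rejected
  expect_error(make_subject(st, 100, 1, seed = 1), "n_vox")
})

test_that("inter-subject synchrony decreases with subject noise", {
  st <- c(11L, 21L, 31L)
  iss_at <- function(noise_sd) {
    mean(sapply(1:50, function(r) {
      pat <- matrix(rnorm(4 * 20), 4, 20)
      s1 <- make_subject(st, 40, 20, noise_sd = noise_sd, jitter_sd = 0,
                         seed = 1000 + r, patterns = pat)$data
      s2 <- make_subject(st, 40, 20, noise_sd = noise_sd, jitter_sd = 0,
                         seed = 5000 + r, patterns = pat)$data
      iss(s1, list(s2))
    }))
  }
  set.seed(7)
  expect_gt(iss_at(0.1), iss_at(1.0))
})

test_that("cohorts are bit-reproducible from the spec seed", {
  sc <- cohort_spec(n_groups = 3, group_size = 2, n_tr = 50, n_vox = 10, seed = 11)
  c1 <- make_cohort(sc)
  c2 <- make_cohort(sc)
  expect_identical(c1$groups, c2$groups)
  expect_identical(c1$truth$event_times_s, c2$truth$event_times_s)
})

test_that("jitter-free cohorts carry their planted boundaries into every subject", {
  sc <- cohort_spec(n_groups = 3, group_size = 3, n_tr = 60, n_vox = 10,
                    jitter_sd = 0, seed = 2)
  coh <- make_cohort(sc)
  for (g in 1:3) {
    for (s in 1:3) {
      expect_identical(coh$truth$subject_boundaries[[g]][[s]],
                       coh$truth$true_boundaries[[g]])
    }
  }
  # planted median duration in tidy() equals direct recomputation
  td <- tidy(coh)
  expect_equal(td$median_duration_tr[2],
               median(state_durations(coh$truth$true_boundaries[[2]], 60)))
})

test_that("a flat duration map plants no age trend", {
  sc <- cohort_spec(n_groups = 5, group_size = 1, n_tr = 60, n_vox = 8,
                    duration_map = function(age) 6, seed = 3)
  coh <- make_cohort(sc)
  expect_true(all(coh$truth$mean_durations == 6))
})

test_that("with event_fraction 1 every eligible planted boundary becomes an event TR", {
  sc <- cohort_spec(n_groups = 2, group_size = 1, n_tr = 80, n_vox = 10,
                    TR = 2.47, min_dur = 4L, event_fraction = 1,
                    duration_map = function(age) 8, seed = 6)
  coh <- make_cohort(sc)
  b1 <- coh$truth$true_boundaries[[1]]
  eligible <- b1[(b1 - 1) * 2.47 - 5 >= 0]
  expect_identical(coh$truth$event_boundary_trs, eligible)
  tl <- event_timeline(coh$truth$event_times_s, TR = 2.47)
  ev <- event_tr_set(tl, 80)
  expect_true(all(eligible %in% ev))
})

test_that("an increasing duration map is recovered end to end on clean data", {
  sc <- cohort_spec(n_groups = 6, group_size = 1, n_tr = 80, n_vox = 30,
                    duration_map = function(age) 4 + 8 * (age - 18) / 70,
                    min_dur = 3L, noise_sd = 0.05, jitter_sd = 0, seed = 8)
  coh <- make_cohort(sc)
  med <- sapply(coh$groups, function(g) {
    fit <- gsbs(g$subjects[[1]], k_max = 26)
    median(state_durations(fit$optimal, 80))
  })
  expect_gt(spearman_cor(coh$truth$group_ages, med)$estimate, 0.9)
})

test_that("cohorts round-trip through the TSV/JSON writers", {
  sc <- cohort_spec(n_groups = 2, group_size = 2, n_tr = 30, n_vox = 6, seed = 4)
  coh <- make_cohort(sc)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  m <- read_subject_tsv(file.path(dir, "group01_subject02.tsv"))
  expect_equal(unclass(m)[seq_len(30), ], coh$groups[[1]]$subjects[[2]],
               ignore_attr = TRUE)
  expect_equal(attr(m, "TR"), 2.47)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$group_ages, coh$truth$group_ages)
})
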