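#' Draw a piecewise-stationary state sequence
#'
#' Partitions `n_tr` timepoints into states whose durations are
#' `min_dur` plus a rounded gamma draw with shape `shape` and mean
#' `mean_dur - min_dur`.  The shape parameter sets the duration variability
#' (coefficient of variation `1/sqrt(shape)` before rounding): the default of
#' 4 gives moderately variable states whose group medians track the target
#' mean closely; `shape = 1` reproduces the heavy-tailed exponential limit.
#' The final state is truncated to fill the series exactly; if the remainder
#' is shorter than `min_dur` it is merged into the previous state.
#'
#' @param n_tr number of timepoints.
#' @param mean_dur target mean state duration in TRs; must satisfy
#'   `min_dur <= mean_dur < n_tr`.
#' @param min_dur minimum state duration in TRs (>= 1).
#' @param seed integer RNG seed.
#' @param shape gamma shape of the duration distribution (> 0).
#' @return sorted integer vector of state-start TRs (1-based, in `2..n_tr`).
#' @export
#' @examples
#' make_state_sequence(193, mean_dur = 5, min_dur = 2, seed = 1)
make_state_sequence <- function(n_tr, mean_dur, min_dur = 1L, seed = 1L,
                                shape = 4) {
  n_tr <- assert_count(n_tr, min = 2L)
  min_dur <- assert_count(min_dur, min = 1L)
  mean_dur <- assert_number(mean_dur, min = 1)
  shape <- assert_number(shape, min = 1e-9)
  if (mean_dur < min_dur) abort("`mean_dur` must be >= `min_dur`.")
  if (mean_dur >= n_tr) {
    abort("`mean_dur` must be < `n_tr`: cannot place at least one state change.")
  }
  scale <- (mean_dur - min_dur) / shape
  with_seed(seed, {
    durs <- integer(0)
    total <- 0L
    while (total < n_tr) {
      d <- min_dur + (if (scale <= 0) 0L else
        as.integer(round(rgamma(1L, shape = shape, scale = scale))))
      durs <- c(durs, d)
      total <- total + d
    }
    # truncate the overshoot; merge a too-short tail into the previous state
    excess <- total - n_tr
    durs[length(durs)] <- durs[length(durs)] - excess
    if (length(durs) > 1L && durs[length(durs)] < min_dur) {
      durs[length(durs) - 1L] <- durs[length(durs) - 1L] + durs[length(durs)]
      durs <- durs[-length(durs)]
    }
    if (length(durs) == 1L) integer(0) else cumsum(durs)[-length(durs)] + 1L
  })
}

#' Simulate one subject's activity matrix around planted boundaries
#'
#' Each state carries a fixed voxel pattern drawn i.i.d. Normal(0,
#' `pattern_sd`^2) (or supplied via `patterns`); per-subject boundary jitter
#' displaces each boundary by `round(Normal(0, jitter_sd^2))` TRs, resampling
#' any displacement that would break the strict ordering of boundaries; and
#' i.i.d. Normal(0, `noise_sd`^2) measurement noise is added per voxel per TR.
#'
#' @param starts planted boundary vector (state-start TRs, 1-based).
#' @param n_tr number of timepoints.
#' @param n_vox number of voxels (>= 2; a single voxel has no spatial pattern
#'   and pattern correlations are undefined).
#' @param pattern_sd SD of state pattern amplitudes.
#' @param noise_sd SD of additive measurement noise.
#' @param jitter_sd SD (in TRs) of per-boundary displacement.
#' @param seed integer RNG seed.
#' @param patterns optional k x `n_vox` matrix of state patterns to reuse
#'   (rows = states in order); drawn when `NULL`.
#' @return a list with `data` (T x V matrix), `starts` (the jittered
#'   boundaries actually used) and `patterns`.
#' @export
make_subject <- function(starts, n_tr, n_vox, pattern_sd = 1, noise_sd = 0.5,
                         jitter_sd = 0, seed = 1L, patterns = NULL) {
  n_tr <- assert_count(n_tr, min = 2L)
  n_vox <- assert_count(n_vox, min = 2L)
  starts <- validate_starts(starts, n_tr)
  pattern_sd <- assert_number(pattern_sd, min = 0)
  noise_sd <- assert_number(noise_sd, min = 0)
  jitter_sd <- assert_number(jitter_sd, min = 0)
  k <- length(starts) + 1L
  with_seed(seed, {
    if (is.null(patterns)) {
      patterns <- matrix(rnorm(k * n_vox, 0, pattern_sd), k, n_vox)
    } else {
      patterns <- as.matrix(patterns)
      if (nrow(patterns) < k || ncol(patterns) != n_vox) {
        abort("`patterns` must have at least k rows and exactly `n_vox` columns.")
      }
      patterns <- patterns[seq_len(k), , drop = FALSE]
    }
    jstarts <- starts
    if (jitter_sd > 0 && length(starts) > 0L) {
      nb <- length(starts)
      for (j in seq_len(nb)) {
        prev <- if (j == 1L) 1L else jstarts[j - 1L]
        nxt <- if (j == nb) n_tr + 1L else starts[j + 1L]
        for (try in 1:100) {
          cand <- starts[j] + as.integer(round(rnorm(1L, 0, jitter_sd)))
          if (cand > prev && cand < nxt && cand >= 2L && cand <= n_tr) {
            jstarts[j] <- cand
            break
          }
          if (try == 100L) jstarts[j] <- starts[j]
        }
      }
    }
    g <- state_labels(n_tr, jstarts)
    data <- patterns[g, , drop = FALSE] +
      matrix(rnorm(n_tr * n_vox, 0, noise_sd), n_tr, n_vox)
    list(data = data, starts = jstarts, patterns = patterns)
  })
}

#' Convenience constructor for a noisy planted-state matrix
#'
#' A thin wrapper around [make_subject()] returning only the data matrix,
#' with no boundary jitter.  Handy for examples and quick experiments.
#'
#' @inheritParams make_subject
#' @return a T x V numeric matrix.
#' @export
planted_states_matrix <- function(n_tr, n_vox, starts, pattern_sd = 1,
                                  noise_sd = 0, seed = 1L, patterns = NULL) {
  make_subject(starts, n_tr, n_vox, pattern_sd = pattern_sd,
               noise_sd = noise_sd, jitter_sd = 0, seed = seed,
               patterns = patterns)$data
}

#' Specification of a synthetic multi-group cohort
#'
#' Collects the parameters of the synthetic cohort generator.  Defaults mirror
#' the study design this package models: 34 age groups of 17 participants,
#' 193 timepoints at TR = 2.47 s, regions of 97 voxels, and events aligned
#' (after a 5-s hemodynamic shift) with a subset of the youngest group's
#' boundaries.
#'
#' @param n_groups number of age groups (>= 2).
#' @param group_size subjects per group (>= 1).
#' @param n_tr timepoints per subject.
#' @param n_vox voxels per region.
#' @param TR repetition time, seconds.
#' @param duration_map function mapping age (years) to mean state duration in
#'   TRs; must be monotone nondecreasing.  Default rises linearly from 4 TRs
#'   at age 18 to 9 TRs at age 88.
#' @param min_dur minimum state duration in TRs.
#' @param duration_shape gamma shape of the duration distribution (see
#'   [make_state_sequence()]).
#' @param pattern_sd SD of state pattern amplitudes.
#' @param noise_sd SD of per-subject additive noise.
#' @param jitter_sd SD (TRs) of per-subject boundary displacement.
#' @param event_fraction fraction of the first (youngest) group's eligible
#'   boundaries that receive a matching perceived-event onset, in `[0, 1]`.
#' @param hrf_shift_s hemodynamic delay used when back-placing event onsets.
#' @param seed master integer seed; the cohort is bit-reproducible from it.
#' @return an object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_groups = 34L, group_size = 17L, n_tr = 193L,
                        n_vox = 97L, TR = 2.47,
                        duration_map = function(age) 4 + 5 * (age - 18) / 70,
                        min_dur = 2L, duration_shape = 4, pattern_sd = 1,
                        noise_sd = 0.5, jitter_sd = 0.5, event_fraction = 0.5,
                        hrf_shift_s = 5, seed = 1L) {
  spec <- list(
    n_groups = assert_count(n_groups, min = 2L),
    group_size = assert_count(group_size, min = 1L),
    n_tr = assert_count(n_tr, min = 10L),
    n_vox = assert_count(n_vox, min = 2L),
    TR = assert_number(TR, min = 1e-9),
    duration_map = duration_map,
    min_dur = assert_count(min_dur, min = 1L),
    duration_shape = assert_number(duration_shape, min = 1e-9),
    pattern_sd = assert_number(pattern_sd, min = 0),
    noise_sd = assert_number(noise_sd, min = 0),
    jitter_sd = assert_number(jitter_sd, min = 0),
    event_fraction = assert_number(event_fraction, min = 0),
    hrf_shift_s = assert_number(hrf_shift_s, min = 0),
    seed = assert_count(seed, min = 0L)
  )
  if (!is.function(duration_map)) abort("`duration_map` must be a function age -> TRs.")
  if (spec$event_fraction > 1) abort("`event_fraction` must be in [0, 1].")
  structure(spec, class = "cohort_spec")
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Builds `n_groups` age groups of `group_size` subjects each.  Group ages are
#' evenly spaced over 18-88 years; group g's planted mean state duration is
#' `duration_map(age_g)`.  All groups reuse the same pool of state patterns
#' (same content, different durations) so that age effects are purely
#' temporal.  Event onsets are placed at `(b - 1) * TR - hrf_shift_s` seconds
#' for a deterministic, seeded subset of the youngest group's boundaries, so
#' that after the analysis pipeline's forward hemodynamic shift they align
#' with those planted boundaries; boundaries too early to admit a nonnegative
#' onset are skipped with a warning when `event_fraction` is 1.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `"state_cohort"`: a list with `groups` (per
#'   group: `age`, `starts`, `subjects` = list of T x V matrices,
#'   `subject_starts`) and `truth` (group ages, planted boundaries, jittered
#'   per-subject boundaries, `event_times_s`, noise level, and the spec).
#' @export
#' @examples
#' sc <- cohort_spec(n_groups = 3, group_size = 2, n_tr = 60, n_vox = 12)
#' coh <- make_cohort(sc)
#' tidy(coh)
make_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec().")
  ages <- seq(18, 88, length.out = spec$n_groups)
  mean_durs <- vapply(ages, spec$duration_map, numeric(1))
  if (any(diff(mean_durs) < -1e-9)) {
    abort("`duration_map` must be monotone nondecreasing in age.")
  }

  # shared pattern pool: enough rows for the maximum possible state count
  n_pool <- ceiling(spec$n_tr / spec$min_dur)
  pool <- with_seed(derive_seed(spec$seed, 1L), {
    matrix(rnorm(n_pool * spec$n_vox, 0, spec$pattern_sd), n_pool, spec$n_vox)
  })

  groups <- vector("list", spec$n_groups)
  true_boundaries <- vector("list", spec$n_groups)
  subject_boundaries <- vector("list", spec$n_groups)
  for (g in seq_len(spec$n_groups)) {
    starts <- make_state_sequence(spec$n_tr, mean_durs[g], spec$min_dur,
                                  seed = derive_seed(spec$seed, 2L, g),
                                  shape = spec$duration_shape)
    subjects <- vector("list", spec$group_size)
    sstarts <- vector("list", spec$group_size)
    for (s in seq_len(spec$group_size)) {
      sub <- make_subject(starts, spec$n_tr, spec$n_vox,
                          pattern_sd = spec$pattern_sd,
                          noise_sd = spec$noise_sd,
                          jitter_sd = spec$jitter_sd,
                          seed = derive_seed(spec$seed, 3L, g, s),
                          patterns = pool)
      subjects[[s]] <- sub$data
      sstarts[[s]] <- sub$starts
    }
    groups[[g]] <- list(age = ages[g], starts = starts, subjects = subjects,
                        subject_starts = sstarts)
    true_boundaries[[g]] <- starts
    subject_boundaries[[g]] <- sstarts
  }

  # perceived events: back-shifted onsets for a subset of group-1 boundaries
  b1 <- true_boundaries[[1]]
  onset_all <- (b1 - 1L) * spec$TR - spec$hrf_shift_s
  eligible <- which(onset_all >= 0)
  if (length(eligible) < length(b1) && spec$event_fraction == 1) {
    warn(sprintf("%d group-1 boundaries fall before the hemodynamic shift and cannot carry an event onset.",
                 length(b1) - length(eligible)))
  }
  n_ev <- round(spec$event_fraction * length(eligible))
  chosen <- if (n_ev == 0L) integer(0) else {
    with_seed(derive_seed(spec$seed, 4L),
              sort(sample(eligible, n_ev)))
  }
  event_times_s <- onset_all[chosen]

  structure(list(
    groups = groups,
    truth = list(
      group_ages = ages,
      mean_durations = mean_durs,
      true_boundaries = true_boundaries,
      subject_boundaries = subject_boundaries,
      event_times_s = event_times_s,
      event_boundary_trs = b1[chosen],
      noise_sd_used = rep(spec$noise_sd, spec$n_groups * spec$group_size),
      spec = spec
    )
  ), class = "state_cohort")
}

#' @export
print.state_cohort <- function(x, ...) {
  sp <- x$truth$spec
  cat(sprintf("<state_cohort> %d groups x %d subjects; T = %d, V = %d, TR = %.2f s\n",
              sp$n_groups, sp$group_size, sp$n_tr, sp$n_vox, sp$TR))
  cat(sprintf("planted events: %d; ages %.0f-%.0f\n",
              length(x$truth$event_times_s), min(x$truth$group_ages),
              max(x$truth$group_ages)))
  invisible(x)
}

#' Tidy a synthetic cohort's planted truth
#'
#' @param x a `"state_cohort"`.
#' @param ... unused.
#' @return a tibble with one row per group: `group`, `age`, planted `n_states`,
#'   target `mean_duration_tr`, and the realised `median_duration_tr`.
#' @export
tidy.state_cohort <- function(x, ...) {
  sp <- x$truth$spec
  purrr::map_dfr(seq_along(x$groups), function(g) {
    st <- x$truth$true_boundaries[[g]]
    dur <- state_durations(st, sp$n_tr)
    tibble(group = g, age = x$truth$group_ages[g],
           n_states = length(st) + 1L,
           mean_duration_tr = x$truth$mean_durations[g],
           median_duration_tr = median(dur))
  })
}

#' Write a cohort to disk as plain text
#'
#' One TSV per subject (`group<g>_subject<s>.tsv`, T rows x V columns, with the
#' repetition time recorded in a leading `# TR:` comment line) plus a
#' `truth.json` carrying the planted ground truth.
#'
#' @param cohort a `"state_cohort"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "state_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- cohort$truth$spec
  for (g in seq_along(cohort$groups)) {
    for (s in seq_along(cohort$groups[[g]]$subjects)) {
      path <- file.path(dir, sprintf("group%02d_subject%02d.tsv", g, s))
      con <- file(path, "w")
      writeLines(sprintf("# TR: %.10g", sp$TR), con)
      utils::write.table(cohort$groups[[g]]$subjects[[s]], con, sep = "\t",
                         row.names = FALSE, col.names = TRUE, quote = FALSE)
      close(con)
    }
  }
  truth <- cohort$truth
  truth$spec <- truth$spec[setdiff(names(truth$spec), "duration_map")]
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a subject matrix written by [write_cohort()]
#'
#' @param path TSV path.
#' @return the T x V matrix, with the TR in attribute `"TR"`.
#' @export
read_subject_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  tr <- if (grepl("^# TR:", first)) as.numeric(sub("^# TR:\\s*", "", first)) else NA_real_
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   comment.char = "#"))
  dimnames(m) <- NULL
  attr(m, "TR") <- tr
  m
}

#' Export a cohort's group-average matrices as 4-D NIfTI
#'
#' Arranges the V voxels of each group-averaged matrix into the `TRUE` cells
#' of a supplied 3-D mask and writes one 4-D volume per group.  Requires the
#' RNifti package.
#'
#' @param cohort a `"state_cohort"`.
#' @param dir output directory.
#' @param mask logical 3-D array with exactly `n_vox` `TRUE` cells.
#' @return `dir`, invisibly.
#' @export
write_cohort_nifti <- function(cohort, dir, mask) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("NIfTI export requires the RNifti package.")
  }
  stopifnot(inherits(cohort, "state_cohort"))
  sp <- cohort$truth$spec
  if (sum(mask) != sp$n_vox) abort("`mask` must contain exactly n_vox TRUE voxels.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- which(mask)
  for (g in seq_along(cohort$groups)) {
    avg <- group_average(cohort$groups[[g]]$subjects)
    vol <- array(NA_real_, c(dim(mask), sp$n_tr))
    nxyz <- prod(dim(mask))
    for (t in seq_len(sp$n_tr)) vol[idx + (t - 1L) * nxyz] <- avg[t, ]
    img <- RNifti::asNifti(vol, pixdim = c(1, 1, 1, sp$TR))
    RNifti::writeNifti(img, file.path(dir, sprintf("group%02d.nii.gz", g)))
  }
  invisible(dir)
}
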