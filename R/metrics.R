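#' Consensus perceived-event boundaries from observer keypresses
#'
#' Pools the keypresses of all observers, clusters them by single linkage
#' (a new cluster starts wherever the gap between consecutive pooled presses
#' exceeds `cluster_window_s`), and emits the median time of every cluster
#' endorsed by at least `min_agree` distinct observers.
#'
#' @param presses data frame with columns `observer` and `time_s`, one row per
#'   keypress.
#' @param cluster_window_s single-linkage distance in seconds (default one TR,
#'   2.47 s).
#' @param min_agree minimum number of distinct observers per cluster
#'   (default 5).
#' @return tibble with `onset_s` (cluster median), `n_observers`, `n_presses`,
#'   sorted by onset.
#' @export
consensus_events <- function(presses, cluster_window_s = 2.47, min_agree = 5L) {
  if (!is.data.frame(presses) || !all(c("observer", "time_s") %in% names(presses))) {
    abort("`presses` must be a data frame with columns `observer` and `time_s`.")
  }
  if (nrow(presses) == 0L) {
    return(tibble(onset_s = numeric(0), n_observers = integer(0),
                  n_presses = integer(0)))
  }
  d <- dplyr::arrange(as_tibble(presses), .data$time_s)
  gap <- c(0, diff(d$time_s))
  d$cluster <- cumsum(gap > cluster_window_s)
  out <- d |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(onset_s = median(.data$time_s),
                     n_observers = dplyr::n_distinct(.data$observer),
                     n_presses = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_observers >= min_agree) |>
    dplyr::arrange(.data$onset_s) |>
    dplyr::select(-"cluster")
  out
}

#' Event timeline: onsets plus hemodynamic shift and tolerance window
#'
#' @param onsets_s sorted event onsets in seconds.
#' @param TR repetition time in seconds.
#' @param hrf_shift_s hemodynamic delay added to every onset (default 5 s).
#' @param window_s total width of the tolerance window centred on the shifted
#'   onset (default 1 s, i.e. +/- 0.5 s).
#' @return an object of class `"event_timeline"`.
#' @export
event_timeline <- function(onsets_s, TR, hrf_shift_s = 5, window_s = 1) {
  onsets_s <- sort(as.double(onsets_s))
  if (any(onsets_s < 0)) abort("Event onsets must be nonnegative.")
  structure(list(onsets_s = onsets_s, TR = assert_number(TR, min = 1e-9),
                 hrf_shift_s = assert_number(hrf_shift_s, min = 0),
                 window_s = assert_number(window_s, min = 0)),
            class = "event_timeline")
}

#' Map an event timeline to the set of event TRs
#'
#' Each onset `o` is shifted to `o + hrf_shift_s` and surrounded by a window
#' of total width `window_s`; a TR is an event TR iff its acquisition interval
#' overlaps that window.  TR `i` (1-based) covers `[(i-1) * TR, i * TR)`
#' seconds, so a window endpoint exactly on a TR edge includes both adjacent
#' TRs.  Events whose window starts at or after the end of the stimulus are
#' dropped with a warning.
#'
#' @param tl an [event_timeline()].
#' @param n_tr number of TRs in the stimulus.
#' @return sorted integer vector of event TR indices (1-based).
#' @export
#' @examples
#' tl <- event_timeline(100, TR = 2.47)
#' event_tr_set(tl, 193)  # window [104.5, 105.5] s -> TR 43 ([103.74, 106.21) s)
event_tr_set <- function(tl, n_tr) {
  stopifnot(inherits(tl, "event_timeline"))
  n_tr <- assert_count(n_tr, min = 1L)
  total_s <- n_tr * tl$TR
  trs <- integer(0)
  dropped <- 0L
  for (o in tl$onsets_s) {
    lo <- o + tl$hrf_shift_s - tl$window_s / 2
    hi <- o + tl$hrf_shift_s + tl$window_s / 2
    if (lo >= total_s) {
      dropped <- dropped + 1L
      next
    }
    i_min <- max(1L, as.integer(floor(lo / tl$TR)) + 1L)
    i_max <- min(n_tr, as.integer(floor(hi / tl$TR)) + 1L)
    if (i_max >= i_min) trs <- c(trs, i_min:i_max)
  }
  if (dropped > 0L) {
    warn(sprintf("%d event(s) shifted past the end of the stimulus were dropped.",
                 dropped))
  }
  sort(unique(trs))
}

#' Median state duration in seconds
#'
#' @param starts boundary vector.
#' @param n_tr number of TRs.
#' @param TR repetition time in seconds.
#' @return median of the state lengths (TRs) times `TR`.
#' @export
#' @examples
#' median_duration_s(c(3L, 5L, 7L), 8L, TR = 2.47)  # durations 2,2,2,2 -> 4.94 s
median_duration_s <- function(starts, n_tr, TR) {
  TR <- assert_number(TR, min = 1e-9)
  median(state_durations(starts, n_tr)) * TR
}

#' Nonparametric coefficient of variation of state durations
#'
#' IQR of the state durations divided by their median, both in TRs.  Quartiles
#' use the discontinuous averaging convention (`type = 2` in
#' [stats::quantile()], i.e. the inverse empirical CDF with averaging at
#' discontinuities, matching Tukey's hinges on even-length samples); the
#' convention is fixed so values are reproducible.
#'
#' @inheritParams median_duration_s
#' @return `IQR / median`, dimensionless.
#' @export
duration_cv <- function(starts, n_tr) {
  durs <- state_durations(starts, n_tr)
  if (length(durs) < 2L) abort("`duration_cv` requires at least 2 states.")
  qs <- quantile(durs, c(0.25, 0.75), type = 2, names = FALSE)
  (qs[2] - qs[1]) / median(durs)
}

#' Strength of each neural state boundary
#'
#' One minus the Pearson correlation between the mean activity patterns of the
#' two states flanking each boundary; ranges over (0, 2), with larger values
#' marking more dissimilar consecutive states.
#'
#' @param m T x V activity matrix.
#' @param starts boundary vector (k >= 2 states).
#' @return tibble with `boundary` (index), `tr` (the boundary's state-start
#'   TR) and `strength`.
#' @export
boundary_strength <- function(m, starts) {
  Z <- zscore_rows(m)
  starts <- validate_starts(starts, nrow(Z))
  if (length(starts) == 0L) abort("`boundary_strength` requires at least 2 states.")
  pat <- state_mean_patterns(m, starts)
  sds <- apply(pat, 1L, sd)
  strength <- numeric(length(starts))
  for (j in seq_along(starts)) {
    if (sds[j] == 0 || sds[j + 1L] == 0) {
      abort(sprintf("Boundary %d (TR %d): a flanking state has a constant mean pattern; correlation undefined.",
                    j, starts[j]))
    }
    strength[j] <- 1 - cor(pat[j, ], pat[j + 1L, ])
  }
  tibble(boundary = seq_along(starts), tr = starts, strength = strength)
}

#' Mean within-state timepoint correlation
#'
#' Average Pearson correlation over all pairs of TRs that fall inside the same
#' state.
#'
#' @inheritParams boundary_strength
#' @return a single number.
#' @export
within_state_correlation <- function(m, starts) {
  Z <- zscore_rows(m)
  starts <- validate_starts(starts, nrow(Z))
  pr <- tdistance_pairs(starts, nrow(Z))
  if (is.null(pr$within)) {
    abort("All states are single TRs: no within-state pairs.")
  }
  C <- tcrossprod(Z) / (ncol(Z) - 1)
  mean(C[pr$within])
}

#' Inter-subject synchrony (ISS) of one subject against a group
#'
#' For every voxel, the Pearson correlation between the subject's time course
#' and the voxel-wise mean time course of the other subjects, averaged over
#' voxels.  Voxels with a constant time course on either side are skipped with
#' a warning.
#'
#' @param subject T x V matrix.
#' @param others nonempty list of T x V matrices (the rest of the group).
#' @return mean correlation, a single number.
#' @export
iss <- function(subject, others) {
  if (!is.list(others) || length(others) == 0L) {
    abort("`others` must be a nonempty list of matrices.")
  }
  if (!all(vapply(others, function(o) identical(dim(o), dim(subject)), logical(1)))) {
    abort("All matrices must share the subject's dimensions.")
  }
  mo <- Reduce(`+`, others) / length(others)
  vals <- numeric(ncol(subject))
  skip <- logical(ncol(subject))
  for (v in seq_len(ncol(subject))) {
    if (sd(subject[, v]) == 0 || sd(mo[, v]) == 0) {
      skip[v] <- TRUE
    } else {
      vals[v] <- cor(subject[, v], mo[, v])
    }
  }
  if (any(skip)) {
    warn(sprintf("%d voxel(s) with constant time courses skipped in ISS.", sum(skip)))
  }
  if (all(skip)) abort("ISS undefined: every voxel has a constant time course.")
  mean(vals[!skip])
}

#' Mean ISS of a whole group
#'
#' Leave-one-out [iss()] for each subject against the rest of the group,
#' averaged.
#'
#' @param subjects list of T x V matrices (>= 2).
#' @return mean ISS, a single number.
#' @export
group_iss <- function(subjects) {
  if (length(subjects) < 2L) abort("`group_iss` needs at least 2 subjects.")
  mean(vapply(seq_along(subjects), function(i) {
    iss(subjects[[i]], subjects[-i])
  }, numeric(1)))
}

#' Chance-corrected absolute overlap from counts
#'
#' Core arithmetic of the absolute-overlap statistic: with `n_state_bounds`
#' neural state boundaries, `n_event_trs` event TRs and `n_tr` timepoints, the
#' expected overlap under independence is
#' `n_state_bounds * n_event_trs / n_tr`, and the absolute overlap rescales
#' the observed count so that chance maps to 0 and complete overlap of all
#' state boundaries maps to 1:
#' `(observed - expected) / (n_state_bounds - expected)`.
#'
#' @param n_state_bounds number of neural state boundaries (>= 1).
#' @param n_event_trs number of event TRs.
#' @param n_tr number of timepoints.
#' @param observed number of state boundaries on event TRs.
#' @return one-row tibble with `n_state_bounds`, `n_event_trs`, `n_tr`,
#'   `observed`, `expected`, `absolute`.
#' @export
#' @examples
#' overlap_stat(20, 10, 100, 8)  # expected 2, absolute (8 - 2)/18
overlap_stat <- function(n_state_bounds, n_event_trs, n_tr, observed) {
  n_state_bounds <- assert_count(n_state_bounds, min = 1L)
  n_event_trs <- assert_count(n_event_trs, min = 0L)
  n_tr <- assert_count(n_tr, min = 1L)
  observed <- assert_count(observed, min = 0L)
  expected <- n_state_bounds * n_event_trs / n_tr
  denom <- n_state_bounds - expected
  if (abs(denom) < 1e-12) {
    abort("Absolute overlap undefined: expected overlap equals the number of state boundaries.")
  }
  tibble(n_state_bounds = n_state_bounds, n_event_trs = n_event_trs,
         n_tr = n_tr, observed = observed, expected = expected,
         absolute = (observed - expected) / denom)
}

#' Absolute overlap between state boundaries and event TRs
#'
#' Counts how many state-boundary TRs fall in the event-TR set and rescales
#' via [overlap_stat()].
#'
#' @param starts boundary vector.
#' @param event_trs sorted event TR indices (1-based), e.g. from
#'   [event_tr_set()].
#' @param n_tr number of timepoints.
#' @return one-row tibble as in [overlap_stat()].
#' @export
absolute_overlap <- function(starts, event_trs, n_tr) {
  n_tr <- assert_count(n_tr, min = 1L)
  starts <- validate_starts(starts, n_tr)
  if (length(starts) == 0L) abort("Absolute overlap requires at least one state boundary.")
  observed <- length(intersect(starts, as.integer(event_trs)))
  overlap_stat(length(starts), length(unique(as.integer(event_trs))), n_tr, observed)
}

#' Boundary occurrence on versus off event TRs
#'
#' For each group's boundary vector: the fraction of event TRs that are state
#' boundaries (`on_event`) and the fraction of non-event TRs that are state
#' boundaries (`off_event`).
#'
#' @param boundaries_per_group list of boundary vectors sharing `n_tr`.
#' @param event_trs event TR indices (nonempty).
#' @param n_tr number of timepoints.
#' @return tibble with `group`, `on_event`, `off_event`.
#' @export
boundary_occurrence_split <- function(boundaries_per_group, event_trs, n_tr) {
  n_tr <- assert_count(n_tr, min = 1L)
  event_trs <- unique(as.integer(event_trs))
  if (length(event_trs) == 0L) {
    abort("Empty event-TR set: on-event occurrence undefined.")
  }
  off_trs <- setdiff(seq_len(n_tr), event_trs)
  if (length(off_trs) == 0L) {
    warn("Every TR is an event TR; off-event occurrence is NA.")
  }
  purrr::map_dfr(seq_along(boundaries_per_group), function(g) {
    b <- validate_starts(boundaries_per_group[[g]], n_tr)
    tibble(
      group = g,
      on_event = length(intersect(b, event_trs)) / length(event_trs),
      off_event = if (length(off_trs) == 0L) NA_real_ else
        length(intersect(b, off_trs)) / length(off_trs)
    )
  })
}
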