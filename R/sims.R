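#' Add graded Gaussian noise scaled to each voxel's signal SD
#'
#' Adds i.i.d. Normal noise per voxel per TR with standard deviation
#' `level` times that voxel's observed (pre-z-scoring) signal SD.
#' `level = 0` returns the input unchanged.
#'
#' @param m T x V activity matrix.
#' @param level noise SD as a fraction of each voxel's signal SD (the study's
#'   conditions use 0.05, 0.50 and 1.00).
#' @param seed integer RNG seed.
#' @return a T x V matrix.
#' @export
add_noise <- function(m, level, seed = 1L) {
  m <- as_timepoint_matrix(m)
  level <- assert_number(level, min = 0)
  if (level == 0) return(m)
  sds <- apply(m, 2L, sd)
  with_seed(seed, {
    noise <- matrix(rnorm(length(m)), nrow(m), ncol(m))
    m + sweep(noise, 2L, level * sds, `*`)
  })
}

#' Average a time series with a delayed copy of itself
#'
#' Emulates half the subjects carrying each state boundary `shift` TRs later:
#' output row `t` is the mean of rows `t` and `t - shift` of the original,
#' evaluated on the interior window after trimming `trim` TRs from both ends.
#' The output has `nrow(m) - 2 * trim` rows.
#'
#' @param m T x V activity matrix.
#' @param shift delay in TRs (1 or 2 in the study's conditions; 0 is the
#'   identity on the interior window).
#' @param trim TRs removed from each end (default 2); requires
#'   `T > 2 * trim + shift`.
#' @return the averaged, trimmed matrix.
#' @export
shift_average <- function(m, shift, trim = 2L) {
  m <- as_timepoint_matrix(m)
  shift <- assert_count(shift, min = 0L)
  trim <- assert_count(trim, min = 0L)
  n_tr <- nrow(m)
  if (n_tr <= 2L * trim + shift) {
    abort("`m` must have more than 2 * trim + shift rows.")
  }
  rows <- (trim + 1L):(n_tr - trim)
  (m[rows, , drop = FALSE] + m[rows - shift, , drop = FALSE]) / 2
}

#' Trim a matrix's ends (the baseline for shift simulations)
#'
#' @inheritParams shift_average
#' @return `m` without its first and last `trim` rows.
#' @export
trim_ends <- function(m, trim = 2L) {
  m <- as_timepoint_matrix(m)
  trim <- assert_count(trim, min = 0L)
  if (nrow(m) <= 2L * trim) abort("`m` must have more than 2 * trim rows.")
  m[(trim + 1L):(nrow(m) - trim), , drop = FALSE]
}

sim_segment_row <- function(m, k_max, ...) {
  tryCatch({
    fit <- gsbs(m, k_max = k_max, ...)
    b <- fit$optimal
    C <- tcrossprod(zscore_rows(m)) / (ncol(m) - 1)
    pr <- tdistance_pairs(b, nrow(m))
    tibble(optimal_k = fit$optimal_k,
           mean_within = if (is.null(pr$within)) NA_real_ else mean(C[pr$within]),
           mean_between = mean(C[pr$between]),
           error = NA_character_)
  }, error = function(e) {
    tibble(optimal_k = NA_integer_, mean_within = NA_real_,
           mean_between = NA_real_, error = conditionMessage(e))
  })
}

#' Noise-injection simulation
#'
#' For each noise level and repetition, adds voxel-scaled noise
#' ([add_noise()]), re-runs [gsbs()], and records the estimated number of
#' states together with the mean within/between-state timepoint correlations
#' at the estimated boundaries.  Lets users check whether the number of states
#' decreases systematically with noise.
#'
#' @param m T x V activity matrix (typically a group average).
#' @param levels noise levels as fractions of per-voxel signal SD.
#' @param reps repetitions per level (default 100).
#' @param k_max passed to [gsbs()].
#' @param seed master seed; per-repetition seeds are derived from it.
#' @param ... further arguments to [gsbs()].
#' @return object of class `"noise_sim"`: list with `results` (tibble:
#'   `level`, `rep`, `optimal_k`, `mean_within`, `mean_between`, `error`),
#'   `baseline_k`, `reps`.
#' @export
run_noise_sim <- function(m, levels = c(0.05, 0.50, 1.00), reps = 100L,
                          k_max = NULL, seed = 1L, ...) {
  m <- as_timepoint_matrix(m)
  reps <- assert_count(reps, min = 0L)
  baseline_k <- gsbs(m, k_max = k_max, ...)$optimal_k
  rows <- list()
  if (reps > 0L) {
    for (li in seq_along(levels)) {
      for (r in seq_len(reps)) {
        noisy <- add_noise(m, levels[li], seed = derive_seed(seed, li, r))
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble(level = levels[li], rep = r),
          sim_segment_row(noisy, k_max, ...)
        )
      }
    }
  }
  res <- if (length(rows) == 0L) {
    tibble(level = numeric(0), rep = integer(0), optimal_k = integer(0),
           mean_within = numeric(0), mean_between = numeric(0),
           error = character(0))
  } else dplyr::bind_rows(rows)
  structure(list(results = res, baseline_k = baseline_k, reps = reps,
                 levels = levels),
            class = c("noise_sim", "state_sim"))
}

#' Boundary-shift simulation
#'
#' For each shift, averages the data with a copy of itself delayed by `shift`
#' TRs ([shift_average()]), re-runs [gsbs()], and compares the estimated
#' number of states to a baseline computed on the trimmed (same-length)
#' original — removing the length confound.
#'
#' @inheritParams run_noise_sim
#' @param shifts delays in TRs (default 1 and 2).
#' @param trim TRs trimmed from both ends (default 2).
#' @return object of class `"shift_sim"`: list with `results` (tibble:
#'   `shift`, `optimal_k`, `mean_within`, `mean_between`, `error`) and
#'   `baseline_k` (on the trimmed original).
#' @export
run_shift_sim <- function(m, shifts = c(1L, 2L), trim = 2L, k_max = NULL, ...) {
  m <- as_timepoint_matrix(m)
  baseline <- trim_ends(m, trim)
  baseline_k <- gsbs(baseline, k_max = k_max, ...)$optimal_k
  rows <- lapply(shifts, function(s) {
    shifted <- shift_average(m, s, trim = trim)
    dplyr::bind_cols(tibble(shift = as.integer(s)),
                     sim_segment_row(shifted, k_max, ...))
  })
  structure(list(results = dplyr::bind_rows(rows), baseline_k = baseline_k,
                 trim = trim),
            class = c("shift_sim", "state_sim"))
}

#' @export
print.state_sim <- function(x, ...) {
  lab <- if (inherits(x, "noise_sim")) "noise" else "shift"
  cat(sprintf("<%s_sim> baseline k = %d; %d result row(s)\n",
              lab, x$baseline_k, nrow(x$results)))
  invisible(x)
}

#' Tidy a simulation report
#'
#' @param x a `"noise_sim"` or `"shift_sim"`.
#' @param ... unused.
#' @return the per-repetition results tibble with `baseline_k` attached as a
#'   column.
#' @export
tidy.state_sim <- function(x, ...) {
  dplyr::mutate(x$results, baseline_k = x$baseline_k)
}

#' Summarise a simulation report per condition
#'
#' @inheritParams tidy.state_sim
#' @return tibble with one row per condition: median/mean/range of the
#'   estimated k, failure count, and the baseline k.
#' @export
glance.state_sim <- function(x, ...) {
  cond <- if (inherits(x, "noise_sim")) "level" else "shift"
  x$results |>
    dplyr::group_by(condition = .data[[cond]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_failed = sum(!is.na(.data$error)),
      median_k = median(.data$optimal_k, na.rm = TRUE),
      mean_k = mean(.data$optimal_k, na.rm = TRUE),
      min_k = suppressWarnings(min(.data$optimal_k, na.rm = TRUE)),
      max_k = suppressWarnings(max(.data$optimal_k, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::mutate(baseline_k = x$baseline_k)
}

#' Plot the distribution of estimated state counts per condition
#'
#' @param object a `"noise_sim"` or `"shift_sim"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.state_sim <- function(object, ...) {
  cond <- if (inherits(object, "noise_sim")) "level" else "shift"
  d <- tidy.state_sim(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data[[cond]]), y = .data$optimal_k)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = object$baseline_k, linetype = 2) +
    ggplot2::labs(x = cond, y = "estimated number of states",
                  title = "Perturbation simulation") +
    ggplot2::theme_minimal()
}

#' Write a simulation report to disk
#'
#' JSON summary plus a TSV of per-repetition state counts.
#'
#' @param x a `"noise_sim"` or `"shift_sim"`.
#' @param dir output directory.
#' @param name file stem (default from the class).
#' @return `dir`, invisibly.
#' @export
write_sim_report <- function(x, dir, name = NULL) {
  stopifnot(inherits(x, "state_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(name)) name <- if (inherits(x, "noise_sim")) "noise_sim" else "shift_sim"
  readr::write_tsv(tidy.state_sim(x), file.path(dir, paste0(name, ".tsv")))
  jsonlite::write_json(
    list(baseline_k = x$baseline_k, summary = glance.state_sim(x)),
    file.path(dir, paste0(name, ".json")), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
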