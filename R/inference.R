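#' Assign subjects to contiguous age groups
#'
#' Sorts subjects by age (ties kept adjacent, stable order) and slices
#' consecutive blocks of `group_size`; when `n_groups * group_size` exceeds
#' the number of subjects, the last blocks shrink by one subject each until
#' everyone is consumed.
#'
#' @param ages numeric vector of ages in years (length >= `n_groups`).
#' @param n_groups number of groups (default 34).
#' @param group_size nominal subjects per group (default 17).
#' @return tibble with `subject` (original index), `age`, `group` (1-based,
#'   youngest first), plus `median_age` of the subject's group.
#' @export
#' @examples
#' assign_age_groups(seq(18, 88, length.out = 577), 34, 17) |>
#'   dplyr::count(group)
assign_age_groups <- function(ages, n_groups = 34L, group_size = 17L) {
  n_groups <- assert_count(n_groups, min = 1L)
  group_size <- assert_count(group_size, min = 1L)
  n <- length(ages)
  if (n < n_groups) abort("Need at least one subject per group.")
  if (n > n_groups * group_size) {
    abort("More subjects than `n_groups * group_size` can hold.")
  }
  sizes <- rep(group_size, n_groups)
  deficit <- n_groups * group_size - n
  i <- n_groups
  while (deficit > 0L) {
    if (sizes[i] > 1L) {
      sizes[i] <- sizes[i] - 1L
      deficit <- deficit - 1L
    }
    i <- if (i == 1L) n_groups else i - 1L
  }
  ord <- order(ages)  # stable: ties keep original adjacency
  grp_sorted <- rep(seq_len(n_groups), times = sizes)
  out <- tibble(subject = ord, age = ages[ord], group = grp_sorted) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(median_age = median(.data$age)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$subject)
  out
}

rank_mid <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation with t-approximation p value
#'
#' Mid-rank transform of both vectors followed by a Pearson correlation; the
#' p value uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`
#' with `n - 2` degrees of freedom, two-sided.
#'
#' @param x,y numeric vectors, length >= 4; ties allowed.
#' @return one-row tibble with `estimate` (rho), `statistic` (t), `p.value`,
#'   `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n < 4L || length(y) != n) abort("`x` and `y` must share length >= 4.")
  if (sd(x) == 0 || sd(y) == 0) abort("Spearman correlation undefined for a constant vector.")
  rho <- cor(rank_mid(x), rank_mid(y))
  if (abs(rho) >= 1) {
    tstat <- sign(rho) * Inf
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(estimate = rho, statistic = tstat, p.value = p, n = n,
         method = "spearman (t approximation)")
}

#' Partial Spearman correlation controlling for one covariate
#'
#' All three vectors are mid-rank transformed; the partial Pearson correlation
#' of the ranks is `(r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))`,
#' with a two-sided t-approximation p value on `n - 3` degrees of freedom.
#'
#' @param x,y numeric vectors of interest, length >= 5.
#' @param z covariate to control for.
#' @return one-row tibble as in [spearman_cor()].
#' @export
partial_spearman_cor <- function(x, y, z) {
  n <- length(x)
  if (n < 5L || length(y) != n || length(z) != n) {
    abort("`x`, `y`, `z` must share length >= 5.")
  }
  if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0) {
    abort("Partial Spearman correlation undefined for a constant vector.")
  }
  rx <- rank_mid(x); ry <- rank_mid(y); rz <- rank_mid(z)
  r_xy <- cor(rx, ry); r_xz <- cor(rx, rz); r_yz <- cor(ry, rz)
  den <- sqrt((1 - r_xz^2) * (1 - r_yz^2))
  num <- r_xy - r_xz * r_yz
  if (den < 1e-12) {
    # a variable rank-collinear with the covariate: no variance left to share
    if (abs(num) < 1e-12) {
      num <- 0
      den <- 1
    } else {
      abort("Partial correlation undefined: a variable is (rank-)collinear with the covariate.")
    }
  }
  rho <- num / den
  rho <- max(-1, min(1, rho))
  if (abs(rho) >= 1) {
    tstat <- sign(rho) * Inf
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 3) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 3)
  }
  tibble(estimate = rho, statistic = tstat, p.value = p, n = n,
         method = "partial spearman (t approximation)")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values (monotone enforced) with a significance mask at
#' level `q`.
#'
#' @param p vector of p values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return tibble with `p`, `q_value`, `significant`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p values must lie in [0, 1].")
  }
  adj <- p.adjust(p, method = "BH")
  tibble(p = p, q_value = adj, significant = adj < q)
}

#' Test whether per-group overlap differs from zero
#'
#' One-sample Wilcoxon signed-rank test of the values against zero,
#' two-sided.  Exact null distribution when n <= 25 with no zeros or tied
#' absolute values, normal approximation (with continuity correction)
#' otherwise.  All-zero input returns p = 1 with a warning.
#'
#' @param x numeric vector of per-group overlap values, length >= 5.
#' @return the two-sided p value.
#' @export
overlap_vs_zero_test <- function(x) {
  if (length(x) < 5L) abort("Need at least 5 groups.")
  nz <- x[x != 0]
  if (length(nz) == 0L) {
    warn("All overlap values are exactly zero; p = 1 by convention.")
    return(1)
  }
  use_exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
  res <- suppressWarnings(
    wilcox.test(nz, mu = 0, alternative = "two.sided",
                exact = use_exact, correct = !use_exact)
  )
  unname(res$p.value)
}

#' Per-searchlight age-effect map
#'
#' For each searchlight, the Spearman correlation between group age and a
#' metric across age groups, with BH-FDR correction across searchlights.
#'
#' @param data tibble with one row per (searchlight, group).
#' @param metric name of the metric column (string).
#' @param age name of the age column (default `"age"`).
#' @param searchlight name of the searchlight id column (default
#'   `"searchlight"`).
#' @param covariate optional column name; when given, a partial Spearman
#'   correlation controlling for it is computed instead.
#' @param q FDR level (default 0.05).
#' @return tibble with `searchlight`, `rho`, `p`, `q_value`, `significant`.
#' @export
age_effect_map <- function(data, metric, age = "age",
                           searchlight = "searchlight", covariate = NULL,
                           q = 0.05) {
  need <- c(metric, age, searchlight, covariate)
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` must contain columns: %s.", paste(need, collapse = ", ")))
  }
  per_sl <- data |>
    dplyr::group_by(sl = .data[[searchlight]]) |>
    dplyr::summarise(res = list(
      if (is.null(covariate)) {
        spearman_cor(.data[[age]], .data[[metric]])
      } else {
        partial_spearman_cor(.data[[age]], .data[[metric]], .data[[covariate]])
      }
    ), .groups = "drop") |>
    tidyr::unnest("res")
  adj <- fdr_bh(per_sl$p.value, q = q)
  tibble(searchlight = per_sl$sl, rho = per_sl$estimate, p = per_sl$p.value,
         q_value = adj$q_value, significant = adj$significant)
}

#' Youngest-versus-oldest contrast over significant searchlights
#'
#' Summarises the differences `old - young` restricted to the searchlights
#' flagged significant.
#'
#' @param metric_young,metric_old aligned numeric vectors, one value per
#'   searchlight.
#' @param significant logical mask of the same length.
#' @return one-row tibble with `mean_difference`, `sd`, `min`, `max`,
#'   `pct_positive`, `n`.
#' @export
youngest_oldest_contrast <- function(metric_young, metric_old, significant) {
  n <- length(metric_young)
  if (length(metric_old) != n || length(significant) != n) {
    abort("Inputs must be aligned vectors of equal length.")
  }
  if (!any(significant)) abort("No significant searchlights to contrast.")
  d <- (metric_old - metric_young)[significant]
  tibble(mean_difference = mean(d), sd = sd(d), min = min(d), max = max(d),
         pct_positive = 100 * mean(d > 0), n = length(d))
}
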