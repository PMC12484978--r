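#' Z-score each timepoint (row) of an activity matrix
#'
#' Rescales every row to mean 0 and unit sample standard deviation, so that
#' the Pearson correlation between any two rows equals their dot product
#' divided by `V - 1`.  All segmentation internals rely on this form.
#'
#' @param m numeric T x V matrix (rows = TRs, columns = voxels).
#' @return matrix of the same shape with z-scored rows.
#' @export
#' @examples
#' zscore_rows(matrix(1:6, 2, 3, byrow = TRUE))
zscore_rows <- function(m) {
  m <- as_timepoint_matrix(m)
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  bad <- which(s == 0)
  if (length(bad) > 0) {
    abort(sprintf("Row(s) %s are constant and cannot be z-scored (TR index %s).",
                  paste(bad, collapse = ", "), paste(bad, collapse = ", ")))
  }
  (m - mu) / s
}

as_timepoint_matrix <- function(m) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.matrix(m) || !is.numeric(m)) abort("`m` must be a numeric matrix.")
  if (anyNA(m)) abort("`m` must not contain missing values.")
  if (ncol(m) < 2L) abort("`m` must have at least 2 voxels (columns).")
  m
}

# Row-cumulative-sum prefix with a leading zero row: colMeans of rows a..b is
# (P[b + 1, ] - P[a, ]) / (b - a + 1).
row_prefix <- function(Z) {
  rbind(0, apply(Z, 2L, cumsum))
}

# Sum over TRs a..b of the correlation between each (z-scored) row and the
# state-mean pattern of rows a..b.  For unit-SD zero-mean rows this collapses
# to (b - a + 1) * sd(colMeans(rows)); a constant mean pattern contributes 0.
contrib_prefix <- function(P, a, b, V) {
  L <- b - a + 1
  m <- (P[b + 1L, ] - P[a, ]) / L
  ss <- sum(m * m) - V * mean(m)^2
  if (ss < 0) ss <- 0
  L * sqrt(ss / (V - 1))
}

state_contribs <- function(P, starts, n_tr, V) {
  bounds <- c(1L, starts, n_tr + 1L)
  k <- length(bounds) - 1L
  out <- numeric(k)
  for (s in seq_len(k)) {
    out[s] <- contrib_prefix(P, bounds[s], bounds[s + 1L] - 1L, V)
  }
  out
}

#' Mean activity pattern of each state
#'
#' @param m numeric T x V matrix.
#' @param starts boundary vector (first TR of each new state, 1-based).
#' @return k x V matrix; row i is the mean of the z-scored rows of state i.
#' @export
state_mean_patterns <- function(m, starts) {
  Z <- zscore_rows(m)
  starts <- validate_starts(starts, nrow(Z))
  g <- state_labels(nrow(Z), starts)
  rowsum(Z, g) / as.vector(table(g))
}

#' Within-state fit of a segmentation
#'
#' Mean, over all TRs, of the Pearson correlation between each z-scored TR
#' pattern and the mean pattern of the state it belongs to.  Singleton states
#' contribute correlation 1; a state whose mean pattern is constant
#' contributes 0.
#'
#' @inheritParams state_mean_patterns
#' @return a single number in `[-1, 1]` (in practice `[0, 1]`).
#' @export
fit_score <- function(m, starts) {
  Z <- zscore_rows(m)
  starts <- validate_starts(starts, nrow(Z))
  P <- row_prefix(Z)
  sum(state_contribs(P, starts, nrow(Z), ncol(Z))) / nrow(Z)
}

# Index pairs (i, j), i < j, within the same state, and pairs spanning exactly
# adjacent states, as two 2-column matrices.
tdistance_pairs <- function(starts, n_tr) {
  bounds <- c(1L, starts, n_tr + 1L)
  k <- length(bounds) - 1L
  within <- list(); between <- list()
  for (s in seq_len(k)) {
    a <- bounds[s]; b <- bounds[s + 1L] - 1L
    if (b > a) {
      idx <- a:b
      cmb <- utils::combn(idx, 2L)
      within[[length(within) + 1L]] <- t(cmb)
    }
    if (s < k) {
      a2 <- bounds[s + 1L]; b2 <- bounds[s + 2L] - 1L
      between[[length(between) + 1L]] <-
        cbind(rep(a:b, each = b2 - a2 + 1L), rep(a2:b2, times = b - a + 1L))
    }
  }
  list(within = do.call(rbind, within), between = do.call(rbind, between))
}

tdistance_from_cor <- function(C, starts, n_tr, var.equal = TRUE) {
  if (length(starts) == 0L) {
    abort("t-distance requires at least 2 states.")
  }
  pr <- tdistance_pairs(starts, n_tr)
  if (is.null(pr$within)) {
    abort("t-distance is undefined: every state is a single TR (no within-state pairs).")
  }
  w <- C[pr$within]
  b <- C[pr$between]
  nw <- length(w); nb <- length(b)
  if (nw + nb < 3L) abort("t-distance is undefined: too few TR pairs.")
  mw <- mean(w); mb <- mean(b)
  if (var.equal) {
    sp2 <- (sum((w - mw)^2) + sum((b - mb)^2)) / (nw + nb - 2)
    (mw - mb) / sqrt(sp2 * (1 / nw + 1 / nb))
  } else {
    vw <- if (nw > 1) sum((w - mw)^2) / (nw - 1) else 0
    vb <- if (nb > 1) sum((b - mb)^2) / (nb - 1) else 0
    (mw - mb) / sqrt(vw / nw + vb / nb)
  }
}

#' t-distance of a segmentation
#'
#' Two-sample t statistic contrasting the Pearson correlations of all TR pairs
#' that fall inside the same state against the correlations of all TR pairs
#' spanning exactly adjacent states.  Large positive values indicate coherent
#' states separated by distinct boundaries; the statistic peaks at the
#' best-supported number of states and drives model selection in [gsbs()].
#'
#' @inheritParams state_mean_patterns
#' @param var.equal use the pooled-variance form (default); `FALSE` gives the
#'   Welch form.
#' @return the t statistic (may be `Inf` on noiseless data).
#' @export
tdistance <- function(m, starts, var.equal = TRUE) {
  Z <- zscore_rows(m)
  starts <- validate_starts(starts, nrow(Z))
  C <- tcrossprod(Z) / (ncol(Z) - 1)
  tdistance_from_cor(C, starts, nrow(Z), var.equal = var.equal)
}

# One greedy addition on a pre-z-scored matrix with prefix sums.  Returns the
# augmented boundary vector; ties broken by the earliest TR.
greedy_step_core <- function(Z, P, starts, criterion = "fit",
                             C = NULL, var.equal = TRUE) {
  n_tr <- nrow(Z); V <- ncol(Z)
  if (length(starts) + 1L >= n_tr) {
    abort("No candidate boundaries left: every TR already starts a state.")
  }
  bounds <- c(1L, starts, n_tr + 1L)
  k <- length(bounds) - 1L
  if (criterion == "fit") {
    contribs <- state_contribs(P, starts, n_tr, V)
    base <- sum(contribs)
    best_val <- -Inf; best_c <- NA_integer_
    for (s in seq_len(k)) {
      a <- bounds[s]; b <- bounds[s + 1L] - 1L
      if (b == a) next
      for (cc in (a + 1L):b) {
        val <- base - contribs[s] +
          contrib_prefix(P, a, cc - 1L, V) + contrib_prefix(P, cc, b, V)
        if (val > best_val + 1e-12) {
          best_val <- val; best_c <- cc
        }
      }
    }
    sort(c(starts, best_c))
  } else if (criterion == "tdistance") {
    cand <- setdiff(2:n_tr, starts)
    best_val <- -Inf; best_c <- NA_integer_
    for (cc in cand) {
      val <- tryCatch(
        tdistance_from_cor(C, sort(c(starts, cc)), n_tr, var.equal = var.equal),
        error = function(e) NA_real_
      )
      if (!is.na(val) && val > best_val + 1e-12) {
        best_val <- val; best_c <- cc
      }
    }
    if (is.na(best_c)) abort("t-distance undefined for every candidate boundary.")
    sort(c(starts, best_c))
  } else {
    abort("`criterion` must be \"fit\" or \"tdistance\".")
  }
}

#' Add one state boundary greedily
#'
#' Places the single new boundary (at any TR that is not already a state
#' start) that maximises the within-state fit ([fit_score()]); ties are broken
#' by the earliest TR.
#'
#' @inheritParams state_mean_patterns
#' @param criterion objective for the greedy choice: `"fit"` (default) or
#'   `"tdistance"`.
#' @return the augmented boundary vector.
#' @export
greedy_step <- function(m, starts = integer(0), criterion = c("fit", "tdistance")) {
  criterion <- match.arg(criterion)
  Z <- zscore_rows(m)
  starts <- validate_starts(starts, nrow(Z))
  C <- if (criterion == "tdistance") tcrossprod(Z) / (ncol(Z) - 1) else NULL
  greedy_step_core(Z, row_prefix(Z), starts, criterion, C = C)
}

finetune_core <- function(Z, P, starts, window = 1L, max_passes = 10L) {
  n_tr <- nrow(Z); V <- ncol(Z)
  if (length(starts) == 0L || window == 0L) return(starts)
  for (pass in seq_len(max_passes)) {
    moved <- FALSE
    nb <- length(starts)
    for (j in seq_len(nb)) {
      cur <- starts[j]
      prev <- if (j == 1L) 1L else starts[j - 1L]
      nxt <- if (j == nb) n_tr + 1L else starts[j + 1L]
      lo <- max(prev + 1L, cur - window)
      hi <- min(nxt - 1L, cur + window)
      # only the two flanking states change when boundary j moves
      base_two <- contrib_prefix(P, prev, cur - 1L, V) +
        contrib_prefix(P, cur, nxt - 1L, V)
      best_p <- cur; best_val <- base_two
      for (p in lo:hi) {
        if (p == cur) next
        val <- contrib_prefix(P, prev, p - 1L, V) +
          contrib_prefix(P, p, nxt - 1L, V)
        # strict improvement only; scanning lo..hi makes ties resolve to the
        # earliest improving TR
        if (val > best_val + 1e-12) {
          best_val <- val; best_p <- p
        }
      }
      if (best_p != cur) {
        starts[j] <- best_p
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  starts
}

#' Locally refine boundary locations
#'
#' Each boundary in turn may move to any position within `window` TRs
#' (staying strictly between its neighbouring boundaries) if doing so strictly
#' increases the within-state fit; passes repeat until no boundary moves (at
#' most `max_passes`).  The number of states never changes and the fit never
#' decreases.
#'
#' @inheritParams state_mean_patterns
#' @param window maximum displacement per move, in TRs.
#' @param max_passes upper bound on refinement sweeps.
#' @return the refined boundary vector.
#' @export
finetune <- function(m, starts, window = 1L, max_passes = 10L) {
  Z <- zscore_rows(m)
  starts <- validate_starts(starts, nrow(Z))
  window <- assert_count(window, min = 0L)
  finetune_core(Z, row_prefix(Z), starts, window, assert_count(max_passes))
}

gsbs_engine <- function(Z, k_max, finetune_window, criterion, var.equal) {
  n_tr <- nrow(Z); V <- ncol(Z)
  P <- row_prefix(Z)
  C <- tcrossprod(Z) / (V - 1)
  boundaries <- vector("list", k_max)
  tdist <- rep(NA_real_, k_max)
  fit <- rep(NA_real_, k_max)
  starts <- integer(0)
  fit[1] <- sum(state_contribs(P, starts, n_tr, V)) / n_tr
  for (k in 2:k_max) {
    starts <- greedy_step_core(Z, P, starts, criterion, C = C,
                               var.equal = var.equal)
    starts <- finetune_core(Z, P, starts, window = finetune_window)
    boundaries[[k]] <- starts
    fit[k] <- sum(state_contribs(P, starts, n_tr, V)) / n_tr
    tdist[k] <- tryCatch(
      tdistance_from_cor(C, starts, n_tr, var.equal = var.equal),
      error = function(e) {
        warn(sprintf("t-distance undefined at k = %d; skipped (%s)",
                     k, conditionMessage(e)))
        NA_real_
      }
    )
  }
  list(boundaries = boundaries, tdistance = tdist, fit = fit)
}

#' Greedy State Boundary Search (GSBS)
#'
#' Segments a timepoint-by-voxel activity matrix into neural states: starting
#' from a single state, one boundary is added per iteration at the TR that
#' maximises the within-state fit, followed by local finetuning of all
#' boundary locations.  At each number of states k the t-distance
#' ([tdistance()]) is recorded; the optimal k is the one maximising it (ties
#' resolved toward the smallest k).  The procedure is fully deterministic.
#'
#' @param m numeric T x V matrix (rows = TRs in acquisition order).
#' @param k_max largest number of states considered; defaults to `floor(T/2)`
#'   so states average at least 2 TRs.
#' @param finetune_window displacement window for [finetune()] (TRs);
#'   0 disables finetuning.
#' @param criterion greedy objective, `"fit"` (default) or `"tdistance"`.
#' @param var.equal pooled-variance t-distance (default) or Welch.
#' @param TR repetition time in seconds, carried as metadata.
#' @return an object of class `"gsbs"`: a list with `boundaries_per_k`
#'   (boundary vector for each k), `tdistance_per_k`, `fit_per_k`,
#'   `optimal_k`, `optimal` (its boundary vector), `n_tr`, `n_vox`, `TR`, and
#'   the call parameters.  Use [tidy.gsbs()], [glance.gsbs()],
#'   [autoplot.gsbs()].
#' @seealso [gsbs_fixed_k()] for segmentation at a preset number of states.
#' @export
#' @examples
#' m <- planted_states_matrix(n_tr = 30, n_vox = 12, starts = c(11L, 21L),
#'                            noise_sd = 0.1, seed = 1)
#' fit <- gsbs(m, k_max = 8)
#' fit$optimal_k
gsbs <- function(m, k_max = NULL, finetune_window = 1L,
                 criterion = c("fit", "tdistance"), var.equal = TRUE,
                 TR = NA_real_) {
  criterion <- match.arg(criterion)
  Z <- zscore_rows(m)
  n_tr <- nrow(Z)
  if (n_tr < 4L) abort("`m` must have at least 4 TRs.")
  if (is.null(k_max)) k_max <- n_tr %/% 2L
  k_max <- assert_count(k_max, min = 2L)
  if (k_max > n_tr) abort("`k_max` cannot exceed the number of TRs.")
  finetune_window <- assert_count(finetune_window, min = 0L)

  res <- gsbs_engine(Z, k_max, finetune_window, criterion, var.equal)
  td <- res$tdistance
  if (all(is.na(td))) abort("t-distance undefined at every k; cannot select a model.")
  optimal_k <- which(td == max(td, na.rm = TRUE))[1]

  structure(list(
    boundaries_per_k = res$boundaries,
    tdistance_per_k = td,
    fit_per_k = res$fit,
    optimal_k = optimal_k,
    optimal = res$boundaries[[optimal_k]],
    n_tr = n_tr, n_vox = ncol(Z), TR = TR,
    k_max = k_max, finetune_window = finetune_window,
    criterion = criterion, var.equal = var.equal
  ), class = "gsbs")
}

#' Segmentation with a preset number of states
#'
#' Runs the same greedy-plus-finetune procedure as [gsbs()] but stops at
#' exactly `k` states, without model selection.  Used for single-subject
#' segmentation where the optimal k was derived from group data.
#'
#' @inheritParams gsbs
#' @param k number of states (2..T).
#' @return a boundary vector of length `k - 1`.
#' @export
gsbs_fixed_k <- function(m, k, finetune_window = 1L,
                         criterion = c("fit", "tdistance"), var.equal = TRUE) {
  criterion <- match.arg(criterion)
  Z <- zscore_rows(m)
  n_tr <- nrow(Z)
  k <- assert_count(k, min = 2L)
  if (k > n_tr) abort("`k` cannot exceed the number of TRs.")
  finetune_window <- assert_count(finetune_window, min = 0L)
  P <- row_prefix(Z)
  C <- if (criterion == "tdistance") tcrossprod(Z) / (ncol(Z) - 1) else NULL
  starts <- integer(0)
  for (kk in 2:k) {
    starts <- greedy_step_core(Z, P, starts, criterion, C = C,
                               var.equal = var.equal)
    starts <- finetune_core(Z, P, starts, window = finetune_window)
  }
  starts
}

#' @export
print.gsbs <- function(x, ...) {
  cat(sprintf("<gsbs> %d TRs x %d voxels; optimal k = %d (t-distance %.3f)\n",
              x$n_tr, x$n_vox, x$optimal_k, x$tdistance_per_k[x$optimal_k]))
  cat("state starts:", paste(x$optimal, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a GSBS fit
#'
#' @param x a `"gsbs"` object.
#' @param ... unused.
#' @return a tibble with one row per candidate k: `k`, `tdistance`, `fit`,
#'   and `optimal`.
#' @export
tidy.gsbs <- function(x, ...) {
  tibble(
    k = seq_len(x$k_max),
    tdistance = x$tdistance_per_k,
    fit = x$fit_per_k,
    optimal = seq_len(x$k_max) == x$optimal_k
  ) |> dplyr::filter(.data$k >= 2L)
}

#' One-row summary of a GSBS fit
#'
#' @inheritParams tidy.gsbs
#' @return a tibble with `optimal_k`, `tdistance`, `fit`,
#'   `median_duration_tr`, `n_tr`, `n_vox`.
#' @export
glance.gsbs <- function(x, ...) {
  dur <- state_durations(x$optimal, x$n_tr)
  tibble(
    optimal_k = x$optimal_k,
    tdistance = x$tdistance_per_k[x$optimal_k],
    fit = x$fit_per_k[x$optimal_k],
    median_duration_tr = median(dur),
    n_tr = x$n_tr,
    n_vox = x$n_vox
  )
}

#' Plot the t-distance model-selection curve of a GSBS fit
#'
#' @param object a `"gsbs"` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gsbs <- function(object, ...) {
  d <- tidy.gsbs(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$tdistance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = d[d$optimal, ], colour = "red", size = 2) +
    ggplot2::labs(x = "number of states (k)", y = "t-distance",
                  title = "GSBS model selection") +
    ggplot2::theme_minimal()
}
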