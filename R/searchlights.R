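#' Build an analysis mask from subject activity maps and a grey-matter prior
#'
#' A voxel enters the mask iff, for every subject, its mean activity is at
#' least `activity_frac` times that subject's mean activity over all voxels,
#' and its grey-matter probability exceeds `gm_thresh`.
#'
#' @param activity list of 3-D numeric arrays (one mean-activity map per
#'   subject), all sharing dimensions.
#' @param gm_prob 3-D array of grey-matter probabilities in `[0, 1]`.
#' @param activity_frac activity threshold as a fraction of each subject's
#'   grand mean (default 0.70).
#' @param gm_thresh grey-matter probability threshold (default 0.2,
#'   exclusive).
#' @return a logical 3-D array.
#' @export
build_mask <- function(activity, gm_prob, activity_frac = 0.70,
                       gm_thresh = 0.2) {
  if (!is.list(activity) || length(activity) == 0L) {
    abort("`activity` must be a nonempty list of 3-D arrays.")
  }
  dims <- dim(activity[[1]])
  if (length(dims) != 3L) abort("Activity maps must be 3-D arrays.")
  keep <- array(TRUE, dims)
  for (a in activity) {
    if (!identical(dim(a), dims)) abort("All activity maps must share dimensions.")
    keep <- keep & (a >= activity_frac * mean(a))
  }
  if (!identical(dim(gm_prob), dims)) abort("`gm_prob` must share dimensions with the activity maps.")
  mask <- keep & (gm_prob > gm_thresh)
  if (!any(mask)) abort("Mask is empty: no voxel passes both thresholds.")
  mask
}

# integer offsets within a Euclidean ball of the given radius
ball_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE]
}

#' Define spherical searchlights over a mask
#'
#' Centres lie on a lattice with spacing `step` voxels, anchored at the
#' minimum corner of the mask's bounding box and restricted to in-mask voxels.
#' Each searchlight collects the mask voxels within Euclidean distance
#' `radius` of its centre; searchlights with fewer than `min_size` members are
#' dropped.
#'
#' @param mask logical 3-D array.
#' @param radius sphere radius in voxels (default 3).
#' @param step lattice spacing in voxels (default 2).
#' @param min_size minimum member count to keep a searchlight (default 15).
#' @return a tibble with one row per searchlight: `searchlight`, `cx`, `cy`,
#'   `cz`, `n_members`, and `members` (list-column of linear voxel indices
#'   into `mask`).
#' @export
define_searchlights <- function(mask, radius = 3, step = 2L, min_size = 15L) {
  if (!is.logical(mask) || length(dim(mask)) != 3L) {
    abort("`mask` must be a logical 3-D array.")
  }
  if (!any(mask)) abort("`mask` is empty.")
  dims <- dim(mask)
  step <- assert_count(step, min = 1L)
  min_size <- assert_count(min_size, min = 1L)
  radius <- assert_number(radius, min = 0)

  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2L, min)
  cx <- seq(lo[1], dims[1], by = step)
  cy <- seq(lo[2], dims[2], by = step)
  cz <- seq(lo[3], dims[3], by = step)
  centers <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  in_mask <- mask[centers]
  centers <- centers[in_mask, , drop = FALSE]

  off <- as.matrix(ball_offsets(radius))
  rows <- vector("list", nrow(centers))
  n_keep <- 0L
  for (i in seq_len(nrow(centers))) {
    pts <- sweep(off, 2L, centers[i, ], `+`)
    ok <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
      pts[, 2] >= 1 & pts[, 2] <= dims[2] &
      pts[, 3] >= 1 & pts[, 3] <= dims[3]
    pts <- pts[ok, , drop = FALSE]
    lin <- pts[, 1] + (pts[, 2] - 1L) * dims[1] + (pts[, 3] - 1L) * dims[1] * dims[2]
    lin <- lin[mask[lin]]
    if (length(lin) >= min_size) {
      n_keep <- n_keep + 1L
      rows[[n_keep]] <- tibble(cx = centers[i, 1], cy = centers[i, 2],
                               cz = centers[i, 3], n_members = length(lin),
                               members = list(sort(lin)))
    }
  }
  if (n_keep == 0L) {
    abort(sprintf("No searchlight reaches the minimum size of %d voxels.", min_size))
  }
  out <- dplyr::bind_rows(rows[seq_len(n_keep)])
  dplyr::mutate(out, searchlight = dplyr::row_number(), .before = 1L)
}

#' Orthogonal Procrustes transform aligning one subject to a reference
#'
#' Returns the orthogonal V x V matrix `R` minimising
#' `||reference - subject %*% R||_F` (no scaling or translation; inputs are
#' expected to have z-scored columns).  Computed from the SVD of
#' `t(subject) %*% reference` as `U %*% t(V)`; reflections are permitted (the
#' full orthogonal group), and the sign convention follows the SVD of the
#' cross-product matrix as returned by [base::svd()].
#'
#' @param reference T x V matrix.
#' @param subject T x V matrix.
#' @return a V x V orthogonal matrix.
#' @export
procrustes_align <- function(reference, subject) {
  if (!identical(dim(reference), dim(subject))) {
    abort("`reference` and `subject` must share dimensions.")
  }
  s <- svd(crossprod(subject, reference))
  s$u %*% t(s$v)
}

zscore_cols <- function(m) {
  mu <- colMeans(m)
  sd_ <- sqrt(colSums((m - rep(mu, each = nrow(m)))^2) / (nrow(m) - 1))
  if (any(sd_ == 0)) {
    abort(sprintf("Voxel(s) %s have constant time courses and cannot be aligned.",
                  paste(which(sd_ == 0), collapse = ", ")))
  }
  sweep(sweep(m, 2L, mu), 2L, sd_, `/`)
}

#' Hyperalign a group of subjects into a shared voxel space
#'
#' Two-pass Procrustes template alignment within one region/searchlight.
#' Pass 1 aligns subject 2 to subject 1 and each following subject to the
#' running mean of the already-aligned subjects; pass 2 re-aligns every
#' subject to the pass-1 mean.  Deterministic given the input order.
#'
#' @param subjects list of T x V matrices (>= 2 for a meaningful alignment;
#'   a single subject is passed through with a warning).
#' @param sort_ids optional vector of subject identifiers; when supplied,
#'   subjects are processed in `order(sort_ids)` and returned in the original
#'   order.
#' @return list of aligned T x V matrices (column z-scored).
#' @export
hyperalign_group <- function(subjects, sort_ids = NULL) {
  if (!is.list(subjects) || length(subjects) == 0L) {
    abort("`subjects` must be a nonempty list of matrices.")
  }
  if (length(subjects) == 1L) {
    warn("Single subject: hyperalignment is an identity pass-through.")
    return(list(zscore_cols(subjects[[1]])))
  }
  ord <- if (is.null(sort_ids)) seq_along(subjects) else order(sort_ids)
  zs <- lapply(subjects[ord], zscore_cols)
  n <- length(zs)

  # pass 1: incremental template
  aligned <- vector("list", n)
  aligned[[1]] <- zs[[1]]
  running <- zs[[1]]
  for (i in 2:n) {
    R <- procrustes_align(running / (i - 1), zs[[i]])
    aligned[[i]] <- zs[[i]] %*% R
    running <- running + aligned[[i]]
  }
  template <- running / n

  # pass 2: re-align everyone to the pass-1 mean
  out <- vector("list", n)
  for (i in seq_len(n)) {
    R <- procrustes_align(template, zs[[i]])
    out[[i]] <- zs[[i]] %*% R
  }
  out[order(ord)]
}

#' Average aligned subjects into one group matrix
#'
#' Element-wise mean of the input matrices followed by row (timepoint)
#' z-scoring, the form consumed by [gsbs()].
#'
#' @param mats nonempty list of T x V matrices.
#' @return a T x V matrix with z-scored rows.
#' @export
group_average <- function(mats) {
  if (!is.list(mats) || length(mats) == 0L) abort("`mats` must be a nonempty list.")
  avg <- Reduce(`+`, mats) / length(mats)
  zscore_rows(avg)
}

#' Project per-searchlight values back to voxels
#'
#' Each voxel receives the mean value of all searchlights containing it;
#' voxels covered by no searchlight are `NA`.
#'
#' @param values numeric vector, one value per searchlight row.
#' @param searchlights tibble from [define_searchlights()].
#' @param dims 3-element integer vector, the grid dimensions.
#' @return a 3-D numeric array.
#' @export
project_to_voxels <- function(values, searchlights, dims) {
  if (length(values) != nrow(searchlights)) {
    abort("`values` must supply exactly one value per searchlight.")
  }
  acc <- array(0, dims)
  cnt <- array(0L, dims)
  for (i in seq_len(nrow(searchlights))) {
    mem <- searchlights$members[[i]]
    acc[mem] <- acc[mem] + values[i]
    cnt[mem] <- cnt[mem] + 1L
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  out
}

#' Write a voxel map as NIfTI
#'
#' @param map 3-D numeric array (e.g. from [project_to_voxels()]).
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_voxel_map <- function(map, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("NIfTI export requires the RNifti package.")
  }
  RNifti::writeNifti(RNifti::asNifti(map), path)
  invisible(path)
}
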