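#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange group_by summarise ungroup bind_rows
#' @importFrom stats cor sd median quantile rnorm rgeom pt wilcox.test p.adjust
#' @importFrom utils head tail
NULL

# Stable integer seed fan-out: one master seed plus a path of small integers
# maps to a child seed < 2^31 - 1.  Polynomial rolling combination; collisions
# are astronomically unlikely for the short paths used here.
derive_seed <- function(master, ...) {
  path <- c(...)
  h <- as.double(master %% 2147483647L)
  for (x in path) {
    h <- (h * 69069 + as.double(x) + 1) %% 2147483647
  }
  as.integer(h) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_count <- function(x, min = 1L, name = deparse(substitute(x))) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d (got %s).",
                  name, min, paste(format(x), collapse = ", ")))
  }
  as.integer(x)
}

assert_number <- function(x, min = -Inf, name = deparse(substitute(x))) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %g.", name, min))
  }
  as.double(x)
}

#' Validate a boundary (state-start) vector
#'
#' Boundaries are 1-based TR indices in `2..n_tr`, strictly increasing, each
#' marking the first TR of a new state; TR 1 implicitly starts the first
#' state.  An empty vector encodes a single state spanning all TRs.
#'
#' @param starts integer vector of state-start TRs.
#' @param n_tr total number of TRs.
#' @return the validated integer vector (invisibly usable).
#' @keywords internal
validate_starts <- function(starts, n_tr) {
  if (length(starts) == 0L) return(integer(0))
  if (any(starts != round(starts))) abort("Boundary starts must be integers.")
  starts <- as.integer(starts)
  if (any(starts < 2L) || any(starts > n_tr)) {
    abort(sprintf("Boundary starts must lie in [2, %d].", n_tr))
  }
  if (any(diff(starts) <= 0L)) abort("Boundary starts must be strictly increasing.")
  starts
}

# State label per TR (1..k).
state_labels <- function(n_tr, starts) {
  findInterval(seq_len(n_tr), c(1L, starts))
}

#' State durations in TRs
#'
#' @param starts boundary vector (see [validate_starts()]).
#' @param n_tr total number of TRs.
#' @return integer vector of state lengths, summing to `n_tr`.
#' @export
#' @examples
#' state_durations(c(4L, 9L), 12L)
state_durations <- function(starts, n_tr) {
  n_tr <- assert_count(n_tr)
  starts <- validate_starts(starts, n_tr)
  diff(c(1L, starts, n_tr + 1L))
}
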