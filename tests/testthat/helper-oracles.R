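# Brute-force / independent oracles used across test files.  These stay
# deliberately naive (loops over pairs, exhaustive enumeration) so they are
# independent of the package's vectorised implementations.

# mean over TRs of cor(row, state mean of z-scored rows), computed naively
oracle_fit <- function(m, starts) {
  Z <- t(apply(m, 1, function(r) (r - mean(r)) / sd(r)))
  n_tr <- nrow(Z)
  g <- findInterval(seq_len(n_tr), c(1, starts))
  vals <- numeric(n_tr)
  for (t in seq_len(n_tr)) {
    rows <- which(g == g[t])
    mu <- colMeans(Z[rows, , drop = FALSE])
    vals[t] <- if (sd(mu) == 0) 0 else cor(Z[t, ], mu)
  }
  mean(vals)
}

# exhaustive best segmentation into k states (T small)
oracle_best_fit <- function(m, k) {
  n_tr <- nrow(m)
  best <- -Inf
  for (comb in utils::combn(2:n_tr, k - 1, simplify = FALSE)) {
    f <- oracle_fit(m, comb)
    if (f > best) best <- f
  }
  best
}

# naive within-state mean pairwise correlation
oracle_within_cor <- function(m, starts) {
  Z <- t(apply(m, 1, function(r) (r - mean(r)) / sd(r)))
  g <- findInterval(seq_len(nrow(Z)), c(1, starts))
  vals <- c()
  for (i in seq_len(nrow(Z) - 1)) {
    for (j in (i + 1):nrow(Z)) {
      if (g[i] == g[j]) vals <- c(vals, cor(Z[i, ], Z[j, ]))
    }
  }
  mean(vals)
}

# BH step-up by direct scan
oracle_bh <- function(p, q = 0.05) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(n)) if (ps[i] <= i / n * q) k <- i
  sig <- rep(FALSE, n)
  if (k > 0) sig[o[seq_len(k)]] <- TRUE
  sig
}

# exact one-sample signed-rank p by enumerating all sign patterns
oracle_signed_rank_p <- function(x) {
  stopifnot(all(x != 0), !any(duplicated(abs(x))))
  n <- length(x)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  pl <- mean(w_all <= w_obs)
  pg <- mean(w_all >= w_obs)
  min(1, 2 * min(pl, pg))
}

# random orthogonal matrix
random_orthogonal <- function(v, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(v * v), v, v)))
}

# column z-scoring, naive
zscore_cols_oracle <- function(m) apply(m, 2, function(x) (x - mean(x)) / sd(x))
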