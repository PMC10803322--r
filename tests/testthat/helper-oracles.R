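# Independent brute-force oracles used to validate the package's
# statistical machinery. These deliberately avoid the code paths (and
# where possible the library calls) used by the implementation.

# textbook Pearson correlation, explicit double loop
oracle_cor_matrix <- function(x) {
  p <- ncol(x)
  out <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      xi <- x[, i]; xj <- x[, j]
      num <- sum((xi - mean(xi)) * (xj - mean(xj)))
      den <- sqrt(sum((xi - mean(xi))^2)) * sqrt(sum((xj - mean(xj))^2))
      out[i, j] <- num / den
    }
  }
  out
}

# per-row absolute sums excluding the diagonal, explicit double loop
oracle_nodal_strength <- function(W) {
  n <- nrow(W)
  s <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) s[i] <- s[i] + abs(W[i, j])
    }
  }
  s
}

# literal Benjamini-Hochberg step-up definition:
# adjusted p_(i) = min_{k >= i} m * p_(k) / k, clipped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- m * ps[i:m] / (i:m)
    adj[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the ranks of |d| (valid when |d| are untied, nonzero)
oracle_wilcox_exact <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  min(1, 2 * min(p_ge, p_le))
}

# VIF via explicit normal equations for each auxiliary regression
oracle_vif <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  vapply(seq_len(p), function(j) {
    y <- x[, j]
    Z <- cbind(1, x[, -j, drop = FALSE])
    beta <- solve(crossprod(Z), crossprod(Z, y))
    res <- y - Z %*% beta
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    1 / (1 - r2)
  }, numeric(1))
}

# small acceleration set built directly from a named list of n x 3
# matrices (bypasses the preprocessing chain)
make_acc_set <- function(mats, fs = 120, subject = "S01",
                         condition = "off", trial = 1L) {
  acceleration_set(subject, condition, trial, fs, mats)
}

# acceleration set with one axis taken from the columns of `m` and
# small deterministic variation on the other two axes
acc_from_matrix <- function(m, axis = "ML", fs = 120) {
  n <- nrow(m)
  filler <- function(k) sin(seq_len(n) / 7 + k) + cos(seq_len(n) / 3 - k)
  mats <- lapply(seq_len(ncol(m)), function(j) {
    d <- cbind(filler(j), filler(j + 0.5), filler(j + 1))
    d[, match(axis, c("ML", "AP", "VT"))] <- m[, j]
    d
  })
  names(mats) <- if (!is.null(colnames(m))) colnames(m) else
    paste0("M", seq_len(ncol(m)))
  make_acc_set(mats, fs = fs)
}

# random valid correlation matrix of dimension p (from random data)
random_corr <- function(p, n = 50) {
  stats::cor(matrix(stats::rnorm(n * p), n, p))
}

# tiny cohort configuration for structural tests
tiny_config <- function(...) {
  cohort_config(n_subjects = 2, n_trials = 2, seed = 99, ...)
}

# long-format strength table built directly (bypasses the pipeline)
toy_strengths <- function(values_off, values_on, nodes, axis = "ML") {
  n_sub <- nrow(values_off)
  do.call(rbind, lapply(seq_len(n_sub), function(i) {
    rbind(
      data.frame(subject = sprintf("S%02d", i), condition = "off",
                 axis = axis, node = nodes, strength = values_off[i, ],
                 n_trials = 4, stringsAsFactors = FALSE),
      data.frame(subject = sprintf("S%02d", i), condition = "on",
                 axis = axis, node = nodes, strength = values_on[i, ],
                 n_trials = 4, stringsAsFactors = FALSE))
  }))
}
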