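# Independent oracles, coded from literal definitions and kept free of any
# package internals they are used to check.

# Sequential (Type I) sum-of-squares by explicit orthogonal projection onto
# nested design-matrix column spaces.
oracle_sequential_ss <- function(y, meta, categorical, continuous = character()) {
  n <- length(y)
  blocks <- c(
    lapply(continuous, function(v) matrix(as.numeric(meta[[v]]), n, 1)),
    lapply(categorical, function(v) {
      f <- factor(meta[[v]])
      # full indicator block; rank handled by the projection itself
      stats::model.matrix(~ f - 1)
    }))
  names(blocks) <- c(continuous, categorical)
  proj_ss <- function(X) {
    q <- qr(X)
    fit <- qr.fitted(q, y)
    sum(fit^2)
  }
  X <- matrix(1, n, 1)
  ss_prev <- proj_ss(X)
  ss <- numeric(length(blocks))
  for (i in seq_along(blocks)) {
    X <- cbind(X, blocks[[i]])
    ss_cur <- proj_ss(X)
    ss[i] <- ss_cur - ss_prev
    ss_prev <- ss_cur
  }
  resid <- sum(y^2) - ss_prev
  c(setNames(ss, names(blocks)), Residuals = resid)
}

# Literal-definition p-value adjustments ------------------------------------

oracle_bonferroni <- function(p) pmin(1, length(p) * p)

oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((n - seq_len(n) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

oracle_hochberg <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin((n - (n - seq_len(n) + 1) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n - seq_len(n) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

oracle_by <- function(p) {
  n <- length(p)
  cn <- sum(1 / seq_len(n))
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(cn * n / (n - seq_len(n) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Hommel by explicit closed testing: every intersection hypothesis is tested
# with Simes' test; the adjusted p of H_i is the largest Simes p over all
# subsets containing i. Exponential in n; intended for n <= 10.
oracle_hommel <- function(p) {
  n <- length(p)
  stopifnot(n <= 10)
  out <- numeric(n)
  subsets <- lapply(seq_len(2^n - 1), function(code) {
    which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
  })
  simes <- vapply(subsets, function(I) {
    k <- length(I)
    min(k * sort(p[I]) / seq_len(k))
  }, numeric(1))
  for (i in seq_len(n)) {
    inI <- vapply(subsets, function(I) i %in% I, logical(1))
    out[i] <- min(1, max(simes[inI]))
  }
  out
}

oracle_adjust <- function(p, method) {
  switch(method,
         BH = oracle_bh(p), bonferroni = oracle_bonferroni(p),
         holm = oracle_holm(p), hochberg = oracle_hochberg(p),
         hommel = oracle_hommel(p), BY = oracle_by(p))
}

# Mean-of-order-statistics quantile normalization on complete data.
oracle_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) ref[rank(col, ties.method = "average")])
}
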