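test_that("log2 transform maps worked values and flags non-positives", {
  m <- matrix(c(8, 1, 0, 4), 2, 2, dimnames = list(c("F1", "F2"),
                                                   c("S1", "S2")))
  expr <- as_expression(m)
  expect_warning(out <- log2_transform(expr), "1 non-positive")
  v <- expr_values(out)
  expect_equal(v["F1", "S1"], 3)
  expect_equal(v["F2", "S1"], 0)
  expect_true(is.na(v["F1", "S2"]))  # log2(0) becomes missing, not an error
  expect_equal(v["F2", "S2"], 2)
  expect_equal(expr_scale(out), "log2")
  expect_error(log2_transform(out), "raw-scale")
})

test_that("quantile normalization reproduces the mean-order-statistics oracle", {
  m <- cbind(S1 = c(2, 4, 6), S2 = c(4, 6, 8))
  rownames(m) <- paste0("F", 1:3)
  out <- expr_values(quantile_normalize(as_expression(m, scale = "log2")))
  expect_equal(unname(out[, "S1"]), c(3, 5, 7))
  expect_equal(unname(out[, "S2"]), c(3, 5, 7))

  set.seed(21)
  big <- matrix(rnorm(300, 20, 2), 50, 6,
                dimnames = list(sprintf("F%02d", 1:50), sprintf("S%d", 1:6)))
  qn <- expr_values(quantile_normalize(as_expression(big, scale = "log2")))
  expect_equal(unname(qn), unname(oracle_quantile_normalize(big)),
               tolerance = 1e-12)
  sorted <- apply(qn, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  expect_lt(diff(range(colMeans(qn))), 1e-10)
  expect_equal(mean(qn), mean(rowMeans(apply(big, 2, sort))),
               tolerance = 1e-10)
})

test_that("quantile normalization preserves masks, ties and identical columns", {
  m <- cbind(S1 = c(2, NA, 6, 4), S2 = c(4, 6, 8, 6), S3 = c(1, 2, 3, 2))
  rownames(m) <- paste0("F", 1:4)
  expr <- as_expression(m, scale = "log2")
  out <- expr_values(quantile_normalize(expr))
  expect_equal(is.na(out), is.na(m))
  # monotone within each column, ties preserved
  for (j in 1:3) {
    ok <- !is.na(m[, j])
    expect_equal(order(out[ok, j]), order(m[ok, j]))
    expect_equal(out[2, "S2"], out[4, "S2"])  # tied inputs stay tied
  }
  dup <- cbind(S1 = c(1, 5, 9), S2 = c(1, 5, 9))
  rownames(dup) <- paste0("F", 1:3)
  same <- expr_values(quantile_normalize(as_expression(dup, scale = "log2")))
  expect_equal(unname(same), unname(dup))
  single <- as_expression(matrix(1:3, 3, 1,
    dimnames = list(paste0("F", 1:3), "S1")), scale = "log2")
  expect_warning(res <- quantile_normalize(single), ">= 2 samples")
  expect_equal(expr_values(res), expr_values(single))
})

test_that("VSN absorbs per-sample scale factors", {
  set.seed(42)
  base <- 2^rnorm(80, 12, 1.5)
  for (c_fac in c(0.5, 3)) {
    m <- cbind(S1 = base, S2 = c_fac * base)
    rownames(m) <- sprintf("F%02d", seq_len(nrow(m)))
    out <- vsn_normalize(as_expression(m))
    v <- expr_values(out)
    expect_lt(max(abs(v[, 1] - v[, 2])), 1e-6)
    fit <- vsn_fit(out)
    expect_equal(unname(fit$b["S1"] / fit$b["S2"]), c_fac, tolerance = 0.01)
    expect_true(all(fit$b > 0))
  }
})

test_that("VSN approaches log2 at high intensity and stabilizes variance", {
  set.seed(7)
  m <- matrix(2^rnorm(600, 10, 2), 100, 6,
              dimnames = list(sprintf("F%03d", 1:100), sprintf("S%d", 1:6)))
  out <- vsn_normalize(as_expression(m))
  v <- expr_values(out)
  # top-decile differences match log2 ratios within 2%
  idx <- order(m[, 1], decreasing = TRUE)[1:10]
  dh <- outer(v[idx, 1], v[idx, 1], "-")
  dl <- log2(outer(m[idx, 1], m[idx, 1], "/"))
  keep <- abs(dl) > 0.1
  expect_lt(max(abs(dh[keep] - dl[keep]) / abs(dl[keep])), 0.02)
  # monotone within each sample
  for (j in 1:6) expect_equal(order(v[, j]), order(m[, j]))

  set.seed(9)
  mu <- rnorm(200, 10, 2)
  rep4 <- 2^(matrix(mu, 200, 4) + matrix(rnorm(800, 0, 0.2), 200, 4))
  dimnames(rep4) <- list(sprintf("F%03d", 1:200), sprintf("S%d", 1:4))
  outr <- vsn_normalize(as_expression(rep4))
  b <- vsn_fit(outr)$b
  expect_lt((max(b) - min(b)) / mean(b), 0.05)
  # residual spread should not grow with the mean
  vr <- expr_values(outr)
  ct <- stats::cor.test(rowMeans(vr), apply(vr, 1, sd),
                        alternative = "greater")
  expect_gt(ct$p.value, 0.05)
})

test_that("VSN input guards reject unusable data", {
  tiny <- rand_expr(5, 3, seed = 2, scale = "raw")
  expect_error(vsn_normalize(tiny), "10 complete features")
  logd <- rand_expr(20, 3, seed = 2, scale = "log2")
  expect_error(vsn_normalize(logd), "raw-scale")
  one <- as_expression(matrix(2^rnorm(20, 10), 20, 1,
    dimnames = list(sprintf("F%02d", 1:20), "S1")))
  expect_error(vsn_normalize(one), ">= 2 samples")
})

test_that("apply_normalization dispatches the four options", {
  expr <- rand_expr(30, 6, seed = 5, scale = "raw")
  expect_identical(apply_normalization(expr, "none"), expr)
  qn <- apply_normalization(expr, "QN")
  expect_equal(qn, quantile_normalize(log2_transform(expr)))
  expect_equal(expr_scale(qn), "log2")   # QN runs on log2-transformed data
  expect_equal(expr_scale(apply_normalization(expr, "VSN")), "glog")
  expect_equal(expr_scale(apply_normalization(expr, "log2")), "log2")
})

test_that("group-wise QN equalizes within but not across groups", {
  expr <- rand_expr(40, 6, seed = 8, scale = "raw")
  meta <- meta_for(expr, Norm_Imp_Group = rep(c(1, 2), each = 3))
  out <- apply_normalization(expr, "QN", meta, groupwise = TRUE)
  v <- expr_values(out)
  s1 <- apply(v[, 1:3], 2, sort)
  s2 <- apply(v[, 4:6], 2, sort)
  expect_lt(max(abs(s1 - s1[, 1])), 1e-12)
  expect_lt(max(abs(s2 - s2[, 1])), 1e-12)
  expect_gt(max(abs(s1[, 1] - s2[, 1])), 1e-6)
  expect_error(apply_normalization(expr, "QN", meta_for(expr), TRUE),
               "Norm_Imp_Group")
})
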