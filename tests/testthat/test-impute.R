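test_that("KNN recovers exact duplicates and constant rows", {
  m <- rbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, NA), C = c(9, 8, 7, 6))
  colnames(m) <- paste0("S", 1:4)
  out <- impute_knn(as_expression(m, scale = "log2"), k = 1)
  expect_equal(expr_values(out)["B", "S4"], 4)     # zero-distance neighbour
  expect_false(anyNA(expr_values(out)))
  expect_equal(expr_values(out)[c("A", "C"), ], m[c("A", "C"), ])

  const <- matrix(5, 6, 3, dimnames = list(paste0("F", 1:6), paste0("S", 1:3)))
  const[2, 2] <- NA
  outc <- impute_knn(as_expression(const, scale = "log2"), k = 3)
  expect_equal(expr_values(outc)[2, 2], 5)
})

test_that("KNN recovery error stays within the noise level under MCAR", {
  set.seed(31)
  mu <- matrix(rnorm(100, 20, 1), 100, 1)[, rep(1, 12)] +
    matrix(rep(rnorm(3, 0, 1), each = 4), 100, 12, byrow = TRUE)
  noise <- matrix(rnorm(1200, 0, 0.1), 100, 12)
  truth <- mu + noise
  dimnames(truth) <- list(sprintf("F%03d", 1:100), sprintf("S%02d", 1:12))
  mask <- matrix(runif(1200) < 0.05, 100, 12)
  obs <- truth
  obs[mask] <- NA
  out <- expr_values(impute_knn(as_expression(obs, scale = "log2"), k = 10))
  rmse <- sqrt(mean((out[mask] - truth[mask])^2))
  expect_lt(rmse, 0.3)    # < 3x the noise SD of 0.1
  expect_equal(out[!mask], truth[!mask])
})

test_that("KNN guards: fallback rows, empty columns, too-large k", {
  m <- matrix(rnorm(40, 10), 10, 4,
              dimnames = list(sprintf("F%02d", 1:10), paste0("S", 1:4)))
  m[1, 1:3] <- NA   # 75% missing > 0.5 -> column-mean fallback
  expr <- as_expression(m, scale = "log2")
  out <- expr_values(impute_knn(expr, k = 3))
  expect_equal(out[1, 1:3], colMeans(m[, 1:3], na.rm = TRUE))
  m2 <- m
  m2[, 2] <- NA
  expect_error(impute_knn(as_expression(m2, scale = "log2"), k = 3),
               "entirely missing")
  expect_error(impute_knn(expr, k = 10), "donors")
  expect_error(impute_knn(rand_expr(scale = "raw")), "normalized")
})

test_that("rank-1 SVD completion recovers the held-out outer-product cell", {
  m <- outer(c(1, 2), c(1, 2, 3))
  dimnames(m) <- list(c("F1", "F2"), c("S1", "S2", "S3"))
  m[2, 3] <- NA
  out <- impute_svd(as_expression(m, scale = "log2"), rank = 1, tol = 1e-10,
                    max_iter = 1000)
  expect_equal(expr_values(out)["F2", "S3"], 6, tolerance = 1e-4)
  expect_true(attr(out, "svd_converged"))
})

test_that("SVD imputation is a fixpoint on complete data and monotone", {
  complete <- rand_expr(15, 5, seed = 12)
  out <- impute_svd(complete, rank = 2)
  expect_equal(expr_values(out), expr_values(complete))
  expect_length(attr(out, "svd_deltas"), 0)   # zero iterations

  set.seed(13)
  # a genuine rank-2 factor model: baseline direction + one varying factor
  u <- cbind(rnorm(200, 20, 2), rnorm(200))
  v <- cbind(rnorm(36, 1, 0.05), rnorm(36))
  truth <- u %*% t(v) + matrix(rnorm(200 * 36, 0, 0.05), 200, 36)
  dimnames(truth) <- list(sprintf("F%03d", 1:200), sprintf("S%02d", 1:36))
  mask <- matrix(runif(200 * 36) < 0.10, 200, 36)
  obs <- truth
  obs[mask] <- NA
  out2 <- impute_svd(as_expression(obs, scale = "log2"), rank = 2)
  expect_gt(cor(expr_values(out2)[mask], truth[mask]), 0.95)
  expect_equal(expr_values(out2)[!mask], truth[!mask])
  deltas <- attr(out2, "svd_deltas")
  expect_true(all(diff(deltas) <= 1e-8))   # successive fills contract
})

test_that("imputation dispatch honours method, level and grouping", {
  expr <- rand_expr(30, 8, seed = 14)
  expect_identical(expr_values(apply_imputation(expr, "SVD")),
                   expr_values(expr))
  m <- expr_values(expr)
  m[3, 2] <- NA
  m[10, 7] <- NA
  holey <- as_expression(m, scale = "log2")
  meta <- meta_for(holey, Norm_Imp_Group = rep(c(1, 2), each = 4))
  g1 <- expr_values(apply_imputation(holey, "KNN", meta, groupwise = TRUE,
                                     k = 5))
  # group 1's imputations must ignore group 2's values entirely
  m_alt <- m
  m_alt[, 5:8] <- m_alt[, 5:8] + 100
  alt <- as_expression(m_alt, scale = "log2")
  g1_alt <- expr_values(apply_imputation(alt, "KNN", meta, groupwise = TRUE,
                                         k = 5))
  expect_equal(g1_alt[3, 2], g1[3, 2])
  expect_error(apply_imputation(holey, "KNN", meta_for(holey), TRUE), "Norm_Imp_Group")
})
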