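test_that("one-way worked example decomposes exactly", {
  meta <- tibble::tibble(sample_id = paste0("S", 1:4),
                         g = c("lo", "lo", "hi", "hi"))
  res <- fit_feature(c(1, 3, 5, 7), meta, categorical = "g")
  expect_equal(res$sumsq, c(16, 4))
  expect_equal(res$pct_ss, c(80, 20))
  expect_equal(res$statistic[1], 8)
  expect_equal(res$df, c(1L, 2L))
  expect_equal(res$p_value[1], stats::pf(8, 1, 2, lower.tail = FALSE))
  # SS conservation against the definition of total SS
  y <- c(1, 3, 5, 7)
  expect_equal(sum(res$sumsq), sum((y - mean(y))^2))
})

test_that("constant responses yield zero SS and missing p-values", {
  meta <- tibble::tibble(sample_id = paste0("S", 1:6),
                         g = rep(c("a", "b"), 3))
  res <- fit_feature(rep(4.2, 6), meta, categorical = "g")
  expect_equal(res$sumsq, c(0, 0))
  expect_equal(res$pct_ss, c(0, 0))
  expect_true(all(is.na(res$p_value)))
  expect_equal(res$df, c(1L, 4L))
})

test_that("degenerate designs are rejected with informative errors", {
  meta <- tibble::tibble(sample_id = paste0("S", 1:6),
                         g1 = rep(c("a", "b"), each = 3),
                         g2 = rep(c("x", "y"), each = 3))   # aliased with g1
  y <- rnorm(6)
  expect_error(fit_feature(y, meta, categorical = c("g1", "g2")),
               "rank-deficient|aliased")
  meta2 <- tibble::tibble(sample_id = paste0("S", 1:4),
                          g = c("a", "b", "c", "d"))
  expect_error(fit_feature(rnorm(4), meta2, categorical = "g"),
               "residual degrees")
  expect_error(fit_feature(c(1, NA, 3, 4), meta2, categorical = "g"),
               "missing")
  one_level <- tibble::tibble(sample_id = paste0("S", 1:4), g = "a")
  expect_error(fit_feature(rnorm(4), one_level, categorical = "g"),
               "fewer than 2 levels")
})

test_that("sequential SS matches the nested-projection oracle", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(8:12, 1)
    meta <- tibble::tibble(
      sample_id = paste0("S", seq_len(n)),
      g1 = sample(c("a", "b"), n, replace = TRUE),
      g2 = sample(c("x", "y", "z"), n, replace = TRUE),
      age = round(rnorm(n, 40, 10)))
    # ensure both factors have >= 2 levels and no aliasing by redraw
    if (dplyr::n_distinct(meta$g1) < 2 || dplyr::n_distinct(meta$g2) < 2) next
    y <- rnorm(n, 10, 2)
    cats <- if (rep %% 2) c("g1", "g2") else "g1"
    conts <- if (rep %% 3) "age" else character()
    fit <- tryCatch(fit_feature(y, meta, cats, conts), error = function(e) NULL)
    if (is.null(fit)) next
    oracle <- oracle_sequential_ss(y, meta, cats, conts)
    expect_equal(setNames(fit$sumsq, fit$term), oracle, tolerance = 1e-8)
    expect_equal(sum(fit$pct_ss), 100, tolerance = 1e-6)
  }
})

test_that("balanced designs make the categorical decomposition order-invariant", {
  meta <- tidyr::expand_grid(m1 = c("A1", "A2"), m2 = c("B1", "B2", "B3"),
                             r = 1:2)
  meta$sample_id <- paste0("S", seq_len(nrow(meta)))
  set.seed(5)
  y <- rnorm(nrow(meta), 20, 3)
  f12 <- fit_feature(y, meta, c("m1", "m2"))
  f21 <- fit_feature(y, meta, c("m2", "m1"))
  expect_equal(f12$sumsq[f12$term == "m1"], f21$sumsq[f21$term == "m1"],
               tolerance = 1e-8)
  expect_equal(f12$sumsq[f12$term == "m2"], f21$sumsq[f21$term == "m2"],
               tolerance = 1e-8)
})

test_that("the two-group F statistic equals the squared pooled t", {
  set.seed(6)
  meta <- tibble::tibble(sample_id = paste0("S", 1:10),
                         g = rep(c("a", "b"), each = 5))
  y <- rnorm(10, 5, 1)
  fit <- fit_feature(y, meta, "g")
  tt <- stats::t.test(y ~ meta$g, var.equal = TRUE)
  expect_equal(fit$statistic[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$p_value[1], tt$p.value, tolerance = 1e-10)
})

test_that("adjustment wrapper reproduces worked examples and handles NAs", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "holm"),
               c(0.03, 0.04, 0.04))
  expect_equal(adjust_pvalues(0.2, "bonferroni"), 0.2)
  p <- c(0.04, NA, 0.01)
  adj <- adjust_pvalues(p, "BH")
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], stats::p.adjust(p[c(1, 3)], "BH"))
  expect_error(adjust_pvalues(c(0.5, 1.2), "BH"), "\\[0, 1\\]")
  for (m in c("BH", "bonferroni", "holm", "hochberg", "hommel", "BY")) {
    pp <- c(0.005, 0.04, 0.2, 0.9)
    expect_true(all(adjust_pvalues(pp, m) >= pp), info = m)
  }
})

test_that("the model stage summarises, adjusts within term, and counts", {
  set.seed(8)
  meta <- small_design_meta()
  m <- matrix(rnorm(25 * 12, 18, 1), 25, 12,
              dimnames = list(sprintf("F%02d", 1:25), meta$sample_id))
  m[1:5, meta$g1 == "b"] <- m[1:5, meta$g1 == "b"] + 4   # strong g1 effects
  m[25, ] <- 7                                            # constant feature
  expr <- as_expression(m, scale = "log2")
  res <- run_model_stage(expr, meta, c("g1", "g2"), "age",
                         alpha = 0.05, adjust_method = "BH")
  tab <- tidy(res)
  expect_setequal(as.character(unique(tab$term)),
                  c("age", "g1", "g2", "Residuals"))
  # adjustment is across features within each term
  g1p <- tab |> dplyr::filter(term == "g1")
  expect_equal(g1p$p_adjusted, adjust_pvalues(g1p$p_value, "BH"))
  # conservation per feature
  tot <- tab |> dplyr::group_by(feature_id) |>
    dplyr::summarise(s = sum(pct_ss))
  expect_true(all(abs(tot$s - 100) < 1e-6 | tot$s == 0))
  cnt <- res$counts
  expect_true(all(cnt$n_significant_adjusted <= cnt$n_significant_raw))
  expect_gte(cnt$n_significant_adjusted[cnt$term == "g1"], 5)
  # constant feature kept in the table, excluded from counts
  expect_true("F25" %in% tab$feature_id)
  expect_true(all(is.na(tab$p_value[tab$feature_id == "F25"])))
  expect_true(all(cnt$n_features == 25))
  g <- glance(res)
  expect_equal(g$n_features, 25)
  expect_equal(g$adjust_method, "BH")
})
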