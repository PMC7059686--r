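ADJUST_METHODS <- c(BH = "BH", bonferroni = "bonferroni", holm = "holm",
                    hochberg = "hochberg", hommel = "hommel", BY = "BY")

#' Adjust p-values for multiple testing
#'
#' Thin, validating wrapper around [stats::p.adjust()] exposing the six
#' classic procedures: Benjamini-Hochberg (`"BH"`, the default downstream),
#' Bonferroni, Holm, Hochberg, Hommel and Benjamini-Yekutieli (`"BY"`).
#' Missing entries stay missing and do not count towards the number of
#' tests.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @param method one of `"BH"`, `"bonferroni"`, `"holm"`, `"hochberg"`,
#'   `"hommel"`, `"BY"`.
#' @return vector of adjusted p-values, same length and order as `p`.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03), "BH")
#' @export
adjust_pvalues <- function(p, method = names(ADJUST_METHODS)) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) wf_stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = ADJUST_METHODS[[method]])
  out
}

build_model_frame <- function(meta, categorical, continuous) {
  miss <- setdiff(c(categorical, continuous), names(meta))
  if (length(miss)) {
    wf_stop("variable(s) not in metadata: ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(meta[c(continuous, categorical)])
  for (v in categorical) {
    df[[v]] <- factor(df[[v]])
    if (nlevels(df[[v]]) < 2) {
      wf_stop("categorical variable '", v, "' has fewer than 2 levels")
    }
  }
  for (v in continuous) {
    if (!is.numeric(df[[v]])) wf_stop("continuous variable '", v,
                                      "' is not numeric")
    if (anyNA(df[[v]])) wf_stop("continuous variable '", v,
                                "' contains missing values")
  }
  df
}

#' Fit the fixed-effects ANOVA/ANCOVA model for a single feature
#'
#' Fits a main-effects linear model of the feature's (complete) per-sample
#' response on the selected variables and decomposes the total sum of
#' squares sequentially (Type I), with continuous covariates entered first
#' and categorical variables following in the given order — the ANCOVA
#' convention. On balanced, complete designs the categorical decomposition
#' is order-invariant. Each term's F statistic is its mean square over the
#' residual mean square, with the p-value from the upper tail of the F
#' distribution; `%SS` is the term's share of the total sum of squares about
#' the mean (the residual counts as its own share, so shares sum to 100).
#'
#' A constant response yields zero sums of squares, zero shares and missing
#' p-values rather than 0/0 statistics.
#'
#' @param y numeric response, one value per metadata row, no missing values.
#' @param meta metadata tibble (rows aligned with `y`).
#' @param categorical,continuous character vectors naming the model terms.
#' @return a tibble with one row per term plus a `"Residuals"` row:
#'   `term`, `df`, `sumsq`, `pct_ss`, `statistic`, `p_value`.
#' @export
fit_feature <- function(y, meta, categorical, continuous = character()) {
  if (anyNA(y)) wf_stop("response contains missing values; exclude or impute first")
  df <- build_model_frame(meta, categorical, continuous)
  if (nrow(df) != length(y)) wf_stop("length(y) != number of samples")
  terms <- c(continuous, categorical)
  form <- as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  df$.y <- y
  ss_total <- sum((y - mean(y))^2)
  if (ss_total < 1e-12) {
    fit0 <- lm(form, data = df)
    dfs <- attr(stats::model.matrix(fit0), "assign")
    term_df <- vapply(seq_along(terms), function(i) sum(dfs == i), integer(1))
    return(tibble(
      term = c(terms, "Residuals"),
      df = c(term_df, length(y) - 1L - sum(term_df)),
      sumsq = 0, pct_ss = 0,
      statistic = NA_real_, p_value = NA_real_))
  }
  fit <- lm(form, data = df)
  if (anyNA(coef(fit))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    wf_stop("rank-deficient (confounded) design; aliased coefficients: ",
            paste(aliased, collapse = ", "))
  }
  if (df.residual(fit) == 0) {
    wf_stop("zero residual degrees of freedom: model is saturated")
  }
  an <- anova(fit)
  tibble(
    term = rownames(an),
    df = as.integer(an$Df),
    sumsq = an$`Sum Sq`,
    pct_ss = 100 * an$`Sum Sq` / sum(an$`Sum Sq`),
    statistic = an$`F value`,
    p_value = an$`Pr(>F)`)
}

#' Run the per-feature sum-of-squares analysis stage
#'
#' Fits [fit_feature()] for every feature of a complete expression table,
#' adjusts raw p-values across features separately within each model term,
#' summarizes the distribution of `%SS` per term and counts significant
#' features at level `alpha` before and after adjustment. Features whose fit
#' fails (e.g. confounded within a degenerate response) are excluded with a
#' logged reason; constant features are retained in the table but excluded
#' from significance counts.
#'
#' @param expr a complete expression table (post exclusion or imputation).
#' @param meta metadata tibble aligned with the expression columns.
#' @param categorical,continuous model terms (see [fit_feature()]).
#' @param alpha significance level in (0, 1).
#' @param adjust_method adjustment passed to [adjust_pvalues()].
#' @return an object of class `wfvar_model`: a list with `table` (one row
#'   per feature x term, with `p_adjusted`), `ss_summary` (per-term min, Q1,
#'   median, mean, Q3, max of `%SS`), `counts` (significant features per
#'   term, raw and adjusted), `skipped` (features excluded from fitting),
#'   `alpha` and `adjust_method`. `tidy()` returns the long table,
#'   `glance()` a one-row overview, `autoplot()` the `%SS` box plot.
#' @export
run_model_stage <- function(expr, meta, categorical, continuous = character(),
                            alpha = 0.05, adjust_method = "BH") {
  stopifnot(is.numeric(alpha), length(alpha) == 1)
  if (!(alpha > 0 && alpha < 1)) wf_stop("alpha must lie in (0, 1)")
  adjust_method <- match.arg(adjust_method, names(ADJUST_METHODS))
  expr <- align_samples(expr, meta)
  m <- expr_values(expr)
  if (anyNA(m)) {
    wf_stop("expression table still contains missing values; ",
            "run the exclude or impute step first")
  }
  fits <- vector("list", nrow(m))
  skipped <- character(0)
  for (i in seq_len(nrow(m))) {
    res <- tryCatch(fit_feature(m[i, ], meta, categorical, continuous),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped <- c(skipped, setNames(res, rownames(m)[i]))
    } else {
      fits[[i]] <- dplyr::bind_cols(tibble(feature_id = rownames(m)[i]), res)
    }
  }
  table <- dplyr::bind_rows(fits)
  if (nrow(table) == 0) wf_stop("no feature could be fitted")
  table <- table |>
    group_by(.data$term) |>
    mutate(p_adjusted = ifelse(.data$term == "Residuals", NA_real_,
                               adjust_pvalues(.data$p_value, adjust_method))) |>
    ungroup()
  term_order <- c(continuous, categorical, "Residuals")
  table$term <- factor(table$term, levels = term_order)
  ss_summary <- table |>
    group_by(.data$term) |>
    summarise(
      min = min(.data$pct_ss), q1 = quantile(.data$pct_ss, 0.25),
      median = median(.data$pct_ss), mean = mean(.data$pct_ss),
      q3 = quantile(.data$pct_ss, 0.75), max = max(.data$pct_ss),
      .groups = "drop")
  counts <- table |>
    filter(.data$term != "Residuals") |>
    group_by(.data$term) |>
    summarise(
      n_features = dplyr::n(),
      n_significant_raw = sum(.data$p_value < alpha, na.rm = TRUE),
      n_significant_adjusted = sum(.data$p_adjusted < alpha, na.rm = TRUE),
      .groups = "drop")
  structure(
    list(table = table, ss_summary = ss_summary, counts = counts,
         skipped = skipped, alpha = alpha, adjust_method = adjust_method),
    class = "wfvar_model")
}

#' @export
tidy.wfvar_model <- function(x, ...) x$table

#' @export
glance.wfvar_model <- function(x, ...) {
  tibble(
    n_features = dplyr::n_distinct(x$table$feature_id),
    n_terms = dplyr::n_distinct(x$table$term) - 1L,
    n_skipped = length(x$skipped),
    alpha = x$alpha,
    adjust_method = x$adjust_method)
}

#' @export
print.wfvar_model <- function(x, ...) {
  cat("Per-feature ANOVA/ANCOVA sum-of-squares decomposition\n")
  cat("  features:", dplyr::n_distinct(x$table$feature_id),
      " terms:", paste(setdiff(levels(x$table$term), "Residuals"),
                       collapse = ", "), "\n")
  cat("  alpha:", x$alpha, " adjustment:", x$adjust_method, "\n\n")
  cat("%SS summary:\n")
  print(as.data.frame(x$ss_summary), row.names = FALSE, digits = 4)
  cat("\nSignificant features:\n")
  print(as.data.frame(x$counts), row.names = FALSE)
  invisible(x)
}

#' Wide per-feature sum-of-squares table
#'
#' Reshapes the long model table into the downloadable layout: one row per
#' feature with an `SS`, `%SS`, `p` and `p_adj` column group per term.
#'
#' @param model a `wfvar_model` from [run_model_stage()].
#' @return a wide tibble, one row per feature.
#' @export
ss_wide_table <- function(model) {
  model$table |>
    mutate(term = as.character(.data$term)) |>
    select("feature_id", "term", "sumsq", "pct_ss", "p_value", "p_adjusted") |>
    tidyr::pivot_wider(
      names_from = "term",
      values_from = c("sumsq", "pct_ss", "p_value", "p_adjusted"),
      names_glue = "{term}_{.value}")
}
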