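#' Per-group coefficient of variation
#'
#' For every feature and every level of each selected categorical variable,
#' computes the coefficient of variation, 100 x sample SD / sample mean,
#' over the samples at that level, on whatever scale the expression table
#' currently carries (the same preprocessed matrix that enters the model
#' stage, so the SS and CV rankings are comparable; note that the CV of
#' log-scale values is not the CV of raw intensities). Cells whose group
#' mean is not positive (<= 1e-12) or that have fewer than 2 observations
#' are missing rather than infinite; a level with fewer than 2 samples
#' yields an all-missing column with a warning.
#'
#' @param expr a complete expression table.
#' @param meta metadata tibble aligned with the expression columns.
#' @param vars categorical variable names to analyze.
#' @return a tidy tibble with columns `feature_id`, `variable`, `level`,
#'   `cv` (percent).
#' @examples
#' expr <- as_expression(matrix(c(2, 4, 6), 1, 3,
#'   dimnames = list("F1", c("S1", "S2", "S3"))))
#' meta <- tibble::tibble(sample_id = c("S1", "S2", "S3"), g = "A")
#' compute_cv(expr, meta, "g")  # CV = 50
#' @export
compute_cv <- function(expr, meta, vars) {
  expr <- align_samples(expr, meta)
  m <- expr_values(expr)
  miss <- setdiff(vars, names(meta))
  if (length(miss)) wf_stop("variable(s) not in metadata: ",
                            paste(miss, collapse = ", "))
  out <- purrr::map(vars, function(v) {
    levels <- unique(as.character(meta[[v]]))
    purrr::map(levels, function(l) {
      sel <- which(as.character(meta[[v]]) == l)
      if (length(sel) < 2) {
        wf_warn("level '", l, "' of '", v, "' has fewer than 2 samples; ",
                "its CV column is all-missing")
        cv <- rep(NA_real_, nrow(m))
      } else {
        mu <- rowMeans(m[, sel, drop = FALSE])
        s <- apply(m[, sel, drop = FALSE], 1, sd)
        cv <- unname(ifelse(mu > 1e-12, 100 * s / mu, NA_real_))
      }
      tibble(feature_id = rownames(m), variable = v, level = l, cv = cv)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out
}

#' Summarize a CV table across features
#'
#' @param cv_table output of [compute_cv()].
#' @return per (variable, level): min, Q1, median, mean, Q3, max of the CV
#'   across features, skipping missing cells; all-missing columns yield
#'   all-missing summary rows.
#' @export
summarize_cv <- function(cv_table) {
  if (nrow(cv_table) == 0) wf_stop("empty CV table")
  q <- function(x, p) if (all(is.na(x))) NA_real_ else
    quantile(x, p, na.rm = TRUE, names = FALSE)
  stat <- function(f, x) if (all(is.na(x))) NA_real_ else f(x, na.rm = TRUE)
  cv_table |>
    group_by(.data$variable, .data$level) |>
    summarise(
      min = stat(min, .data$cv), q1 = q(.data$cv, 0.25),
      median = stat(median, .data$cv), mean = stat(mean, .data$cv),
      q3 = q(.data$cv, 0.75), max = stat(max, .data$cv),
      .groups = "drop")
}

#' Wide per-feature CV table
#'
#' One row per feature, one `variable.level` column per group — the
#' downloadable layout of the CV analysis.
#'
#' @inheritParams summarize_cv
#' @return a wide tibble.
#' @export
cv_wide_table <- function(cv_table) {
  cv_table |>
    tidyr::pivot_wider(names_from = c("variable", "level"),
                       values_from = "cv", names_sep = ".")
}
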