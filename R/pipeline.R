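NORM_METHODS <- c("log2", "QN", "VSN", "none")

#' Analysis configuration
#'
#' Collects every user choice of the workflow-variability analysis: the
#' feature level at which to analyze, the peptide-to-protein aggregation
#' summary, whether to exclude or impute missing values (and with which
#' imputer), the transformation/normalization option and whether it is
#' applied group-wise, the model variables, the significance level and the
#' multiple-testing adjustment.
#'
#' @param feature_type level of analysis, `"protein"` or `"peptide"`.
#' @param aggregation `"mean"`, `"median"`, `"sum"` or `"maximum"`.
#' @param analysis_method `"exclude_mv"` (drop features with any missing
#'   value) or `"impute_mv"`.
#' @param imputation `"SVD"` or `"KNN"`; consulted only when
#'   `analysis_method = "impute_mv"`.
#' @param knn_k,svd_rank tuning of the two imputers.
#' @param normalization `"log2"`, `"QN"`, `"VSN"` or `"none"`.
#' @param groupwise apply QN/VSN and imputation per `Norm_Imp_Group`?
#' @param categorical_vars,continuous_vars model variables (metadata column
#'   names).
#' @param alpha significance level in (0, 1); default 0.05.
#' @param adjust_method one of `"BH"` (default), `"bonferroni"`, `"holm"`,
#'   `"hochberg"`, `"hommel"`, `"BY"`.
#' @param seed integer seed recorded with the run.
#' @return a validated `wfvar_config` list.
#' @export
analysis_config <- function(feature_type = c("protein", "peptide"),
                            aggregation = c("mean", "median", "sum", "maximum"),
                            analysis_method = c("exclude_mv", "impute_mv"),
                            imputation = c("SVD", "KNN"),
                            knn_k = 10L, svd_rank = 2L,
                            normalization = NORM_METHODS,
                            groupwise = FALSE,
                            categorical_vars = character(),
                            continuous_vars = character(),
                            alpha = 0.05, adjust_method = "BH",
                            seed = 1L) {
  cfg <- list(
    feature_type = match.arg(feature_type),
    aggregation = match.arg(aggregation),
    analysis_method = match.arg(analysis_method),
    imputation = match.arg(imputation),
    knn_k = as.integer(knn_k), svd_rank = as.integer(svd_rank),
    normalization = match.arg(normalization),
    groupwise = isTRUE(groupwise),
    categorical_vars = as.character(categorical_vars),
    continuous_vars = as.character(continuous_vars),
    alpha = as.numeric(alpha),
    adjust_method = match.arg(adjust_method, names(ADJUST_METHODS)),
    seed = as.integer(seed))
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) wf_stop("alpha must lie in (0, 1)")
  if (cfg$knn_k < 1 || cfg$svd_rank < 1) wf_stop("knn_k and svd_rank must be >= 1")
  structure(cfg, class = "wfvar_config")
}

#' Load an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config()]; unknown keys are an
#' error, omitted keys take their defaults (alpha 0.05, BH adjustment,
#' global normalization/imputation).
#'
#' @param path path to a YAML file; `NULL` yields the all-defaults config.
#' @param ... overrides applied on top of the file (e.g. from CLI flags).
#' @return a `wfvar_config`.
#' @export
load_config <- function(path = NULL, ...) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  overrides <- list(...)
  vals <- modifyList(vals, overrides)
  unknown <- setdiff(names(vals), names(formals(analysis_config)))
  if (length(unknown)) {
    wf_stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, vals)
}

#' Flat key-value echo of a configuration
#'
#' @param config a `wfvar_config`.
#' @return tibble with columns `setting` and `value` (character); parse it
#'   back with [config_from_echo()].
#' @export
echo_inputs <- function(config) {
  stopifnot(inherits(config, "wfvar_config"))
  tibble(
    setting = names(unclass(config)),
    value = unname(vapply(unclass(config), function(v)
      paste(as.character(v), collapse = ","), character(1))))
}

#' @rdname echo_inputs
#' @param echo a tibble as produced by [echo_inputs()].
#' @export
config_from_echo <- function(echo) {
  vals <- setNames(as.list(echo$value), echo$setting)
  split_chr <- function(x) if (identical(x, "")) character() else
    strsplit(x, ",", fixed = TRUE)[[1]]
  vals$knn_k <- as.integer(vals$knn_k)
  vals$svd_rank <- as.integer(vals$svd_rank)
  vals$groupwise <- as.logical(vals$groupwise)
  vals$alpha <- as.numeric(vals$alpha)
  vals$seed <- as.integer(vals$seed)
  vals$categorical_vars <- split_chr(vals$categorical_vars)
  vals$continuous_vars <- split_chr(vals$continuous_vars)
  do.call(analysis_config, vals)
}

#' @export
print.wfvar_config <- function(x, ...) {
  cat("Workflow-variability analysis configuration:\n")
  e <- echo_inputs(x)
  cat(sprintf("  %-16s %s\n", e$setting, e$value), sep = "")
  invisible(x)
}

#' Run the full workflow-variability pipeline
#'
#' Executes, in order: sample alignment; missing-value handling and
#' normalization — in exclude mode features with any missing value are
#' dropped first, then the data is normalized, then aggregated if needed; in
#' impute mode the data is normalized first, then imputed at the level it
#' was provided, then aggregated — followed by the per-feature
#' sum-of-squares model stage, the CV stage and (when `outdir` is given) all
#' result tables, plots and the input echo.
#'
#' @param expression an expression table (e.g. from [read_expression()] or
#'   [simulate_dataset()]).
#' @param metadata a metadata tibble with matching `sample_id`s.
#' @param config a `wfvar_config` from [analysis_config()]; its
#'   `categorical_vars` / `continuous_vars` select the model.
#' @param outdir optional output directory for tables and plots.
#' @return a `wfvar_result` list: `processed` (expression table entering the
#'   analyses), `model` (`wfvar_model`), `cv_table`, `cv_summary`, `config`,
#'   `log` (per-stage feature/sample counts) and `files` (paths written).
#' @export
run_pipeline <- function(expression, metadata, config = analysis_config(),
                         outdir = NULL) {
  stopifnot(inherits(config, "wfvar_config"))
  set.seed(config$seed)
  log <- list()
  note <- function(stage, expr) {
    log[[length(log) + 1]] <<- tibble(
      stage = stage, n_features = nrow(expr),
      n_samples = length(sample_ids(expr)),
      n_missing = sum(is.na(expr_values(expr))))
  }
  expr <- align_samples(expression, metadata)
  note("input", expr)

  needs_aggregation <- config$feature_type == "protein" &&
    feature_type(expr) == "peptide"

  if (config$analysis_method == "exclude_mv") {
    keep <- complete.cases(expr_values(expr))
    if (!any(keep)) {
      wf_stop("no features remain after excluding missing values; ",
              "consider the impute analysis method")
    }
    expr <- structure(expr[keep, ], scale = expr_scale(expr),
                      feature_type = feature_type(expr))
    note("exclude_missing", expr)
    expr <- apply_normalization(expr, config$normalization, metadata,
                                config$groupwise)
    note("normalize", expr)
  } else {
    expr <- apply_normalization(expr, config$normalization, metadata,
                                config$groupwise)
    note("normalize", expr)
    if (expr_scale(expr) == "raw") {
      # imputation distances/low-rank structure assume a log-like scale
      expr <- set_scale(expr, "log2")
    }
    expr <- apply_imputation(expr, config$imputation, metadata,
                             config$groupwise, k = config$knn_k,
                             rank = config$svd_rank)
    note("impute", expr)
  }
  if (needs_aggregation) {
    expr <- aggregate_features(expr, config$aggregation, by = "protein_id")
    note("aggregate", expr)
  } else if (anyDuplicated(expr$feature_id)) {
    expr <- aggregate_features(expr, config$aggregation, by = "feature_id")
    note("merge_redundant", expr)
  }

  model <- run_model_stage(expr, metadata, config$categorical_vars,
                           config$continuous_vars, alpha = config$alpha,
                           adjust_method = config$adjust_method)
  cv_table <- compute_cv(expr, metadata, config$categorical_vars)
  cv_summary <- summarize_cv(cv_table)

  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    tabs <- list(
      inputs.csv = echo_inputs(config),
      ss_table.csv = ss_wide_table(model),
      ss_summary.csv = model$ss_summary,
      significance_counts.csv = model$counts,
      cv_table.csv = cv_wide_table(cv_table),
      cv_summary.csv = cv_summary,
      stage_log.csv = dplyr::bind_rows(log))
    for (nm in names(tabs)) {
      write_result_table(tabs[[nm]], file.path(outdir, nm))
    }
    files <- c(file.path(outdir, names(tabs)),
               write_plots(expr, model, cv_table, outdir))
  }
  structure(
    list(processed = expr, model = model, cv_table = cv_table,
         cv_summary = cv_summary, config = config,
         log = dplyr::bind_rows(log), files = files),
    class = "wfvar_result")
}

#' @export
print.wfvar_result <- function(x, ...) {
  cat("Workflow-variability analysis\n")
  cat("  pipeline stages:\n")
  print(as.data.frame(x$log), row.names = FALSE)
  cat("\n")
  print(x$model)
  cat("\nCV summary (%):\n")
  print(as.data.frame(x$cv_summary), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.wfvar_result <- function(x, ...) x$model$table

#' @export
glance.wfvar_result <- function(x, ...) {
  dplyr::bind_cols(glance(x$model),
                   tibble(n_samples = length(sample_ids(x$processed)),
                          normalization = x$config$normalization,
                          analysis_method = x$config$analysis_method))
}

#' @export
autoplot.wfvar_result <- function(object, type = c("ss", "cv", "box",
                                                   "density", "cor"), ...) {
  switch(match.arg(type),
         ss = plot_ss(object$model),
         cv = plot_cv(object$cv_table),
         box = plot_sample_box(object$processed),
         density = plot_sample_density(object$processed),
         cor = plot_sample_cor(object$processed))
}
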