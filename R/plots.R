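expr_long <- function(expr) {
  tidyr::pivot_longer(as_tibble(expr[c("feature_id", sample_ids(expr))]),
                      -"feature_id",
                      names_to = "sample_id", values_to = "intensity")
}

#' Exploratory plots of a (preprocessed) expression table
#'
#' `plot_sample_box()` draws one intensity box per sample,
#' `plot_sample_density()` overlays per-sample intensity densities and
#' `plot_sample_cor()` draws the sample-by-sample Pearson correlation
#' heatmap computed on pairwise-complete observations. All three are pure
#' readers returning ggplot objects.
#'
#' @param expr an expression table.
#' @return a ggplot object.
#' @export
plot_sample_box <- function(expr) {
  expr_long(expr) |>
    ggplot(aes(x = .data$sample_id, y = .data$intensity)) +
    geom_boxplot(outlier.size = 0.4, na.rm = TRUE) +
    labs(x = NULL, y = paste0("intensity (", expr_scale(expr), ")")) +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' @rdname plot_sample_box
#' @export
plot_sample_density <- function(expr) {
  expr_long(expr) |>
    ggplot(aes(x = .data$intensity, colour = .data$sample_id)) +
    geom_density(na.rm = TRUE, show.legend = ncol(expr) <= 14) +
    labs(x = paste0("intensity (", expr_scale(expr), ")"), y = "density") +
    theme_bw()
}

#' @rdname plot_sample_box
#' @export
plot_sample_cor <- function(expr) {
  cc <- cor(expr_values(expr), use = "pairwise.complete.obs")
  ids <- colnames(cc)
  as_tibble(cc, .name_repair = "minimal") |>
    mutate(sample_1 = factor(ids, levels = ids)) |>
    tidyr::pivot_longer(-"sample_1", names_to = "sample_2",
                        values_to = "correlation") |>
    mutate(sample_2 = factor(.data$sample_2, levels = ids)) |>
    ggplot(aes(x = .data$sample_1, y = .data$sample_2,
               fill = .data$correlation)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = stats::median(cc[lower.tri(cc)])) +
    labs(x = NULL, y = NULL, fill = "Pearson r") +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Result plots: %SS by variable and CV by group
#'
#' `plot_ss()` draws one `%SS` box per model term (including the residual);
#' `plot_cv()` one CV box per (variable, level) pair.
#'
#' @param model a `wfvar_model` from [run_model_stage()].
#' @return a ggplot object.
#' @export
plot_ss <- function(model) {
  model$table |>
    ggplot(aes(x = .data$term, y = .data$pct_ss)) +
    geom_boxplot(outlier.size = 0.4, na.rm = TRUE) +
    labs(x = "model term", y = "% of total sum of squares") +
    theme_bw()
}

#' @rdname plot_ss
#' @param cv_table output of [compute_cv()].
#' @export
plot_cv <- function(cv_table) {
  if (nrow(cv_table) == 0 || all(is.na(cv_table$cv))) {
    wf_warn("CV table empty or all-missing; no CV plot drawn")
    return(invisible(NULL))
  }
  cv_table |>
    ggplot(aes(x = .data$level, y = .data$cv)) +
    geom_boxplot(outlier.size = 0.4, na.rm = TRUE) +
    facet_grid(cols = ggplot2::vars(.data$variable), scales = "free_x",
               space = "free_x") +
    labs(x = "group (level within categorical variable)",
         y = "coefficient of variation (%)") +
    theme_bw()
}

#' @export
autoplot.wfvar_model <- function(object, ...) plot_ss(object)

save_plot_files <- function(p, outdir, stem, width = 7, height = 5) {
  if (is.null(p)) return(character(0))
  paths <- file.path(outdir, paste0(stem, c(".png", ".pdf")))
  ggsave(paths[1], p, width = width, height = height, dpi = 150)
  ggsave(paths[2], p, width = width, height = height)
  paths
}

#' Write the exploratory and result plots of a run to disk
#'
#' Saves `boxplot_samples`, `density_samples`, `corr_heatmap`, `ss_boxplot`
#' and `cv_boxplot` (each as PNG and PDF) under `outdir`.
#'
#' @param expr the preprocessed expression table.
#' @param model a `wfvar_model` (or NULL to skip the SS plot).
#' @param cv_table a CV table (or NULL to skip the CV plot).
#' @param outdir output directory, created if absent.
#' @return invisible character vector of the files written.
#' @export
write_plots <- function(expr, model = NULL, cv_table = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    save_plot_files(plot_sample_box(expr), outdir, "boxplot_samples"),
    save_plot_files(plot_sample_density(expr), outdir, "density_samples"),
    save_plot_files(plot_sample_cor(expr), outdir, "corr_heatmap",
                    width = 7, height = 6))
  if (!is.null(model)) {
    files <- c(files, save_plot_files(plot_ss(model), outdir, "ss_boxplot"))
  }
  if (!is.null(cv_table)) {
    files <- c(files,
               save_plot_files(plot_cv(cv_table), outdir, "cv_boxplot"))
  }
  invisible(files)
}
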