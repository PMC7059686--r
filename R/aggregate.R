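agg_funs <- list(
  mean    = function(x) mean(x),
  median  = function(x) median(x),
  sum     = function(x) sum(x),
  maximum = function(x) max(x)
)

#' Aggregate peptide-level features to protein level
#'
#' Collapses rows sharing a protein id (or redundant duplicate feature ids)
#' with a chosen summary: mean, median, sum or maximum. Within each output
#' cell the summary is taken over non-missing contributing values only; a
#' cell is missing iff all contributing values are missing. Output rows
#' appear in first-appearance order of the grouping key and the scale tag of
#' the input is preserved.
#'
#' @param expr an expression table.
#' @param method one of `"mean"`, `"median"`, `"sum"`, `"maximum"`.
#' @param by grouping column: `"protein_id"` (default, peptide-to-protein
#'   roll-up) or `"feature_id"` (merge redundant duplicate features).
#' @return a protein-level expression table (one row per distinct group key,
#'   no `protein_id` column when rolled up by protein).
#' @examples
#' expr <- as_expression(tibble::tibble(
#'   protein_id = c("P1", "P1"), feature_id = c("pep1", "pep2"),
#'   S1 = c(2, 4), S2 = c(NA, 5)))
#' aggregate_features(expr, "mean")
#' @export
aggregate_features <- function(expr,
                               method = c("mean", "median", "sum", "maximum"),
                               by = c("protein_id", "feature_id")) {
  method <- match.arg(method)
  by <- match.arg(by)
  if (nrow(expr) == 0) wf_stop("cannot aggregate an empty expression table")
  if (by == "protein_id" && !"protein_id" %in% names(expr)) {
    wf_stop("no `protein_id` column: peptide-to-protein aggregation needs one")
  }
  if (anyNA(expr[[by]])) wf_stop("missing values in grouping key '", by, "'")
  f <- agg_funs[[method]]
  samples <- sample_ids(expr)
  keys <- expr[[by]]
  ord <- unique(keys)                    # first-appearance order
  m <- expr_values(expr)
  out <- matrix(NA_real_, length(ord), length(samples),
                dimnames = list(ord, samples))
  idx <- split(seq_along(keys), factor(keys, levels = ord))
  for (j in seq_along(samples)) {
    col <- m[, j]
    out[, j] <- vapply(idx, function(i) {
      v <- col[i][!is.na(col[i])]
      if (length(v) == 0) NA_real_ else f(v)
    }, numeric(1))
  }
  ids <- tibble(feature_id = ord)
  out_type <- "protein"
  if (by == "feature_id" && "protein_id" %in% names(expr)) {
    # merging redundant peptides: keep each feature's protein mapping
    ids$protein_id <- unname(vapply(idx, function(i) expr$protein_id[i[1]],
                                    character(1)))
    ids <- ids[c("protein_id", "feature_id")]
    out_type <- feature_type(expr)
  }
  res <- dplyr::bind_cols(ids, as_tibble(out, .name_repair = "minimal"))
  structure(as_tibble(res), scale = expr_scale(expr), feature_type = out_type)
}
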