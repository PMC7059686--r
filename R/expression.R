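#' Expression tables
#'
#' An expression table is an ordinary tibble with one row per feature
#' (peptide or protein) and one numeric column per sample, plus a
#' `feature_id` character column and, for peptide-level data, a `protein_id`
#' column mapping each peptide to its protein. Two attributes travel with the
#' tibble: `scale`, one of `"raw"`, `"log2"` or `"glog"`, recording the
#' current transform state, and `feature_type`, `"peptide"` or `"protein"`.
#'
#' @param x a numeric matrix (features x samples, with dimnames) or a data
#'   frame containing a `feature_id` column, optionally `protein_id`, and
#'   numeric sample columns.
#' @param scale transform state of the values, `"raw"`, `"log2"` or `"glog"`.
#' @param feature_type `"protein"` or `"peptide"`; defaults to `"peptide"`
#'   when a `protein_id` column is present, `"protein"` otherwise.
#' @return a tibble with class attributes as described above.
#' @examples
#' m <- matrix(2^rnorm(12, 20), 4, 3,
#'             dimnames = list(paste0("P", 1:4), paste0("S", 1:3)))
#' expr <- as_expression(m)
#' sample_ids(expr)
#' expr_scale(expr)
#' @export
as_expression <- function(x, scale = c("raw", "log2", "glog"),
                          feature_type = NULL) {
  scale <- match.arg(scale)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("F", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- paste0("S", seq_len(ncol(x)))
    x <- dplyr::bind_cols(tibble(feature_id = rownames(x)),
                          as_tibble(x, .name_repair = "minimal"))
  }
  x <- as_tibble(x)
  if (!"feature_id" %in% names(x)) {
    wf_stop("expression table needs a `feature_id` column")
  }
  x$feature_id <- as.character(x$feature_id)
  if ("protein_id" %in% names(x)) x$protein_id <- as.character(x$protein_id)
  ids <- c("feature_id", if ("protein_id" %in% names(x)) "protein_id")
  x <- x[c(ids, setdiff(names(x), ids))]
  feature_type <- feature_type %||%
    if ("protein_id" %in% names(x)) "peptide" else "protein"
  out <- structure(x, scale = scale, feature_type = feature_type)
  validate_expression(out)
  out
}

#' @rdname as_expression
#' @param expr an expression table.
#' @export
expr_scale <- function(expr) attr(expr, "scale") %||% "raw"

#' @rdname as_expression
#' @export
feature_type <- function(expr) {
  attr(expr, "feature_type") %||%
    if ("protein_id" %in% names(expr)) "peptide" else "protein"
}

#' @rdname as_expression
#' @export
sample_ids <- function(expr) setdiff(names(expr), c("feature_id", "protein_id"))

set_scale <- function(expr, scale) {
  attr(expr, "scale") <- scale
  expr
}

#' Extract the intensity values of an expression table as a matrix
#'
#' @param expr an expression table (see [as_expression()]).
#' @return numeric matrix, features x samples, with feature ids as rownames.
#' @export
expr_values <- function(expr) {
  m <- as.matrix(expr[sample_ids(expr)])
  storage.mode(m) <- "double"
  rownames(m) <- expr$feature_id
  m
}

## replace the sample columns wholesale, keeping ids and attributes
set_expr_values <- function(expr, m) {
  stopifnot(nrow(m) == nrow(expr))
  expr[colnames(m)] <- as_tibble(m, .name_repair = "minimal")
  expr
}

validate_expression <- function(expr) {
  samples <- sample_ids(expr)
  if (length(samples) == 0) wf_stop("expression table has zero samples")
  if (anyDuplicated(samples)) wf_stop("sample ids must be unique")
  bad <- samples[!vapply(expr[samples], is.numeric, logical(1))]
  if (length(bad)) {
    wf_stop("non-numeric sample column(s): ", paste(bad, collapse = ", "))
  }
  if (expr_scale(expr) == "raw") {
    m <- expr_values(expr)
    neg <- which(!is.na(m) & m < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      wf_stop("negative raw intensity at feature '",
              expr$feature_id[neg[1, 1]], "', sample '",
              colnames(m)[neg[1, 2]], "'")
    }
  }
  invisible(expr)
}
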