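MISSING_TOKENS <- c("", "na", "nan")

sniff_delim <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (length(line) == 0) wf_stop("file '", path, "' is empty")
  if (lengths(regmatches(line, gregexpr("\t", line))) >=
      lengths(regmatches(line, gregexpr(",", line)))) "\t" else ","
}

parse_intensity_cols <- function(tbl, id_cols) {
  samples <- setdiff(names(tbl), id_cols)
  if (length(samples) == 0) wf_stop("expression file has zero sample columns")
  for (s in samples) {
    raw <- trimws(as.character(tbl[[s]]))
    miss <- is.na(raw) | tolower(raw) %in% MISSING_TOKENS
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!miss & is.na(val))
    if (length(bad)) {
      wf_stop("non-numeric intensity '", raw[bad[1]], "' at row ", bad[1],
              " (feature '", tbl[[id_cols[length(id_cols)]]][bad[1]],
              "'), column '", s, "'")
    }
    val[miss] <- NA_real_
    tbl[[s]] <- val
  }
  tbl
}

#' Read an expression matrix from a delimited text file
#'
#' Protein-level files carry columns `[Protein, <samples...>]`; peptide-level
#' files carry `[Protein, Peptide, <samples...>]`. The delimiter (tab or
#' comma) is sniffed from the header line. Empty cells, `NA` and `NaN`
#' (case-insensitive) are read as missing. Values must be non-negative raw
#' intensities; duplicate feature ids are permitted at read time and are
#' merged by [aggregate_features()].
#'
#' @param path path to a CSV/TSV expression file.
#' @param feature_type `"protein"` or `"peptide"` — the level at which the
#'   file quantifies features.
#' @return an expression table (see [as_expression()]) with scale `"raw"`.
#' @export
read_expression <- function(path, feature_type = c("protein", "peptide")) {
  feature_type <- match.arg(feature_type)
  if (!file.exists(path)) wf_stop("cannot read expression file '", path, "'")
  delim <- sniff_delim(path)
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), na = character(), progress = FALSE)
  if (feature_type == "peptide") {
    if (ncol(tbl) < 3) wf_stop("peptide file needs [Protein, Peptide, samples...]")
    names(tbl)[1:2] <- c("protein_id", "feature_id")
  } else {
    names(tbl)[1] <- "feature_id"
  }
  id_cols <- intersect(c("protein_id", "feature_id"), names(tbl))
  tbl <- parse_intensity_cols(tbl, id_cols)
  as_expression(tbl, scale = "raw",
                feature_type = feature_type)
}

#' Read the sample-metadata (additional information) file
#'
#' The first column holds sample ids; every other column is a candidate
#' analysis variable. A column is typed continuous iff every non-missing
#' entry parses as a number, categorical otherwise. A column literally named
#' `Norm_Imp_Group` is lifted out of the candidate pool and used for
#' group-wise normalization/imputation.
#'
#' @param path path to a CSV/TSV metadata file.
#' @return a tibble with first column `sample_id`; the typing of each
#'   variable is available through [metadata_variables()].
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) wf_stop("cannot read metadata file '", path, "'")
  delim <- sniff_delim(path)
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), na = character(), progress = FALSE)
  names(tbl)[1] <- "sample_id"
  if (anyDuplicated(tbl$sample_id)) {
    wf_stop("duplicate sample ids: ",
            paste(unique(tbl$sample_id[duplicated(tbl$sample_id)]),
                  collapse = ", "))
  }
  for (v in setdiff(names(tbl), "sample_id")) {
    raw <- trimws(tbl[[v]])
    miss <- is.na(raw) | tolower(raw) %in% MISSING_TOKENS
    num <- suppressWarnings(as.numeric(raw))
    if (all(!is.na(num) | miss)) {
      num[miss] <- NA_real_
      tbl[[v]] <- num
    } else {
      raw[miss] <- NA_character_
      tbl[[v]] <- raw
    }
  }
  tbl
}

#' List candidate analysis variables of a metadata table
#'
#' @param meta a metadata tibble from [read_metadata()] (or built in code
#'   with a `sample_id` first column).
#' @return tibble with columns `variable` and `type`
#'   (`"categorical"`/`"continuous"`); `Norm_Imp_Group` is excluded.
#' @export
metadata_variables <- function(meta) {
  vars <- setdiff(names(meta), c("sample_id", "Norm_Imp_Group"))
  tibble(
    variable = vars,
    type = ifelse(unname(vapply(meta[vars], is.numeric, logical(1))),
                  "continuous", "categorical")
  )
}

#' Align expression columns to metadata row order
#'
#' Reorders the sample columns of an expression table to the row order of the
#' metadata; alignment is by sample id, never by position. Values follow
#' their ids; the operation is idempotent.
#'
#' @inheritParams expr_values
#' @param meta metadata tibble with a `sample_id` column.
#' @return the expression table with reordered sample columns.
#' @export
align_samples <- function(expr, meta) {
  es <- sample_ids(expr)
  ms <- meta$sample_id
  if (!setequal(es, ms) || length(es) != length(ms)) {
    wf_stop("sample id mismatch; in expression only: [",
            paste(setdiff(es, ms), collapse = ", "),
            "]; in metadata only: [",
            paste(setdiff(ms, es), collapse = ", "), "]")
  }
  ids <- intersect(c("feature_id", "protein_id"), names(expr))
  out <- expr[c(ids, ms)]
  structure(out, scale = expr_scale(expr), feature_type = feature_type(expr))
}

#' Write a result table to CSV
#'
#' Plain CSV with a header row; missing entries are written as `NA`. A
#' round-trip through [readr::read_csv()] reproduces numeric values to at
#' least 12 significant digits.
#'
#' @param x a data frame / tibble.
#' @param path output file path.
#' @return `x`, invisibly.
#' @export
write_result_table <- function(x, path) {
  readr::write_csv(as_tibble(x), path, na = "NA", progress = FALSE)
  invisible(x)
}
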