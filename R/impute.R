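check_impute_input <- function(m) {
  if (!expr_scale_ok(m)) {
    wf_stop("imputation expects normalized (log2/glog) data")
  }
}

expr_scale_ok <- function(expr) expr_scale(expr) %in% c("log2", "glog")

#' K-nearest-neighbour missing-value imputation
#'
#' For each feature with missing entries, the k nearest donor features are
#' found by Euclidean distance computed over the coordinates observed in
#' both rows and rescaled by the number of shared coordinates (root mean
#' squared difference), so donors need not be complete. Each missing cell is
#' imputed by the inverse-distance-weighted average of donor values at that
#' cell, skipping donors that are also missing there (an exact-duplicate
#' donor at distance zero is copied verbatim). Features missing more than
#' `max_missing_row_frac` of their samples fall back to per-sample column
#' means, as do cells for which no donor carries a value. Ties in distance
#' are broken by feature input order. Appropriate under MCAR/MAR
#' missingness; not designed for left-censored (MNAR) data.
#'
#' @param expr an expression table on a normalized scale (log2/glog).
#' @param k number of donor neighbours.
#' @param max_missing_row_frac rows missing more than this fraction of
#'   samples are column-mean imputed instead of neighbour imputed.
#' @return the expression table with zero missing entries; observed cells
#'   are never modified.
#' @export
impute_knn <- function(expr, k = 10L, max_missing_row_frac = 0.5) {
  check_impute_input(expr)
  m <- expr_values(expr)
  if (!anyNA(m)) return(expr)
  if (any(colSums(!is.na(m)) == 0)) {
    wf_stop("sample(s) entirely missing: ",
            paste(colnames(m)[colSums(!is.na(m)) == 0], collapse = ", "),
            " — no column fallback can be established")
  }
  n <- nrow(m)
  if (k >= n) wf_stop("k = ", k, " but only ", n - 1, " candidate donors exist")
  col_means <- colMeans(m, na.rm = TRUE)
  miss_frac <- rowMeans(is.na(m))
  out <- m
  heavy <- miss_frac > max_missing_row_frac
  for (i in which(heavy)) {
    out[i, is.na(m[i, ])] <- col_means[is.na(m[i, ])]
  }
  todo <- which(!heavy & rowSums(is.na(m)) > 0)
  for (i in todo) {
    xi <- m[i, ]
    diffs <- sweep(m, 2, xi, "-")^2
    shared <- rowSums(!is.na(diffs))
    d2 <- rowMeans(diffs, na.rm = TRUE)   # mean over shared coordinates
    d2[i] <- Inf
    d2[shared == 0] <- Inf
    ord <- order(d2, seq_len(n))          # deterministic tie-break: input order
    nb <- ord[seq_len(min(k, sum(is.finite(d2))))]
    d <- sqrt(d2[nb])
    for (j in which(is.na(xi))) {
      have <- !is.na(m[nb, j])
      if (!any(have)) {
        out[i, j] <- col_means[j]
      } else if (any(have & d == 0)) {
        out[i, j] <- mean(m[nb[have & d == 0], j])
      } else {
        w <- 1 / d[have]
        out[i, j] <- sum(w * m[nb[have], j]) / sum(w)
      }
    }
  }
  set_expr_values(expr, out)
}

#' Iterative low-rank (SVD) missing-value imputation
#'
#' Missing cells are initialized with feature (row) means, then the matrix is
#' repeatedly approximated by its rank-`rank` truncated singular value
#' decomposition and the missing cells are refreshed with the low-rank
#' reconstruction, until the relative change of the imputed cells drops
#' below `tol` or `max_iter` iterations are reached. Observed cells are
#' never modified. Appropriate under MCAR/MAR missingness.
#'
#' @inheritParams impute_knn
#' @param rank rank of the truncated SVD.
#' @param tol relative-change convergence tolerance on the imputed cells.
#' @param max_iter maximum number of SVD refinement iterations; on
#'   non-convergence the current fill is returned with a warning and the
#'   attribute `"svd_converged" = FALSE`.
#' @return the expression table with zero missing entries.
#' @export
impute_svd <- function(expr, rank = 2L, tol = 1e-6, max_iter = 100L) {
  check_impute_input(expr)
  m <- expr_values(expr)
  if (!anyNA(m)) {
    attr(expr, "svd_converged") <- TRUE
    attr(expr, "svd_deltas") <- numeric(0)   # fixpoint: zero iterations
    return(expr)
  }
  if (rank >= min(dim(m))) {
    wf_stop("rank must be < min(n_features, n_samples) = ", min(dim(m)))
  }
  miss <- is.na(m)
  row_means <- rowMeans(m, na.rm = TRUE)
  row_means[is.nan(row_means)] <- mean(m, na.rm = TRUE)  # fully missing rows
  fill <- m
  fill[miss] <- row_means[row(m)[miss]]
  converged <- FALSE
  deltas <- numeric(0)
  for (it in seq_len(max_iter)) {
    sv <- svd(fill, nu = rank, nv = rank)
    recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    new_vals <- recon[miss]
    delta <- sqrt(sum((new_vals - fill[miss])^2)) /
      max(sqrt(sum(fill[miss]^2)), 1e-12)
    fill[miss] <- new_vals
    deltas <- c(deltas, delta)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    wf_warn("SVD imputation did not converge in ", max_iter, " iterations")
  }
  out <- set_expr_values(expr, fill)
  attr(out, "svd_converged") <- converged
  attr(out, "svd_deltas") <- deltas   # successive-fill distances, per iteration
  out
}

#' Apply the configured imputation
#'
#' Dispatches SVD or KNN imputation globally or, with `groupwise = TRUE`,
#' independently on each `Norm_Imp_Group`'s sample subset. Imputation runs
#' at the level at which the data was provided; for peptide data analyzed at
#' protein level the pipeline imputes peptides first and aggregates
#' afterwards.
#'
#' @inheritParams apply_normalization
#' @param method `"SVD"` or `"KNN"`.
#' @param k,rank,max_missing_row_frac,tol,max_iter passed to [impute_knn()] /
#'   [impute_svd()].
#' @return the imputed expression table.
#' @export
apply_imputation <- function(expr, method = c("SVD", "KNN"), meta = NULL,
                             groupwise = FALSE, k = 10L, rank = 2L,
                             max_missing_row_frac = 0.5, tol = 1e-6,
                             max_iter = 100L) {
  method <- match.arg(method)
  impute1 <- function(e) {
    switch(method,
           SVD = impute_svd(e, rank = rank, tol = tol, max_iter = max_iter),
           KNN = impute_knn(e, k = k,
                            max_missing_row_frac = max_missing_row_frac))
  }
  if (!groupwise) return(impute1(expr))
  samples <- sample_ids(expr)
  groups <- norm_imp_groups(meta)[samples]
  if (anyNA(groups)) wf_stop("Norm_Imp_Group missing for some samples")
  m_out <- NULL
  for (g in unique(groups)) {
    sub <- expr[c(intersect(c("feature_id", "protein_id"), names(expr)),
                  samples[groups == g])]
    sub <- structure(sub, scale = expr_scale(expr),
                     feature_type = feature_type(expr))
    m_out <- cbind(m_out, expr_values(impute1(sub)))
  }
  set_expr_values(expr, m_out[, samples, drop = FALSE])
}
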