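#' Log2 transformation
#'
#' Replaces each non-missing raw intensity x by log2(x). Non-positive values
#' cannot be log-transformed and become missing; their count is reported in a
#' warning rather than silently offset, because a pseudo-count would shift
#' every downstream sum-of-squares invisibly.
#'
#' @param expr an expression table on the raw scale.
#' @return the expression table on the `"log2"` scale.
#' @export
log2_transform <- function(expr) {
  if (expr_scale(expr) != "raw") {
    wf_stop("log2_transform expects raw-scale data, got '", expr_scale(expr), "'")
  }
  m <- expr_values(expr)
  bad <- !is.na(m) & m <= 0
  if (any(bad)) {
    wf_warn(sum(bad), " non-positive intensit",
            if (sum(bad) == 1) "y" else "ies",
            " set to missing by log2 transformation")
    m[bad] <- NA_real_
  }
  m <- log2(m)
  set_scale(set_expr_values(expr, m), "log2")
}

#' Quantile normalization
#'
#' Classic mean-of-order-statistics quantile normalization of log2 data:
#' every sample's observed values are replaced by the across-sample mean of
#' order statistics at matching quantiles, so that on complete data all
#' samples share an identical sorted vector. Columns containing missing
#' values are mapped through rank-based interpolation against the reference
#' distribution built from observed values; tied values receive the average
#' of the reference values at their tied ranks. The missingness mask is
#' preserved exactly. Delegates to [limma::normalizeQuantiles()].
#'
#' @param expr an expression table on the log2 scale.
#' @return the quantile-normalized expression table (scale stays `"log2"`).
#' @export
quantile_normalize <- function(expr) {
  if (expr_scale(expr) != "log2") {
    wf_stop("quantile_normalize expects log2-scale data, got '",
            expr_scale(expr), "'")
  }
  m <- expr_values(expr)
  if (ncol(m) < 2) {
    wf_warn("quantile normalization needs >= 2 samples; returning input unchanged")
    return(expr)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  set_expr_values(expr, out)
}

## Negative profile log-likelihood of the glog model
##   h_ks = asinh(a_s + b_s * x_ks) = mu_k + eps,  eps ~ N(0, sigma^2),
## with the Jacobian term so that the objective is minimized by a transform
## that both stabilizes variance and stays data-calibrated. Parameters are
## p = (a_1..a_S, log b_1..log b_S).
vsn_objective <- function(p, m, obs, nobs) {
  S <- ncol(m)
  a <- p[seq_len(S)]
  b <- exp(p[S + seq_len(S)])
  f <- sweep(sweep(m, 2, b, "*"), 2, a, "+")
  h <- asinh(f)
  r <- h - rowMeans(h, na.rm = TRUE)
  rss <- sum(r^2, na.rm = TRUE)
  jac <- sum(colSums(obs) * log(b)) - 0.5 * sum(log1p(f^2), na.rm = TRUE)
  nobs / 2 * log(rss) - jac
}

vsn_gradient <- function(p, m, obs, nobs) {
  S <- ncol(m)
  a <- p[seq_len(S)]
  b <- exp(p[S + seq_len(S)])
  f <- sweep(sweep(m, 2, b, "*"), 2, a, "+")
  h <- asinh(f)
  r <- h - rowMeans(h, na.rm = TRUE)
  rss <- sum(r^2, na.rm = TRUE)
  w <- 1 / (1 + f^2)          # h'(f)^2
  g <- sqrt(w)                # dh/df
  xb <- f - rep(a, each = nrow(m))   # b_s * x_ks
  da <- (nobs / rss) * colSums(r * g, na.rm = TRUE) +
    colSums(f * w, na.rm = TRUE)
  dlb <- (nobs / rss) * colSums(r * g * xb, na.rm = TRUE) -
    colSums(obs) + colSums(f * xb * w, na.rm = TRUE)
  c(da, dlb)
}

#' Variance-stabilizing normalization (glog)
#'
#' Fits, per sample, an affine calibration `(a_s, b_s)` with `b_s > 0` and
#' applies the generalized-log transform `asinh(a_s + b_s x) / log(2)` plus a
#' constant chosen so that at high intensities the transform agrees with
#' `log2(x)` up to an additive constant. The calibration minimizes a
#' profile-likelihood variance-stabilization objective (constant-variance
#' additive error model with the transform Jacobian) by BFGS with an analytic
#' gradient and deterministic initialization from column quartiles, so a
#' pure per-sample scale factor is absorbed and low-intensity variance is
#' damped instead of exploding.
#'
#' @param expr an expression table on the raw scale with at least 2 samples.
#' @param tol relative convergence tolerance of the optimizer.
#' @param max_iter maximum optimizer iterations.
#' @return the transformed expression table (scale `"glog"`); the fitted
#'   calibration is attached as attribute `"vsn_fit"` and can be retrieved
#'   with [vsn_fit()] or tidied with `tidy()`.
#' @export
vsn_normalize <- function(expr, tol = 1e-8, max_iter = 200L) {
  if (expr_scale(expr) != "raw") {
    wf_stop("vsn_normalize expects raw-scale data, got '", expr_scale(expr), "'")
  }
  m <- expr_values(expr)
  if (ncol(m) < 2) wf_stop("VSN needs >= 2 samples")
  if (sum(complete.cases(m)) < 10) {
    wf_stop("fewer than 10 complete features: the VSN fit is unstable; ",
            "consider log2 + quantile normalization instead")
  }
  obs <- !is.na(m)
  nobs <- sum(obs)
  q25 <- apply(m, 2, quantile, probs = 0.25, na.rm = TRUE)
  iqr <- apply(m, 2, IQR, na.rm = TRUE)
  iqr[iqr <= 0] <- max(iqr[iqr > 0], 1)
  b0 <- 1 / iqr
  p0 <- c(-q25 * b0, log(b0))
  opt <- optim(p0, vsn_objective, vsn_gradient, m = m, obs = obs, nobs = nobs,
               method = "BFGS",
               control = list(maxit = max_iter, reltol = tol))
  S <- ncol(m)
  a <- opt$par[seq_len(S)]
  b <- exp(opt$par[S + seq_len(S)])
  fit <- structure(
    list(a = setNames(a, colnames(m)), b = setNames(b, colnames(m)),
         ref_log2b = mean(log2(b)), objective = opt$value,
         converged = opt$convergence == 0),
    class = "wfvar_vsn_fit")
  out <- predict(fit, m)
  res <- set_scale(set_expr_values(expr, out), "glog")
  attr(res, "vsn_fit") <- fit
  res
}

#' @rdname vsn_normalize
#' @export
vsn_fit <- function(expr) attr(expr, "vsn_fit")

#' @export
predict.wfvar_vsn_fit <- function(object, newdata, ...) {
  m <- if (is.matrix(newdata)) newdata else expr_values(newdata)
  f <- sweep(sweep(m, 2, object$b[colnames(m)], "*"), 2,
             object$a[colnames(m)], "+")
  # asinh(b x) ~ log(2 b x) for large x, so dividing by log 2 and removing
  # the average log2(2 b) puts the output on a log2-intensity-like scale
  asinh(f) / log(2) - 1 - object$ref_log2b
}

#' @export
tidy.wfvar_vsn_fit <- function(x, ...) {
  tibble(sample_id = names(x$a), offset = unname(x$a), scale = unname(x$b))
}

#' @export
print.wfvar_vsn_fit <- function(x, ...) {
  cat("VSN calibration for", length(x$a), "samples;",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(objective %.4g)\n", x$objective))
  invisible(x)
}

#' Apply the configured transformation/normalization
#'
#' Dispatches the four options: `"log2"` (log transform only), `"QN"` (log2
#' then quantile normalization), `"VSN"` (glog on raw data) and `"none"`
#' (pass-through, for data the user normalized elsewhere). With
#' `groupwise = TRUE`, QN or VSN runs independently on each
#' `Norm_Imp_Group`'s sample subset and the columns are re-assembled in the
#' original order.
#'
#' @param expr an expression table on the raw scale (unless `method = "none"`).
#' @param method `"log2"`, `"QN"`, `"VSN"` or `"none"`.
#' @param meta metadata tibble; required when `groupwise = TRUE` (must carry
#'   a `Norm_Imp_Group` column).
#' @param groupwise apply QN/VSN independently within each normalization
#'   group?
#' @return the normalized expression table.
#' @export
apply_normalization <- function(expr, method = c("log2", "QN", "VSN", "none"),
                                meta = NULL, groupwise = FALSE) {
  method <- match.arg(method)
  if (method == "none") return(expr)
  if (method == "log2") return(log2_transform(expr))
  if (!groupwise) {
    return(switch(method,
                  QN = quantile_normalize(log2_transform(expr)),
                  VSN = vsn_normalize(expr)))
  }
  samples <- sample_ids(expr)
  groups <- norm_imp_groups(meta)[samples]
  if (anyNA(groups)) wf_stop("Norm_Imp_Group missing for some samples")
  m_out <- NULL
  for (g in unique(groups)) {
    sub <- expr[c(intersect(c("feature_id", "protein_id"), names(expr)),
                  samples[groups == g])]
    sub <- structure(sub, scale = expr_scale(expr),
                     feature_type = feature_type(expr))
    sub <- switch(method,
                  QN = quantile_normalize(log2_transform(sub)),
                  VSN = vsn_normalize(sub))
    m_out <- cbind(m_out, expr_values(sub))
  }
  out <- set_expr_values(expr, m_out[, samples, drop = FALSE])
  set_scale(out, if (method == "VSN") "glog" else "log2")
}

norm_imp_groups <- function(meta) {
  if (is.null(meta) || !"Norm_Imp_Group" %in% names(meta)) {
    wf_stop("group-wise normalization/imputation requires a 'Norm_Imp_Group' ",
            "column in the metadata")
  }
  setNames(as.character(meta$Norm_Imp_Group), meta$sample_id)
}
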