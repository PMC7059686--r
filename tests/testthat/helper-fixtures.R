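# Small fixture builders used across the test files.

rand_expr <- function(n_features = 20, n_samples = 6, seed = 1,
                      scale = "log2", mean = 20, sd = 2) {
  set.seed(seed)
  m <- matrix(rnorm(n_features * n_samples, mean, sd), n_features, n_samples,
              dimnames = list(sprintf("F%03d", seq_len(n_features)),
                              sprintf("S%02d", seq_len(n_samples))))
  if (scale == "raw") m <- 2^(m / 4 + 10)
  as_expression(m, scale = scale)
}

meta_for <- function(expr, ...) {
  tibble::tibble(sample_id = sample_ids(expr), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_sim_yaml <- function() {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("n_proteins: 12", "n_peptides: 30", "replicates: 2",
               "mcar_rate: 0.02"), path)
  path
}

# a small balanced two-factor + covariate design (12 samples)
small_design_meta <- function(seed = 1) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("S%02d", 1:12),
    g1 = rep(c("a", "b"), each = 6),
    g2 = rep(rep(c("x", "y", "z"), each = 2), 2),
    age = rep(c(30, 50), 6))
}
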