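#' Design of the synthetic LC-MS workflow experiment
#'
#' Describes a three-factor balanced design: a two-level workflow step M1
#' (tissue storage, levels A1/A2), a three-level step M2 (tissue extraction,
#' levels B1/B2/B3), biological replicates (subjects) per M1 x M2 cell, and
#' repeated MS runs of each subject, plus subject age as a continuous
#' covariate. Defaults reproduce the 2 x 3 x 3 x 2 = 36-sample layout with
#' 1000 peptides mapping to 200 proteins.
#'
#' Log2-scale intensities follow a protein baseline plus peptide offset plus
#' additive per-protein level, run and age effects plus Gaussian noise whose
#' SD depends on the M1/M2 levels: M2's effect spread is twice M1's (so M2
#' contributes more sum of squares), the age slope is small (least
#' contribution), A1 is 1.5x noisier than A2, and B1/B3 are 1.5x/1.8x
#' noisier than B2 (so B2 is the least-variable extraction option).
#' Missingness is MCAR at `mcar_rate`, optionally plus an
#' intensity-dependent (MNAR) logistic component for robustness studies.
#'
#' @param n_proteins,n_peptides numbers of proteins and peptides; every
#'   protein receives at least one peptide, remaining peptides are assigned
#'   uniformly at random.
#' @param m1_levels,m2_levels level labels of the two workflow steps.
#' @param replicates biological replicates (subjects) per M1 x M2 cell.
#' @param runs MS runs per subject.
#' @param age_range range the subject ages span (years); subjects are
#'   age-matched across design cells — replicate i of every M1 x M2 cell
#'   sits at the i-th evenly spaced age in this range — with per-subject
#'   jitter of SD `age_jitter_sd`, emulating the age-matched allocation of a
#'   designed experiment (and keeping Age near-orthogonal to the factors).
#' @param age_jitter_sd SD (years) of the rounding jitter on the matched
#'   ages.
#' @param baseline_mean,baseline_sd protein log2 abundance distribution.
#' @param peptide_offset_sd SD of the peptide-within-protein log2 offset.
#' @param m1_effect_sd,m2_effect_sd,run_effect_sd per-protein SD of the
#'   level/run effects (log2 units).
#' @param age_slope_sd per-protein SD of the age slope (log2 units / year).
#' @param sigma0 baseline residual SD (log2 units).
#' @param m1_noise_mult,m2_noise_mult named per-level multipliers of
#'   `sigma0`; a sample's residual SD is `sigma0 * m1_mult * m2_mult`.
#' @param mcar_rate probability in \[0, 1) that any cell is missing
#'   completely at random.
#' @param mnar_intercept,mnar_slope optional logistic missingness on the
#'   log2 intensity (`NULL` = disabled).
#' @param norm_imp_group include a two-group `Norm_Imp_Group` column (split
#'   by MS run) in the metadata?
#' @return a `wfvar_sim_design` list of the validated settings.
#' @export
simulation_design <- function(n_proteins = 200, n_peptides = 1000,
                              m1_levels = c("A1", "A2"),
                              m2_levels = c("B1", "B2", "B3"),
                              replicates = 3, runs = 2,
                              age_range = c(25, 65), age_jitter_sd = 2,
                              baseline_mean = 22, baseline_sd = 1.5,
                              peptide_offset_sd = 1,
                              m1_effect_sd = 0.5, m2_effect_sd = 1,
                              run_effect_sd = 0.25, age_slope_sd = 0.015,
                              sigma0 = 0.4,
                              m1_noise_mult = c(A1 = 1.5, A2 = 1),
                              m2_noise_mult = c(B1 = 1.5, B2 = 1, B3 = 1.8),
                              mcar_rate = 0.05,
                              mnar_intercept = NULL, mnar_slope = NULL,
                              norm_imp_group = FALSE) {
  design <- as.list(environment())
  if (replicates < 1 || runs < 1) wf_stop("need >= 1 replicate and >= 1 run")
  if (n_peptides < n_proteins) wf_stop("need n_peptides >= n_proteins")
  if (mcar_rate < 0 || mcar_rate >= 1) wf_stop("mcar_rate must lie in [0, 1)")
  if (sigma0 <= 0 || any(m1_noise_mult <= 0) || any(m2_noise_mult <= 0)) {
    wf_stop("all noise SDs must be positive")
  }
  if (!setequal(names(m1_noise_mult), m1_levels) ||
      !setequal(names(m2_noise_mult), m2_levels)) {
    wf_stop("noise multipliers must be named by the factor levels")
  }
  structure(design, class = "wfvar_sim_design")
}

#' Simulate a peptide-level workflow-standardization dataset
#'
#' Draws a raw-scale peptide expression matrix, its sample metadata (M1, M2,
#' Run, Age and optionally Norm_Imp_Group) and a ground-truth record holding
#' every drawn parameter plus the complete pre-masking log2 matrix.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed driving all randomness.
#' @return a `wfvar_sim` list with elements `expression` (raw-scale peptide
#'   expression table), `metadata` (tibble) and `truth` (list).
#' @examples
#' sim <- simulate_dataset(simulation_design(n_proteins = 10,
#'                                           n_peptides = 30), seed = 1)
#' dim(expr_values(sim$expression))
#' @export
simulate_dataset <- function(design = simulation_design(), seed = 1L) {
  stopifnot(inherits(design, "wfvar_sim_design"))
  set.seed(as.integer(seed))
  d <- design
  subjects <- tidyr::expand_grid(M1 = d$m1_levels, M2 = d$m2_levels,
                                 replicate = seq_len(d$replicates))
  subjects$subject <- sprintf("subj%02d", seq_len(nrow(subjects)))
  age_grid <- d$age_range[1] +
    (seq_len(d$replicates) - 0.5) / d$replicates * diff(d$age_range)
  subjects$Age <- round(age_grid[subjects$replicate] +
                          rnorm(nrow(subjects), 0, d$age_jitter_sd))
  samples <- tidyr::expand_grid(subjects,
                                Run = sprintf("R%d", seq_len(d$runs)))
  samples$sample_id <- sprintf("S%02d", seq_len(nrow(samples)))

  np <- d$n_proteins
  protein_of <- sort(c(seq_len(np),
                       sample.int(np, d$n_peptides - np, replace = TRUE)))
  protein_ids <- sprintf("P%03d", seq_len(np))
  peptide_ids <- sprintf("pep%04d", seq_len(d$n_peptides))

  baseline <- rnorm(np, d$baseline_mean, d$baseline_sd)
  pep_offset <- rnorm(d$n_peptides, 0, d$peptide_offset_sd)
  eff_m1 <- matrix(rnorm(np * length(d$m1_levels), 0, d$m1_effect_sd), np,
                   dimnames = list(NULL, d$m1_levels))
  eff_m2 <- matrix(rnorm(np * length(d$m2_levels), 0, d$m2_effect_sd), np,
                   dimnames = list(NULL, d$m2_levels))
  eff_run <- matrix(rnorm(np * d$runs, 0, d$run_effect_sd), np,
                    dimnames = list(NULL, sprintf("R%d", seq_len(d$runs))))
  slope <- rnorm(np, 0, d$age_slope_sd)
  age_c <- samples$Age - mean(samples$Age)
  noise_sd <- d$sigma0 * d$m1_noise_mult[samples$M1] *
    d$m2_noise_mult[samples$M2]

  n_samp <- nrow(samples)
  log2_mat <- matrix(NA_real_, d$n_peptides, n_samp,
                     dimnames = list(peptide_ids, samples$sample_id))
  for (s in seq_len(n_samp)) {
    prot_part <- baseline + eff_m1[, samples$M1[s]] +
      eff_m2[, samples$M2[s]] + eff_run[, samples$Run[s]] + slope * age_c[s]
    log2_mat[, s] <- prot_part[protein_of] + pep_offset +
      rnorm(d$n_peptides, 0, noise_sd[s])
  }

  miss <- matrix(runif(length(log2_mat)) < d$mcar_rate, d$n_peptides, n_samp)
  if (!is.null(d$mnar_intercept) && !is.null(d$mnar_slope)) {
    p_mnar <- plogis(d$mnar_intercept + d$mnar_slope * log2_mat)
    miss <- miss | (matrix(runif(length(log2_mat)), d$n_peptides) < p_mnar)
  }
  raw <- 2^log2_mat
  raw[miss] <- NA_real_

  expr <- dplyr::bind_cols(
    tibble(protein_id = protein_ids[protein_of], feature_id = peptide_ids),
    as_tibble(raw, .name_repair = "minimal"))
  expr <- as_expression(expr, scale = "raw", feature_type = "peptide")

  metadata <- tibble(
    sample_id = samples$sample_id, M1 = samples$M1, M2 = samples$M2,
    Run = samples$Run, Age = as.numeric(samples$Age))
  if (isTRUE(d$norm_imp_group)) {
    metadata$Norm_Imp_Group <- as.integer(factor(samples$Run))
  }

  truth <- list(
    seed = as.integer(seed), design = unclass(d),
    protein_of = protein_of, baseline = baseline, peptide_offset = pep_offset,
    effect_m1 = eff_m1, effect_m2 = eff_m2, effect_run = eff_run,
    age_slope = slope, noise_sd = noise_sd, ages = subjects$Age,
    log2_complete = log2_mat, missing_mask = miss)
  structure(list(expression = expr, metadata = metadata, truth = truth),
            class = "wfvar_sim")
}

#' @export
print.wfvar_sim <- function(x, ...) {
  cat("Simulated workflow dataset:", nrow(x$expression), "peptides /",
      dplyr::n_distinct(x$expression$protein_id), "proteins x",
      length(sample_ids(x$expression)), "samples;",
      sum(is.na(expr_values(x$expression))), "missing cells\n")
  invisible(x)
}

#' Write a simulated dataset as fixture files
#'
#' Writes `expression.csv` (peptide dialect: Protein, Peptide, samples),
#' `metadata.csv` and `truth.json` under `dir`. Files are byte-identical
#' across runs for a fixed seed. The expression/metadata pair round-trips
#' through [read_expression()] / [read_metadata()].
#'
#' @param sim a `wfvar_sim` from [simulate_dataset()].
#' @param dir output directory, created if absent.
#' @return invisible named character vector of the three paths.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "wfvar_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.csv"),
             metadata = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "truth.json"))
  expr_out <- sim$expression |>
    rename(Protein = "protein_id", Peptide = "feature_id") |>
    select("Protein", "Peptide", dplyr::everything())
  readr::write_csv(expr_out, paths["expression"], na = "NA", progress = FALSE)
  readr::write_csv(sim$metadata, paths["metadata"], na = "NA",
                   progress = FALSE)
  jsonlite::write_json(sim$truth, paths["truth"], digits = NA,
                       auto_unbox = TRUE, pretty = FALSE)
  invisible(paths)
}
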