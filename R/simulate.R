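#' Configuration for the synthetic cohort generator
#'
#' Defines a cohort in which a chosen number of lncRNA-miRNA-mRNA triplets
#' carry a planted conditional-correlation structure and the remaining decoy
#' triplets are pure noise. For a planted triplet, the latent (log-scale)
#' lncRNA and mRNA have conditional correlation `rho_star` given the shared
#' miRNA in normal samples; in tumor samples the conditional correlation is
#' shifted by `delta` (clipped to feasibility). Decoy genes are i.i.d.
#' log-normal background. Defaults describe a TCGA-like design: 100 normal
#' samples (a BRCA-scale normal cohort), 50 tumor samples, 20 planted
#' triplets with a strong reference coupling (`rho_star = 0.9`, the level
#' that survives the `|rho| > 0.7` edge filter) perturbed by
#' `delta = -0.5` in tumors, and 10 decoys per planted triplet.
#'
#' @param n_normal,n_tumor sample counts.
#' @param n_planted number of planted triplets.
#' @param n_decoy number of decoy triplets (default `10 * n_planted`).
#' @param rho_star target conditional correlation of planted triplets in
#'   normal samples, `|rho_star| < 1`; recycled over planted triplets.
#' @param delta shift of the conditional correlation in tumor samples;
#'   `|rho_star + delta| < 1` required; recycled.
#' @param loading latent correlation of lncRNA (and mRNA) with the shared
#'   miRNA for planted triplets.
#' @param noise_sd standard deviation of additive measurement noise on the
#'   latent log scale.
#' @param baseline_log_mean,baseline_log_sd location and scale used to map
#'   latent values to expression: `v = 2^(mean + sd * latent) - 1`, which is
#'   affine on the `log2(v + 1)` analysis scale, so latent partial
#'   correlations are preserved exactly by the default transform.
#' @param surv_lambda baseline hazard per day (default `log(2)/1095`:
#'   three-year median survival).
#' @param surv_beta planted log hazard ratio for the at-risk sub-pattern.
#' @param surv_censoring expected censoring fraction in `[0, 1)`.
#' @param seed integer seed; every simulation routine is deterministic given
#'   the seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_normal = 100L, n_tumor = 50L, n_planted = 20L,
                       n_decoy = 10L * n_planted, rho_star = 0.9,
                       delta = -0.5, loading = 0.5, noise_sd = 0.05,
                       baseline_log_mean = 8, baseline_log_sd = 1.5,
                       surv_lambda = log(2) / 1095, surv_beta = log(3),
                       surv_censoring = 0.6, seed = 1L) {
  n_planted <- as.integer(n_planted); n_decoy <- as.integer(n_decoy)
  stopifnot(n_normal >= 4L, n_tumor >= 1L, n_planted >= 0L, n_decoy >= 0L,
            n_planted + n_decoy >= 1L, noise_sd >= 0,
            baseline_log_sd > 0, surv_censoring >= 0, surv_censoring < 1)
  if (surv_lambda <= 0)
    psnet_error("baseline hazard must be positive", "psnet_config_error")
  rho_star <- rep_len(rho_star, max(1L, n_planted))
  delta <- rep_len(delta, max(1L, n_planted))
  if (any(abs(rho_star) >= 1) || any(abs(loading) >= 1))
    psnet_error("|rho_star| and |loading| must be < 1", "psnet_config_error")
  if (any(abs(rho_star + delta) >= 1))
    psnet_error("infeasible perturbation: |rho_star + delta| must be < 1",
                "psnet_config_error")
  structure(list(n_normal = as.integer(n_normal),
                 n_tumor = as.integer(n_tumor),
                 n_planted = n_planted, n_decoy = n_decoy,
                 rho_star = rho_star, delta = delta, loading = loading,
                 noise_sd = noise_sd,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 surv_lambda = surv_lambda, surv_beta = surv_beta,
                 surv_censoring = surv_censoring,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# latent -> non-negative expression, affine on the log2(v+1) scale
latent_to_expr <- function(latent, cfg) {
  w <- cfg$baseline_log_mean + cfg$baseline_log_sd * latent
  pmax(2^w - 1, 0)
}

#' Simulate a synthetic ceRNA cohort with planted ground truth
#'
#' Generates expression matrices (lncRNA, miRNA, mRNA; genes x samples),
#' normal/tumor sample labels, the association lists that give rise to
#' exactly the simulated triplets, and a truth table flagging planted
#' triplets. Planted triplets follow a latent Gaussian model: the miRNA is
#' standard normal, lncRNA and mRNA load on it with `loading`, and their
#' residuals are correlated `rho_star` (normal samples) or
#' `rho_star + delta` (tumor samples), so the partial correlation given the
#' miRNA is controlled exactly on the latent scale. Latents are mapped to
#' non-negative expression by `v = 2^(mean + sd*latent) - 1`, an affine map
#' on the `log2(v+1)` analysis scale.
#'
#' @param cfg a [sim_config()].
#' @return list with `expr` (list of matrices `lnc`, `mi`, `mrna`),
#'   `sample_class` (named vector), `associations` (list of two
#'   `association_table`s), `truth` (data frame with `planted`, `rho_star`,
#'   `delta`), and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_normal + cfg$n_tumor
  tumor <- c(rep(FALSE, cfg$n_normal), rep(TRUE, cfg$n_tumor))
  sample_ids <- c(sprintf("N%03d", seq_len(cfg$n_normal)),
                  sprintf("T%03d", seq_len(cfg$n_tumor)))
  nt <- cfg$n_planted + cfg$n_decoy
  lnc_ids <- sprintf("LNC%04d", seq_len(nt))
  mi_ids <- sprintf("hsa-mir-%04d", seq_len(nt))
  mrna_ids <- sprintf("G%04d", seq_len(nt))

  lnc <- matrix(NA_real_, nt, n, dimnames = list(lnc_ids, sample_ids))
  mi <- matrix(NA_real_, nt, n, dimnames = list(mi_ids, sample_ids))
  mrna <- matrix(NA_real_, nt, n, dimnames = list(mrna_ids, sample_ids))

  a <- cfg$loading
  for (t in seq_len(nt)) {
    z <- rnorm(n)
    if (t <= cfg$n_planted) {
      rho_c <- ifelse(tumor, cfg$rho_star[t] + cfg$delta[t], cfg$rho_star[t])
      e1 <- rnorm(n)
      e2 <- rho_c * e1 + sqrt(1 - rho_c^2) * rnorm(n)
      x <- a * z + sqrt(1 - a^2) * e1
      y <- a * z + sqrt(1 - a^2) * e2
    } else {
      x <- rnorm(n)
      y <- rnorm(n)
    }
    if (cfg$noise_sd > 0) {
      x <- x + rnorm(n, sd = cfg$noise_sd)
      y <- y + rnorm(n, sd = cfg$noise_sd)
      z <- z + rnorm(n, sd = cfg$noise_sd)
    }
    lnc[t, ] <- latent_to_expr(x, cfg)
    mrna[t, ] <- latent_to_expr(y, cfg)
    mi[t, ] <- latent_to_expr(z, cfg)
  }

  truth <- data.frame(lncRNA = lnc_ids, miRNA = mi_ids, mRNA = mrna_ids,
                      planted = seq_len(nt) <= cfg$n_planted,
                      rho_star = c(cfg$rho_star[seq_len(cfg$n_planted)],
                                   rep(0, cfg$n_decoy)),
                      delta = c(cfg$delta[seq_len(cfg$n_planted)],
                                rep(0, cfg$n_decoy)),
                      stringsAsFactors = FALSE)
  assoc <- list(
    lnc_mi = new_association_table(
      data.frame(regulator = lnc_ids, mirna = mi_ids,
                 stringsAsFactors = FALSE), "lncRNA-miRNA"),
    mrna_mi = new_association_table(
      data.frame(regulator = mrna_ids, mirna = mi_ids,
                 stringsAsFactors = FALSE), "mRNA-miRNA"))
  list(expr = list(lnc = lnc, mi = mi, mrna = mrna),
       sample_class = setNames(ifelse(tumor, "tumor", "normal"), sample_ids),
       associations = assoc, truth = truth, config = cfg)
}

#' Simulate survival with a planted prognostic sub-pattern
#'
#' Draws exponential event times with hazard
#' \eqn{\lambda \exp(\beta \cdot \mathrm{indicator})}, where the indicator
#' marks patients whose expression sub-pattern equals `risk_pattern`.
#' Censoring is independent exponential with per-subject rate
#' \eqn{c_i = h_i\, r/(1-r)}, which makes the probability of censoring
#' exactly `r` for every subject; `r = 0` yields fully observed events.
#'
#' @param labeling data frame from [assign_groups()] covering the tumor
#'   samples (columns `sample_id`, `sub_pattern`).
#' @param lambda baseline hazard per day (> 0).
#' @param beta log hazard ratio for the at-risk sub-pattern.
#' @param censoring expected censoring fraction in `[0, 1)`.
#' @param risk_pattern the `sub_pattern` value carrying the excess hazard;
#'   `NULL` (with `beta = 0`) plants no effect.
#' @param seed optional seed.
#' @return data frame with columns `sample_id`, `time`, `event`.
#' @export
simulate_survival <- function(labeling, lambda = log(2) / 1095, beta = 0,
                              censoring = 0.6, risk_pattern = NULL,
                              seed = NULL) {
  if (lambda <= 0)
    psnet_error("baseline hazard must be positive", "psnet_config_error")
  if (censoring < 0 || censoring >= 1)
    psnet_error("censoring rate must be in [0, 1)", "psnet_config_error")
  if (!is.null(seed)) set.seed(seed)
  ids <- labeling$sample_id
  ind <- if (is.null(risk_pattern)) rep(0, length(ids))
         else as.numeric(labeling$sub_pattern == risk_pattern)
  h <- lambda * exp(beta * ind)
  tt <- rexp(length(ids), rate = h)
  if (censoring > 0) {
    cc <- rexp(length(ids), rate = h * censoring / (1 - censoring))
    data.frame(sample_id = ids, time = pmin(tt, cc),
               event = as.integer(tt <= cc), stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = ids, time = tt, event = 1L,
               stringsAsFactors = FALSE)
  }
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits the expression TSVs, the sample-class TSV, the two association
#' TSVs, the truth table and (optionally) a clinical TSV into `dir`.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @param clinical optional data frame from [simulate_survival()].
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, clinical = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(lnc = file.path(dir, "expr_lncRNA.tsv"),
         mi = file.path(dir, "expr_miRNA.tsv"),
         mrna = file.path(dir, "expr_mRNA.tsv"),
         sample_class = file.path(dir, "sample_class.tsv"),
         lnc_mi = file.path(dir, "assoc_lncRNA_miRNA.tsv"),
         mrna_mi = file.path(dir, "assoc_mRNA_miRNA.tsv"),
         truth = file.path(dir, "truth.tsv"))
  write_expression(cohort$expr$lnc, p[["lnc"]])
  write_expression(cohort$expr$mi, p[["mi"]])
  write_expression(cohort$expr$mrna, p[["mrna"]])
  write.table(data.frame(names(cohort$sample_class),
                         unname(cohort$sample_class)),
              p[["sample_class"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(cohort$associations$lnc_mi$pairs, p[["lnc_mi"]], sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(cohort$associations$mrna_mi$pairs, p[["mrna_mi"]], sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(cohort$truth, p[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(clinical)) {
    p[["clinical"]] <- file.path(dir, "clinical.tsv")
    write.table(clinical, p[["clinical"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(p)
}
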