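#' Build and validate a pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Either supply input file
#' paths (`expr_lnc`, `expr_mi`, `expr_mrna`, `sample_class`, optionally
#' `clinical`, and one or more association files per side), or set
#' `simulate = TRUE` to run on a freshly generated synthetic cohort.
#'
#' @param expr_lnc,expr_mi,expr_mrna expression TSV paths (genes x samples).
#' @param sample_class sample-class TSV path (`sample_id<TAB>normal|tumor`).
#' @param clinical optional clinical TSV path (`sample_id`, `time`, `event`).
#' @param assoc_lnc_mi,assoc_mrna_mi character vectors of association TSV
#'   paths; multiple files per side are intersected.
#' @param simulate logical; generate a synthetic cohort instead of reading
#'   files.
#' @param sim a [sim_config()] used when `simulate = TRUE`.
#' @param rho_abs,p_max,ztest_alpha,min_samples,use_edge_filter,signed,se
#'   selection thresholds, see [psnet_control()].
#' @param cox_alpha retention threshold of the prognostic screen
#'   (default 0.01).
#' @param transform `"log2"` or `"none"`.
#' @param collapse_arms strip -5p/-3p miRNA suffixes at ingestion.
#' @param outdir output directory.
#' @param seed integer seed for all randomness in the run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(expr_lnc = NULL, expr_mi = NULL, expr_mrna = NULL,
                            sample_class = NULL, clinical = NULL,
                            assoc_lnc_mi = NULL, assoc_mrna_mi = NULL,
                            simulate = FALSE, sim = sim_config(),
                            rho_abs = 0.7, p_max = 0.05, ztest_alpha = 0.05,
                            min_samples = 3L, use_edge_filter = TRUE,
                            signed = TRUE, se = "shared-reference",
                            cox_alpha = 0.01, transform = "log2",
                            collapse_arms = FALSE,
                            outdir = "psnet_out", seed = 1L) {
  cfg <- list(expr_lnc = expr_lnc, expr_mi = expr_mi, expr_mrna = expr_mrna,
              sample_class = sample_class, clinical = clinical,
              assoc_lnc_mi = assoc_lnc_mi, assoc_mrna_mi = assoc_mrna_mi,
              simulate = isTRUE(simulate), sim = sim,
              rho_abs = rho_abs, p_max = p_max, ztest_alpha = ztest_alpha,
              min_samples = as.integer(min_samples),
              use_edge_filter = isTRUE(use_edge_filter),
              signed = isTRUE(signed), se = se,
              cox_alpha = cox_alpha, transform = transform,
              collapse_arms = isTRUE(collapse_arms),
              outdir = outdir, seed = as.integer(seed))
  if (!cfg$simulate) {
    files <- unlist(cfg[c("expr_lnc", "expr_mi", "expr_mrna", "sample_class",
                          "assoc_lnc_mi", "assoc_mrna_mi")])
    if (length(files) == 0L || any(vapply(
      cfg[c("expr_lnc", "expr_mi", "expr_mrna", "sample_class",
            "assoc_lnc_mi", "assoc_mrna_mi")], is.null, logical(1))))
      psnet_error("file-based run needs all expression, sample-class and association paths",
                  "psnet_config_error")
    missing <- files[!file.exists(files)]
    if (!is.null(cfg$clinical) && !file.exists(cfg$clinical))
      missing <- c(missing, cfg$clinical)
    if (length(missing))
      psnet_error(sprintf("input file(s) not found: %s",
                          paste(missing, collapse = ", ")),
                  "psnet_config_error")
  }
  if (cfg$rho_abs <= 0 || cfg$rho_abs >= 1 || cfg$p_max <= 0 ||
      cfg$p_max >= 1 || cfg$cox_alpha < 0 || cfg$cox_alpha > 1)
    psnet_error("thresholds out of range", "psnet_config_error")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; the `sim`
#' block, if present, is passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}

#' Run the full patient-specific ceRNA pipeline
#'
#' Executes association ingestion, triplet assembly, reference and
#' per-sample network construction, Z-test selection and (when clinical
#' data are available) the prognostic Cox screen; writes the triplet
#' statistics table, the selection table, per-patient SIF networks, the
#' pooled selected network (SIF and GraphML), the Cox results table and a
#' YAML run manifest with per-stage counts. Identical configuration and
#' inputs yield identical manifest counts.
#'
#' @param config a [pipeline_config()] or the path to a YAML file for
#'   [read_pipeline_config()].
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = as.character(packageVersion("psnet")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = config$seed,
                   config = unclass(config)[setdiff(names(config), "sim")],
                   stages = list(), counts = list(), status = "running")
  clinical <- NULL

  if (config$simulate) {
    cohort <- simulate_cohort(config$sim)
    expr <- cohort$expr
    sample_class <- cohort$sample_class
    lnc_mi <- cohort$associations$lnc_mi
    mrna_mi <- cohort$associations$mrna_mi
    write_cohort(cohort, file.path(config$outdir, "cohort"))
    manifest$stages$simulate <- "ok"
  } else {
    expr <- list(lnc = read_expression(config$expr_lnc),
                 mi = read_expression(config$expr_mi),
                 mrna = read_expression(config$expr_mrna))
    sample_class <- read_sample_class(config$sample_class)
    read_side <- function(paths, kind) {
      tabs <- lapply(paths, read_association_file, kind = kind,
                     collapse_arms = config$collapse_arms)
      if (length(tabs) > 1L) intersect_associations(tabs) else tabs[[1L]]
    }
    lnc_mi <- read_side(config$assoc_lnc_mi, "lncRNA-miRNA")
    mrna_mi <- read_side(config$assoc_mrna_mi, "mRNA-miRNA")
    if (!is.null(config$clinical)) clinical <- read_clinical(config$clinical)
    manifest$stages$load <- "ok"
  }
  manifest$counts$lnc_mi_pairs <- nrow(lnc_mi$pairs)
  manifest$counts$mrna_mi_pairs <- nrow(mrna_mi$pairs)

  triplets <- build_initial_triplets(lnc_mi, mrna_mi,
                                     expressed_lnc = rownames(expr$lnc),
                                     expressed_mi = rownames(expr$mi),
                                     expressed_mrna = rownames(expr$mrna))
  manifest$counts$initial_triplets <- nrow(triplets)
  if (nrow(triplets) == 0L) {
    manifest$status <- "failed: no candidate triplets after assembly"
    write_manifest(manifest, config$outdir)
    psnet_error("triplet assembly produced no candidates; check association lists and expressed genes",
                "psnet_empty_error")
  }
  write_triplets(triplets, file.path(config$outdir, "initial_triplets.tsv"))
  manifest$stages$triplets <- "ok"

  ctl <- psnet_control(rho_abs = config$rho_abs, p_max = config$p_max,
                       ztest_alpha = config$ztest_alpha,
                       min_samples = config$min_samples,
                       use_edge_filter = config$use_edge_filter,
                       signed = config$signed, se = config$se)
  fit <- psnet(expr, triplets, sample_class, transform = config$transform,
               control = ctl)
  write.table(triplet_records(fit),
              file.path(config$outdir, "triplet_records.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$counts$excluded_triplets <- sum(fit$triplets$excluded)
  manifest$counts$edge_filter_survivors <- sum(rowSums(fit$passes) > 0)
  manifest$stages$network <- "ok"

  sel <- ztest_select(fit)
  write.table(as.data.frame(sel),
              file.path(config$outdir, "ztest_selection.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  selected <- sel[sel$selected, c("lncRNA", "miRNA", "mRNA"), drop = FALSE]
  manifest$counts$selected_triplets <- nrow(selected)
  manifest$stages$select <- "ok"

  net_dir <- file.path(config$outdir, "patient_networks")
  dir.create(net_dir, showWarnings = FALSE)
  nets <- lapply(fit$tumor_ids, function(s) patient_network(fit, s))
  names(nets) <- fit$tumor_ids
  for (s in fit$tumor_ids) {
    if (nrow(nets[[s]]$edges) > 0L)
      export_sif(nets[[s]], file.path(net_dir, paste0(s, ".sif")))
  }
  if (nrow(selected) > 0L) {
    pooled <- suppressWarnings(pooled_network(nets))
    pooled_sel <- pooled[paste(pooled$lncRNA, pooled$miRNA, pooled$mRNA) %in%
                           paste(selected$lncRNA, selected$miRNA,
                                 selected$mRNA), , drop = FALSE]
    if (nrow(pooled_sel) > 0L) {
      pooled_sel$delta_rho <- pooled_sel$mean_delta_rho
      export_sif(pooled_sel, file.path(config$outdir, "selected_network.sif"))
      export_graphml(pooled_sel,
                     file.path(config$outdir, "selected_network.graphml"))
    }
  }
  manifest$stages$export <- "ok"

  if (config$simulate && nrow(selected) > 0L) {
    # synthetic runs get survival generated from the first selected triplet's
    # labeling so the survival stage is exercised end to end
    tumor_ids <- fit$tumor_ids
    lab <- assign_groups(
      median_dichotomize(log2(expr$lnc[selected$lncRNA[1L], tumor_ids] + 1)),
      median_dichotomize(log2(expr$mi[selected$miRNA[1L], tumor_ids] + 1)),
      median_dichotomize(log2(expr$mrna[selected$mRNA[1L], tumor_ids] + 1)))
    clinical <- simulate_survival(lab, lambda = config$sim$surv_lambda,
                                  beta = config$sim$surv_beta,
                                  censoring = config$sim$surv_censoring,
                                  risk_pattern = "lnc_high.mrna_low")
    write.table(clinical, file.path(config$outdir, "cohort", "clinical.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(clinical) && nrow(selected) > 0L) {
    tumor_expr <- list(lnc = expr$lnc[, fit$tumor_ids, drop = FALSE],
                       mi = expr$mi[, fit$tumor_ids, drop = FALSE],
                       mrna = expr$mrna[, fit$tumor_ids, drop = FALSE])
    screen <- screen_triplets(selected, tumor_expr, clinical,
                              alpha = config$cox_alpha,
                              transform = config$transform)
    write.table(screen$results,
                file.path(config$outdir, "cox_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$prognostic_triplets <- nrow(screen$prognostic)
    manifest$stages$survival <- "ok"
  } else {
    manifest$counts$prognostic_triplets <- NA
    manifest$stages$survival <- if (is.null(clinical))
      "skipped: no clinical data" else "skipped: no selected triplets"
  }

  manifest$status <- "ok"
  write_manifest(manifest, config$outdir)
  invisible(manifest)
}

write_manifest <- function(manifest, outdir) {
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
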