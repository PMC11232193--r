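#' Control parameters for patient-specific network fitting
#'
#' @param rho_abs absolute partial-correlation threshold of the per-sample
#'   edge filter (default 0.7): an edge survives in a perturbed network only
#'   if `|rho| > rho_abs`.
#' @param p_max p-value threshold of the edge filter (default 0.05).
#' @param ztest_alpha significance level of the triplet-selection Z-test
#'   (default 0.05).
#' @param min_samples minimum number of edge-filter-passing tumor samples a
#'   triplet needs to enter the Z-test (default 3).
#' @param use_edge_filter if `TRUE` (default) the Z-test pools only tumor
#'   samples whose perturbed edge passed the filter; if `FALSE` all tumor
#'   samples contribute.
#' @param filter_reference if `TRUE` the edge filter is additionally applied
#'   to the reference (normal-samples) partial correlation; default `FALSE`
#'   applies it to the perturbed correlation only.
#' @param signed if `TRUE` (default) the Z-test is computed on the signed
#'   differential partial correlation `rho_pert - rho_ref`, which is centred
#'   at zero for unperturbed triplets; `FALSE` uses the absolute differential
#'   (the network edge weight), whose mean is positive even without signal —
#'   that variant is anti-conservative and kept for comparison only.
#' @param se standard error for the Z statistic: `"shared-reference"`
#'   (default) uses `sd * sqrt(1/m + 1/n_normal)`, accounting for the fact
#'   that all per-sample differentials share one estimated reference network;
#'   `"iid"` uses the naive `sd / sqrt(m)`.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return list of class `psnet_control`.
#' @export
psnet_control <- function(rho_abs = 0.7, p_max = 0.05, ztest_alpha = 0.05,
                          min_samples = 3L, use_edge_filter = TRUE,
                          filter_reference = FALSE, signed = TRUE,
                          se = c("shared-reference", "iid"),
                          alternative = c("two.sided", "greater")) {
  stopifnot(rho_abs > 0, rho_abs < 1, p_max > 0, p_max < 1,
            ztest_alpha > 0, ztest_alpha < 1, min_samples >= 1)
  structure(list(rho_abs = rho_abs, p_max = p_max, ztest_alpha = ztest_alpha,
                 min_samples = as.integer(min_samples),
                 use_edge_filter = isTRUE(use_edge_filter),
                 filter_reference = isTRUE(filter_reference),
                 signed = isTRUE(signed), se = match.arg(se),
                 alternative = match.arg(alternative)),
            class = "psnet_control")
}

resolve_expression <- function(expr) {
  if (is.list(expr) && !is.data.frame(expr)) {
    mats <- lapply(expr, as.matrix)
    expr <- do.call(rbind, mats)
  }
  expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  validate_expression(expr)
  expr
}

triplet_gene_index <- function(triplets, genes) {
  idx <- function(col) {
    i <- match(triplets[[col]], genes)
    if (anyNA(i)) {
      j <- which(is.na(i))[1L]
      psnet_error(sprintf(
        "gene '%s' of triplet %s|%s|%s not found in the expression matrix",
        triplets[[col]][j], triplets$lncRNA[j], triplets$miRNA[j],
        triplets$mRNA[j]), "psnet_lookup_error")
    }
    i
  }
  list(l = idx("lncRNA"), z = idx("miRNA"), y = idx("mRNA"))
}

#' Fit patient-specific ceRNA networks over a cohort
#'
#' Estimates, for every candidate lncRNA-miRNA-mRNA triplet, the reference
#' partial correlation \eqn{\rho_n} between lncRNA and mRNA conditioned on
#' the shared miRNA using the normal samples, then adds each tumor sample in
#' turn to the normal cohort and re-estimates \eqn{\rho_{n+1}}. The
#' differential partial correlation \eqn{\Delta\rho = |\rho_{n+1} - \rho_n|}
#' is the per-patient edge weight; an edge filter
#' (`|rho| > rho_abs`, `p < p_max`) marks the edges retained in each
#' patient's network. Triplets whose genes have zero variance (or perfectly
#' collinear conditioning) are excluded with a recorded reason rather than
#' failing the run.
#'
#' @param expr expression data: one genes x samples numeric matrix with gene
#'   rownames and sample colnames, or a list of such matrices (e.g. separate
#'   lncRNA / miRNA / mRNA matrices sharing the same samples) which are row-
#'   bound. Values are expected non-negative (RNA-seq expression).
#' @param triplets data frame with columns `lncRNA`, `miRNA`, `mRNA` (see
#'   [build_initial_triplets()]).
#' @param sample_class named character vector mapping every sample id to
#'   `"normal"` or `"tumor"`.
#' @param transform `"log2"` (default) applies `log2(v + 1)` before
#'   correlation; `"none"` uses the values as given.
#' @param control a [psnet_control()] list.
#' @return object of class `psnet` with components `triplets` (including an
#'   `excluded` flag and `reason`), `rho_ref`/`p_ref`, matrices `rho_pert`,
#'   `p_pert`, `delta_signed`, `delta_rho` and `passes` (triplets x tumor
#'   samples), `n_normal`, `tumor_ids`, `control`, `transform`.
#' @seealso [ztest_select()], [patient_network()], [triplet_records()]
#' @export
psnet <- function(expr, triplets, sample_class,
                  transform = c("log2", "none"),
                  control = psnet_control()) {
  transform <- match.arg(transform)
  stopifnot(inherits(control, "psnet_control"))
  expr <- resolve_expression(expr)
  triplets <- as.data.frame(triplets, stringsAsFactors = FALSE)
  if (!all(c("lncRNA", "miRNA", "mRNA") %in% names(triplets)))
    psnet_error("triplets needs columns lncRNA, miRNA, mRNA", "psnet_validate_error")
  if (nrow(triplets) == 0L)
    psnet_error("empty triplet set", "psnet_empty_error")

  sample_class <- sample_class[colnames(expr)]
  if (anyNA(sample_class) || is.null(names(sample_class)))
    psnet_error("sample_class must label every sample in the expression matrix",
                "psnet_validate_error")
  if (!all(sample_class %in% c("normal", "tumor")))
    psnet_error("sample_class values must be 'normal' or 'tumor'",
                "psnet_validate_error")
  normal_ids <- sort(names(sample_class)[sample_class == "normal"])
  tumor_ids <- sort(names(sample_class)[sample_class == "tumor"])
  n <- length(normal_ids)
  if (n < 4L)
    psnet_error("need at least 4 normal samples for the reference network",
                "psnet_insufficient_error")

  X <- t(expr)                       # samples x genes
  if (transform == "log2") X <- log2(X + 1)
  idx <- triplet_gene_index(triplets, colnames(X))
  Xn <- X[normal_ids, , drop = FALSE]

  ref <- triplet_pcor_matrix(Xn, idx$l, idx$z, idx$y)
  nt <- nrow(triplets)
  m <- length(tumor_ids)
  rho_pert <- matrix(NA_real_, nt, m, dimnames = list(NULL, tumor_ids))
  p_pert <- rho_pert
  for (s in seq_along(tumor_ids)) {
    Xs <- rbind(Xn, X[tumor_ids[s], , drop = FALSE])
    ps <- triplet_pcor_matrix(Xs, idx$l, idx$z, idx$y)
    rho_pert[, s] <- ps$rho
    p_pert[, s] <- pcor_pvalue(ifelse(is.na(ps$rho), 0, ps$rho), n + 1L)
    p_pert[is.na(ps$rho), s] <- NA_real_
  }
  delta_signed <- rho_pert - ref$rho
  passes <- !is.na(rho_pert) & abs(rho_pert) > control$rho_abs &
    p_pert < control$p_max
  p_ref <- pcor_pvalue(ifelse(is.na(ref$rho), 0, ref$rho), n)
  p_ref[is.na(ref$rho)] <- NA_real_
  if (control$filter_reference) {
    ref_ok <- !is.na(ref$rho) & abs(ref$rho) > control$rho_abs &
      p_ref < control$p_max
    passes <- passes & ref_ok
  }

  triplets$excluded <- is.na(ref$rho) | apply(is.na(rho_pert), 1L, any)
  triplets$reason <- ref$reason
  still <- triplets$excluded & is.na(triplets$reason)
  if (any(still)) triplets$reason[still] <- "zero variance"
  passes[triplets$excluded, ] <- FALSE

  structure(list(triplets = triplets,
                 rho_ref = ref$rho, p_ref = p_ref,
                 rho_pert = rho_pert, p_pert = p_pert,
                 delta_signed = delta_signed,
                 delta_rho = abs(delta_signed),
                 passes = passes,
                 n_normal = n, tumor_ids = tumor_ids,
                 transform = transform, control = control,
                 call = match.call()),
            class = "psnet")
}

#' @export
print.psnet <- function(x, ...) {
  cat("Patient-specific ceRNA network fit\n")
  cat(sprintf("  triplets: %d (%d excluded)\n", nrow(x$triplets),
              sum(x$triplets$excluded)))
  cat(sprintf("  normal samples: %d, tumor samples: %d\n",
              x$n_normal, length(x$tumor_ids)))
  cat(sprintf("  edge filter: |rho| > %.2f, p < %.2g\n",
              x$control$rho_abs, x$control$p_max))
  cat(sprintf("  edges passing filter: %d of %d (triplet x sample)\n",
              sum(x$passes), length(x$passes)))
  invisible(x)
}

#' @export
summary.psnet <- function(object, ...) {
  sel <- ztest_select(object)
  out <- list(n_triplets = nrow(object$triplets),
              n_excluded = sum(object$triplets$excluded),
              n_normal = object$n_normal,
              n_tumor = length(object$tumor_ids),
              edges_per_sample = colSums(object$passes),
              n_edge_survivors = sum(rowSums(object$passes) > 0),
              n_selected = sum(sel$selected),
              control = object$control)
  class(out) <- "summary.psnet"
  out
}

#' @export
print.summary.psnet <- function(x, ...) {
  cat("Patient-specific ceRNA network summary\n")
  cat(sprintf("  candidate triplets : %d (%d excluded as degenerate)\n",
              x$n_triplets, x$n_excluded))
  cat(sprintf("  cohort             : %d normal + %d tumor samples\n",
              x$n_normal, x$n_tumor))
  cat(sprintf("  edge survivors     : %d triplets pass the edge filter in >= 1 sample\n",
              x$n_edge_survivors))
  cat(sprintf("  median edges/sample: %g\n",
              median(x$edges_per_sample)))
  cat(sprintf("  Z-test selections  : %d at alpha = %.2g\n",
              x$n_selected, x$control$ztest_alpha))
  invisible(x)
}

#' @export
plot.psnet <- function(x, ...) {
  d <- x$delta_rho[!x$triplets$excluded, , drop = FALSE]
  hist(d, breaks = 50, col = "grey80", border = "grey40",
       main = "Differential partial correlations",
       xlab = expression(Delta * rho), ...)
  invisible(x)
}

#' Reference ceRNA network from normal samples
#'
#' Computes the reference partial correlation (and its p-value) for each
#' triplet on the normal samples only, without the per-tumor-sample
#' perturbation loop. A convenience view of the first stage of [psnet()].
#'
#' @inheritParams psnet
#' @param normal_ids character vector of normal sample ids (columns of
#'   `expr`); defaults to all samples.
#' @return data frame: triplet columns plus `rho`, `p_value`, `n`,
#'   `excluded`, `reason`.
#' @export
reference_network <- function(expr, triplets, normal_ids = NULL,
                              transform = c("log2", "none")) {
  transform <- match.arg(transform)
  expr <- resolve_expression(expr)
  triplets <- as.data.frame(triplets, stringsAsFactors = FALSE)
  X <- t(expr)
  if (transform == "log2") X <- log2(X + 1)
  if (is.null(normal_ids)) normal_ids <- rownames(X)
  if (!all(normal_ids %in% rownames(X)))
    psnet_error("unknown normal sample id", "psnet_lookup_error")
  if (length(normal_ids) < 4L)
    psnet_error("need at least 4 normal samples", "psnet_insufficient_error")
  idx <- triplet_gene_index(triplets, colnames(X))
  ref <- triplet_pcor_matrix(X[normal_ids, , drop = FALSE], idx$l, idx$z, idx$y)
  p <- pcor_pvalue(ifelse(is.na(ref$rho), 0, ref$rho), length(normal_ids))
  p[is.na(ref$rho)] <- NA_real_
  cbind(triplets,
        data.frame(rho = ref$rho, p_value = p, n = length(normal_ids),
                   excluded = is.na(ref$rho), reason = ref$reason,
                   stringsAsFactors = FALSE))
}

#' Z-test selection of perturbed triplets
#'
#' For each triplet, pools the per-tumor-sample differential partial
#' correlations (by default only samples whose perturbed edge passed the
#' `|rho| > 0.7`, `p < 0.05` filter) and tests whether their mean differs
#' from zero. By default the signed differential `rho_pert - rho_ref` is
#' used, and the standard error accounts for the shared reference network
#' (`sd * sqrt(1/m + 1/n_normal)`); see [psnet_control()].
#'
#' Triplets with fewer than `min_samples` contributing samples are dropped
#' with reason `"insufficient passing samples"`. A zero standard deviation
#' with a non-zero mean yields an infinite Z (flag `"degenerate-sd"`) and is
#' kept.
#'
#' @param fit a [psnet()] fit.
#' @param alpha significance level; defaults to the fit's `ztest_alpha`.
#' @param min_samples,use_edge_filter,signed,se,alternative overrides of the
#'   corresponding [psnet_control()] settings.
#' @return data frame of class `ztest_selection`: triplet columns plus `m`
#'   (samples pooled), `mean_delta`, `sd_delta`, `z`, `p_value`, `selected`,
#'   `reason`.
#' @export
ztest_select <- function(fit, alpha = NULL, min_samples = NULL,
                         use_edge_filter = NULL, signed = NULL, se = NULL,
                         alternative = NULL) {
  stopifnot(inherits(fit, "psnet"))
  ctl <- fit$control
  alpha <- alpha %||% ctl$ztest_alpha
  min_samples <- min_samples %||% ctl$min_samples
  use_edge_filter <- use_edge_filter %||% ctl$use_edge_filter
  signed <- signed %||% ctl$signed
  se <- se %||% ctl$se
  alternative <- alternative %||% ctl$alternative

  D <- if (signed) fit$delta_signed else fit$delta_rho
  nt <- nrow(fit$triplets)
  out <- fit$triplets[c("lncRNA", "miRNA", "mRNA")]
  out$m <- integer(nt)
  out$mean_delta <- out$sd_delta <- out$z <- out$p_value <- NA_real_
  out$selected <- FALSE
  out$reason <- NA_character_

  for (i in seq_len(nt)) {
    if (fit$triplets$excluded[i]) {
      out$reason[i] <- fit$triplets$reason[i]
      next
    }
    use <- if (use_edge_filter) fit$passes[i, ] else !is.na(D[i, ])
    d <- D[i, use]
    m <- length(d)
    out$m[i] <- m
    if (m < min_samples) {
      out$reason[i] <- "insufficient passing samples"
      next
    }
    mu <- mean(d)
    s <- if (m > 1L) sd(d) else 0
    out$mean_delta[i] <- mu
    out$sd_delta[i] <- s
    sef <- if (se == "shared-reference")
      sqrt(1 / m + 1 / fit$n_normal) else 1 / sqrt(m)
    if (s < DEGENERATE_TOL) {
      if (abs(mu) > DEGENERATE_TOL) {
        out$z[i] <- sign(mu) * Inf
        out$p_value[i] <- 0
        out$selected[i] <- TRUE
        out$reason[i] <- "degenerate-sd"
      } else {
        out$z[i] <- 0
        out$p_value[i] <- 1
      }
      next
    }
    z <- mu / (s * sef)
    out$z[i] <- z
    out$p_value[i] <- if (alternative == "two.sided")
      2 * pnorm(-abs(z)) else pnorm(-z)
    out$selected[i] <- out$p_value[i] < alpha
  }
  structure(out, class = c("ztest_selection", "data.frame"),
            alpha = alpha, min_samples = min_samples,
            use_edge_filter = use_edge_filter, signed = signed, se = se)
}

#' Extract the network specific to one tumor sample
#'
#' Projects a [psnet()] fit onto a single tumor sample: the edges are the
#' triplets whose perturbed partial correlation passed the edge filter for
#' that sample, weighted by the differential partial correlation.
#'
#' @param fit a [psnet()] fit.
#' @param sample_id a tumor sample identifier present in the fit.
#' @return object of class `patient_network`: list with `sample_id` and
#'   `edges` (data frame `lncRNA`, `miRNA`, `mRNA`, `rho_pert`, `delta_rho`).
#' @export
patient_network <- function(fit, sample_id) {
  stopifnot(inherits(fit, "psnet"))
  if (!sample_id %in% fit$tumor_ids)
    psnet_error(sprintf("unknown tumor sample '%s'", sample_id),
                "psnet_lookup_error")
  keep <- fit$passes[, sample_id]
  edges <- fit$triplets[keep, c("lncRNA", "miRNA", "mRNA"), drop = FALSE]
  edges$rho_pert <- fit$rho_pert[keep, sample_id]
  edges$delta_rho <- fit$delta_rho[keep, sample_id]
  rownames(edges) <- NULL
  structure(list(sample_id = sample_id, edges = edges),
            class = "patient_network")
}

#' @export
print.patient_network <- function(x, ...) {
  cat(sprintf("<patient_network> sample %s: %d triplet edge(s)\n",
              x$sample_id, nrow(x$edges)))
  if (nrow(x$edges)) print(head(x$edges, 10L))
  invisible(x)
}

#' Full per-triplet, per-sample statistics table
#'
#' Long-format table of the fit: one row per (triplet, tumor sample) with
#' the reference and perturbed partial correlations, the perturbed p-value,
#' the signed and absolute differential and the edge-filter flag. Suitable
#' for writing to TSV.
#'
#' @param fit a [psnet()] fit.
#' @return data frame.
#' @export
triplet_records <- function(fit) {
  stopifnot(inherits(fit, "psnet"))
  nt <- nrow(fit$triplets)
  m <- length(fit$tumor_ids)
  data.frame(fit$triplets[rep(seq_len(nt), each = m),
                          c("lncRNA", "miRNA", "mRNA")],
             sample_id = rep(fit$tumor_ids, times = nt),
             rho_ref = rep(fit$rho_ref, each = m),
             rho_pert = as.vector(t(fit$rho_pert)),
             p_pert = as.vector(t(fit$p_pert)),
             delta_signed = as.vector(t(fit$delta_signed)),
             delta_rho = as.vector(t(fit$delta_rho)),
             passes_edge_filter = as.vector(t(fit$passes)),
             row.names = NULL, stringsAsFactors = FALSE)
}
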