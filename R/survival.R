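#' Median dichotomization of expression values
#'
#' Labels each sample `"high"` if its value exceeds the cohort median and
#' `"low"` otherwise (values equal to the median are labeled low — a
#' deterministic tie rule). The median, rather than the mean, avoids
#' severely unbalanced partitions in the presence of expression outliers.
#'
#' @param values named numeric vector (one value per tumor sample).
#' @return named character vector of `"high"`/`"low"`.
#' @export
#' @examples
#' median_dichotomize(c(a = 1, b = 2, c = 3, d = 4))
median_dichotomize <- function(values) {
  if (length(values) < 2L)
    psnet_error("median dichotomization needs >= 2 samples",
                "psnet_insufficient_error")
  if (is.null(names(values)))
    psnet_error("values must be named by sample id", "psnet_validate_error")
  med <- median(values)
  out <- ifelse(values > med, "high", "low")
  if (all(out == "low") && length(unique(values)) == 1L)
    psnet_warn("all values equal; every sample labeled 'low'")
  setNames(out, names(values))
}

#' Assign patients to expression-pattern groups
#'
#' With each of the three RNAs of a triplet dichotomized into high/low there
#' are 8 possible expression patterns. Patients are grouped by the lncRNA
#' and mRNA levels only: Group 1 holds patients with opposite lncRNA/mRNA
#' patterns (one high, the other low), Group 2 patients with similar
#' patterns (both high or both low). The miRNA level is carried along but
#' does not influence the grouping (it was found not to affect survival).
#' Within each group the two constituent configurations form the
#' `sub_pattern`, used downstream as the binary Cox covariate.
#'
#' @param lnc_level,mi_level,mrna_level named character vectors of
#'   `"high"`/`"low"` over the same sample ids (see
#'   [median_dichotomize()]).
#' @return data frame with columns `sample_id`, `lnc_level`, `mi_level`,
#'   `mrna_level`, `pattern_group` (`"Group1"`/`"Group2"`) and `sub_pattern`.
#' @export
assign_groups <- function(lnc_level, mi_level, mrna_level) {
  ids <- names(lnc_level)
  if (is.null(ids) || is.null(names(mi_level)) || is.null(names(mrna_level)))
    psnet_error("level maps must be named by sample id", "psnet_validate_error")
  if (!setequal(ids, names(mi_level)) || !setequal(ids, names(mrna_level)))
    psnet_error("the three level maps must cover the same samples",
                "psnet_lookup_error")
  lv <- function(x) {
    if (!all(x %in% c("high", "low")))
      psnet_error("levels must be 'high' or 'low'", "psnet_validate_error")
    x
  }
  l <- lv(lnc_level[ids]); z <- lv(mi_level[ids]); y <- lv(mrna_level[ids])
  grp <- ifelse(l == y, "Group2", "Group1")
  sub <- ifelse(grp == "Group1",
                ifelse(l == "high", "lnc_high.mrna_low", "lnc_low.mrna_high"),
                ifelse(l == "high", "both_high", "both_low"))
  data.frame(sample_id = ids, lnc_level = unname(l), mi_level = unname(z),
             mrna_level = unname(y), pattern_group = unname(grp),
             sub_pattern = unname(sub), stringsAsFactors = FALSE)
}

#' Univariate Cox proportional-hazards fit for a binary covariate
#'
#' Maximizes the Cox partial likelihood (Efron tie handling) for a single
#' binary covariate and returns the coefficient, hazard ratio and two-sided
#' Wald p-value. Inputs that make the model non-estimable — no observed
#' events, or a covariate with an empty arm — raise a typed error so that
#' cohort-level screening can record and skip the triplet.
#'
#' @param time non-negative survival times (days).
#' @param event event indicator (1 = death observed, 0 = censored).
#' @param covariate binary (0/1 or logical) per-sample indicator, same
#'   length as `time`.
#' @return list of class `cox_result`: `coefficient`, `hazard_ratio`,
#'   `se`, `p_value`, `n`, `n_events`, `loglik` (at the optimum) and the
#'   underlying `coxph` fit.
#' @export
cox_univariate <- function(time, event, covariate) {
  covariate <- as.numeric(covariate)
  ok <- complete.cases(time, event, covariate)
  time <- time[ok]; event <- event[ok]; covariate <- covariate[ok]
  if (length(time) == 0L || sum(event) == 0)
    psnet_error("no observed events: Cox model not estimable",
                "psnet_not_estimable")
  if (length(unique(covariate)) < 2L)
    psnet_error("covariate has a single arm: Cox model not estimable",
                "psnet_not_estimable")
  warns <- character()
  fit <- withCallingHandlers(
    coxph(Surv(time, event) ~ covariate, ties = "efron"),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  structure(list(coefficient = unname(coef(fit)),
                 hazard_ratio = unname(exp(coef(fit))),
                 se = unname(sqrt(diag(fit$var))),
                 p_value = unname(s$coefficients[, "Pr(>|z|)"]),
                 score_p = unname(s$sctest["pvalue"]),
                 n = length(time), n_events = sum(event),
                 loglik = fit$loglik[2L], warnings = warns, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH (binary covariate): HR = %.3f, coef = %.3f (se %.3f), p = %.3g, n = %d (%d events)\n",
              x$hazard_ratio, x$coefficient, x$se, x$p_value, x$n, x$n_events))
  invisible(x)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per covariate arm with censoring marks,
#' plus the two-group log-rank chi-square statistic and p-value.
#'
#' @inheritParams cox_univariate
#' @return list of class `km_logrank`: `curves` (data frame `arm`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`), `chisq`, `df`, `p_value`,
#'   `obs`, `exp` (per-arm observed and expected events).
#' @export
km_logrank <- function(time, event, covariate) {
  covariate <- as.factor(covariate)
  if (nlevels(covariate) != 2L || any(table(covariate) == 0L))
    psnet_error("log-rank test needs two nonempty arms", "psnet_not_estimable")
  sf <- survfit(Surv(time, event) ~ covariate)
  ss <- summary(sf, censored = TRUE)
  arm <- sub("^covariate=", "", as.character(ss$strata))
  curves <- data.frame(arm = arm, time = ss$time, n_risk = ss$n.risk,
                       n_event = ss$n.event, n_censor = ss$n.censor,
                       surv = ss$surv, stringsAsFactors = FALSE)
  sd_ <- survdiff(Surv(time, event) ~ covariate)
  p <- pchisq(sd_$chisq, df = 1L, lower.tail = FALSE)
  structure(list(curves = curves, chisq = unname(sd_$chisq), df = 1L,
                 p_value = unname(p), obs = sd_$obs, exp = sd_$exp),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("Log-rank: chisq = %.4g on %d df, p = %.3g\n",
              x$chisq, x$df, x$p_value))
  invisible(x)
}

#' @export
plot.km_logrank <- function(x, xlab = "Time (days)",
                            ylab = "Survival probability", ...) {
  arms <- unique(x$curves$arm)
  cols <- c("#D55E00", "#0072B2")
  plot(NA, xlim = c(0, max(x$curves$time)), ylim = c(0, 1),
       xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(arms)) {
    cv <- x$curves[x$curves$arm == arms[i], ]
    lines(c(0, cv$time), c(1, cv$surv), type = "s", col = cols[i], lwd = 2)
    cens <- cv[cv$n_censor > 0, ]
    if (nrow(cens)) points(cens$time, cens$surv, pch = 3, col = cols[i])
  }
  legend("bottomleft", legend = arms, col = cols[seq_along(arms)],
         lwd = 2, bty = "n")
  invisible(x)
}

#' Prognostic screening of selected triplets
#'
#' For each selected triplet, dichotomizes the three RNAs at their cohort
#' medians over tumor samples, assigns patients to Group 1 (opposite
#' lncRNA/mRNA patterns) and Group 2 (similar patterns), and fits within
#' each group a univariate Cox model whose binary covariate distinguishes
#' the two constituent sub-patterns. Results with `p < alpha` are retained;
#' a triplet is prognostic if at least one of its group results is retained.
#' Benjamini-Hochberg q-values over all fitted models are reported
#' alongside the raw p-values but are not used for the default filter.
#'
#' @param triplets data frame with columns `lncRNA`, `miRNA`, `mRNA` (e.g. a
#'   [ztest_select()] result restricted to `selected`).
#' @param tumor_expr tumor expression: matrix or list of matrices (genes x
#'   tumor samples).
#' @param surv data frame with columns `sample_id`, `time`, `event` (see
#'   [read_clinical()]).
#' @param alpha retention threshold on the raw Cox p-value (default 0.01).
#' @param transform `"log2"` or `"none"` (dichotomization is monotone, so
#'   this does not change labels; kept for interface symmetry).
#' @param method `"subpattern"` (default) fits the within-group binary
#'   covariate; `"patterns8"` additionally reports a likelihood-ratio test
#'   of the full 8-level expression-pattern factor per triplet.
#' @return object of class `triplet_screen`: `results` (one row per triplet
#'   x group: `coefficient`, `hazard_ratio`, `p_value`, `q_value`, `n`,
#'   `n_events`, `retained`, `reason`), `prognostic` (data frame of triplets
#'   with >= 1 retained group), `alpha`, and for `method = "patterns8"` a
#'   `patterns8` table of LRT p-values.
#' @export
screen_triplets <- function(triplets, tumor_expr, surv, alpha = 0.01,
                            transform = c("log2", "none"),
                            method = c("subpattern", "patterns8")) {
  transform <- match.arg(transform)
  method <- match.arg(method)
  stopifnot(alpha >= 0, alpha <= 1)
  expr <- resolve_expression(tumor_expr)
  if (transform == "log2") expr <- log2(expr + 1)
  triplets <- as.data.frame(triplets, stringsAsFactors = FALSE)
  surv <- surv[surv$sample_id %in% colnames(expr), , drop = FALSE]
  if (nrow(surv) == 0L)
    psnet_error("no overlap between expression and survival sample ids",
                "psnet_lookup_error")
  st <- setNames(surv$time, surv$sample_id)
  sv <- setNames(surv$event, surv$sample_id)

  rows <- list()
  lrt <- list()
  for (i in seq_len(nrow(triplets))) {
    tri <- triplets[i, c("lncRNA", "miRNA", "mRNA")]
    genes <- unlist(tri)
    if (!all(genes %in% rownames(expr))) {
      rows[[length(rows) + 1L]] <- data.frame(
        tri, group = NA_character_, sub_pattern_1 = NA_character_,
        coefficient = NA_real_, hazard_ratio = NA_real_, p_value = NA_real_,
        n = NA_integer_, n_events = NA_integer_,
        reason = "gene missing from tumor expression",
        stringsAsFactors = FALSE)
      next
    }
    # medians over all tumor samples of the cohort, labels restricted to
    # patients with survival data afterwards
    lab <- assign_groups(median_dichotomize(expr[tri$lncRNA, ]),
                         median_dichotomize(expr[tri$miRNA, ]),
                         median_dichotomize(expr[tri$mRNA, ]))
    lab <- lab[lab$sample_id %in% names(st), , drop = FALSE]
    for (grp in c("Group1", "Group2")) {
      gl <- lab[lab$pattern_group == grp, , drop = FALSE]
      subs <- sort(unique(gl$sub_pattern))
      res <- tryCatch({
        if (length(subs) < 2L)
          psnet_error("covariate has a single arm: Cox model not estimable",
                      "psnet_not_estimable")
        cx <- cox_univariate(st[gl$sample_id], sv[gl$sample_id],
                             gl$sub_pattern == subs[2L])
        data.frame(tri, group = grp, sub_pattern_1 = subs[2L],
                   coefficient = cx$coefficient,
                   hazard_ratio = cx$hazard_ratio, p_value = cx$p_value,
                   n = cx$n, n_events = cx$n_events, reason = NA_character_,
                   stringsAsFactors = FALSE)
      }, psnet_not_estimable = function(e) {
        data.frame(tri, group = grp, sub_pattern_1 = NA_character_,
                   coefficient = NA_real_, hazard_ratio = NA_real_,
                   p_value = NA_real_, n = nrow(gl),
                   n_events = sum(sv[gl$sample_id]),
                   reason = conditionMessage(e), stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
    if (method == "patterns8") {
      pat <- interaction(lab$lnc_level, lab$mi_level, lab$mrna_level,
                         drop = TRUE)
      p8 <- tryCatch({
        f1 <- coxph(Surv(st[lab$sample_id], sv[lab$sample_id]) ~ pat,
                    ties = "efron")
        stat <- 2 * (f1$loglik[2L] - f1$loglik[1L])
        pchisq(stat, df = nlevels(pat) - 1L, lower.tail = FALSE)
      }, error = function(e) NA_real_)
      lrt[[length(lrt) + 1L]] <- data.frame(tri, lrt_p = p8,
                                            stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  results$q_value <- NA_real_
  ok <- !is.na(results$p_value)
  results$q_value[ok] <- p.adjust(results$p_value[ok], method = "BH")
  results$retained <- ok & results$p_value < alpha
  prog <- unique(results[results$retained, c("lncRNA", "miRNA", "mRNA")])
  rownames(prog) <- NULL
  out <- list(results = results, prognostic = prog, alpha = alpha)
  if (method == "patterns8") out$patterns8 <- do.call(rbind, lrt)
  structure(out, class = "triplet_screen")
}

#' @export
print.triplet_screen <- function(x, ...) {
  nt <- length(unique(paste(x$results$lncRNA, x$results$miRNA,
                            x$results$mRNA)))
  cat(sprintf("Prognostic triplet screen: %d triplet(s), %d group fit(s)\n",
              nt, sum(!is.na(x$results$p_value))))
  cat(sprintf("  retained at p < %.3g: %d group result(s), %d prognostic triplet(s)\n",
              x$alpha, sum(x$results$retained), nrow(x$prognostic)))
  invisible(x)
}

#' @export
summary.triplet_screen <- function(object, ...) {
  r <- object$results[order(object$results$p_value), ]
  cat(sprintf("Top prognostic results (alpha = %.3g):\n", object$alpha))
  print(head(r[!is.na(r$p_value),
               c("lncRNA", "miRNA", "mRNA", "group", "hazard_ratio",
                 "p_value", "q_value", "n", "n_events")], 10L),
        row.names = FALSE)
  invisible(object)
}
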