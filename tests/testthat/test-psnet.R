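# small deterministic cohort used by several blocks
make_cohort <- function(seed = 101, n_planted = 4, n_decoy = 8,
                        n_normal = 30, n_tumor = 6, ...) {
  simulate_cohort(sim_config(n_normal = n_normal, n_tumor = n_tumor,
                             n_planted = n_planted, n_decoy = n_decoy,
                             seed = seed, ...))
}

test_that("reference network recovers planted couplings and flags degeneracy", {
  co <- make_cohort()
  tri <- co$truth[c("lncRNA", "miRNA", "mRNA")]
  ref <- reference_network(co$expr, tri,
                           normal_ids = names(co$sample_class)[
                             co$sample_class == "normal"])
  planted <- co$truth$planted
  expect_true(all(ref$rho[planted] > 0.7))      # rho* = 0.9, n = 30
  expect_true(all(abs(ref$rho[!planted]) < 0.6))

  # a constant miRNA row excludes the triplet with a recorded reason
  co$expr$mi[tri$miRNA[1], ] <- 5
  ref2 <- reference_network(co$expr, tri)
  expect_true(ref2$excluded[1])
  expect_equal(ref2$reason[1], "zero variance")
  expect_false(any(ref2$excluded[-1]))
})

test_that("reference network equals per-triplet partial_cor calls", {
  co <- make_cohort(seed = 102, n_planted = 5, n_decoy = 5)
  tri <- co$truth[c("lncRNA", "miRNA", "mRNA")]
  normals <- names(co$sample_class)[co$sample_class == "normal"]
  ref <- reference_network(co$expr, tri, normal_ids = normals)
  for (i in seq_len(nrow(tri))) {
    x <- log2(co$expr$lnc[tri$lncRNA[i], normals] + 1)
    z <- log2(co$expr$mi[tri$miRNA[i], normals] + 1)
    y <- log2(co$expr$mrna[tri$mRNA[i], normals] + 1)
    expect_equal(ref$rho[i], partial_cor(x, y, z), tolerance = 1e-12)
    expect_equal(ref$p_value[i], pcor_pvalue(partial_cor(x, y, z),
                                             length(normals)),
                 tolerance = 1e-12)
  }
})

test_that("per-sample perturbation recomputes partial correlations on n+1 samples", {
  co <- make_cohort(seed = 103, n_planted = 3, n_decoy = 3, n_tumor = 4)
  tri <- co$truth[c("lncRNA", "miRNA", "mRNA")]
  fit <- psnet(co$expr, tri, co$sample_class)
  normals <- sort(names(co$sample_class)[co$sample_class == "normal"])
  for (s in fit$tumor_ids) {
    cols <- c(normals, s)
    for (i in seq_len(nrow(tri))) {
      x <- log2(co$expr$lnc[tri$lncRNA[i], cols] + 1)
      z <- log2(co$expr$mi[tri$miRNA[i], cols] + 1)
      y <- log2(co$expr$mrna[tri$mRNA[i], cols] + 1)
      rho1 <- partial_cor(x, y, z)
      expect_equal(unname(fit$rho_pert[i, s]), rho1, tolerance = 1e-12)
      expect_equal(unname(fit$delta_rho[i, s]),
                   abs(rho1 - fit$rho_ref[i]), tolerance = 1e-12)
    }
  }
  expect_true(all(fit$delta_rho >= 0))
  expect_equal(fit$delta_rho, abs(fit$delta_signed))
})

test_that("differential partial correlation is symmetric in lncRNA and mRNA", {
  co <- make_cohort(seed = 104, n_planted = 3, n_decoy = 2, n_tumor = 3)
  tri <- co$truth[c("lncRNA", "miRNA", "mRNA")]
  fit <- psnet(co$expr, tri, co$sample_class)
  # swap the roles of x and y: same genes, exchanged columns
  tri_sw <- data.frame(lncRNA = tri$mRNA, miRNA = tri$miRNA,
                       mRNA = tri$lncRNA, stringsAsFactors = FALSE)
  fit_sw <- psnet(co$expr, tri_sw, co$sample_class)
  expect_equal(fit$delta_rho, fit_sw$delta_rho, tolerance = 1e-12)
  expect_equal(fit$rho_ref, fit_sw$rho_ref, tolerance = 1e-12)
})

test_that("edge filter marks exactly the strong, significant perturbed edges", {
  co <- make_cohort(seed = 105)
  fit <- psnet(co$expr, co$truth[1:3], co$sample_class)
  manual <- !is.na(fit$rho_pert) & abs(fit$rho_pert) > 0.7 & fit$p_pert < 0.05
  expect_equal(fit$passes, manual)
})

test_that("Z-test selection logic covers null, signal and degenerate cases", {
  # all differentials zero -> not selected
  f0 <- forge_fit(matrix(0, 1, 10))
  s0 <- ztest_select(f0)
  expect_false(s0$selected)
  expect_equal(s0$p_value, 1)

  # overwhelming signal N(0.5, 0.05), m = 50 -> selected
  set.seed(31)
  f1 <- forge_fit(matrix(rnorm(50, 0.5, 0.05), 1, 50))
  expect_true(ztest_select(f1)$selected)

  # zero sd with nonzero mean -> kept, flagged degenerate
  f2 <- forge_fit(matrix(0.3, 1, 10))
  s2 <- ztest_select(f2)
  expect_true(s2$selected)
  expect_equal(s2$reason, "degenerate-sd")
  expect_equal(s2$p_value, 0)

  # too few passing samples -> dropped with reason
  passes <- matrix(FALSE, 1, 10, dimnames = list(NULL, sprintf("T%03d", 1:10)))
  passes[1, 1:2] <- TRUE
  f3 <- forge_fit(matrix(rnorm(10, 0.5, 0.01), 1, 10), passes = passes)
  s3 <- ztest_select(f3)  # min_samples default 3
  expect_false(s3$selected)
  expect_equal(s3$reason, "insufficient passing samples")
  expect_equal(s3$m, 2L)
})

test_that("Z statistics match an external recomputation from the fit matrices", {
  co <- make_cohort(seed = 106, n_planted = 5, n_decoy = 20, n_tumor = 20,
                    n_normal = 100)
  fit <- psnet(co$expr, co$truth[1:3], co$sample_class)
  sel <- ztest_select(fit)
  for (i in seq_len(nrow(sel))) {
    use <- fit$passes[i, ]
    m <- sum(use)
    if (m < fit$control$min_samples) {
      expect_false(sel$selected[i])
      next
    }
    d <- fit$delta_signed[i, use]
    z <- mean(d) / (sd(d) * sqrt(1 / m + 1 / fit$n_normal))
    expect_equal(sel$z[i], z, tolerance = 1e-12)
    expect_equal(sel$p_value[i], 2 * pnorm(-abs(z)), tolerance = 1e-12)
  }
  # planted triplets dominate the selection on this cohort: decoys never
  # survive the edge filter, and most planted triplets are selected
  expect_false(any(sel$selected[!co$truth$planted]))
  expect_gte(mean(sel$selected[co$truth$planted]), 0.6)
})

test_that("patient networks project the per-sample filtered edges", {
  co <- make_cohort(seed = 107, n_planted = 4, n_decoy = 10, n_tumor = 8)
  fit <- psnet(co$expr, co$truth[1:3], co$sample_class)
  for (s in fit$tumor_ids) {
    nw <- patient_network(fit, s)
    keep <- which(fit$passes[, s])
    expect_equal(nrow(nw$edges), length(keep))
    expect_equal(nw$edges$delta_rho, unname(fit$delta_rho[keep, s]))
    expect_equal(nw$edges$lncRNA, fit$triplets$lncRNA[keep])
  }
  expect_error(patient_network(fit, "nope"), class = "psnet_lookup_error")

  # a fit where nothing passes gives empty (but valid) networks
  f0 <- forge_fit(matrix(0.01, 2, 4),
                  passes = matrix(FALSE, 2, 4,
                                  dimnames = list(NULL,
                                                  sprintf("T%03d", 1:4))))
  expect_equal(nrow(patient_network(f0, "T001")$edges), 0L)
})

test_that("missing genes and bad sample labels are reported by name", {
  co <- make_cohort(seed = 108, n_planted = 2, n_decoy = 2, n_tumor = 3)
  tri <- co$truth[1:3]
  tri$mRNA[1] <- "NOT_A_GENE"
  err <- tryCatch(psnet(co$expr, tri, co$sample_class), error = identity)
  expect_s3_class(err, "psnet_lookup_error")
  expect_match(conditionMessage(err), "NOT_A_GENE")

  bad_class <- co$sample_class
  bad_class[1] <- "weird"
  expect_error(psnet(co$expr, co$truth[1:3], bad_class),
               class = "psnet_validate_error")
})

test_that("triplet_records is a faithful long-format view", {
  co <- make_cohort(seed = 109, n_planted = 2, n_decoy = 3, n_tumor = 4)
  fit <- psnet(co$expr, co$truth[1:3], co$sample_class)
  rec <- triplet_records(fit)
  expect_equal(nrow(rec), nrow(fit$triplets) * length(fit$tumor_ids))
  i <- 3L; s <- fit$tumor_ids[2L]
  row <- rec[rec$lncRNA == fit$triplets$lncRNA[i] & rec$sample_id == s, ]
  expect_equal(row$rho_pert, unname(fit$rho_pert[i, s]))
  expect_equal(row$delta_rho, unname(fit$delta_rho[i, s]))
  expect_equal(row$passes_edge_filter, unname(fit$passes[i, s]))
})
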