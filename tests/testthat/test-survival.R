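test_that("median dichotomization splits at the cohort median with ties low", {
  expect_equal(unname(median_dichotomize(c(a = 1, b = 2, c = 3, d = 4))),
               c("low", "low", "high", "high"))
  expect_warning(lab <- median_dichotomize(c(a = 5, b = 5, c = 5)),
                 class = "psnet_warning")
  expect_true(all(lab == "low"))

  # sorting oracle: partition sizes differ at most by the tie count
  set.seed(41)
  v <- setNames(sample(rep(1:30, length.out = 101)), sprintf("s%03d", 1:101))
  lab <- median_dichotomize(v)
  med <- sort(v)[51]
  expect_equal(sum(lab == "high"), sum(v > med))
  # ties go low, so the imbalance is bounded by the median's tie mass
  expect_lte(abs(sum(lab == "high") - sum(lab == "low")),
             2 * sum(v == med))
  expect_true(all(lab[v <= med] == "low"))
})

test_that("patients split into Group 1/2 by lncRNA-mRNA pattern only", {
  lv <- c("high", "low")
  grid <- expand.grid(l = lv, z = lv, y = lv, stringsAsFactors = FALSE)
  ids <- sprintf("p%d", seq_len(nrow(grid)))
  lab <- assign_groups(setNames(grid$l, ids), setNames(grid$z, ids),
                       setNames(grid$y, ids))
  expect_equal(nrow(lab), 8L)  # 3 RNAs x high/low -> 8 combinations
  expect_equal(sum(lab$pattern_group == "Group1"), 4L)
  expect_equal(sum(lab$pattern_group == "Group2"), 4L)
  # opposite lncRNA/mRNA patterns define Group 1, similar define Group 2
  expect_true(all((lab$lnc_level != lab$mrna_level) ==
                    (lab$pattern_group == "Group1")))
  expect_equal(lab$pattern_group[lab$lnc_level == "high" &
                                   lab$mrna_level == "low"][1], "Group1")
  expect_equal(lab$pattern_group[lab$lnc_level == "low" &
                                   lab$mrna_level == "low"][1], "Group2")

  # the miRNA level never changes the grouping
  lab2 <- assign_groups(setNames(grid$l, ids),
                        setNames(rev(grid$z), ids),
                        setNames(grid$y, ids))
  expect_equal(lab$pattern_group, lab2$pattern_group)

  expect_error(assign_groups(setNames(grid$l, ids),
                             setNames(grid$z[-1], ids[-1]),
                             setNames(grid$y, ids)),
               class = "psnet_lookup_error")
})

test_that("Cox fit matches direct maximization of the partial likelihood", {
  # 8 patients, no ties
  time <- c(5, 8, 12, 16, 21, 27, 33, 40)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(1, 1, 1, 0, 1, 0, 0, 0)
  fit <- cox_univariate(time, event, x)
  opt <- optimize(function(b) -cox_loglik_oracle(b, time, event, x),
                  interval = c(-8, 8), tol = 1e-10)
  expect_equal(fit$coefficient, opt$minimum, tolerance = 1e-6)
  expect_equal(fit$loglik, -opt$objective, tolerance = 1e-8)
  expect_equal(fit$hazard_ratio, exp(fit$coefficient))
})

test_that("Cox direction and null behavior are sane", {
  # arm A strictly shorter survival, all events -> positive log-HR, small p
  time <- c(1, 2, 3, 4, 10, 11, 12, 13, 14, 15)
  event <- rep(1, 10)
  a <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  fit <- cox_univariate(time, event, a)
  expect_gt(fit$coefficient, 0)
  # arms are fully separated (monotone likelihood), so use the score test
  expect_lt(fit$score_p, 0.05)

  # permuted labels under the null: p roughly uniform, median coef near 0
  set.seed(42)
  stats <- replicate(200, {
    tt <- rexp(40); ev <- rbinom(40, 1, 0.8); xx <- sample(rep(0:1, 20))
    f <- cox_univariate(tt, ev, xx)
    c(f$coefficient, f$p_value)
  })
  expect_lt(abs(median(stats[1, ])), 0.15)
  expect_gt(mean(stats[2, ] < 0.5), 0.4)
  expect_lt(mean(stats[2, ] < 0.5), 0.6)
  expect_lt(mean(stats[2, ] < 0.05), 0.12)
})

test_that("non-estimable Cox inputs raise typed errors", {
  expect_error(cox_univariate(c(1, 2, 3, 4), c(0, 0, 0, 0), c(0, 1, 0, 1)),
               class = "psnet_not_estimable")
  expect_error(cox_univariate(c(1, 2, 3, 4), c(1, 1, 0, 1), c(1, 1, 1, 1)),
               class = "psnet_not_estimable")
})

test_that("hazard ratio inverts when the covariate is flipped", {
  set.seed(43)
  tt <- rexp(60, rate = 0.1 * exp(0.8 * rep(0:1, 30)))
  ev <- rbinom(60, 1, 0.9)
  x <- rep(0:1, 30)
  f1 <- cox_univariate(tt, ev, x)
  f2 <- cox_univariate(tt, ev, 1 - x)
  expect_equal(f2$hazard_ratio, 1 / f1$hazard_ratio, tolerance = 1e-8)
  expect_equal(f2$p_value, f1$p_value, tolerance = 1e-8)
})

test_that("log-rank test is exactly null on identical arms", {
  time <- c(3, 6, 9, 12, 15)
  event <- c(1, 1, 0, 1, 1)
  km <- km_logrank(c(time, time), c(event, event), rep(0:1, each = 5))
  expect_equal(km$chisq, 0, tolerance = 1e-12)
  expect_equal(km$p_value, 1, tolerance = 1e-12)
})

test_that("log-rank terms match hand-enumerated hypergeometric computation", {
  # 6-patient worked fixture, no tied event times
  time <- c(2, 4, 5, 7, 9, 12)
  event <- c(1, 1, 0, 1, 1, 1)
  arm <- c(0, 1, 0, 1, 0, 1)
  km <- km_logrank(time, event, arm)
  oracle <- logrank_terms_oracle(time, event, arm)
  expect_equal(km$obs[1], oracle$O, tolerance = 1e-12)
  expect_equal(km$exp[1], oracle$E, tolerance = 1e-10)
  expect_equal(km$chisq, oracle$chisq, tolerance = 1e-10)
})

test_that("log-rank p is approximately uniform under random splits", {
  set.seed(44)
  ps <- replicate(200, {
    tt <- rexp(40); ev <- rbinom(40, 1, 0.8)
    km_logrank(tt, ev, sample(rep(0:1, 20)))$p_value
  })
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps < 0.5), 0.38)
})

test_that("log-rank p agrees with the Cox score test on untied data", {
  set.seed(45)
  for (rep in 1:5) {
    tt <- rexp(80, rate = 0.1 * exp(0.5 * rep(0:1, 40)))
    ev <- rbinom(80, 1, 0.85)
    x <- rep(0:1, 40)
    km <- km_logrank(tt, ev, x)
    cx <- cox_univariate(tt, ev, x)
    expect_equal(km$p_value, cx$score_p, tolerance = 0.1)
  }
})

test_that("Kaplan-Meier curves carry censoring marks and start at 1", {
  time <- c(2, 4, 5, 7, 9, 12)
  event <- c(1, 1, 0, 1, 1, 1)
  km <- km_logrank(time, event, c(0, 1, 0, 1, 0, 1))
  expect_true(all(km$curves$surv <= 1 & km$curves$surv >= 0))
  expect_equal(sum(km$curves$n_censor), 1)
})

test_that("screening retains a planted Group 1 effect and only that", {
  set.seed(46)
  n <- 200
  ids <- sprintf("T%03d", 1:n)
  # construct expression so the three RNAs give balanced high/low splits
  lnc <- matrix(2^rnorm(n, 8, 1.5), 1, n,
                dimnames = list("LNCX", ids))
  mi <- matrix(2^rnorm(n, 8, 1.5), 1, n, dimnames = list("hsa-mir-x", ids))
  mrna <- matrix(2^rnorm(n, 8, 1.5), 1, n, dimnames = list("GX", ids))
  lab <- assign_groups(median_dichotomize(log2(lnc[1, ] + 1)),
                       median_dichotomize(log2(mi[1, ] + 1)),
                       median_dichotomize(log2(mrna[1, ] + 1)))
  surv <- simulate_survival(lab, lambda = 1 / 1000, beta = log(3),
                            censoring = 0.2,
                            risk_pattern = "lnc_high.mrna_low", seed = 47)
  tri <- data.frame(lncRNA = "LNCX", miRNA = "hsa-mir-x", mRNA = "GX")
  sc <- screen_triplets(tri, list(lnc = lnc, mi = mi, mrna = mrna), surv,
                        alpha = 0.01)
  g1 <- sc$results[sc$results$group == "Group1", ]
  g2 <- sc$results[sc$results$group == "Group2", ]
  expect_true(g1$retained)
  expect_false(isTRUE(g2$retained))
  expect_equal(nrow(sc$prognostic), 1L)

  # vacuous threshold
  sc0 <- screen_triplets(tri, list(lnc = lnc, mi = mi, mrna = mrna), surv,
                         alpha = 0)
  expect_equal(nrow(sc0$prognostic), 0L)
})

test_that("simulated survival recovers planted log hazard ratios", {
  # planted beta in {0.5, 1.0}: mean estimate within 0.1 over replicates
  set.seed(48)
  for (beta in c(0.5, 1.0)) {
    est <- replicate(40, {
      n <- 500
      ids <- sprintf("p%03d", 1:n)
      lab <- data.frame(sample_id = ids,
                        sub_pattern = sample(rep(c("a", "b"), n / 2)),
                        stringsAsFactors = FALSE)
      surv <- simulate_survival(lab, lambda = 1 / 1500, beta = beta,
                                censoring = 0.3, risk_pattern = "b")
      cox_univariate(surv$time, surv$event,
                     lab$sub_pattern == "b")$coefficient
    })
    expect_lt(abs(mean(est) - beta), 0.1)
  }
})

test_that("the optional 8-level pattern screen reports an LRT p-value", {
  set.seed(49)
  n <- 120
  ids <- sprintf("T%03d", 1:n)
  mats <- lapply(c(8, 8, 8), function(m)
    matrix(2^rnorm(n, m, 1.5), 1, n))
  rownames(mats[[1]]) <- "LNCX"; rownames(mats[[2]]) <- "hsa-mir-x"
  rownames(mats[[3]]) <- "GX"
  for (m in mats) colnames(m) <- ids
  colnames(mats[[1]]) <- colnames(mats[[2]]) <- colnames(mats[[3]]) <- ids
  surv <- data.frame(sample_id = ids, time = rexp(n, 1 / 500),
                     event = rbinom(n, 1, 0.7), stringsAsFactors = FALSE)
  tri <- data.frame(lncRNA = "LNCX", miRNA = "hsa-mir-x", mRNA = "GX")
  sc <- screen_triplets(tri, list(lnc = mats[[1]], mi = mats[[2]],
                                  mrna = mats[[3]]),
                        surv, method = "patterns8")
  expect_true(is.data.frame(sc$patterns8))
  expect_true(sc$patterns8$lrt_p >= 0 && sc$patterns8$lrt_p <= 1)
})
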