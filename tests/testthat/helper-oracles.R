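# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# partial correlation as the Pearson correlation of least-squares residuals
pcor_residual_oracle <- function(x, y, z) {
  rx <- stats::resid(stats::lm(x ~ z))
  ry <- stats::resid(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# two-pass definitional Pearson correlation
pearson_definitional_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# brute-force triple loop over all (lncRNA, miRNA, mRNA) combinations
triplet_bruteforce_oracle <- function(lnc_pairs, mrna_pairs,
                                      lncs, mis, mrnas) {
  keep <- list()
  for (x in lncs) for (z in mis) for (y in mrnas) {
    if (any(lnc_pairs$regulator == x & lnc_pairs$mirna == z) &&
        any(mrna_pairs$regulator == y & mrna_pairs$mirna == z) &&
        x != y && x != z && y != z)
      keep[[length(keep) + 1L]] <- c(x, z, y)
  }
  length(keep)
}

# hand-written Cox log partial likelihood for a single covariate, no ties
cox_loglik_oracle <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  eta <- beta * x
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      ll <- ll + eta[i] - log(sum(exp(eta[risk])))
    }
  }
  ll
}

# log-rank observed/expected/variance terms by direct hypergeometric
# enumeration over event times
logrank_terms_oracle <- function(time, event, arm) {
  stopifnot(length(unique(arm)) == 2L)
  arms <- sort(unique(arm))
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tt in ev_times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & arm == arms[1L])
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & arm == arms[1L])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(O = O, E = E, V = V, chisq = (O - E)^2 / V)
}

# forge a minimal psnet fit for unit-testing selection logic
forge_fit <- function(delta_signed, passes = NULL, n_normal = 100L,
                      control = psnet_control()) {
  nt <- nrow(delta_signed)
  m <- ncol(delta_signed)
  tumor_ids <- sprintf("T%03d", seq_len(m))
  colnames(delta_signed) <- tumor_ids
  if (is.null(passes)) passes <- matrix(TRUE, nt, m,
                                        dimnames = list(NULL, tumor_ids))
  triplets <- data.frame(lncRNA = sprintf("L%d", seq_len(nt)),
                         miRNA = sprintf("hsa-mir-%d", seq_len(nt)),
                         mRNA = sprintf("G%d", seq_len(nt)),
                         excluded = FALSE, reason = NA_character_,
                         stringsAsFactors = FALSE)
  structure(list(triplets = triplets,
                 rho_ref = rep(0.9, nt),
                 p_ref = rep(0, nt),
                 rho_pert = delta_signed + 0.9,
                 p_pert = matrix(0, nt, m, dimnames = list(NULL, tumor_ids)),
                 delta_signed = delta_signed,
                 delta_rho = abs(delta_signed),
                 passes = passes, n_normal = n_normal,
                 tumor_ids = tumor_ids, transform = "log2",
                 control = control),
            class = "psnet")
}

# small deterministic association fixture written to a temp file
write_assoc_tmp <- function(rows, header = NULL) {
  path <- tempfile(fileext = ".tsv")
  lines <- vapply(rows, function(r) paste(r, collapse = "\t"), character(1))
  if (!is.null(header)) lines <- c(paste(header, collapse = "\t"), lines)
  writeLines(lines, path)
  path
}
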