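DEGENERATE_TOL <- 1e-12

#' Pearson correlation with degenerate-input checks
#'
#' Thin wrapper around the product-moment correlation that turns
#' zero-variance input into a typed error so that cohort-level code can
#' exclude the affected triplet instead of propagating `NA`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y))
    psnet_error("x and y must have equal length", "psnet_validate_error")
  if (length(x) < 3L)
    psnet_error("need at least 3 observations", "psnet_insufficient_error")
  if (sd(x) < DEGENERATE_TOL || sd(y) < DEGENERATE_TOL)
    psnet_error("zero variance input", "psnet_degenerate_error")
  min(1, max(-1, cor(x, y)))
}

#' First-order partial correlation
#'
#' Correlation between `x` (lncRNA) and `y` (mRNA) after removing the linear
#' effect of `z` (the shared miRNA):
#' \deqn{\rho(x,y|z) = \frac{r_{xy} - r_{xz} r_{yz}}
#'   {\sqrt{1-r_{xz}^2}\sqrt{1-r_{yz}^2}}}
#' where \eqn{r} denotes the Pearson correlation. The result is clipped to
#' \[-1, 1\] against floating-point overshoot. Equivalent to the Pearson
#' correlation of the residuals of `x` and `y` after least-squares regression
#' on `z`.
#'
#' @param x,y,z numeric vectors of equal length >= 4.
#' @return partial correlation in \[-1, 1\].
#' @export
#' @examples
#' set.seed(1)
#' z <- rnorm(30); x <- z + rnorm(30); y <- z + rnorm(30)
#' partial_cor(x, y, z)
partial_cor <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n)
    psnet_error("x, y, z must have equal length", "psnet_validate_error")
  if (n < 4L)
    psnet_error("need at least 4 observations for a first-order partial correlation",
                "psnet_insufficient_error")
  rxy <- pearson_cor(x, y)
  rxz <- pearson_cor(x, z)
  ryz <- pearson_cor(y, z)
  den <- sqrt(max(0, 1 - rxz^2)) * sqrt(max(0, 1 - ryz^2))
  if (den < DEGENERATE_TOL)
    psnet_error("degenerate conditioning: |cor(x,z)| or |cor(y,z)| is 1",
                "psnet_degenerate_error")
  min(1, max(-1, (rxy - rxz * ryz) / den))
}

#' P-value for a first-order partial correlation
#'
#' Two-sided p-value from the t statistic
#' \eqn{t = \rho \sqrt{(n-3)/(1-\rho^2)}} referred to a t distribution with
#' `n - 3` degrees of freedom (n observations, one conditioning variable).
#' `rho = +/-1` gives `p = 0`.
#'
#' @param rho partial correlation(s) in \[-1, 1\]; vectorized.
#' @param n number of observations used (>= 4).
#' @return two-sided p-value(s) in \[0, 1\].
#' @export
pcor_pvalue <- function(rho, n) {
  if (any(n < 4L))
    psnet_error("partial-correlation test needs n >= 4", "psnet_insufficient_error")
  if (any(abs(rho) > 1 + 1e-8, na.rm = TRUE))
    psnet_error("|rho| must be <= 1", "psnet_validate_error")
  rho <- pmin(1, pmax(-1, rho))
  p <- ifelse(abs(rho) >= 1, 0,
              2 * pt(-abs(rho) * sqrt((n - 3) / pmax(1 - rho^2, .Machine$double.eps)),
                     df = n - 3))
  pmin(1, pmax(0, p))
}

# Vectorized per-triplet partial correlations.
# X: samples x genes numeric matrix; li/zi/yi: equal-length index vectors into
# the columns of X (lncRNA, miRNA, mRNA per triplet). Returns rho (NA where
# degenerate) and a reason string for degenerate triplets.
triplet_pcor_matrix <- function(X, li, zi, yi) {
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, check.margin = FALSE)
  ss <- sqrt(colSums(Xc^2))
  zero_var <- ss < DEGENERATE_TOL * sqrt(n)
  ss[ss == 0] <- 1
  Z <- sweep(Xc, 2L, ss, "/", check.margin = FALSE)
  cc <- function(a, b) colSums(Z[, a, drop = FALSE] * Z[, b, drop = FALSE])
  rxy <- cc(li, yi); rxz <- cc(li, zi); ryz <- cc(yi, zi)
  den <- sqrt(pmax(0, 1 - rxz^2)) * sqrt(pmax(0, 1 - ryz^2))
  rho <- (rxy - rxz * ryz) / den
  rho <- pmin(1, pmax(-1, rho))
  bad_var <- zero_var[li] | zero_var[zi] | zero_var[yi]
  bad_den <- !bad_var & (den < DEGENERATE_TOL)
  rho[bad_var | bad_den] <- NA_real_
  reason <- rep(NA_character_, length(li))
  reason[bad_var] <- "zero variance"
  reason[bad_den] <- "degenerate conditioning"
  list(rho = rho, reason = reason, n = n)
}
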