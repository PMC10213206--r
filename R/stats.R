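# Study-level statistics: paired Wilcoxon signed-rank (exact enumeration for
# small samples), Pearson correlations and their dependent-groups comparison,
# robust Mahalanobis outlier exclusion, and z-scoring.

#' Build a paired sample, excluding participants with missing values
#'
#' @param ids Participant labels.
#' @param x,y Paired measurements (same length as `ids`).
#' @return An object of class `paired_sample` with complete pairs only and
#'   `n_excluded_missing`.
#' @export
paired_sample <- function(ids, x, y) {
  stopifnot(length(x) == length(y), length(ids) == length(x))
  ok <- is.finite(x) & is.finite(y)
  structure(list(ids = ids[ok], x = x[ok], y = y[ok],
                 n_excluded_missing = sum(!ok)),
            class = "paired_sample")
}

#' Two-sided Wilcoxon signed-rank test for paired data
#'
#' Zero differences are dropped; absolute differences are ranked with
#' midranks for ties. For `m <= exact_limit` non-zero differences the
#' two-sided p-value is exact, by enumeration of all `2^m` sign assignments
#' (`p = min(1, 2 min(P(W+ <= w), P(W+ >= w)))`); otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. All differences zero gives `p = 1` with a degenerate flag.
#'
#' @param sample A [paired_sample()], or a numeric vector `x` of first
#'   measurements.
#' @param y Second measurements when `sample` is a plain vector.
#' @param exact_limit Largest `m` for exact enumeration.
#' @return A list of class `wbcg_test`: `statistic` (`W = min(W+, W-)`),
#'   `w_plus`, `p_value`, `method` (`"exact_enumeration"` or
#'   `"normal_approx"`), `n` (non-zero differences), `degenerate`, `alpha`.
#' @export
wilcoxon_signed_rank <- function(sample, y = NULL, exact_limit = 12L) {
  if (inherits(sample, "paired_sample")) {
    d <- sample$x - sample$y
  } else {
    stopifnot(!is.null(y), length(sample) == length(y))
    d <- sample - y
  }
  d <- d[is.finite(d)]
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    return(structure(list(statistic = 0, w_plus = 0, p_value = 1,
                          method = "degenerate", n = 0L, degenerate = TRUE,
                          alpha = 0.05), class = "wbcg_test"))
  }
  if (m < 3) warning("fewer than 3 non-zero differences; test is uninformative")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  if (m <= exact_limit) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    all_w <- as.vector(signs %*% r)
    p_lo <- mean(all_w <= w_plus + 1e-9)
    p_hi <- mean(all_w >= w_plus - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact_enumeration"
  } else {
    e_w <- m * (m + 1) / 4
    ties <- table(r)
    v_w <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - e_w - 0.5 * sign(w_plus - e_w)) / sqrt(v_w)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  structure(list(statistic = w, w_plus = w_plus, p_value = p, method = method,
                 n = m, degenerate = FALSE, alpha = 0.05),
            class = "wbcg_test")
}

#' @export
print.wbcg_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): W = %g, n = %d, p = %.4g\n",
              x$method, x$statistic, x$n, x$p_value))
  invisible(x)
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation with input validation (at least 3 complete
#' pairs, non-degenerate variance).
#'
#' @param x,y Numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)
}

#' Compare two dependent, overlapping correlations
#'
#' Steiger-type z-test for `H0: rho_jk = rho_jh` when both correlations share
#' the variable `j` (measured on the same subjects): the Fisher-transformed
#' difference is scaled by the covariance implied by `r_kh`, using the mean
#' correlation in the covariance term.
#'
#' @param r_jk,r_jh The two correlations sharing variable `j`.
#' @param r_kh Correlation between the non-shared variables.
#' @param n Number of subjects (>= 10).
#' @return A list of class `wbcg_test` with `statistic` (z), `p_value`,
#'   `method`.
#' @export
compare_dependent_correlations <- function(r_jk, r_jh, r_kh, n) {
  stopifnot(n >= 10, abs(r_kh) < 1)
  if (abs(r_jk) >= 1 || abs(r_jh) >= 1)
    stop("degenerate correlation: |r| = 1")
  z1 <- atanh(r_jk)
  z2 <- atanh(r_jh)
  rbar <- (r_jk + r_jh) / 2
  # covariance of the two correlations (shared-variable term), Steiger's psi
  psi <- (r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)) /
    (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * psi))
  structure(list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
                 method = "steiger_dependent_z", n = n, degenerate = FALSE,
                 alpha = 0.05), class = "wbcg_test")
}

#' Robust Mahalanobis outlier detection
#'
#' Location and scatter from a minimum-covariance-determinant fit (subset
#' fraction 0.75, deterministic given `seed`), followed by the standard
#' reweighting step (classical moments of the points inside the 97.5%
#' chi-square radius of the raw fit, which removes the raw MCD's
#' anti-conservative bias); points whose squared reweighted distance exceeds
#' the chi-square quantile at `1 - alpha` (df = number of columns) are
#' flagged.
#'
#' @param points n-by-d numeric matrix (n >= 10).
#' @param alpha Chi-square significance level.
#' @param subset_fraction MCD subset fraction.
#' @param seed Seed for the MCD subset search.
#' @return Logical outlier mask of length n, with attribute `d2` (squared
#'   robust distances).
#' @export
robust_mahalanobis_outliers <- function(points, alpha = 0.05,
                                        subset_fraction = 0.75, seed = 1) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 10)
  fit <- tryCatch(
    with_seed(seed,
      MASS::cov.rob(points, method = "mcd",
                    quantile.used = floor(subset_fraction * n))),
    error = function(e) stop("outlier-detection error: ", conditionMessage(e)))
  if (!is.finite(determinant(fit$cov)$modulus) ||
      rcond(fit$cov) < .Machine$double.eps * 100)
    stop("outlier-detection error: singular robust scatter")
  p <- ncol(points)
  d2_raw <- stats::mahalanobis(points, fit$center, fit$cov)
  q <- stats::qchisq(0.975, df = p)
  keep <- d2_raw <= q
  center <- colMeans(points[keep, , drop = FALSE])
  # classical moments of the retained points, rescaled for the truncation
  # bias (normal-model consistency factor of the reweighted MCD)
  consistency <- stats::pchisq(q, df = p + 2) / stats::pchisq(q, df = p)
  scatter <- stats::cov(points[keep, , drop = FALSE]) / consistency
  if (rcond(scatter) < .Machine$double.eps * 100)
    stop("outlier-detection error: singular robust scatter")
  d2 <- stats::mahalanobis(points, center, scatter)
  mask <- d2 > stats::qchisq(1 - alpha, df = ncol(points))
  attr(mask, "d2") <- d2
  mask
}

#' Z-score normalization across the whole sample
#'
#' @param x Numeric vector with non-zero standard deviation.
#' @return `(x - mean) / sd`, NA values propagated.
#' @export
zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("zero standard deviation: cannot z-score")
  (x - mean(x, na.rm = TRUE)) / s
}
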