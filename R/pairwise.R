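# Variance and significance machinery for the difference of two measured
# quantities: paired/correlated or independent, continuous or binary.

#' Variance of a difference of two correlated quantities
#'
#' \deqn{var(A-B) = \sigma_A^2 + \sigma_B^2 - 2 r \sigma_A \sigma_B}
#' which reduces to the independent sum at `r = 0` and is bounded by
#' \eqn{(\sigma_A - \sigma_B)^2} and \eqn{(\sigma_A + \sigma_B)^2}.
#'
#' @param var_a,var_b Component variances (nonnegative).
#' @param r Pearson correlation between the two quantities, in \[-1, 1\].
#' @return The variance of `A - B`.
#' @examples
#' variance_of_difference(9, 16, 0)   # half-widths 3 and 4 compose to 5
#' @export
variance_of_difference <- function(var_a, var_b, r = 0) {
  if (var_a < 0 || var_b < 0) stop("variances must be nonnegative")
  if (abs(r) > 1) stop("|r| must not exceed 1")
  var_a + var_b - 2 * r * sqrt(var_a * var_b)
}

#' Paired-difference summary statistics
#'
#' Mean, (n-1)-denominator variance and standard error of the elementwise
#' differences of two aligned result vectors (the paired-t building block).
#' Algebraically the variance equals [variance_of_difference()] evaluated at
#' the sample moments of `a` and `b`.
#'
#' @param a,b Numeric vectors of equal length `n >= 2`, aligned by system.
#' @return List with `mean_diff`, `var_diff`, `se_diff` and `n`.
#' @export
paired_difference_stats <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least two paired observations")
  d <- a - b
  var_diff <- stats::var(d)
  list(mean_diff = mean(d), var_diff = var_diff,
       se_diff = sqrt(var_diff / n), n = n)
}

#' Two-sample t statistic
#'
#' Pooled-variance form with `df = n_a + n_b - 2`, or the unequal-variance
#' form with Welch–Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric vectors, each of length at least 2.
#' @param equal_variance Pool the variance estimates? Default `TRUE`.
#' @return List with `t`, `df`, `p` (two-sided) and the method used. A zero
#'   pooled variance with unequal means yields an infinite statistic with a
#'   warning.
#' @export
two_sample_t <- function(a, b, equal_variance = TRUE) {
  n_a <- length(a); n_b <- length(b)
  if (n_a < 2 || n_b < 2) stop("need at least two observations per sample")
  va <- stats::var(a); vb <- stats::var(b)
  dm <- mean(a) - mean(b)
  if (equal_variance) {
    df <- n_a + n_b - 2
    pooled <- ((n_a - 1) * va + (n_b - 1) * vb) / df
    denom <- sqrt(1 / n_a + 1 / n_b) * sqrt(pooled)
    method <- "pooled two-sample t"
  } else {
    sa <- va / n_a; sb <- vb / n_b
    denom <- sqrt(sa + sb)
    df <- (sa + sb)^2 / (sa^2 / (n_a - 1) + sb^2 / (n_b - 1))
    method <- "Welch two-sample t"
  }
  if (denom == 0) {
    if (dm == 0) {
      t <- 0
    } else {
      warning("zero variance with unequal means: infinite t statistic")
      t <- sign(dm) * Inf
    }
  } else {
    t <- dm / denom
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), method = method)
}

#' Variance of a difference of two proportions
#'
#' Bernoulli variances \eqn{p(1-p)} fed through
#' [variance_of_difference()]. The complementary two-category case
#' (`p_a + p_b = 1`, `r = -1`) collapses to `4 * p_a * (1 - p_a)`.
#'
#' @param p_a,p_b Proportions in \[0, 1\].
#' @param r Correlation between the two indicator vectors.
#' @return Variance of the per-observation difference variable.
#' @export
binary_diff_variance <- function(p_a, p_b, r = 0) {
  if (p_a < 0 || p_a > 1 || p_b < 0 || p_b > 1)
    stop("proportions must lie in [0, 1]")
  variance_of_difference(p_a * (1 - p_a), p_b * (1 - p_b), r)
}

#' The 2/sqrt(N) rule for a binary split
#'
#' Is an observed yes/no split significantly different from 50:50 at roughly
#' the 95% level? The complementary-category variance gives the rule
#' \eqn{(\Delta N)^2 > 4N}; both sides of the inequality are reported.
#' 120 compounds splitting 70/50 give \eqn{400 < 480}: not significant.
#'
#' @param n_yes,n_no Nonnegative counts.
#' @return List with `delta_n_squared`, `threshold` (`4N`), `significant`,
#'   and the counts.
#' @export
binary_split_test <- function(n_yes, n_no) {
  if (n_yes < 0 || n_no < 0 || n_yes != round(n_yes) || n_no != round(n_no))
    stop("counts must be nonnegative integers")
  n <- n_yes + n_no
  if (n == 0) stop("no observations")
  dn2 <- (n_yes - n_no)^2
  list(delta_n_squared = dn2, threshold = 4 * n,
       significant = dn2 > 4 * n, n = n, n_yes = n_yes, n_no = n_no)
}
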