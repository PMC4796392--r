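# Comparing Pearson correlation coefficients: Fisher z machinery,
# triangle bounds, the independent-noise product rule, and Pearson's
# covariance of two correlations sharing a reference variable.

#' Fisher z-transform and its inverse
#'
#' \eqn{z = \tfrac{1}{2}\ln\frac{1+r}{1-r}}; renders the sampling
#' distribution of Pearson r approximately Gaussian with variance
#' \eqn{1/(n-3)}.
#'
#' @param r Correlation with `|r| < 1`.
#' @param z Transformed value.
#' @return The transformed (or back-transformed) value.
#' @examples
#' fisher_z(0.8)   # 1.099
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be strictly less than 1")
  atanh(r)
}

#' @rdname fisher_z
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Confidence interval for a Pearson correlation
#'
#' Symmetric Gaussian limits in Fisher z-space,
#' \eqn{z \pm z_{crit}/\sqrt{n-3}}, back-transformed to r-space where they
#' become asymmetric (shorter toward the nearer bound).
#'
#' @param r Observed correlation, `|r| < 1`.
#' @param n Sample size, at least 4.
#' @param level Confidence level, default 0.95.
#' @return An [asym_interval()] in r-space.
#' @examples
#' r_confidence_interval(0.8, 50)   # [0.671, 0.882]
#' @export
r_confidence_interval <- function(r, n, level = 0.95) {
  if (n < 4) stop("need n >= 4 so that n - 3 > 0")
  z <- fisher_z(r)
  half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  lo <- inverse_fisher_z(z - half)
  hi <- inverse_fisher_z(z + half)
  asym_interval(r, lower = r - lo, upper = hi - r, level = level)
}

#' Compare two independent correlations
#'
#' Fisher z difference over its standard error,
#' \eqn{(z_a - z_b)/\sqrt{1/(n_a-3) + 1/(n_b-3)}}, tested against a Student t
#' critical value with `min(n_a, n_b) - 2` degrees of freedom (the
#' convention giving 2.01 at n = 50), or a plain normal value.
#'
#' @param r_a,r_b The two correlations.
#' @param n_a,n_b Their sample sizes.
#' @param level Two-sided confidence level, default 0.95.
#' @param critical `"t"` (default) or `"normal"`.
#' @return List with `statistic`, `critical_value`, `df` (NA for normal),
#'   `significant` and `p`.
#' @export
compare_independent_r <- function(r_a, n_a, r_b, n_b = n_a, level = 0.95,
                                  critical = c("t", "normal")) {
  critical <- match.arg(critical)
  if (n_a < 4 || n_b < 4) stop("need n >= 4 in both samples")
  se <- sqrt(1 / (n_a - 3) + 1 / (n_b - 3))
  stat <- (fisher_z(r_a) - fisher_z(r_b)) / se
  alpha <- 1 - level
  if (critical == "t") {
    df <- min(n_a, n_b) - 2
    crit <- stats::qt(1 - alpha / 2, df)
    p <- 2 * stats::pt(-abs(stat), df)
  } else {
    df <- NA_real_
    crit <- stats::qnorm(1 - alpha / 2)
    p <- 2 * stats::pnorm(-abs(stat))
  }
  list(statistic = stat, critical_value = crit, df = df,
       significant = abs(stat) > crit, p = p)
}

#' Triangle bounds on an inter-method correlation
#'
#' Because `1 - r` is a metric distance, two correlations with a shared
#' reference constrain the correlation between the methods themselves:
#' \deqn{r_{xy} + r_{xz} - 1 < r_{yz} < 1 - |r_{xy} - r_{xz}|}
#'
#' @param r_xy,r_xz Correlations of the two methods with the shared reference.
#' @return Numeric `c(lower, upper)`.
#' @examples
#' triangle_bounds(0.9, 0.8)   # (0.7, 0.9)
#' @export
triangle_bounds <- function(r_xy, r_xz) {
  if (abs(r_xy) > 1 || abs(r_xz) > 1) stop("|r| must not exceed 1")
  c(lower = r_xy + r_xz - 1, upper = 1 - abs(r_xy - r_xz))
}

#' Expected inter-method correlation under independent noise
#'
#' If the two methods' errors about the shared reference are independent,
#' the expected correlation between them is simply the product
#' \eqn{\langle r_{yz} \rangle \approx r_{xy} r_{xz}}.
#'
#' @inheritParams triangle_bounds
#' @return The product `r_xy * r_xz`.
#' @export
expected_ryz <- function(r_xy, r_xz) {
  if (abs(r_xy) > 1 || abs(r_xz) > 1) stop("|r| must not exceed 1")
  r_xy * r_xz
}

#' Covariance and correlation of two correlation coefficients
#'
#' Pearson's approximation for two correlations sharing a reference variable:
#' \deqn{cov(r_{xy}, r_{xz}) = \frac{1}{N}\left[r_{yz}^3 +
#'   (r_{yz} - \tfrac{1}{2} r_{xy} r_{xz})
#'   (1 - r_{yz}^2 - r_{xy}^2 - r_{xz}^2)\right]}
#' The variance of a single r follows from the self case,
#' \eqn{var(r) = (1 - r^2)^2 / N}. The correlation is the covariance
#' normalised by the two variances, clipped to \[-1, 1\] with a warning when
#' the approximation strays outside.
#'
#' @param r_xy,r_xz Correlations of the two methods with the reference.
#' @param r_yz Inter-method correlation.
#' @param n Sample size.
#' @return `cov_of_correlations`: the covariance. `corr_of_correlations`: the
#'   normalised correlation. `var_of_correlation`: the Eq-46 variance.
#' @examples
#' corr_of_correlations(0.9, 0.8, 0.72, 50)   # 0.36
#' @export
cov_of_correlations <- function(r_xy, r_xz, r_yz, n) {
  if (abs(r_xy) > 1 || abs(r_xz) > 1 || abs(r_yz) > 1)
    stop("|r| must not exceed 1")
  if (n < 1) stop("n must be positive")
  (r_yz^3 + (r_yz - 0.5 * r_xy * r_xz) *
     (1 - r_yz^2 - r_xy^2 - r_xz^2)) / n
}

#' @rdname cov_of_correlations
#' @export
var_of_correlation <- function(r_xy, n) (1 - r_xy^2)^2 / n

#' @rdname cov_of_correlations
#' @export
corr_of_correlations <- function(r_xy, r_xz, r_yz, n) {
  cc <- cov_of_correlations(r_xy, r_xz, r_yz, n) /
    sqrt(var_of_correlation(r_xy, n) * var_of_correlation(r_xz, n))
  if (abs(cc) > 1) {
    warning("correlation-of-correlations approximation outside [-1, 1]; clipped")
    cc <- sign(cc)
  }
  cc
}

#' Dependent-correlation difference interval
#'
#' Confidence interval for the difference of two correlations measured
#' against the same reference on the same sample. Builds asymmetric r-space
#' intervals via [r_confidence_interval()], estimates the correlation between
#' the two r values via [corr_of_correlations()] (with `r_yz` defaulting to
#' the independent-noise product rule), and combines the half-widths with
#' [combine_asymmetric_correlated()] directly in r-space (the route that
#' reproduces the worked arithmetic). A z-space variant instead returns the
#' interval for the difference of Fisher-transformed values, in z units.
#'
#' @param r_xy,r_xz The two correlations with the shared reference.
#' @param n Common sample size.
#' @param r_yz Inter-method correlation; default `r_xy * r_xz`.
#' @param level Confidence level, default 0.95.
#' @param space `"r"` (default, matches the worked arithmetic) or `"z"`.
#' @return List with the difference `interval` (an [asym_interval()]), the
#'   `corr_rr` used, and the two component intervals.
#' @examples
#' compare_dependent_r(0.9, 0.8, n = 50)   # [0.013, 0.22]
#' @export
compare_dependent_r <- function(r_xy, r_xz, n, r_yz = r_xy * r_xz,
                                level = 0.95, space = c("r", "z")) {
  space <- match.arg(space)
  tb <- triangle_bounds(r_xy, r_xz)
  if (r_yz < tb[["lower"]] || r_yz > tb[["upper"]])
    warning("r_yz lies outside the metric triangle bounds")
  corr_rr <- corr_of_correlations(r_xy, r_xz, r_yz, n)
  ia <- r_confidence_interval(r_xy, n, level)
  ib <- r_confidence_interval(r_xz, n, level)
  if (space == "r") {
    iv <- combine_asymmetric_correlated(ia, ib, corr_rr)
  } else {
    half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
    za <- asym_interval(fisher_z(r_xy), half, half, level)
    zb <- asym_interval(fisher_z(r_xz), half, half, level)
    iv <- combine_asymmetric_correlated(za, zb, corr_rr)
  }
  list(interval = iv, corr_rr = corr_rr, r_yz = r_yz,
       interval_a = ia, interval_b = ib, space = space)
}
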