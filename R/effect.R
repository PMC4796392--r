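# Size-of-effect measures and Bayesian reinterpretation of p-values.

#' Cohen's d (root-sum-of-variances form)
#'
#' Standardised absolute mean difference,
#' \eqn{d = |\langle B\rangle - \langle A\rangle| / \sqrt{\sigma_A^2 +
#' \sigma_B^2}}. Note the denominator is the root of the *sum* of the two
#' variances; the classic pooled-average convention
#' (\eqn{\sqrt{(\sigma_A^2+\sigma_B^2)/2}}) is available as an option.
#'
#' @param a,b Numeric sample vectors, or single means if `sd_a`/`sd_b` are
#'   supplied.
#' @param sd_a,sd_b Optional summary standard deviations (with scalar `a`,
#'   `b` as means).
#' @param pooled Use the classic pooled-average denominator? Default `FALSE`.
#' @return The effect size `d >= 0`.
#' @export
cohens_d <- function(a, b, sd_a = NULL, sd_b = NULL, pooled = FALSE) {
  if (is.null(sd_a) != is.null(sd_b))
    stop("supply both summary standard deviations or neither")
  if (is.null(sd_a)) {
    mean_a <- mean(a); mean_b <- mean(b)
    va <- stats::var(a); vb <- stats::var(b)
  } else {
    stopifnot(length(a) == 1L, length(b) == 1L)
    mean_a <- a; mean_b <- b
    va <- sd_a^2; vb <- sd_b^2
  }
  denom2 <- if (pooled) (va + vb) / 2 else va + vb
  if (denom2 == 0) stop("both variances are zero")
  abs(mean_b - mean_a) / sqrt(denom2)
}

#' Probability of superiority from Cohen's d
#'
#' Chance that a random draw from the better method's performance
#' distribution beats a random draw from the other's. The linear rule
#' \eqn{p \approx 0.25 d + 0.5} is a good approximation on `d` in \[0, 1\];
#' the exact equal-width Gaussian result is \eqn{\Phi(d/\sqrt{2})}.
#'
#' @param d Effect size, `d >= 0`.
#' @param mode `"linear"` or `"exact"`.
#' @return Probability in \[0.5, 1\]; the linear mode warns (and caps at 1)
#'   outside its validity range.
#' @examples
#' prob_superiority(0.8)   # 0.7
#' @export
prob_superiority <- function(d, mode = c("linear", "exact")) {
  mode <- match.arg(mode)
  if (d < 0) stop("d must be nonnegative (absolute effect size)")
  if (mode == "linear") {
    if (d > 1) warning("linear rule is calibrated for d in [0, 1]")
    min(0.25 * d + 0.5, 1)
  } else {
    stats::pnorm(d / sqrt(2))
  }
}

#' Minimum Bayes odds in favour of a real effect
#'
#' The best-case odds ratio for a new effect versus the null implied by a
#' p-value under the most favourable objective prior:
#' \deqn{O = -\frac{1}{e \, p \ln p}}
#' optionally scaled by a prior probability `q` that a new mechanism is in
#' play. The posterior probability of the null is `1 / (1 + O)`. Meaningful
#' for `p < 1/e` (beyond which the odds do not favour the effect; flagged).
#'
#' @param p Two-sided p-value in (0, 1).
#' @param prior_q Optional prior probability of a real effect in (0, 1\].
#' @return List with `odds`, `posterior_null` and `favours_effect`.
#' @examples
#' minimum_bayes_odds(0.05)   # odds 2.46, posterior null ~ 0.29
#' @export
minimum_bayes_odds <- function(p, prior_q = NULL) {
  if (p <= 0 || p >= 1) stop("p must lie strictly between 0 and 1")
  odds <- -1 / (exp(1) * p * log(p))
  if (!is.null(prior_q)) {
    if (prior_q <= 0 || prior_q > 1) stop("prior_q must lie in (0, 1]")
    odds <- prior_q * odds
  }
  favours <- p < exp(-1)
  if (!favours)
    warning("p >= 1/e: minimum odds do not favour the effect")
  list(odds = odds, posterior_null = 1 / (1 + odds),
       favours_effect = favours)
}

#' Posterior probability of a condition given a positive test
#'
#' Bayes' rule for a diagnostic test:
#' \deqn{p(D^+|T^+) = \frac{power \cdot prev}
#'   {power \cdot prev + \alpha (1 - prev)}}
#' The canonical teaching example (prevalence 2%, power 90%, false-positive
#' rate 5%) gives 18/67, about one in four — not 95%.
#'
#' @param prevalence Base rate of the condition in \[0, 1\].
#' @param power Sensitivity p(test positive | condition) in \[0, 1\].
#' @param alpha False-positive rate p(test positive | no condition).
#' @return The posterior probability.
#' @examples
#' posterior_positive(0.02, 0.9, 0.05)   # 18/67
#' @export
posterior_positive <- function(prevalence, power, alpha) {
  vals <- c(prevalence, power, alpha)
  if (any(vals < 0 | vals > 1)) stop("all rates must lie in [0, 1]")
  denom <- power * prevalence + alpha * (1 - prevalence)
  if (denom == 0) stop("degenerate test: zero probability of a positive")
  power * prevalence / denom
}

#' Posterior density of a true difference
#'
#' Under a flat prior the posterior for the true difference given an
#' observed mean difference and its standard error is the CLT Gaussian
#' centred on the observation. A user-supplied prior (tabulated on a grid)
#' is multiplied in and renormalised.
#'
#' @param observed_mean Observed mean difference.
#' @param se Standard error of the observed mean, `se > 0`.
#' @param prior `NULL` for flat, or a list/data frame with elements `diff`
#'   (ascending grid) and `density` (nonnegative, not all zero).
#' @param grid_points Grid resolution for the flat-prior case, default 2001
#'   over ±6 se.
#' @return List with `diff` (grid), `density` (normalised to unit trapezoid
#'   integral; a point-mass prior returns a single atom with `density = 1`),
#'   `mean` and `level95` (central 95% interval endpoints).
#' @export
posterior_difference_density <- function(observed_mean, se, prior = NULL,
                                         grid_points = 2001) {
  if (se <= 0) stop("se must be positive")
  if (is.null(prior)) {
    grid <- seq(observed_mean - 6 * se, observed_mean + 6 * se,
                length.out = grid_points)
    dens <- stats::dnorm(grid, observed_mean, se)
  } else {
    grid <- as.numeric(prior$diff)
    w <- as.numeric(prior$density)
    if (length(grid) != length(w) || any(w < 0) || all(w == 0))
      stop("prior grid must give nonnegative density, not all zero")
    if (is.unsorted(grid, strictly = length(grid) > 1))
      stop("prior grid must be strictly ascending")
    dens <- stats::dnorm(grid, observed_mean, se) * w
    if (all(dens == 0)) stop("non-normalizable posterior (prior excludes data)")
  }
  if (length(grid) == 1L) {
    return(list(diff = grid, density = 1, mean = grid,
                level95 = c(grid, grid)))
  }
  # trapezoid normalisation
  dx <- diff(grid)
  z <- sum((dens[-1] + dens[-length(dens)]) / 2 * dx)
  if (z == 0) stop("non-normalizable posterior")
  dens <- dens / z
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * dx))
  q <- function(p) grid[which.min(abs(cdf - p))]
  list(diff = grid, density = dens,
       mean = sum((grid[-1] * dens[-1] + grid[-length(grid)] *
                     dens[-length(dens)]) / 2 * dx),
       level95 = c(q(0.025), q(0.975)))
}
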