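# Seeded synthetic-data generators: the noisy-predictor simulation designs
# behind the correlation-comparison results, plus generic score-set and
# performance-matrix fixtures with prescribed correlation structure.

#' Generate correlated noisy predictors of a shared reference
#'
#' Two predictors of a fixed reference `x` (fifty evenly spaced values on
#' \[0, 4\] by default):
#' \deqn{y_i = x_i + \gamma N(0,1)_{y,i} + \eta N(0,1)_{z,i}}
#' \deqn{z_i = x_i + \delta N(0,1)_{z,i} + \epsilon N(0,1)_{y,i}}
#' With `eta = epsilon = 0` the noise streams are independent and the
#' inter-predictor correlation peaks at the product of the individual
#' correlations; sharing noise (`eta > 0`) tightens the distribution of the
#' difference of r values while preserving the marginals when the amplitudes
#' obey the quadrature identity (e.g. 0.595^2 + 0.708^2 = 0.925^2).
#' `gamma = 0.595` makes r(x, y) peak at 0.9; `0.925` peaks at 0.8.
#'
#' @param n_points Points per replicate, default 50.
#' @param x_range Inclusive range of the evenly spaced reference grid.
#' @param gamma,eta Noise amplitudes for `y` (own stream, shared stream).
#' @param delta,epsilon Noise amplitudes for `z` (own stream, shared stream).
#' @param replicates Number of replicates, default 1.
#' @param seed Optional integer seed for reproducibility.
#' @return List with `x` (vector) and `y`, `z` (n_points-by-replicates
#'   matrices), plus `r_xy`, `r_xz`, `r_yz` (per-replicate correlations).
#' @export
gen_correlated_predictors <- function(n_points = 50, x_range = c(0, 4),
                                      gamma = 0.595, eta = 0,
                                      delta = 0.925, epsilon = 0,
                                      replicates = 1, seed = NULL) {
  if (any(c(gamma, eta, delta, epsilon) < 0))
    stop("noise amplitudes must be nonnegative")
  if (replicates < 1) stop("need at least one replicate")
  if (!is.null(seed)) set.seed(seed)
  x <- seq(x_range[1], x_range[2], length.out = n_points)
  ny <- matrix(stats::rnorm(n_points * replicates), n_points)
  nz <- matrix(stats::rnorm(n_points * replicates), n_points)
  y <- x + gamma * ny + eta * nz
  z <- x + delta * nz + epsilon * ny
  list(x = x, y = y, z = z,
       r_xy = as.numeric(stats::cor(x, y)),
       r_xz = as.numeric(stats::cor(x, z)),
       r_yz = diag(stats::cor(y, z)))
}

#' Generate a pair of correlated binormal score sets
#'
#' Scores for two methods over the same actives and inactives. Each
#' compound's score under method m is
#' \eqn{s^m = \mu + \sqrt{\rho}\, c + \sqrt{1-\rho}\, e^m} with a shared
#' stream `c`, private streams `e^m`, and mean shift `mu = separation` for
#' actives only. `correlation = 1` makes the two methods identical;
#' `separation = 0` gives a true AUC of one half; the true AUC is
#' \eqn{\Phi(separation/\sqrt 2)}.
#'
#' @param n_active,n_inactive Class sizes, at least 1.
#' @param separation Mean score shift of actives, in score SD units.
#' @param correlation Inter-method score correlation knob in \[0, 1\].
#' @param seed Optional integer seed.
#' @return List with [score_set()]s `a` and `b`.
#' @export
gen_score_set <- function(n_active, n_inactive, separation = 1,
                          correlation = 0, seed = NULL) {
  if (n_active < 1 || n_inactive < 1) stop("need at least one of each class")
  if (correlation < 0 || correlation > 1)
    stop("correlation knob must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- n_active + n_inactive
  shared <- stats::rnorm(n)
  mk <- function(id) {
    s <- sqrt(correlation) * shared + sqrt(1 - correlation) * stats::rnorm(n)
    s[seq_len(n_active)] <- s[seq_len(n_active)] + separation
    score_set(s[seq_len(n_active)], s[-seq_len(n_active)], id)
  }
  list(a = mk("A"), b = mk("B"))
}

#' Generate a performance matrix with prescribed method covariance
#'
#' Gaussian per-system draws with given per-method means and a prescribed
#' method-to-method covariance across systems (via a Cholesky factor).
#'
#' @param n_methods,n_systems Matrix dimensions (`M`, `N`).
#' @param means Per-method means (recycled scalar allowed).
#' @param covariance M-by-M symmetric positive-definite matrix; default
#'   identity.
#' @param seed Optional integer seed.
#' @return A [performance_matrix()] (systems in rows, methods in columns).
#' @export
gen_performance_matrix <- function(n_methods, n_systems, means = 0,
                                   covariance = NULL, seed = NULL) {
  if (is.null(covariance)) covariance <- diag(n_methods)
  if (any(dim(covariance) != n_methods))
    stop("covariance must be n_methods x n_methods")
  ch <- tryCatch(chol(covariance),
                 error = function(e) stop("covariance must be positive definite"))
  means <- rep_len(means, n_methods)
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n_systems * n_methods), n_systems)
  m <- sweep(z %*% ch, 2, means, "+")
  colnames(m) <- paste0("method", seq_len(n_methods))
  performance_matrix(m)
}
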