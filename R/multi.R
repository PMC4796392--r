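# Family-wise comparison of many methods: FWER arithmetic, sequential
# p-value procedures, Pearson chi-squared, one-way ANOVA and its nested-model
# reading, covariance whitening, Tukey HSD and the equivalence-grouping
# layout.

#' Family-wise error rate
#'
#' Probability of at least one false positive among `k` independent tests
#' each run at per-test level `p`: \eqn{1 - (1 - p)^k}.
#'
#' @param p Per-comparison false-positive probability.
#' @param k Number of comparisons, at least 1.
#' @return The family-wise error probability.
#' @examples
#' fwer(0.05, 5)   # 0.226
#' @export
fwer <- function(p, k) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (k < 1) stop("k must be at least 1")
  1 - (1 - p)^k
}

# shared machinery: stable ascending-p order (ties broken by input position)
.p_order <- function(p) order(p, seq_along(p))

#' Holm-Bonferroni step-down procedure
#'
#' Orders the family by ascending p; the k-th smallest is tested against
#' `alpha / (N + 1 - k)` (strict inequality). The first failure stops the
#' scan and that method plus all larger-p methods are declared
#' non-significant. Controls the FWER at `alpha` and is conservative under
#' positive correlation between tests.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param alpha Family-wise level, default 0.05.
#' @param labels Optional method labels; defaults to names or indices.
#' @return Data frame (one row per method, input order) with `label`, `p`,
#'   `threshold`, `significant`.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05, labels = NULL) {
  fam <- .check_family(p_values, alpha, labels)
  n <- length(fam$p)
  ord <- .p_order(fam$p)
  thr <- alpha / (n + 1 - seq_len(n))
  pass <- fam$p[ord] < thr
  if (any(!pass)) pass[seq(which.min(pass), n)] <- FALSE  # stop at first failure
  sig <- logical(n); sig[ord] <- pass
  threshold <- numeric(n); threshold[ord] <- thr
  data.frame(label = fam$labels, p = fam$p, threshold = threshold,
             significant = sig, stringsAsFactors = FALSE)
}

#' Hochberg step-up procedure
#'
#' Scans from the largest p downward; the first index (counting from the
#' large-p end) with `p_(k) <= alpha / (N + 1 - k)` makes that method and all
#' smaller-p methods significant. Rejects at least everything Holm rejects,
#' at the price of an independence assumption between tests.
#'
#' @inheritParams holm_bonferroni
#' @return Data frame as in [holm_bonferroni()].
#' @export
hochberg_step_up <- function(p_values, alpha = 0.05, labels = NULL) {
  fam <- .check_family(p_values, alpha, labels)
  n <- length(fam$p)
  ord <- .p_order(fam$p)
  thr <- alpha / (n + 1 - seq_len(n))
  pass <- fam$p[ord] <= thr
  k <- if (any(pass)) max(which(pass)) else 0L  # largest index that passes
  sig <- logical(n)
  if (k > 0) sig[ord[seq_len(k)]] <- TRUE
  threshold <- numeric(n); threshold[ord] <- thr
  data.frame(label = fam$labels, p = fam$p, threshold = threshold,
             significant = sig, stringsAsFactors = FALSE)
}

.check_family <- function(p_values, alpha, labels) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.null(labels)) {
    labels <- names(p_values)
    if (is.null(labels)) labels <- as.character(seq_along(p_values))
  }
  if (length(labels) != length(p_values))
    stop("labels and p-values must have the same length")
  list(p = as.numeric(p_values), labels = labels)
}

#' Chi-squared test between two categorisations
#'
#' Paired classification counts `E` and `F` over the same categories; the
#' expected frequency per category is the average of the two:
#' \deqn{\chi^2 = \sum_i \frac{(E_i - (E_i + F_i)/2)^2}{(E_i + F_i)/2}}
#' with `M - 1` degrees of freedom.
#'
#' @param e,f Nonnegative integer count vectors of equal length and total.
#' @return List with `chi2`, `df`, `p`.
#' @export
chi2_two_methods <- function(e, f) {
  if (length(e) != length(f)) stop("count vectors must align")
  if (sum(e) != sum(f)) stop("paired categorisations must have equal totals")
  expected <- (e + f) / 2
  if (any(expected == 0)) stop("zero expected count in a category")
  chi2 <- sum((e - expected)^2 / expected)
  df <- length(e) - 1
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Chi-squared test against expected frequencies
#'
#' \deqn{\chi^2 = \sum_i (E_i - O_i)^2 / O_i} with `M - 1` degrees of
#' freedom, `O` being the reference frequencies.
#'
#' @param e Observed counts.
#' @param o Expected counts (all positive).
#' @return List with `chi2`, `df`, `p`.
#' @export
chi2_vs_expected <- function(e, o) {
  if (length(e) != length(o)) stop("count vectors must align")
  if (any(o <= 0)) stop("expected counts must be positive")
  chi2 <- sum((e - o)^2 / o)
  df <- length(e) - 1
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Performance matrix constructor
#'
#' An M-methods by N-systems grid of a scalar metric (e.g. per-target AUC),
#' stored methods-in-columns.
#'
#' @param x Numeric matrix or data frame, one column per method, one row per
#'   system; complete (no missing cells), `M >= 2`, `N >= 2`.
#' @return A numeric matrix of class `performance_matrix`.
#' @export
performance_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("performance matrix must be complete (no missing cells)")
  if (ncol(m) < 2) stop("need at least two methods")
  if (nrow(m) < 2) stop("need at least two systems")
  if (is.null(colnames(m))) colnames(m) <- paste0("method", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("system", seq_len(nrow(m)))
  class(m) <- c("performance_matrix", class(m))
  m
}

#' One-way analysis of variance over a performance matrix
#'
#' Decomposes the total sum of squares about the grand mean into a
#' between-method ("global") part, \eqn{SS_{global} = N \sum_i (\bar x_i -
#' \bar x)^2}, and a within-method ("local") part, and forms
#' \eqn{F = (SS_{global}/df_{global}) / (SS_{local}/df_{local})} with
#' `df_global = M - 1` and `df_local = M(N - 1)`. With unequal group sizes
#' the global term weights each group by its own `n_i`.
#'
#' @param pm A [performance_matrix()] (methods in columns), or a plain matrix.
#' @param level Confidence level for the critical value, default 0.95.
#' @return List with the three sums of squares, degrees of freedom, `F`, `p`,
#'   `critical_value` and the verdict `equivalent`. A zero local sum with
#'   nonzero global sum is reported as an infinite-F condition.
#' @export
anova_oneway <- function(pm, level = 0.95) {
  m <- if (inherits(pm, "performance_matrix")) pm else performance_matrix(pm)
  n <- nrow(m); M <- ncol(m)
  grand <- mean(m)
  local_means <- colMeans(m)
  ss_global <- n * sum((local_means - grand)^2)
  ss_local <- sum(sweep(m, 2, local_means)^2)
  ss_total <- sum((m - grand)^2)
  df_global <- M - 1
  df_local <- M * (n - 1)
  if (ss_local == 0) {
    if (ss_global > 0) warning("zero within-method variance: infinite F")
    f <- if (ss_global > 0) Inf else NaN
  } else {
    f <- (ss_global / df_global) / (ss_local / df_local)
  }
  crit <- stats::qf(level, df_global, df_local)
  list(ss_global = ss_global, ss_local = ss_local, ss_total = ss_total,
       df_global = df_global, df_local = df_local, df_total = n * M - 1,
       F = f, p = stats::pf(f, df_global, df_local, lower.tail = FALSE),
       critical_value = crit, level = level,
       equivalent = !is.nan(f) && f <= crit,
       method_means = local_means, grand_mean = grand)
}

#' F test for nested models
#'
#' Compares a simpler model (larger residual sum of squares, more residual
#' degrees of freedom) with a more complex one nested above it:
#' \deqn{F = \frac{(SS_{simple} - SS_{complex})/(df_{simple} - df_{complex})}
#'              {SS_{complex}/df_{complex}}}
#' One-way ANOVA is the special case "single grand mean" vs "one mean per
#' method".
#'
#' @param ss_simple,df_simple Residual sum of squares and df of the simpler
#'   model.
#' @param ss_complex,df_complex Same for the more complex model.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
f_test_nested <- function(ss_simple, df_simple, ss_complex, df_complex) {
  if (df_simple <= df_complex) stop("simpler model must have more residual df")
  if (ss_simple < ss_complex - 1e-12 * max(1, abs(ss_simple)))
    stop("nested complex model cannot fit worse than the simple one")
  df1 <- df_simple - df_complex
  f <- (max(ss_simple - ss_complex, 0) / df1) / (ss_complex / df_complex)
  list(F = f, df1 = df1, df2 = df_complex,
       p = stats::pf(f, df1, df_complex, lower.tail = FALSE))
}

#' Adjusted r-squared
#'
#' Penalises \eqn{r^2} for the `p` parameters used to fit `n` points:
#' \deqn{\bar r^2 = r^2 - (1 - r^2)\frac{p}{n - p - 1}}
#'
#' @param r2 Coefficient of determination in \[0, 1\].
#' @param p_params Number of fitted parameters.
#' @param n Number of data points; requires `n - p_params - 1 > 0`.
#' @return The adjusted value.
#' @export
adjusted_r2 <- function(r2, p_params, n) {
  if (n - p_params - 1 <= 0) stop("need n - p - 1 > 0")
  r2 - (1 - r2) * p_params / (n - p_params - 1)
}

#' Whitening transform for correlated methods
#'
#' Builds the M-by-M method covariance matrix from system-wise deviations
#' (1/(N-1) normalisation), eigendecomposes \eqn{V = A \Lambda^2 A^T} and
#' returns the inverse square root \eqn{W = A \Lambda^{-1} A^T}, which maps
#' the original, correlated method results into uncorrelated unit-variance
#' coordinates (\eqn{W V W^T = I}). Near-zero eigenvalues (duplicated
#' methods) are floored at `floor_frac` times the largest and flagged.
#'
#' @param pm A [performance_matrix()] (methods in columns).
#' @param floor_frac Relative eigenvalue floor, default `1e-10`.
#' @return List with `V`, `W`, `eigenvalues` (of V), `rotation`, and
#'   `floored` (logical per eigenvalue).
#' @export
whiten <- function(pm, floor_frac = 1e-10) {
  m <- if (inherits(pm, "performance_matrix")) pm else performance_matrix(pm)
  V <- stats::cov(unclass(m))
  eig <- eigen(V, symmetric = TRUE)
  lam2 <- eig$values
  if (max(lam2) <= 0) stop("all-zero variance: nothing to whiten")
  floor_val <- floor_frac * max(lam2)
  floored <- lam2 < floor_val
  if (any(floored)) {
    warning(sprintf("%d eigenvalue(s) below floor; floored (near-duplicate methods?)",
                    sum(floored)))
    lam2[floored] <- floor_val
  }
  W <- eig$vectors %*% diag(1 / sqrt(lam2), length(lam2)) %*% t(eig$vectors)
  dimnames(W) <- dimnames(V)
  list(V = V, W = W, eigenvalues = lam2, rotation = eig$vectors,
       floored = floored)
}

#' Correlation-corrected chi-squared for method means
#'
#' Quadratic form of the method means about their covariance-weighted common
#' mean \eqn{\mu = (1^T V^{-1} 1)^{-1} 1^T V^{-1} \bar x}:
#' \deqn{\chi^2 = n \,(\bar x - \mu 1)^T V^{-1} (\bar x - \mu 1)}
#' with `M - 1` degrees of freedom. `V` is the method covariance across
#' systems; `n_systems` supplies the sample-size scaling (the covariance of
#' the means is `V / n`). With `V = I` and `n_systems = 1` this reduces to
#' the plain between-method sum of squares about the arithmetic mean.
#'
#' @param means Vector of per-method means.
#' @param V Method covariance matrix (symmetric, invertible after flooring).
#' @param n_systems Number of systems each mean averages over; default 1.
#' @param level Confidence level for the verdict, default 0.95.
#' @return List with `chi2`, `df`, `p`, `mu`.
#' @export
correlated_chi2 <- function(means, V, n_systems = 1, level = 0.95) {
  M <- length(means)
  if (!is.matrix(V) || any(dim(V) != M)) stop("V must be M x M")
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular covariance matrix; whiten() with flooring first"))
  one <- rep(1, M)
  mu <- drop((one %*% Vi %*% means) / (one %*% Vi %*% one))
  d <- means - mu
  chi2 <- n_systems * drop(t(d) %*% Vi %*% d)
  df <- M - 1
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE), mu = mu,
       critical_value = stats::qchisq(level, df))
}

#' Studentized range quantile
#'
#' The critical value used by Tukey's HSD: the `p`-quantile of the maximal
#' standardised spread among `nmeans` group means with `df` error degrees of
#' freedom. Tabulated versions are hard to come by; this exposes the
#' numerical routine directly.
#'
#' @param p Probability, e.g. 0.95.
#' @param nmeans Number of group means.
#' @param df Error degrees of freedom.
#' @return The quantile (3.77 for `p = 0.95`, 3 means, 12 df).
#' @export
studentized_range_quantile <- function(p, nmeans, df) {
  stats::qtukey(p, nmeans, df)
}

#' Tukey honest significant difference over a performance matrix
#'
#' Every pairwise mean difference is standardised by the common pooled
#' standard error \eqn{\sqrt{\sum_i var_i / (N M)}} (per-method
#' (n-1)-denominator variances) and compared to the studentized range
#' quantile `q(M, M(N-1))`.
#'
#' @param pm A [performance_matrix()].
#' @param level Confidence level, default 0.95.
#' @return List with the `statistic` matrix, `pooled_se`,
#'   `critical_value`, and the logical `different` matrix.
#' @export
tukey_hsd <- function(pm, level = 0.95) {
  m <- if (inherits(pm, "performance_matrix")) pm else performance_matrix(pm)
  n <- nrow(m); M <- ncol(m)
  vars <- apply(m, 2, stats::var)
  pooled_se <- sqrt(sum(vars) / (n * M))
  if (pooled_se == 0) stop("zero pooled variance")
  means <- colMeans(m)
  stat <- abs(outer(means, means, "-")) / pooled_se
  crit <- studentized_range_quantile(level, M, M * (n - 1))
  list(statistic = stat, pooled_se = pooled_se, critical_value = crit,
       different = stat > crit, means = means, level = level)
}

#' Equivalence-grouping layout for a set of methods
#'
#' Arranges methods into columns of statistical indistinguishability: within
#' a column every pair is non-significant; columns are ordered by their best
#' member's mean (best first) and members best-to-worst within each column.
#' Remaining non-significant pairs that straddle columns become dotted
#' edges. Columns are grown greedily from the worst-ranked method upward,
#' the rule that reproduces the canonical depiction (a method that is
#' equivalent to the leader of a large clique but not to its other members
#' stands alone, joined by a dotted edge).
#'
#' @param means Named vector of per-method means, or a
#'   [performance_matrix()] (in which case `different` defaults to the
#'   [tukey_hsd()] verdicts).
#' @param different Logical M-by-M matrix, `TRUE` where a pair is
#'   significantly different; must be symmetric.
#' @return Object of class `grouping_layout`: `columns` (list of label
#'   vectors), `edges` (two-column character matrix of dotted pairs),
#'   `means`.
#' @export
grouping_layout <- function(means, different = NULL) {
  if (inherits(means, "performance_matrix") ||
      (is.matrix(means) && is.null(different))) {
    hsd <- tukey_hsd(means)
    different <- hsd$different
    means <- hsd$means
  }
  if (is.null(names(means))) names(means) <- colnames(different)
  if (is.null(names(means))) names(means) <- as.character(seq_along(means))
  M <- length(means)
  if (!is.matrix(different) || any(dim(different) != M))
    stop("'different' must be an M x M matrix")
  if (!isTRUE(all(different == t(different))))
    stop("pairwise verdict matrix must be symmetric")
  dimnames(different) <- list(names(means), names(means))
  ord <- order(means, decreasing = TRUE)  # best first
  labs <- names(means)[ord]
  # grow cliques from the worst method upward
  cols <- list()
  current <- character(0)
  for (lab in rev(labs)) {
    if (length(current) == 0 || !any(different[lab, current])) {
      current <- c(lab, current)  # keep best-first order inside the column
    } else {
      cols <- c(list(current), cols)
      current <- lab
    }
  }
  cols <- c(list(current), cols)
  # dotted edges: equivalent pairs split across columns
  col_of <- stats::setNames(rep(seq_along(cols), lengths(cols)), unlist(cols))
  edges <- NULL
  for (i in seq_len(M - 1)) {
    for (j in seq(i + 1, M)) {
      a <- labs[i]; b <- labs[j]
      if (!different[a, b] && col_of[[a]] != col_of[[b]])
        edges <- rbind(edges, c(a, b))
    }
  }
  structure(list(columns = cols, edges = edges, means = means[labs]),
            class = "grouping_layout")
}

#' @export
print.grouping_layout <- function(x, ...) {
  cat(render_layout(x, format = "text"))
  invisible(x)
}
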