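# Shared statistical primitives: Storey q-values, permutation machinery,
# pseudo-R-squared.

#' Storey q-values with smoothed pi0 estimation
#'
#' Computes false-discovery-rate q-values from a vector of p-values.  The
#' proportion of true nulls `pi0` is estimated on a lambda grid,
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))`, smoothed with a cubic
#' spline and read off at the largest lambda, then clamped to (0, 1].  The
#' q-value of a p-value is `pi0 * min over p_j >= p_i of m * p_j / rank(p_j)`
#' (the step-up construction); with `pi0 = 1` this is exactly the
#' Benjamini-Hochberg adjustment.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @param lambda_grid grid in \[0, 1) on which pi0 is estimated.
#' @param pi0 optional fixed null proportion; overrides estimation (use
#'   `pi0 = 1` for plain Benjamini-Hochberg).
#' @return object of class `qvalue_result`: list with `pvalues`, `pi0`
#'   and `qvalues` (same order as the input).
#' @examples
#' q <- storey_qvalue(runif(100))
#' q$pi0
#' @export
storey_qvalue <- function(pvalues, lambda_grid = seq(0.05, 0.95, by = 0.05),
                          pi0 = NULL) {
  p <- as.numeric(pvalues)
  m <- length(p)
  if (m == 0L) stop_config("storey_qvalue: empty p-value vector")
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop_config("storey_qvalue: p-values must lie in [0, 1]")
  }
  if (is.null(pi0)) {
    pi0 <- estimate_pi0(p, lambda_grid)
  } else {
    if (pi0 <= 0 || pi0 > 1) stop_config("pi0 must lie in (0, 1]")
  }
  # step-up with ties given the largest rank
  r <- rank(p, ties.method = "max")
  q0 <- pi0 * p * m / r
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- cummin(pmin(q0[o], 1))
  structure(list(pvalues = p, pi0 = pi0, qvalues = q),
            class = "qvalue_result")
}

# Smoothed-lambda pi0 estimator.  Falls back to the conservative pi0 = 1 when
# the input is too small or degenerate for the spline to be meaningful.
estimate_pi0 <- function(p, lambda_grid) {
  lambda_grid <- sort(unique(as.numeric(lambda_grid)))
  if (any(lambda_grid < 0) || any(lambda_grid >= 1)) {
    stop_config("lambda_grid must lie in [0, 1)")
  }
  m <- length(p)
  if (m < 50L || length(lambda_grid) < 4L) return(1)
  pi0_l <- vapply(lambda_grid, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- try(stats::smooth.spline(lambda_grid, pi0_l, df = 3), silent = TRUE)
  pi0 <- if (inherits(fit, "try-error")) {
    pi0_l[length(pi0_l)]
  } else {
    stats::predict(fit, x = max(lambda_grid))$y
  }
  min(max(pi0, 1 / m), 1)
}

#' @exportS3Method base::print
print.qvalue_result <- function(x, ...) {
  cat("Storey q-values:", length(x$pvalues), "tests, pi0 =",
      format(x$pi0, digits = 3), "\n")
  cat("  q < 0.05:", sum(x$qvalues < 0.05),
      "  q < 0.1:", sum(x$qvalues < 0.1), "\n")
  invisible(x)
}

#' Pseudo R-squared for fractional outcomes
#'
#' Two conventions for the share of outcome variability captured by fitted
#' values: `squared_correlation` (Pearson r^2 of fitted vs observed, the
#' default) and `deviance_ratio` (1 - residual/null binomial deviance, for
#' logit-link fits on fractions).
#'
#' @param observed observed outcome fractions in \[0, 1\].
#' @param fitted fitted values on the same scale.
#' @param method `"squared_correlation"` or `"deviance_ratio"`.
#' @return single value in \[0, 1\].
#' @export
pseudo_r2 <- function(observed, fitted,
                      method = c("squared_correlation", "deviance_ratio")) {
  method <- match.arg(method)
  observed <- as.numeric(observed); fitted <- as.numeric(fitted)
  if (length(observed) != length(fitted) || length(observed) < 3L) {
    stop_config("pseudo_r2: need >= 3 paired values of equal length")
  }
  if (any(observed < 0 | observed > 1) || anyNA(observed) || anyNA(fitted)) {
    stop_config("pseudo_r2: fractions must lie in [0, 1] with no NAs")
  }
  if (stats::var(observed) == 0) {
    stop_config("pseudo_r2: observed vector is constant (undefined variance)")
  }
  if (method == "squared_correlation") {
    if (stats::var(fitted) == 0) return(0)
    r2 <- stats::cor(observed, fitted)^2
  } else {
    mu <- pmin(pmax(fitted, 1e-12), 1 - 1e-12)
    mu0 <- mean(observed)
    r2 <- 1 - binom_deviance(observed, mu) / binom_deviance(observed, mu0)
  }
  min(max(r2, 0), 1)
}

# Binomial deviance for fractional y; y log(y/mu) terms vanish at y = 0, 1.
binom_deviance <- function(y, mu) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - mu)), 0)
  2 * sum(t1 + t2)
}

#' Permutation null for a labelled count statistic
#'
#' Re-evaluates `statistic_fn` on `n_perm` label shufflings that preserve the
#' class sizes (e.g. 125 CM / 59 EPDC), giving the null distribution of a
#' count such as the number of differentially expressed genes.
#'
#' @param statistic_fn function taking a label vector and returning a single
#'   number.
#' @param labels vector with exactly the observed class assignment; both
#'   classes must be present.
#' @param n_perm number of permutations (the reference analysis used 100).
#' @param seed integer seed; results are reproducible given the seed.
#' @return numeric vector of length `n_perm` of null statistics.
#' @export
permutation_count_null <- function(statistic_fn, labels, n_perm = 100,
                                   seed = 1) {
  if (n_perm < 1) stop_config("n_perm must be >= 1")
  labels <- as.vector(labels)
  if (length(unique(labels)) < 2L) {
    stop_config("labels must contain at least two classes")
  }
  n <- length(labels)
  with_seed(seed, vapply(seq_len(n_perm), function(i) {
    as.numeric(statistic_fn(labels[sample.int(n)]))
  }, numeric(1)))
}
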