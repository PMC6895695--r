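# Covariate and genotype associations with differentiation outcome, and
# relatedness (clone/twin) concordance.

#' Covariate GLM for binary fate
#'
#' Logistic regression of the binary fate (1 = CM, 0 = EPDC) on subject and
#' line covariates, with Wald Z-test p-values.  Categorical covariates are
#' one-hot encoded against their most frequent level.  If the fit separates
#' perfectly the model is refit with Firth's bias-reducing penalty and
#' flagged.  Lines with missing values are dropped and counted.
#'
#' @param metadata data.frame of covariates per line (e.g. sex, age,
#'   ethnicity, passage).
#' @param fate binary outcome per line (0/1, logical, or `"CM"`/`"EPDC"`).
#' @param terms covariate columns to use (default: all columns of
#'   `metadata`).
#' @return object of class `covariate_fit`: data.frame with term,
#'   coefficient, se, z, p; attributes `firth`, `n_used`, `n_dropped`.
#' @export
covariate_glm <- function(metadata, fate, terms = names(metadata)) {
  metadata <- as.data.frame(metadata)[, terms, drop = FALSE]
  if (is.character(fate) || is.factor(fate)) {
    fate <- as.integer(as.character(fate) == "CM")
  }
  fate <- as.numeric(fate)
  if (!all(fate %in% c(0, 1))) stop_config("fate must be binary (0/1 or CM/EPDC)")
  if (length(unique(fate)) < 2L) stop_config("single-class outcome")
  keep <- stats::complete.cases(metadata) & !is.na(fate)
  metadata <- metadata[keep, , drop = FALSE]
  fate <- fate[keep]
  if (min(table(fate)) < 2L) stop_config("need >= 2 lines per fate class")

  # reference level of each categorical covariate = most frequent level
  for (j in names(metadata)) {
    if (is.character(metadata[[j]]) || is.factor(metadata[[j]])) {
      tab <- sort(table(metadata[[j]]), decreasing = TRUE)
      metadata[[j]] <- stats::relevel(factor(metadata[[j]]),
                                      ref = names(tab)[1])
    }
  }
  X <- stats::model.matrix(~ ., data = metadata)

  fit <- withCallingHandlers(
    stats::glm.fit(X, fate, family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning"))
  mu <- fit$fitted.values
  separated <- any(mu > 1 - 1e-8 | mu < 1e-8) ||
    any(abs(fit$coefficients) > 15, na.rm = TRUE)
  if (separated) {
    fl <- firth_logistic(X, fate)
    coefs <- fl$coefficients; se <- fl$se
  } else {
    W <- mu * (1 - mu)
    info <- crossprod(X * W, X)
    se <- sqrt(diag(solve(info)))
    coefs <- fit$coefficients
  }
  z <- coefs / se
  out <- data.frame(term = colnames(X), coefficient = unname(coefs),
                    se = unname(se), z = unname(z),
                    p = 2 * stats::pnorm(abs(unname(z)), lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  attr(out, "firth") <- separated
  attr(out, "n_used") <- length(fate)
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("covariate_fit", "data.frame")
  out
}

# Firth-penalised logistic regression by Newton-Raphson on the modified
# score U = X'(y - mu + h (1/2 - mu)), h the leverage under the current fit.
firth_logistic <- function(X, y, max_iter = 200, tol = 1e-10) {
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- pmax(mu * (1 - mu), 1e-12)
    info <- crossprod(X * W, X)
    info_inv <- solve(info)
    h <- rowSums((X %*% info_inv) * X) * W
    U <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    delta <- drop(info_inv %*% U)
    # step-halving for stability
    while (max(abs(delta)) > 5) delta <- delta / 2
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  list(coefficients = stats::setNames(beta, colnames(X)),
       se = sqrt(diag(info_inv)))
}

#' Genome-wide variant association scan
#'
#' Per-variant ordinary least squares of the outcome (CM fraction) on
#' dosage plus covariates, vectorised by projecting outcome and dosages onto
#' the orthogonal complement of the covariate space.  Variants below the
#' minor-allele-frequency filter or monomorphic after filtering are skipped
#' and tallied.  `genome_wide` flags p below the conventional 5e-8.
#'
#' @param dosages variants x lines matrix with values in \[0, 2\].
#' @param outcome numeric outcome per line.
#' @param covariates optional data.frame of per-line covariates (e.g.
#'   passage and sex).
#' @param maf_filter minimum minor-allele frequency (default 0.05).
#' @param gw_sig genome-wide significance level.
#' @return object of class `variant_scan`: data.frame variant, maf, beta,
#'   se, p, genome_wide; `attr(, "lambda_gc")` is the genomic inflation
#'   factor, `attr(, "n_skipped")` the filtered-variant tally.
#' @export
variant_scan <- function(dosages, outcome, covariates = NULL,
                         maf_filter = 0.05, gw_sig = 5e-8) {
  dosages <- as.matrix(dosages)
  if (any(dosages < 0) || any(dosages > 2)) {
    stop_config("dosages must lie in [0, 2]")
  }
  outcome <- as.numeric(outcome)
  n <- length(outcome)
  if (ncol(dosages) != n) stop_config("dosage columns must match outcome length")

  af <- rowMeans(dosages) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf >= maf_filter & maf > 0
  n_skipped <- sum(!keep)
  G <- dosages[keep, , drop = FALSE]

  C <- if (is.null(covariates)) {
    matrix(1, n, 1)
  } else {
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  qrC <- qr(C)
  rankC <- qrC$rank
  y_r <- stats::setNames(qr.resid(qrC, outcome), NULL)
  G_r <- t(qr.resid(qrC, t(G)))

  gg <- rowSums(G_r^2)
  gy <- drop(G_r %*% y_r)
  beta <- gy / gg
  df <- n - rankC - 1L
  sigma2 <- pmax(sum(y_r^2) - beta * gy, 0) / df
  se <- sqrt(sigma2 / gg)
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)

  out <- data.frame(variant = rownames(G) %||% seq_len(nrow(G)),
                    maf = maf[keep], beta = beta, se = se, p = p,
                    genome_wide = p < gw_sig,
                    stringsAsFactors = FALSE, row.names = NULL)
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  attr(out, "lambda_gc") <- stats::median(chisq) / stats::qchisq(0.5, 1)
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("variant_scan", "data.frame")
  out
}

#' @exportS3Method base::print
print.variant_scan <- function(x, ...) {
  cat("Variant scan:", nrow(x), "variants tested,",
      attr(x, "n_skipped"), "filtered;",
      sum(x$genome_wide), "genome-wide significant; lambda_GC =",
      format(attr(x, "lambda_gc"), digits = 3), "\n")
  invisible(x)
}

#' Outcome concordance of related line pairs
#'
#' Compares the absolute outcome difference within related pairs (clones of
#' the same individual, or twin pairs) to all unrelated cross-line pairs,
#' with a two-sided Mann-Whitney test.
#'
#' @param outcomes named numeric vector: line -> outcome (CM fraction).
#' @param pairs two-column matrix/data.frame of related line identifiers.
#' @return list with `within` and `between` |difference| vectors and `p`.
#' @export
relatedness_concordance <- function(outcomes, pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 2L) stop_config("need >= 2 related pairs")
  lines <- names(outcomes)
  if (is.null(lines)) stop_config("outcomes must be named by line")
  related_key <- apply(pairs, 1, function(p) paste(sort(p), collapse = "|"))
  within <- abs(outcomes[pairs[, 1]] - outcomes[pairs[, 2]])
  cmb <- utils::combn(lines, 2)
  keys <- apply(cmb, 2, function(p) paste(sort(p), collapse = "|"))
  unrelated <- cmb[, !(keys %in% related_key), drop = FALSE]
  if (ncol(unrelated) == 0L) stop_config("no unrelated pairs")
  between <- abs(outcomes[unrelated[1, ]] - outcomes[unrelated[2, ]])
  wt <- stats::wilcox.test(within, between, exact = FALSE)
  list(within = unname(within), between = unname(between), p = wt$p.value)
}
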