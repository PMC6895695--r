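# Per-gene and joint models of the variance in differentiation outcome
# explained by signature-gene expression.

#' Fit a single-gene fate model
#'
#' Regresses the outcome fraction (CM fraction of the derived sample) on one
#' gene's log2(TPM+1) iPSC expression.  `link = "identity"` is ordinary
#' least squares; `link = "logit"` is a quasi-binomial GLM appropriate for a
#' fractional outcome.  The share of variance explained is a pseudo-R^2 on
#' fitted values (squared correlation by default).
#'
#' @param expr_g expression of one gene across lines (TPM).
#' @param outcome CM fraction per line, in \[0, 1\].
#' @param link `"identity"` or `"logit"`.
#' @param r2_method passed to [pseudo_r2()].
#' @return object of class `gene_fate_fit`: list with `link`, `estimate`,
#'   `se`, `p`, `r2`, `n`.
#' @export
fit_gene_fate_model <- function(expr_g, outcome,
                                link = c("identity", "logit"),
                                r2_method = "squared_correlation") {
  link <- match.arg(link)
  expr_g <- as.numeric(expr_g); outcome <- as.numeric(outcome)
  if (length(expr_g) != length(outcome) || length(outcome) < 10L) {
    stop_config("need >= 10 paired lines")
  }
  if (any(outcome < 0 | outcome > 1)) {
    stop_config("outcome must lie in [0, 1]")
  }
  x <- log2p1(expr_g)
  if (stats::var(x) == 0) stop_config("constant expression vector")
  if (link == "identity") {
    fit <- stats::lm(outcome ~ x)
    co <- summary(fit)$coefficients
  } else {
    fit <- stats::glm(outcome ~ x, family = stats::quasibinomial())
    co <- summary(fit)$coefficients
  }
  r2 <- pseudo_r2(outcome, stats::fitted(fit), method = r2_method)
  structure(list(link = link, estimate = co["x", 1], se = co["x", 2],
                 p = co["x", 4], r2 = r2, n = length(outcome)),
            class = "gene_fate_fit")
}

#' @exportS3Method base::print
print.gene_fate_fit <- function(x, ...) {
  cat(sprintf("Gene-fate fit (%s link): estimate %.4g (se %.3g), p %.3g, R2 %.3g\n",
              x$link, x$estimate, x$se, x$p, x$r2))
  invisible(x)
}

#' Per-gene fate fits for a gene set
#'
#' Convenience wrapper applying [fit_gene_fate_model()] across the rows of a
#' signature-gene expression matrix.
#' @param expr genes x lines TPM matrix.
#' @param outcome CM fraction per line.
#' @param link model link.
#' @return data.frame gene, estimate, se, p, r2.
#' @export
fit_signature_gene_models <- function(expr, outcome, link = "identity") {
  assert_matrix_like(expr)
  rows <- lapply(rownames(expr), function(g) {
    f <- fit_gene_fate_model(expr[g, ], outcome, link = link)
    data.frame(gene = g, estimate = f$estimate, se = f$se, p = f$p,
               r2 = f$r2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' L1-penalised joint model with cross-validation
#'
#' LASSO regression of the outcome fraction on all signature genes'
#' log2(TPM+1) expression, with k-fold cross-validation.  The penalty is
#' chosen at the minimum mean CV squared error on the fraction scale
#' (lambda.min); folds are stratified by outcome deciles so small cohorts
#' keep comparable outcome spread per fold.  The reported per-fold R^2 is
#' predictive: `1 - SSE_heldout / SST_heldout`, floored at 0, computed from
#' a model refit on the fold's training lines only.
#'
#' @param expr signature-gene x line TPM matrix.
#' @param outcome CM fraction per line.
#' @param folds number of CV folds.
#' @param seed integer seed (fold assignment).
#' @return object of class `joint_model`: list with `selected_genes`,
#'   `coefficients`, `cv_r2_mean`, `cv_r2_per_fold`, `lambda`, `folds`,
#'   `seed`.
#' @export
joint_lasso_cv <- function(expr, outcome, folds = 10, seed = 1) {
  if (NROW(expr) == 0L) stop_config("empty gene set")
  assert_matrix_like(expr)
  outcome <- as.numeric(outcome)
  if (folds < 2L) stop_config("folds must be >= 2")
  n <- length(outcome)
  if (n != ncol(expr) || n < 3L * folds) {
    stop_config("need >= 3 x folds lines aligned with the columns")
  }
  # duplicated gene rows are one predictor: keep the first of each set so
  # the L1 path cannot split weight across identical columns
  dup <- duplicated(expr, MARGIN = 1)
  expr_fit <- expr[!dup, , drop = FALSE]
  X <- t(log2p1(expr_fit))
  if (ncol(X) == 1L) X <- cbind(X, 0)  # glmnet needs >= 2 columns

  foldid <- with_seed(substream(seed, 41), stratified_folds(outcome, folds))
  cv <- glmnet::cv.glmnet(X, outcome, foldid = foldid, family = "gaussian")
  lambda <- cv$lambda.min
  coefs <- stats::setNames(numeric(nrow(expr)), rownames(expr))
  coefs[rownames(expr_fit)] <-
    drop(stats::coef(cv, s = "lambda.min"))[-1][seq_len(nrow(expr_fit))]

  r2_fold <- vapply(seq_len(folds), function(k) {
    test <- foldid == k
    fit_k <- glmnet::glmnet(X[!test, , drop = FALSE], outcome[!test],
                            family = "gaussian", lambda = cv$lambda)
    pred <- drop(stats::predict(fit_k, X[test, , drop = FALSE], s = lambda))
    sse <- sum((outcome[test] - pred)^2)
    sst <- sum((outcome[test] - mean(outcome[!test]))^2)
    max(1 - sse / sst, 0)
  }, numeric(1))

  structure(list(selected_genes = names(coefs)[coefs != 0],
                 coefficients = coefs,
                 cv_r2_mean = mean(r2_fold), cv_r2_per_fold = r2_fold,
                 lambda = lambda, folds = folds, seed = seed),
            class = "joint_model")
}

# Fold ids stratified by outcome deciles: within each decile block of the
# outcome order, folds are dealt out in random order.
stratified_folds <- function(outcome, folds) {
  n <- length(outcome)
  foldid <- integer(n)
  ord <- order(outcome)
  for (start in seq(1, n, by = folds)) {
    block <- ord[start:min(start + folds - 1, n)]
    foldid[block] <- sample(seq_len(folds))[seq_along(block)]
  }
  foldid
}

#' @exportS3Method base::print
print.joint_model <- function(x, ...) {
  cat("L1-penalised joint fate model\n")
  cat(sprintf("  lambda (min CV error): %.4g\n", x$lambda))
  cat(sprintf("  selected genes: %d of %d\n", length(x$selected_genes),
              length(x$coefficients)))
  cat(sprintf("  cross-validated R2: %.3f (mean of %d folds)\n",
              x$cv_r2_mean, x$folds))
  invisible(x)
}

#' @export
coef.joint_model <- function(object, ...) object$coefficients
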