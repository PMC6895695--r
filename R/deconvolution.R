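# Cell-population deconvolution of bulk RNA-seq.
#
# The signature matrix is the union of per-population top-N overexpressed
# marker genes; fractions are estimated per sample by nonnegative least
# squares on linear TPM, then renormalised to sum to 1.  The constrained
# least-squares solver replaces the support-vector regression used by
# CIBERSORT-style tools: it is deterministic and validated by recovery tests.

#' Build a marker-gene signature matrix from population profiles
#'
#' For each population, genes are tested one-vs-rest for overexpression
#' (Welch t-test on log2(TPM+1) across replicate profiles), ranked by p, and
#' the `top_n` genes passing `p_cutoff` are retained.  A gene winning in two
#' populations is kept once, assigned to the population where its p-value is
#' smallest.  With three populations and `top_n = 50` this yields the
#' classic 150-gene signature.
#'
#' @param population_profiles genes x replicates matrix of nonnegative
#'   expression (replicates may be pseudo-replicates).
#' @param populations population label per column of `population_profiles`.
#' @param top_n markers to retain per population.
#' @param p_cutoff selection p-value cutoff.
#' @return object of class `signature_matrix`: list with `genes`,
#'   `populations`, `values` (marker x population mean expression) and
#'   `selection_stats`.
#' @export
build_signature_matrix <- function(population_profiles, populations,
                                   top_n = 50, p_cutoff = 1e-13) {
  assert_matrix_like(population_profiles, "population profile matrix")
  populations <- as.character(populations)
  if (length(populations) != ncol(population_profiles)) {
    stop_config("populations must label each profile column")
  }
  pops <- unique(populations)
  if (length(pops) < 2L) stop_config("need >= 2 populations")
  if (min(table(populations)) < 2L) {
    stop_config("need >= 2 replicates per population")
  }
  lx <- log2p1(population_profiles)
  sel <- list()
  for (k in pops) {
    tt <- row_welch_t(lx, which(populations == k), which(populations != k))
    over <- tt$t > 0 & tt$p <= p_cutoff
    if (!any(over)) next
    ord <- order(tt$p[over])
    keep <- which(over)[ord][seq_len(min(top_n, sum(over)))]
    sel[[k]] <- data.frame(gene = rownames(lx)[keep], population = k,
                           statistic = tt$t[keep], p = tt$p[keep],
                           stringsAsFactors = FALSE)
    if (sum(over) < top_n) {
      warning(sprintf("population %s: only %d of %d genes pass p <= %g",
                      k, sum(over), top_n, p_cutoff), call. = FALSE)
    }
  }
  if (length(sel) == 0L) stop_config("no markers pass the selection cutoff ",
                                     "in any population (no signal?)")
  stats_df <- do.call(rbind, sel)
  # duplicate genes -> best population wins
  stats_df <- stats_df[order(stats_df$p), , drop = FALSE]
  stats_df <- stats_df[!duplicated(stats_df$gene), , drop = FALSE]
  rownames(stats_df) <- NULL

  values <- vapply(pops, function(k) {
    rowMeans(population_profiles[stats_df$gene, populations == k,
                                 drop = FALSE])
  }, numeric(nrow(stats_df)))
  values <- matrix(values, nrow = nrow(stats_df),
                   dimnames = list(stats_df$gene, pops))
  structure(list(genes = stats_df$gene, populations = pops, values = values,
                 selection_stats = stats_df, top_n = top_n,
                 p_cutoff = p_cutoff),
            class = "signature_matrix")
}

#' @exportS3Method base::print
print.signature_matrix <- function(x, ...) {
  cat("Signature matrix:", length(x$genes), "marker genes x",
      length(x$populations), "populations (",
      paste(x$populations, collapse = ", "), ")\n")
  print(table(x$selection_stats$population))
  invisible(x)
}

#' Estimate cell-population fractions in bulk samples
#'
#' Per sample, solves nonnegative least squares of marker-gene bulk
#' expression on the signature columns (linear TPM space, where mixing is
#' linear) and renormalises the coefficients to sum to 1.  Markers missing
#' from the bulk matrix are dropped symmetrically; fewer than 50% marker
#' overlap is an error.
#'
#' @param bulk genes x samples TPM matrix.
#' @param signature a `signature_matrix`.
#' @return object of class `fraction_estimates`: data.frame with one row per
#'   sample, one fraction column per population, `residual_norm` and
#'   `n_markers_used`.
#' @export
estimate_fractions <- function(bulk, signature) {
  assert_matrix_like(bulk, "bulk matrix")
  stopifnot(inherits(signature, "signature_matrix"))
  shared <- intersect(signature$genes, rownames(bulk))
  if (length(shared) < 0.5 * length(signature$genes)) {
    missing <- setdiff(signature$genes, rownames(bulk))
    stop_config("only ", length(shared), "/", length(signature$genes),
                " signature genes present in bulk; missing e.g. ",
                paste(utils::head(missing, 5), collapse = ", "))
  }
  S <- signature$values[shared, , drop = FALSE]
  B <- bulk[shared, , drop = FALSE]
  res <- lapply(seq_len(ncol(B)), function(j) {
    b <- B[, j]
    if (all(b == 0)) {
      stop_config("bulk sample ", colnames(B)[j], " is all-zero")
    }
    fit <- nnls_fit(S, b)
    tot <- sum(fit$x)
    frac <- if (tot > 0) fit$x / tot else rep(1 / ncol(S), ncol(S))
    c(frac, fit$residual)
  })
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c(signature$populations, "residual_norm")
  out <- cbind(sample = colnames(B), out, n_markers_used = length(shared),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("fraction_estimates", "data.frame")
  out
}

#' @exportS3Method base::print
print.fraction_estimates <- function(x, ...) {
  pops <- setdiff(names(x), c("sample", "residual_norm", "n_markers_used"))
  cat("Estimated fractions for", nrow(x), "samples; population means:\n")
  print(round(colMeans(as.data.frame(x)[pops]), 3))
  invisible(x)
}

#' @export
plot.fraction_estimates <- function(x, ...) {
  pops <- setdiff(names(x), c("sample", "residual_norm", "n_markers_used"))
  m <- t(as.matrix(as.data.frame(x)[pops]))
  colnames(m) <- x$sample
  ord <- order(m[1, ], decreasing = TRUE)
  graphics::barplot(m[, ord], border = NA, space = 0, xaxt = "n",
                    ylab = "estimated fraction",
                    legend.text = pops, ...)
  invisible(x)
}

#' Correlate an estimated fraction with an orthogonal purity measure
#'
#' Pearson correlation (with t-distributed two-sided p) between a chosen
#' estimated population fraction and a per-sample purity value such as
#' flow-cytometry %cTnT.  Pairs with missing purity are dropped and counted.
#'
#' @param estimates a `fraction_estimates` object.
#' @param purity numeric purity per sample, aligned with `estimates$sample`
#'   (or named by sample).
#' @param population which fraction column to correlate (default first).
#' @return list with `r`, `p`, `n_used`, `n_dropped`.
#' @export
correlate_fraction_with_purity <- function(estimates, purity,
                                           population = NULL) {
  stopifnot(inherits(estimates, "fraction_estimates"))
  pops <- setdiff(names(estimates),
                  c("sample", "residual_norm", "n_markers_used"))
  population <- population %||% pops[1]
  if (!population %in% pops) stop_config("unknown population ", population)
  if (!is.null(names(purity))) purity <- purity[estimates$sample]
  if (length(purity) != nrow(estimates)) {
    stop_config("purity must align with the estimate rows")
  }
  ok <- stats::complete.cases(purity)
  if (sum(ok) < 3L) stop_config("need >= 3 complete sample pairs")
  ct <- stats::cor.test(estimates[[population]][ok], purity[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n_used = sum(ok),
       n_dropped = sum(!ok))
}
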