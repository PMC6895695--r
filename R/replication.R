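# Cross-cohort replication: batch-effect diagnostics, contrast correlation,
# and direction-consistent signature replication with Fisher enrichment.

#' Within- and between-cohort expression correlation diagnostics
#'
#' Spearman correlations of sample expression profiles over the shared gene
#' universe: all within-cohort-A pairs, within-cohort-B pairs, and all cross
#' pairs.  A cross distribution shifted below the within distributions
#' indicates a batch effect between cohorts.
#'
#' @param expr_a,expr_b genes x samples TPM matrices.
#' @return list with numeric vectors `within_a`, `within_b`, `between` and
#'   `n_shared_genes`.
#' @export
cohort_correlation_diagnostics <- function(expr_a, expr_b) {
  assert_matrix_like(expr_a, "cohort A matrix")
  assert_matrix_like(expr_b, "cohort B matrix")
  if (ncol(expr_a) < 2L || ncol(expr_b) < 2L) {
    stop_config("need >= 2 samples per cohort")
  }
  shared <- intersect(rownames(expr_a), rownames(expr_b))
  if (length(shared) < 100L) stop_config("fewer than 100 shared genes")
  ra <- apply(expr_a[shared, , drop = FALSE], 2, rank)
  rb <- apply(expr_b[shared, , drop = FALSE], 2, rank)
  ca <- stats::cor(ra)
  cb <- stats::cor(rb)
  cab <- stats::cor(ra, rb)
  list(within_a = ca[upper.tri(ca)], within_b = cb[upper.tri(cb)],
       between = as.vector(cab), n_shared_genes = length(shared))
}

#' Signature replication across cohorts
#'
#' Correlates the per-gene fate contrasts of two cohorts over the shared
#' gene universe, and asks whether signature genes replicate in the second
#' cohort (nominal `p < alpha` there with the same contrast sign as in
#' cohort A) more often than background.  The expected count under "random
#' expectation" is the signature size times the rate of the same criterion
#' among non-signature genes; enrichment is Fisher's exact test on the 2x2
#' table (signature vs not) x (replicated-criterion vs not).
#'
#' @param contrast_a,contrast_b data.frames with columns gene, mean_diff, p.
#' @param signature data.frame with columns gene and direction (+1/-1, sign
#'   in cohort A).
#' @param alpha nominal replication threshold in cohort B.
#' @return object of class `replication_result`: list with `r`, `r_p`,
#'   `n_signature`, `n_replicated`, `replicated_genes`, `expected`,
#'   `fold_enrichment`, `fisher_p`, `contingency`.
#' @export
contrast_replication <- function(contrast_a, contrast_b, signature,
                                 alpha = 0.05) {
  if (nrow(signature) == 0L) stop_config("empty signature")
  shared <- intersect(contrast_a$gene, contrast_b$gene)
  a <- contrast_a[match(shared, contrast_a$gene), ]
  b <- contrast_b[match(shared, contrast_b$gene), ]
  ct <- stats::cor.test(a$mean_diff, b$mean_diff)

  crit <- b$p < alpha & sign(b$mean_diff) == sign(a$mean_diff)
  is_sig <- shared %in% signature$gene
  n_replicated <- sum(crit & is_sig)
  bg_rate <- if (any(!is_sig)) mean(crit[!is_sig]) else 0
  expected <- sum(is_sig) * bg_rate
  contingency <- matrix(c(sum(crit & is_sig), sum(!crit & is_sig),
                          sum(crit & !is_sig), sum(!crit & !is_sig)),
                        nrow = 2,
                        dimnames = list(replicated = c("yes", "no"),
                                        signature = c("yes", "no")))
  fisher_p <- stats::fisher.test(contingency)$p.value
  structure(list(r = unname(ct$estimate), r_p = ct$p.value,
                 n_signature = sum(is_sig), n_replicated = n_replicated,
                 replicated_genes = shared[crit & is_sig],
                 expected = expected,
                 fold_enrichment = if (expected > 0) n_replicated / expected
                                   else NA_real_,
                 fisher_p = fisher_p, contingency = contingency,
                 alpha = alpha),
            class = "replication_result")
}

#' @exportS3Method base::print
print.replication_result <- function(x, ...) {
  cat("Cross-cohort replication\n")
  cat(sprintf("  contrast correlation r = %.4g (p = %.3g)\n", x$r, x$r_p))
  cat(sprintf("  signature genes replicated: %d / %d (expected %.2f, %.1fx, Fisher p = %.3g)\n",
              x$n_replicated, x$n_signature, x$expected,
              x$fold_enrichment, x$fisher_p))
  invisible(x)
}
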