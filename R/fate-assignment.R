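# Fate assignment: dichotomising lines into CM-fated vs EPDC-fated at a
# CM-fraction threshold, counting differentially expressed genes at each
# candidate threshold, picking the optimum, and calibrating the count
# against a class-size-preserving permutation null.

#' Assign differentiation outcome to iPSC lines
#'
#' Completed lines take their CM fraction from deconvolution; terminated
#' differentiations (no beating syncytium, no day-25 sample) are assigned a
#' CM fraction of 0 (the 0:100 CM/EPDC convention).  At a threshold `k` a
#' line is CM-fated iff `cm_fraction >= k`.
#'
#' @param estimates a `fraction_estimates` object for completed lines.
#' @param terminated_lines identifiers of terminated lines (disjoint from
#'   the estimate samples).
#' @param cm_population name of the CM fraction column (default `"CM"`).
#' @return object of class `fate_table`: data.frame with `line`,
#'   `cm_fraction`, `terminated`.
#' @export
assign_outcome <- function(estimates, terminated_lines = character(),
                           cm_population = "CM") {
  stopifnot(inherits(estimates, "fraction_estimates"))
  if (!cm_population %in% names(estimates)) {
    stop_config("no fraction column named ", cm_population)
  }
  ids <- c(estimates$sample, terminated_lines)
  if (anyDuplicated(ids)) {
    stop_config("duplicate line identifiers: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- data.frame(
    line = ids,
    cm_fraction = c(estimates[[cm_population]],
                    rep(0, length(terminated_lines))),
    terminated = c(rep(FALSE, nrow(estimates)),
                   rep(TRUE, length(terminated_lines))),
    stringsAsFactors = FALSE)
  class(out) <- c("fate_table", "data.frame")
  out
}

#' Fate label at a CM-fraction threshold
#'
#' @param fate_table a `fate_table`.
#' @param threshold CM-fraction cutoff; `>= threshold` is CM-fated.
#' @return character vector of `"CM"` / `"EPDC"` labels, named by line.
#' @export
fate_at_threshold <- function(fate_table, threshold) {
  stopifnot(inherits(fate_table, "fate_table"))
  stats::setNames(ifelse(fate_table$cm_fraction >= threshold, "CM", "EPDC"),
                  fate_table$line)
}

#' Differential expression between fate groups
#'
#' Per-gene Welch two-sample t-test on log2(TPM+1), CM minus EPDC (a
#' positive `mean_diff` means overexpressed in CM-fated lines), with Storey
#' q-values.  Gene filtering (expressed autosomal genes) is applied upstream.
#'
#' @param expr genes x samples TPM matrix.
#' @param labels `"CM"`/`"EPDC"` label per sample (column).
#' @param q_cut significance cutoff on the q-value.
#' @return data.frame gene, t, p, q, mean_diff, significant.
#' @export
differential_expression <- function(expr, labels, q_cut = 0.1) {
  assert_matrix_like(expr)
  labels <- as.character(labels)
  if (length(labels) != ncol(expr)) stop_config("one label per sample needed")
  i_cm <- which(labels == "CM"); i_ep <- which(labels == "EPDC")
  if (length(i_cm) < 3L || length(i_ep) < 3L) {
    stop_config("need >= 3 samples per fate class (have ", length(i_cm),
                " CM, ", length(i_ep), " EPDC)")
  }
  tt <- row_welch_t(log2p1(expr), i_cm, i_ep)
  q <- storey_qvalue(tt$p)$qvalues
  data.frame(gene = rownames(expr), t = tt$t, p = tt$p, q = q,
             mean_diff = tt$mean1 - tt$mean2, significant = q < q_cut,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter to expressed genes
#'
#' Mean TPM >= `min_tpm` across the cohort; the operational definition of
#' "expressed" used before differential expression.
#' @param expr genes x samples TPM matrix.
#' @param min_tpm mean-TPM cutoff.
#' @return filtered matrix.
#' @export
filter_expressed <- function(expr, min_tpm = 1) {
  assert_matrix_like(expr)
  expr[rowMeans(expr) >= min_tpm, , drop = FALSE]
}

#' Completion bookkeeping for a set of differentiations
#'
#' @param terminated logical vector, one entry per attempted differentiation.
#' @return list with `n_total`, `n_completed`, `pct_completed` (one decimal).
#' @export
differentiation_summary <- function(terminated) {
  terminated <- as.logical(terminated)
  n <- length(terminated)
  nc <- sum(!terminated)
  list(n_total = n, n_completed = nc,
       pct_completed = round(100 * nc / n, 1))
}

#' Share of union genes with their strongest p-value at a given threshold
#'
#' Bookkeeping over the union of genes significant at any threshold: how
#' many attain their minimum p-value at the selected threshold.
#'
#' @param p_matrix genes x thresholds matrix of p-values.
#' @param best_threshold column (name or index) of the selected threshold.
#' @return list with `count` and `pct` (one decimal).
#' @export
strongest_fraction <- function(p_matrix, best_threshold) {
  p_matrix <- as.matrix(p_matrix)
  best <- p_matrix[, best_threshold]
  count <- sum(best <= matrixStats::rowMins(p_matrix) * (1 + 1e-12))
  list(count = count, pct = round(100 * count / nrow(p_matrix), 1))
}

#' Threshold sweep over candidate CM/EPDC ratios
#'
#' Runs [differential_expression()] at each candidate CM-fraction threshold,
#' counts genes at `q < q_cut`, selects the threshold with the maximum count
#' (ties broken toward the smaller threshold), computes the union of genes
#' significant at any threshold together with the share strongest at the
#' optimum, and attaches a label-permutation null of the count at the
#' optimum.  Thresholds leaving fewer than 3 lines in either class are
#' skipped and reported.
#'
#' @param expr genes x lines TPM matrix (columns must cover the fate table
#'   lines).
#' @param fate_table a `fate_table`.
#' @param thresholds candidate CM-fraction cutoffs (0:100 to 90:10 in 10%
#'   steps by default).
#' @param q_cut q-value significance cutoff.
#' @param n_perm permutations for the null at the best threshold.
#' @param seed integer seed for the permutation machinery.
#' @return object of class `sweep_result`.
#' @export
threshold_sweep <- function(expr, fate_table, thresholds = (0:9) / 10,
                            q_cut = 0.1, n_perm = 100, seed = 1) {
  assert_matrix_like(expr)
  stopifnot(inherits(fate_table, "fate_table"))
  if (!all(fate_table$line %in% colnames(expr))) {
    stop_config("expression matrix missing lines from the fate table")
  }
  expr <- expr[, fate_table$line, drop = FALSE]

  de <- list(); counts <- numeric(0); used <- numeric(0); skipped <- numeric(0)
  class_sizes <- list()
  for (k in thresholds) {
    lab <- fate_at_threshold(fate_table, k)
    if (min(sum(lab == "CM"), sum(lab == "EPDC")) < 3L) {
      skipped <- c(skipped, k)
      next
    }
    d <- differential_expression(expr, lab, q_cut = q_cut)
    de[[as.character(k)]] <- d
    counts <- c(counts, sum(d$significant))
    used <- c(used, k)
    class_sizes[[as.character(k)]] <- c(CM = sum(lab == "CM"),
                                        EPDC = sum(lab == "EPDC"))
  }
  if (length(used) == 0L) stop_config("all thresholds skipped (classes too small)")

  best <- used[which.max(counts)]  # which.max returns the first maximum
  union_genes <- unique(unlist(lapply(de, function(d) d$gene[d$significant])))
  strongest <- list(count = 0L, pct = NA_real_)
  p_union <- NULL
  if (length(union_genes) > 0) {
    p_union <- vapply(de, function(d) {
      d$p[match(union_genes, d$gene)]
    }, numeric(length(union_genes)))
    p_union <- matrix(p_union, nrow = length(union_genes),
                      dimnames = list(union_genes, names(de)))
    strongest <- strongest_fraction(p_union, as.character(best))
  }

  lab_best <- fate_at_threshold(fate_table, best)
  null_counts <- permutation_count_null(function(perm_lab) {
    sum(differential_expression(expr, perm_lab, q_cut = q_cut)$significant)
  }, lab_best, n_perm = n_perm, seed = seed)

  structure(list(
    thresholds = used, skipped = skipped,
    de_counts = stats::setNames(counts, used),
    class_sizes = class_sizes,
    de_gene_union = union_genes, p_union = p_union,
    best_threshold = best,
    de_best = de[[as.character(best)]],
    strongest_at_best = strongest$count,
    strongest_at_best_pct = strongest$pct,
    null_counts = null_counts, q_cut = q_cut, n_perm = n_perm, seed = seed),
    class = "sweep_result")
}

#' @exportS3Method base::print
print.sweep_result <- function(x, ...) {
  cat("CM/EPDC threshold sweep\n")
  cat("  thresholds tested:", paste(x$thresholds, collapse = ", "), "\n")
  if (length(x$skipped)) {
    cat("  skipped (class < 3):", paste(x$skipped, collapse = ", "), "\n")
  }
  cat("  DE genes (q <", x$q_cut, ") per threshold:\n")
  print(x$de_counts)
  cat("  best threshold:", x$best_threshold,
      "->", x$de_counts[as.character(x$best_threshold)], "DE genes\n")
  cat("  union of DE genes:", length(x$de_gene_union),
      "; strongest at best:", x$strongest_at_best,
      if (!is.na(x$strongest_at_best_pct)) {
        paste0("(", x$strongest_at_best_pct, "%)")
      } else "", "\n")
  cat("  permutation null (", x$n_perm, " shuffles): range [",
      min(x$null_counts), ", ", max(x$null_counts), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ...) {
  graphics::barplot(x$de_counts, xlab = "CM-fraction threshold",
                    ylab = sprintf("DE genes (q < %g)", x$q_cut), ...)
  graphics::abline(h = stats::quantile(x$null_counts, 0.95), lty = 2)
  invisible(x)
}

#' Finalise the signature gene list
#'
#' The signature is the set of genes significant at the best threshold, plus
#' borderline genes (nominal `p < borderline_p` at the best threshold) that
#' carry at least one pathway annotation (WNT / muscle-cardiac / EMT in the
#' motivating analysis).  Each gene carries its direction: +1 overexpressed
#' in CM-fated lines, -1 in EPDC-fated.
#'
#' @param sweep a `sweep_result`.
#' @param borderline_p nominal p-value cutoff for annotated borderline genes.
#' @param pathway_annotations named list: gene -> character vector of
#'   pathway memberships (possibly empty).
#' @return data.frame gene, direction, p, q, borderline.
#' @export
finalize_signature <- function(sweep, borderline_p = 0.0015,
                               pathway_annotations = list()) {
  stopifnot(inherits(sweep, "sweep_result"))
  d <- sweep$de_best
  core <- d$significant
  annotated <- vapply(d$gene, function(g) {
    length(pathway_annotations[[g]] %||% character()) > 0
  }, logical(1))
  borderline <- !core & d$p < borderline_p & annotated
  keep <- core | borderline
  out <- data.frame(gene = d$gene[keep],
                    direction = sign(d$mean_diff[keep]),
                    p = d$p[keep], q = d$q[keep],
                    borderline = borderline[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p), , drop = FALSE]
}
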