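# Gene-set enrichment on the CM-vs-EPDC expression contrast.

#' Normalised mean expression difference between fate groups
#'
#' Per gene, `(mean_CM - mean_EPDC) / SE` on log2(TPM+1), where SE is the
#' Welch standard error of the difference; positive = up in CM-fated lines.
#' Genes with zero pooled variance get statistic 0 and a flag.
#'
#' @param expr genes x samples TPM matrix.
#' @param labels `"CM"`/`"EPDC"` per sample.
#' @return data.frame gene, statistic, zero_variance.
#' @export
contrast_statistic <- function(expr, labels) {
  assert_matrix_like(expr)
  labels <- as.character(labels)
  i_cm <- which(labels == "CM"); i_ep <- which(labels == "EPDC")
  if (length(i_cm) < 3L || length(i_ep) < 3L) {
    stop_config("need >= 3 samples per class")
  }
  tt <- row_welch_t(log2p1(expr), i_cm, i_ep)
  data.frame(gene = rownames(expr), statistic = tt$t,
             zero_variance = tt$zero_variance,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene-set enrichment test on a per-gene statistic
#'
#' For each set, a two-sample Welch t-test of member genes' statistics
#' against non-member genes' statistics; the direction (`up_in_CM` /
#' `down_in_CM`) follows the sign of the mean difference and the reported p
#' is two-sided.  Multiple testing is corrected with Storey q-values
#' independently within each collection.  Sets smaller than `min_size`
#' (after restriction to genes with statistics) are dropped and reported.
#'
#' @param stats named numeric vector of per-gene statistics (e.g. from
#'   [contrast_statistic()]).
#' @param sets named list of collections, each a named list of gene-identifier
#'   vectors (a single flat list of sets is treated as one collection).
#' @param min_size minimum set size after gene restriction.
#' @return data.frame set_name, collection, size_used, direction, p, q;
#'   dropped sets in `attr(, "dropped")`.
#' @export
gene_set_test <- function(stats, sets, min_size = 10) {
  if (is.null(names(stats))) stop_config("stats must be named by gene")
  if (length(sets) && !is.list(sets[[1]])) sets <- list(sets = sets)
  universe <- names(stats)
  out <- list(); dropped <- character()
  for (coll in names(sets)) {
    rows <- list()
    for (nm in names(sets[[coll]])) {
      members <- intersect(sets[[coll]][[nm]], universe)
      if (length(members) < min_size) {
        dropped <- c(dropped, paste0(coll, "/", nm))
        next
      }
      inset <- stats[members]
      outset <- stats[setdiff(universe, members)]
      tt <- stats::t.test(inset, outset)
      rows[[nm]] <- data.frame(
        set_name = nm, collection = coll, size_used = length(members),
        direction = if (mean(inset) >= mean(outset)) "up_in_CM"
                    else "down_in_CM",
        p = tt$p.value, stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) next
    df <- do.call(rbind, rows)
    df$q <- storey_qvalue(df$p)$qvalues  # per-collection correction
    out[[coll]] <- df
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(set_name = character(), collection = character(),
               size_used = integer(), direction = character(),
               p = numeric(), q = numeric())
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}
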