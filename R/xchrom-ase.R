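# Allelic imbalance on the X chromosome: AIF computation, pseudoautosomal
# masking, and tests of X-inactivation differences between fate groups and
# along chrX intervals.

#' Pseudoautosomal region coordinates (1-based inclusive, GRCh37 chrX)
#' @export
PAR1 <- c(60001, 2699520)
#' @rdname PAR1
#' @export
PAR2 <- c(154931044, 155260560)

#' Compute allelic imbalance fractions
#'
#' AIF is the fraction of transcripts from the higher-expressed allele,
#' `max(ref, alt) / (ref + alt)`, in \[0.5, 1\]: 0.5 means balanced biallelic
#' expression, 1 monoallelic.  Rows with total coverage below `min_coverage`
#' are dropped and tallied.
#'
#' @param counts data.frame with columns gene, chrom, start, end, sample,
#'   ref_count, alt_count (nonnegative integers).
#' @param min_coverage minimum total reads per gene-sample row.
#' @return object of class `aif_table`: data.frame adding `aif`, `is_par`
#'   (FALSE until [mask_par()]), `escape_status` (`"unknown"` until
#'   annotated); dropped-row count in `attr(, "n_dropped")`.
#' @export
compute_aif <- function(counts, min_coverage = 20) {
  need <- c("gene", "chrom", "start", "end", "sample", "ref_count",
            "alt_count")
  if (!all(need %in% names(counts))) {
    stop_config("counts must have columns ", paste(need, collapse = ", "))
  }
  if (any(counts$ref_count < 0) || any(counts$alt_count < 0)) {
    stop_config("negative allele counts")
  }
  tot <- counts$ref_count + counts$alt_count
  keep <- tot >= min_coverage
  out <- counts[keep, need, drop = FALSE]
  out$aif <- pmax(out$ref_count, out$alt_count) /
    (out$ref_count + out$alt_count)
  out$is_par <- FALSE
  out$escape_status <- "unknown"
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "min_coverage") <- min_coverage
  class(out) <- c("aif_table", "data.frame")
  out
}

#' Mask pseudoautosomal regions on chrX
#'
#' Flags chrX genes overlapping either PAR interval (any base overlap,
#' 1-based inclusive coordinates); flagged genes are excluded from all chrX
#' statistics downstream.  Autosomal genes are untouched.
#'
#' @param table an `aif_table`.
#' @param par1,par2 `c(start, end)` intervals on chrX.
#' @return the table with `is_par` updated.
#' @export
mask_par <- function(table, par1 = PAR1, par2 = PAR2) {
  stopifnot(inherits(table, "aif_table"))
  for (iv in list(par1, par2)) {
    if (length(iv) != 2L || iv[1] > iv[2]) {
      stop_config("malformed PAR interval (start > end)")
    }
  }
  on_x <- table$chrom %in% c("chrX", "X")
  overlaps <- function(iv) table$start <= iv[2] & table$end >= iv[1]
  table$is_par <- on_x & (overlaps(par1) | overlaps(par2))
  table
}

# scope filter shared by the group tests
aif_scope <- function(table, scope) {
  on_x <- table$chrom %in% c("chrX", "X")
  if (scope == "chrX") table[on_x & !table$is_par, , drop = FALSE]
  else table[!on_x, , drop = FALSE]
}

#' Compare AIF between two sample groups
#'
#' Mann-Whitney U test on the pooled gene-sample AIF values of the two
#' groups, within the chosen scope (chrX excludes PAR-masked genes).  Set
#' `aggregate = "sample"` to average AIF per sample before testing.
#'
#' @param table an `aif_table` (run [mask_par()] first for chrX scope).
#' @param grouping named character vector: sample -> group label (exactly two
#'   groups among the table's samples).
#' @param scope `"chrX"` or `"autosomes"`.
#' @param aggregate `"none"` (pool gene-sample values) or `"sample"`.
#' @return list with `U`, `p`, `n` (per group), `group_medians`.
#' @export
compare_aif_groups <- function(table, grouping,
                               scope = c("chrX", "autosomes"),
                               aggregate = c("none", "sample")) {
  stopifnot(inherits(table, "aif_table"))
  scope <- match.arg(scope); aggregate <- match.arg(aggregate)
  tab <- aif_scope(table, scope)
  g <- grouping[tab$sample]
  tab <- tab[!is.na(g), , drop = FALSE]
  g <- g[!is.na(g)]
  lv <- unique(grouping)
  if (length(lv) != 2L) stop_config("grouping must define exactly two groups")
  vals <- split(tab$aif, factor(g, levels = lv))
  if (aggregate == "sample") {
    bysamp <- split(tab$aif, list(g, tab$sample), drop = TRUE)
    m <- vapply(bysamp, mean, numeric(1))
    grp <- sub("\\..*$", "", names(bysamp))
    vals <- split(unname(m), factor(grp, levels = lv))
  }
  if (any(lengths(vals) == 0L)) stop_config("empty group after scope filter")
  wt <- stats::wilcox.test(vals[[1]], vals[[2]], exact = FALSE, correct = TRUE)
  list(U = unname(wt$statistic), p = wt$p.value, n = lengths(vals),
       group_medians = vapply(vals, stats::median, numeric(1)))
}

#' Regional AIF difference profile along chrX
#'
#' Per gene, the AIF difference `mean(group_a) - mean(group_b)` over samples
#' with a retained value; per named chrX interval, a one-sample Wilcoxon
#' test of the member genes' differences against 0, with escape and
#' non-escape strata tested separately when annotations are supplied.
#'
#' @param table an `aif_table` (PAR-masked).
#' @param group_a,group_b disjoint sample identifier vectors; the sign
#'   convention is group_a minus group_b.
#' @param intervals data.frame with columns name, start, end (chrX, 1-based
#'   inclusive).
#' @param escape_annotations optional named vector: gene -> `"escape"` /
#'   `"non_escape"`.
#' @return list with `delta` (data.frame gene, start, end, delta_aif, n_a,
#'   n_b, escape_status) and `interval_tests` (data.frame name, stratum,
#'   n_genes, p).
#' @export
aif_difference_profile <- function(table, group_a, group_b, intervals,
                                   escape_annotations = NULL) {
  stopifnot(inherits(table, "aif_table"))
  if (length(intersect(group_a, group_b)) > 0) {
    stop_config("group_a and group_b must be disjoint")
  }
  tab <- aif_scope(table, "chrX")
  if (!is.null(escape_annotations)) {
    st <- escape_annotations[tab$gene]
    tab$escape_status <- ifelse(is.na(st), "unknown", st)
  }
  mean_by_gene <- function(samples) {
    sub <- tab[tab$sample %in% samples, , drop = FALSE]
    list(mean = tapply(sub$aif, sub$gene, mean),
         n = tapply(sub$aif, sub$gene, length))
  }
  a <- mean_by_gene(group_a); b <- mean_by_gene(group_b)
  genes <- intersect(names(a$mean), names(b$mean))
  info <- tab[match(genes, tab$gene), c("gene", "start", "end",
                                        "escape_status"), drop = FALSE]
  delta <- data.frame(info[, c("gene", "start", "end")],
                      delta_aif = unname(a$mean[genes] - b$mean[genes]),
                      n_a = as.integer(a$n[genes]),
                      n_b = as.integer(b$n[genes]),
                      escape_status = info$escape_status,
                      stringsAsFactors = FALSE, row.names = NULL)

  test_stratum <- function(d, name, stratum) {
    if (nrow(d) == 0L || all(d$delta_aif == 0)) {
      return(data.frame(name = name, stratum = stratum, n_genes = nrow(d),
                        p = NA_real_, testable = FALSE,
                        stringsAsFactors = FALSE))
    }
    p <- stats::wilcox.test(d$delta_aif, mu = 0, exact = FALSE)$p.value
    data.frame(name = name, stratum = stratum, n_genes = nrow(d), p = p,
               testable = TRUE, stringsAsFactors = FALSE)
  }
  tests <- list()
  for (i in seq_len(nrow(intervals))) {
    iv <- intervals[i, ]
    member <- delta[delta$start <= iv$end & delta$end >= iv$start, ,
                    drop = FALSE]
    tests[[length(tests) + 1L]] <- test_stratum(member, iv$name, "all")
    if (!is.null(escape_annotations)) {
      for (s in c("escape", "non_escape")) {
        tests[[length(tests) + 1L]] <-
          test_stratum(member[member$escape_status == s, , drop = FALSE],
                       iv$name, s)
      }
    }
  }
  list(delta = delta, interval_tests = do.call(rbind, tests))
}
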