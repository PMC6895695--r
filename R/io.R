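# File formats: TSV matrices and tables with '#'-prefixed provenance
# headers, GMT gene sets, BED intervals, dosage matrices, YAML config.
# Internal coordinates are 1-based inclusive; BED is converted at the
# boundary.

pkg_version <- function() {
  as.character(utils::packageVersion("cardiofate"))
}

config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1))
          %% 4294967295)
}

provenance_header <- function(stage, config = NULL) {
  c(sprintf("# cardiofate %s", pkg_version()),
    sprintf("# stage: %s", stage),
    if (!is.null(config)) sprintf("# config: %s", config_hash(config)))
}

check_not_ragged <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#",
                            quote = "")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop_config("ragged row in ", path, " (data line ", bad, ")")
  }
}

#' Read a genes x samples expression matrix from TSV
#'
#' Expects a `gene` identifier column followed by one column per sample;
#' lines starting `#` are provenance comments.  Duplicate gene identifiers
#' and ragged rows are errors.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  check_not_ragged(path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop_config("first column must be 'gene'")
  if (anyDuplicated(df$gene)) {
    stop_config("duplicate gene identifiers: ",
                paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix (or any table) as provenance-stamped TSV
#'
#' @param x matrix (written with a `gene` column) or data.frame.
#' @param path file path.
#' @param stage producing stage name for the header.
#' @param config optional config object whose hash is recorded.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, stage = "cardiofate", config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(stage, config), con)
  if (is.matrix(x)) {
    x <- data.frame(gene = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: per line, set name, description, then gene ids.
#' @return named list of gene-identifier vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) f <- c(f, character(3 - length(f)))
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' Read intervals from a BED file
#'
#' BED is 0-based half-open; returned coordinates are 1-based inclusive
#' (`start + 1`, `end`), the package's internal convention.
#'
#' @param path BED file (chrom, start, end, optional name).
#' @return data.frame chrom, start, end, name.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, fill = TRUE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$start <- df$start + 1L
  if (ncol(df) >= 4L) names(df)[4] <- "name" else df$name <- NA_character_
  df[, c("chrom", "start", "end", "name")]
}

#' Read a variants x lines dosage matrix from TSV
#'
#' @param path TSV with a `variant` column then one column per line; values
#'   must lie in \[0, 2\].
#' @return numeric matrix.
#' @export
read_dosages <- function(path) {
  check_not_ragged(path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "variant") stop_config("first column must be 'variant'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$variant
  storage.mode(m) <- "double"
  if (any(m < 0 | m > 2)) stop_config("dosages must lie in [0, 2]")
  m
}

#' Read an allele-count table from TSV
#'
#' @param path TSV with columns gene, chrom, start, end, sample, ref_count,
#'   alt_count.
#' @return data.frame.
#' @export
read_allele_counts <- function(path) {
  check_not_ragged(path)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "start", "end", "sample", "ref_count",
            "alt_count")
  if (!all(need %in% names(df))) {
    stop_config("allele-count table must have columns ",
                paste(need, collapse = ", "))
  }
  df
}
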