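#' Validate a gene-by-sample count matrix
#'
#' A count matrix is an integer-valued numeric matrix with unique,
#' non-empty rownames (gene identifiers) and colnames (sample
#' identifiers), and no negative or missing entries.
#'
#' @param counts numeric matrix, genes in rows and samples in columns.
#' @return the matrix, invisibly, after validation.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_fmt("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_fmt("counts must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop_fmt("duplicate gene identifiers: %s",
             paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                   collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop_fmt("duplicate sample identifiers")
  if (anyNA(counts)) stop_fmt("counts contain missing values")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_fmt("non-integer or negative count at gene '%s', sample '%s'",
             rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]])
  invisible(counts)
}

## Sniff the field separator of a delimited text file from its header line:
## tab is canonical, comma accepted as a fallback.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
}

#' Read a gene-by-sample count matrix from TSV
#'
#' The file must have a header row of sample identifiers, gene
#' identifiers in the first column, and a non-negative integer body. A
#' comma-separated file is auto-detected from the header line. All rows
#' are retained; nothing is filtered on read.
#'
#' @param path path to a TSV (or CSV) file.
#' @return an integer matrix with gene rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop_fmt("count file needs a gene column plus samples")
  genes <- df[[1L]]
  if (anyDuplicated(genes))
    stop_fmt("duplicate gene identifier '%s' in %s",
             genes[duplicated(genes)][1L], path)
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = dimnames(body)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_fmt("non-integer or negative count at gene '%s', sample '%s'",
             genes[bad[1L, 1L]], colnames(body)[bad[1L, 2L]])
  counts <- matrix(as.integer(round(num)), nrow = nrow(num),
                   dimnames = list(genes, colnames(num)))
  validate_count_matrix(counts)
  counts
}

#' Write a count matrix as TSV
#'
#' @param counts validated count matrix.
#' @param path output file path.
#' @export
write_count_matrix <- function(counts, path) {
  validate_count_matrix(counts)
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a sample design table
#'
#' @param design data frame with columns `sample_id`, `strain`,
#'   `fraction` (one of `"total"`, `"polysomal"`) and `replicate`
#'   (positive integer).
#' @return the design, invisibly.
#' @export
validate_sample_design <- function(design) {
  need <- c("sample_id", "strain", "fraction", "replicate")
  missing <- setdiff(need, names(design))
  if (length(missing) > 0L)
    stop_fmt("sample table lacks column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop_fmt("duplicated sample_id '%s'",
             design$sample_id[duplicated(design$sample_id)][1L])
  bad <- setdiff(unique(design$fraction), c("total", "polysomal"))
  if (length(bad) > 0L)
    stop_fmt("unknown fraction label '%s' (allowed: total, polysomal)", bad[1L])
  rep_num <- suppressWarnings(as.numeric(design$replicate))
  if (anyNA(rep_num) || any(rep_num < 1) || any(rep_num != round(rep_num)))
    stop_fmt("replicate must be a positive integer")
  invisible(design)
}

#' Read a sample design table from TSV
#'
#' @inheritParams read_count_matrix
#' @return a data frame with columns `sample_id`, `strain`, `fraction`,
#'   `replicate` (plus any extra columns present in the file).
#' @export
read_sample_table <- function(path) {
  sep <- detect_sep(path)
  design <- utils::read.delim(path, sep = sep, header = TRUE,
                              check.names = FALSE,
                              stringsAsFactors = FALSE)
  validate_sample_design(design)
  design$replicate <- as.integer(design$replicate)
  design
}

#' Write a sample design table as TSV
#'
#' @param design validated sample design.
#' @param path output file path.
#' @export
write_sample_table <- function(design, path) {
  validate_sample_design(design)
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## Check that counts and design describe the same samples, in order.
## Returns the design reordered to match the count matrix columns.
align_design <- function(counts, design) {
  validate_count_matrix(counts)
  validate_sample_design(design)
  missing <- setdiff(colnames(counts), design$sample_id)
  if (length(missing) > 0L)
    stop_fmt("sample(s) in counts but not in sample table: %s",
             paste(missing, collapse = ", "))
  design[match(colnames(counts), design$sample_id), , drop = FALSE]
}
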