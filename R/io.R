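#' Read a chemical fingerprint table from delimited text
#'
#' Expects a header row of chemical ids and a first column of sample ids.
#'
#' @param path File path.
#' @param sep Field separator (tab by default).
#' @param missing_token String encoding missing values ("NA" default).
#' @return A [chem_table()].
#' @export
read_chem_table <- function(path, sep = "\t", missing_token = "NA") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          na.strings = missing_token, check.names = FALSE,
                          stringsAsFactors = FALSE)
  chem_table(as.matrix(df))
}

#' Write a chemical table as delimited text
#'
#' @param table A [chem_table()].
#' @param path Output file path.
#' @param sep Field separator.
#' @param missing_token Token written for missing entries.
#' @return `path`, invisibly.
#' @export
write_chem_table <- function(table, path, sep = "\t", missing_token = "NA") {
  df <- data.frame(sample_id = rownames(table),
                   unclass_matrix(table), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = missing_token)
  invisible(path)
}

#' Read a gene count matrix (genes in rows) from delimited text
#'
#' @inheritParams read_chem_table
#' @param normalized Whether values are normalized reals rather than counts.
#' @return An [expr_matrix()].
#' @export
read_expr_matrix <- function(path, sep = "\t", normalized = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  expr_matrix(as.matrix(df), normalized = normalized)
}

#' Write a gene expression matrix as delimited text
#'
#' @param expr An [expr_matrix()].
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_expr_matrix <- function(expr, path, sep = "\t") {
  df <- data.frame(gene_id = rownames(expr),
                   unclass_matrix(expr), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene covariate file (two columns: gene_id, value)
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Named numeric vector.
#' @export
read_gene_covariate <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}

#' Read pathway annotation in GMT format
#'
#' Each line: pathway id, description, then member gene ids, tab-separated.
#'
#' @param path GMT file path.
#' @return A `pathway_annotation`: named list of gene-id character vectors,
#'   with a `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    stop(sprintf("malformed GMT: line %d has fewer than 3 fields", bad[1]))
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicated pathway ids in GMT")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(vapply(fields, `[[`, "", 2L), ids)
  class(sets) <- "pathway_annotation"
  sets
}

#' Write pathway annotation in GMT format
#'
#' @param annotation Named list of gene-id vectors (optionally with a
#'   `description` attribute).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotation, path) {
  desc <- attr(annotation, "description")
  if (is.null(desc)) desc <- stats::setNames(names(annotation), names(annotation))
  lines <- vapply(names(annotation), function(id) {
    paste(c(id, desc[[id]], annotation[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# strip S3 class/attrs so data.frame() sees a plain matrix
unclass_matrix <- function(x) {
  y <- as.matrix(x)
  attributes(y) <- list(dim = dim(x), dimnames = dimnames(x))
  y
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
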