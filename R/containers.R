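#' Chemical fingerprint table
#'
#' Container for a samples x chemicals concentration matrix, the chemical
#' block of the multiblock model. Missing entries (not detected, below the
#' limit of detection, or not measured) are encoded as `NA`; no substitution
#' value (such as LOD/2) is ever applied.
#'
#' @param values Numeric matrix, samples in rows, chemicals in columns.
#'   Row and column names are used as sample and chemical identifiers; if
#'   absent, `S1..Sn` / `C1..Cp` are generated.
#' @param chemical_class Optional character vector, one class label per
#'   chemical (e.g. "PAH", "pharmaceutical").
#'
#' @return An object of class `chem_table`: the values matrix with
#'   attributes `chemical_class` and `standardized`.
#' @export
chem_table <- function(values, chemical_class = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x chemicals)")
  }
  if (is.null(rownames(values)) && nrow(values) > 0) {
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(colnames(values)) && ncol(values) > 0) {
    colnames(values) <- paste0("C", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicated chemical ids")
  if (any(!is.finite(values[!is.na(values)]))) {
    stop("non-finite concentration values present")
  }
  if (!is.null(chemical_class)) {
    if (length(chemical_class) != ncol(values)) {
      stop("`chemical_class` must have one entry per chemical")
    }
    names(chemical_class) <- colnames(values)
  }
  structure(values,
            chemical_class = chemical_class,
            standardized = FALSE,
            class = c("chem_table", "matrix", "array"))
}

#' @export
print.chem_table <- function(x, ...) {
  cat(sprintf("chem_table: %d samples x %d chemicals (%d missing entries%s)\n",
              nrow(x), ncol(x), sum(is.na(x)),
              if (isTRUE(attr(x, "standardized"))) ", standardized" else ""))
  invisible(x)
}

sample_ids <- function(x) rownames(x)
chemical_ids <- function(x) colnames(x)

# rebuild a chem_table around a plain matrix, carrying class labels over
as_chem_table <- function(values, template, standardized = FALSE) {
  cls <- attr(template, "chemical_class")
  if (!is.null(cls)) cls <- cls[colnames(values)]
  out <- chem_table(values, chemical_class = unname(cls))
  attr(out, "standardized") <- standardized
  out
}

#' Gene expression matrix
#'
#' Container for a genes x samples matrix: raw non-negative integer counts,
#' or real values on a log-like scale once normalized. The gene block of the
#' multiblock model.
#'
#' @param counts Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are the gene and sample identifiers (generated if absent).
#' @param gene_covariate Optional numeric vector, one value per gene (e.g.
#'   gene length or GC fraction) for covariate-conditional normalization.
#' @param normalized Logical flag; `FALSE` for raw counts.
#'
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(counts, gene_covariate = NULL, normalized = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicated gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample ids")
  if (anyNA(counts)) stop("expression matrix may not contain missing values")
  if (!normalized) {
    if (any(counts < 0)) stop("raw counts must be non-negative")
    if (any(abs(counts - round(counts)) > 1e-8)) {
      stop("raw counts must be integer-valued; set normalized = TRUE for real-valued data")
    }
  }
  if (!is.null(gene_covariate)) {
    if (length(gene_covariate) != nrow(counts)) {
      stop("`gene_covariate` must have one value per gene")
    }
    names(gene_covariate) <- rownames(counts)
  }
  structure(counts,
            gene_covariate = gene_covariate,
            normalized = normalized,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "normalized"))) "normalized" else "raw counts"))
  invisible(x)
}

is_normalized <- function(x) isTRUE(attr(x, "normalized"))
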