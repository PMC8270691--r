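#' Read a gene x sample expression matrix
#'
#' Reads log2-scale expression intensities from either a plain tab-separated
#' table (first column gene symbols, header row sample identifiers) or a
#' GEO-style series-matrix text file in which metadata lines are prefixed
#' with `"!"` and the data table sits between the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers.
#'
#' Duplicate gene rows are preserved on read; merging duplicates is a
#' preprocessing step (see [collapse_duplicates()]). Duplicate sample
#' columns are an error.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"series_matrix"`.
#' @return A numeric matrix (genes x samples) with gene symbols as rownames
#'   and sample identifiers as colnames.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, dialect = c("tsv", "series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_("expression file not found: %s", path)
  lines <- readLines(path)
  if (dialect == "series_matrix") {
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) == 1 && length(end) == 1 && end > beg + 1) {
      lines <- lines[(beg + 1):(end - 1)]
    } else {
      lines <- lines[!startsWith(lines, "!")]
    }
    lines <- gsub('"', "", lines, fixed = TRUE)
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop_("expression file has no data rows: %s", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) {
    stop_("malformed expression header (line 1): need a gene column and >=1 sample")
  }
  samples <- header[-1]
  if (anyDuplicated(samples)) {
    stop_("duplicated sample identifiers in header: %s",
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(body)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    stop_("malformed expression row at line %d: %d fields, expected %d",
          bad + 1L, nf[bad], length(header))
  }
  genes <- vapply(body, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(length(samples)))
  )
  vals <- if (length(samples) == 1) matrix(vals, nrow = 1) else t(vals)
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop_("non-numeric expression value at data row %d, sample '%s'",
          idx[1], samples[idx[2]])
  }
  dimnames(vals) <- list(genes, samples)
  vals
}

#' Write an expression matrix as tab-separated text
#'
#' Genes are written as rows (GEO convention), with a `gene_id` first column.
#'
#' @param mat Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  validate_expression(mat, allow_dup_genes = TRUE)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Checks the container invariants: numeric matrix, named dimensions,
#' finite values, unique sample identifiers, and (unless duplicates are
#' explicitly allowed pre-collapse) unique gene symbols.
#'
#' @param mat Matrix to validate.
#' @param allow_dup_genes Allow duplicated gene rows (pre-collapse state).
#' @return `mat`, invisibly.
#' @export
validate_expression <- function(mat, allow_dup_genes = FALSE) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop_("expression must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop_("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(colnames(mat))) stop_("duplicated sample identifiers")
  if (!allow_dup_genes && anyDuplicated(rownames(mat))) {
    stop_("duplicated gene identifiers (run collapse_duplicates first)")
  }
  if (!all(is.finite(mat))) stop_("expression matrix contains non-finite values")
  invisible(mat)
}
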