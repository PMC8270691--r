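GENESET_MODULES <- c("viral", "bacterial", "fungal", "IFN", "immune", "none")

#' Read gene sets from a GMT file
#'
#' Each GMT line is `term_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' An optional two-column tab-separated `module_map` file (`term_id`,
#' `module`) assigns each term to one of the five functional modules used
#' throughout the pipeline (`viral`, `bacterial`, `fungal`, `IFN`,
#' `immune`); unmapped terms get module `"none"`.
#'
#' @param path Path to the GMT file.
#' @param module_map Optional path to a term -> module map.
#' @return An object of class `geneset_collection`: a `data.frame` with
#'   columns `term_id`, `term_name`, `module` and a list-column `genes`.
#' @export
read_gmt <- function(path, module_map = NULL) {
  if (!file.exists(path)) stop_("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop_("GMT line %d has %d field(s); need term, description and >=1 gene",
          which(nf < 3)[1], nf[which(nf < 3)[1]])
  }
  gs <- data.frame(
    term_id = vapply(fields, `[[`, character(1), 1L),
    term_name = vapply(fields, `[[`, character(1), 2L),
    module = "none",
    stringsAsFactors = FALSE
  )
  gs$genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  if (anyDuplicated(gs$term_id)) stop_("duplicated term_id in GMT")
  if (!is.null(module_map)) {
    mm <- utils::read.table(module_map, sep = "\t", header = FALSE,
                            col.names = c("term_id", "module"),
                            stringsAsFactors = FALSE)
    hit <- match(gs$term_id, mm$term_id)
    gs$module[!is.na(hit)] <- mm$module[hit[!is.na(hit)]]
  }
  bad <- setdiff(unique(gs$module), GENESET_MODULES)
  if (length(bad)) stop_("unknown module label(s): %s", paste(bad, collapse = ", "))
  class(gs) <- c("geneset_collection", "data.frame")
  gs
}

#' Write a geneset collection to GMT (plus optional module map)
#' @param genesets A `geneset_collection`.
#' @param path Output GMT path.
#' @param module_map Optional path for the term -> module map TSV.
#' @export
write_gmt <- function(genesets, path, module_map = NULL) {
  lines <- vapply(seq_len(nrow(genesets)), function(i) {
    paste(c(genesets$term_id[i], genesets$term_name[i], genesets$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  if (!is.null(module_map)) {
    utils::write.table(genesets[, c("term_id", "module")], module_map,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Construct a geneset collection in code
#' @param term_id,term_name Character vectors.
#' @param genes List of character vectors (one per term).
#' @param module Module label per term (default `"none"`).
#' @return A `geneset_collection`.
#' @export
geneset_collection <- function(term_id, genes, term_name = term_id,
                               module = "none") {
  stopifnot(length(term_id) == length(genes))
  if (any(lengths(genes) == 0)) stop_("every gene set must be non-empty")
  if (anyDuplicated(term_id)) stop_("duplicated term_id")
  gs <- data.frame(term_id = term_id, term_name = term_name,
                   module = rep_len(module, length(term_id)),
                   stringsAsFactors = FALSE)
  gs$genes <- genes
  class(gs) <- c("geneset_collection", "data.frame")
  gs
}
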