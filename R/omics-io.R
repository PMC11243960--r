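#' Read an omics feature table with its design file
#'
#' The feature table is delimited text with a `feature` id column followed
#' by one column per sample; the design file maps `sample` to `group`.
#'
#' @param path feature-table file.
#' @param design design file path, or a data.frame with columns `sample`
#'   and `group`.
#' @param layer omics layer tag.
#' @param annotations optional annotations file path (must contain a
#'   `feature` column) or data.frame.
#' @param sep field separator.
#' @return an [omics_table()].
#' @export
read_omics_table <- function(path, design, layer, annotations = NULL,
                             sep = "\t") {
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"feature" %in% names(tab)) {
    stop(sprintf("%s: first column must be named 'feature'", path),
         call. = FALSE)
  }
  m <- as.matrix(tab[, setdiff(names(tab), "feature"), drop = FALSE])
  if (!is.numeric(m)) {
    stop(sprintf("%s: abundance columns must be numeric", path),
         call. = FALSE)
  }
  rownames(m) <- tab$feature
  if (is.character(design)) {
    design <- utils::read.table(design, sep = sep, header = TRUE,
                                stringsAsFactors = FALSE)
  }
  if (is.character(annotations)) {
    annotations <- utils::read.table(annotations, sep = sep, header = TRUE,
                                     stringsAsFactors = FALSE)
  }
  omics_table(m, design, layer, annotations = annotations,
              meta = list(source = path))
}

#' Write an omics feature table (and optionally its design)
#'
#' @param tab an [omics_table()].
#' @param path output file for the feature table.
#' @param design_path optional output file for the design table.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_omics_table <- function(tab, path, design_path = NULL, sep = "\t") {
  stopifnot(inherits(tab, "omics_table"))
  df <- data.frame(feature = rownames(tab$abundance), tab$abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(design_path)) {
    utils::write.table(tab$design, design_path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
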