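#' Read and write loading matrices as TSV
#'
#' Plain-text round trip for S x K loading (or any numeric) matrices;
#' full double precision is preserved.
#'
#' @param V numeric matrix.
#' @param path file path.
#' @return `readLoadings` returns the matrix; `writeLoadings` returns
#'   `path` invisibly.
#' @export
writeLoadings <- function(V, path) {
  if (is.null(colnames(V))) colnames(V) <- sprintf("net%d", seq_len(ncol(V)))
  utils::write.table(format(V, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLoadings
#' @export
readLoadings <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  as.matrix(df)
}

#' Read and write the cohort table as TSV
#'
#' The cohort TSV carries one row per subject with the columns
#' subject_id, age, sex, motion, ef. `readCohort` validates the header
#' and names any missing columns.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  required <- c("subject_id", "age", "sex", "motion", "ef")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("malformed cohort table, missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

#' Write per-vertex labels as TSV
#'
#' @param labels integer per-vertex labels.
#' @param path file path.
#' @export
writeLabels <- function(labels, path) {
  utils::write.table(
    data.frame(vertex_index = seq_along(labels), label = labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLabels
#' @export
readLabels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("vertex_index", "label") %in% names(df))) {
    stop("malformed label table: need vertex_index and label columns")
  }
  df$label[order(df$vertex_index)]
}
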