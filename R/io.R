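# Labeled-TSV matrix serialization shared by every similarity/feature matrix.
# First header cell is "id", then column ids; one row per entity; values
# printed with %.10g; UTF-8, Unix newlines.

#' Write a labeled matrix to TSV
#'
#' @param M numeric matrix with row and column names.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(M, path) {
  stopifnot(is.matrix(M), !is.null(rownames(M)), !is.null(colnames(M)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(M)), collapse = "\t"), con, sep = "\n")
  vals <- formatC(M, format = "g", digits = 10)
  lines <- paste(rownames(M), apply(vals, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a labeled matrix written by [write_matrix_tsv()]
#'
#' @param path TSV file with an `id` first column.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                          stringsAsFactors = FALSE)
  as.matrix(df)
}
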