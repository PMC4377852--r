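# Plain-text readers/writers for the pipeline's tabular interchange formats.

#' Write / read a genes x samples expression matrix as TSV
#'
#' The first column (`gene_id`) holds gene IDs; remaining columns are
#' samples.
#'
#' @param expr genes x samples matrix.
#' @param path file path.
#' @return `read_expression_tsv` returns the matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write / read transcript models as JSON
#'
#' Schema per transcript: `transcript_id`, `gene_id`, `strand`, `exons`
#' (1-based inclusive genomic spans), `cds_sequence`,
#' `downstream_utr_sequence`.
#'
#' @param transcripts named list of transcript models.
#' @param path file path.
#' @export
write_transcripts_json <- function(transcripts, path) {
  jsonlite::write_json(transcripts, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transcripts_json
#' @export
read_transcripts_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(tr) {
    tr$exons <- as.data.frame(tr$exons)
    tr
  })
}

#' Write a data frame as TSV (no quoting, no row names)
#'
#' @param df data frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path file path.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}
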