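# Delimited-text input/output for the command-line interface.

#' Read a numeric matrix from delimited text
#'
#' Accepts CSV or TSV (delimiter sniffed from the first line), one observation
#' per row, numeric columns only. With `header = "auto"` the first row is
#' treated as a header when any of its fields is non-numeric.
#'
#' @param path File path.
#' @param header `"auto"`, `"yes"`, or `"no"`.
#' @return A numeric matrix.
#' @export
read_matrix <- function(path, header = c("auto", "yes", "no")) {
  header <- match.arg(header)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  hdr <- switch(header,
    yes = TRUE,
    no = FALSE,
    auto = anyNA(suppressWarnings(
      as.numeric(strsplit(first, sep, fixed = TRUE)[[1]]))))
  df <- utils::read.table(path, sep = sep, header = hdr,
                          comment.char = "#", strip.white = TRUE)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop(sprintf("non-numeric cells in %s", path), call. = FALSE)
  }
  check_matrix(as.matrix(df), basename(path))
}

#' Write a neighbour result as TSV
#'
#' One row per (query, rank): columns `query_id`, `rank`, `train_index`,
#' `distance`. A leading comment line states that `train_index` is the 1-based
#' training row number. The file is written atomically (temp file + rename) so
#' a failure leaves no partial output.
#'
#' @param result An `"stnn_knn"` object.
#' @param path Output file.
#' @export
write_neighbors <- function(result, path) {
  stopifnot(inherits(result, "stnn_knn"))
  df <- as.data.frame(result)
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  writeLines("# train_index is the 1-based row number in the training matrix",
             con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a neighbour TSV back as a data frame
#'
#' @param path File written by [write_neighbors()].
#' @return A data frame with `query_id`, `rank`, `train_index`, `distance`.
#' @export
read_neighbors <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
}
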