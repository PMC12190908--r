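`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Read a tab-separated file into a data.frame
#' @noRd
.read_tsv <- function(path, ...) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Write a data.frame as TSV (deterministic formatting, no quoting)
#' @noRd
.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' @noRd
.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    .stopf("%s is missing required column(s): %s", what,
           paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Open a (possibly gzip-compressed) text connection
#' @noRd
.text_lines <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}
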