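# Reading and writing signal tables as delimited text.

#' Read a DEXSY signal table from delimited text
#'
#' Reads a CSV (or other delimiter) file with at least the columns
#' `encoding`, `b1`, `b2`, `tm_ms`, `signal` - the schema written by
#' [write_signal_table()] and consumed by [estimate_axr()].
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return A `signal_table` data frame.
#' @export
read_signal_table <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  req <- c("encoding", "b1", "b2", "tm_ms", "signal")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0)
    stop("signal table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  class(tab) <- c("signal_table", "data.frame")
  tab
}

#' Write a DEXSY signal table to CSV
#'
#' @param table A `signal_table` data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_signal_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
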