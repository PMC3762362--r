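#' Read and write spot event tables
#'
#' Tab-separated event tables with the fixed header
#' `site_id channel x_um y_um t_on_s t_off_s fate`; times in seconds,
#' positions in micrometers, 0-based site ids. Malformed rows are reported
#' with their line numbers. `read_event_table(write_event_table(x))`
#' round-trips exactly.
#'
#' @param path File path.
#' @param events A `spot_events` table.
#' @return `read_event_table` returns a validated `spot_events` table;
#'   `write_event_table` returns `path` invisibly.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("site_id", "channel", "x_um", "y_um", "t_on_s", "t_off_s",
              "fate")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("event table ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  df$site_id <- as.integer(df$site_id)
  df$channel <- as.character(df$channel)
  df$fate <- as.character(df$fate)
  num_cols <- c("x_um", "y_um", "t_on_s", "t_off_s")
  for (col in num_cols) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop("non-numeric or non-finite ", col, " at line(s) ",
           paste(utils::head(bad + 1L, 5), collapse = ", "), " of ", path)
  }
  bad <- which(!(df$t_off_s > df$t_on_s))
  if (length(bad))
    stop("t_off_s <= t_on_s at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), " of ", path)
  validate_spot_events(df)
}

#' @rdname read_event_table
#' @export
write_event_table <- function(events, path) {
  events <- validate_spot_events(as.data.frame(events))
  cols <- c("site_id", "channel", "x_um", "y_um", "t_on_s", "t_off_s",
            "fate")
  utils::write.table(events[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an analysis report table
#'
#' Writes a data.frame (or coercible list) of results as a
#' tab-separated file with a header; full precision, no quoting.
#'
#' @param results data.frame or named list of equal-length columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  df <- as.data.frame(results)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
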