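#' Read and write face tracks as CSV
#'
#' Tracks use a flat CSV schema with one header line and `.` as decimal
#' separator: `frame,capture_time_ms,tx,ty,tz,rx,ry,rz,AU01,...,AU45,valid,
#' confidence`. Columns are matched by header name, so shuffled column order
#' round-trips; a missing required column is a format error. Values
#' round-trip to within 1e-6 absolute tolerance.
#'
#' @param track A face track `data.frame` (see [sample_states()]).
#' @param path File path.
#' @return `read_track()` returns a face track; `write_track()` returns
#'   `path` invisibly.
#' @export
write_track <- function(track, path) {
  if (nrow(track) < 1) stop("cannot write an empty track")
  missing <- setdiff(track_columns(), names(track))
  if (length(missing))
    stop("track is missing required column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(track[track_columns()], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(track_columns(), names(df))
  if (length(missing)) {
    stop(errorCondition(
      paste0("track file ", path, " is missing required column(s): ",
             paste(missing, collapse = ", ")),
      class = c("mirror_format_error", "error", "condition")
    ))
  }
  df <- df[track_columns()]
  df$frame <- as.integer(df$frame)
  df$valid <- as.logical(df$valid)
  df
}

track_columns <- function() {
  c("frame", "capture_time_ms", POSE_FIELDS, AU_SET, "valid", "confidence")
}
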