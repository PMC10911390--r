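#' Read a particle track table
#'
#' Reads either the spot-table CSV dialect exported by tracking tools
#' (columns `TRACK_ID`, `FRAME`, `POSITION_T`, `POSITION_X`, `POSITION_Y`
#' and optionally `POSITION_Z`) or the package's tidy dialect (`track_id`,
#' `frame`, `t`, `x`, `y`[, `z`]). Positions are in um and times in
#' seconds. Rows with missing mandatory fields are rejected and counted;
#' duplicated (track, frame) pairs and non-monotone per-track times raise
#' validation errors naming the offender.
#'
#' @param path CSV file path (comma-separated, header row, '.' decimal).
#' @param dialect `"spot_table_csv"` or `"tidy_csv"`; default guesses from
#'   the header.
#' @return A tibble with columns `track_id`, `frame`, `t`, `x`, `y` and,
#'   when present, `z`.
#' @export
read_track_table <- function(path, dialect = c("auto", "spot_table_csv",
                                               "tidy_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE)
  spot_cols <- c("TRACK_ID", "FRAME", "POSITION_T", "POSITION_X",
                 "POSITION_Y")
  tidy_cols <- c("track_id", "frame", "t", "x", "y")
  if (dialect == "auto") {
    dialect <- if (all(spot_cols %in% names(raw))) "spot_table_csv"
               else "tidy_csv"
  }
  need <- if (dialect == "spot_table_csv") spot_cols else tidy_cols
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    abort(sprintf("Missing mandatory column(s): %s (expected: %s)",
                  paste(missing_cols, collapse = ", "),
                  paste(need, collapse = ", ")))
  d <- if (dialect == "spot_table_csv") {
    out <- tibble(track_id = raw$TRACK_ID, frame = raw$FRAME,
                  t = raw$POSITION_T, x = raw$POSITION_X,
                  y = raw$POSITION_Y)
    if ("POSITION_Z" %in% names(raw)) out$z <- raw$POSITION_Z
    out
  } else {
    out <- tibble(track_id = raw$track_id, frame = raw$frame, t = raw$t,
                  x = raw$x, y = raw$y)
    if ("z" %in% names(raw)) out$z <- raw$z
    out
  }
  ok <- stats::complete.cases(d[, c("track_id", "frame", "t", "x", "y")])
  if (any(!ok)) {
    inform(sprintf("Rejected %d malformed row(s).", sum(!ok)))
    d <- d[ok, ]
  }
  dup <- duplicated(d[, c("track_id", "frame")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf("Duplicated (track, frame) row: track %s, frame %s.",
                  d$track_id[i], d$frame[i]))
  }
  d <- d[order(d$track_id, d$frame), ]
  bad <- vapply(split(d$t, d$track_id), function(tt) any(diff(tt) <= 0),
                logical(1))
  if (any(bad))
    abort(sprintf("Non-monotone time in track(s): %s.",
                  paste(names(bad)[bad], collapse = ", ")))
  d
}

#' Write a track table
#'
#' @param tracks A tidy track table (`track_id`, `frame`, `t`, `x`,
#'   `y`[, `z`]).
#' @param path Output CSV path.
#' @param dialect `"tidy_csv"` (default) or `"spot_table_csv"`.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(tracks, path,
                              dialect = c("tidy_csv", "spot_table_csv")) {
  dialect <- match.arg(dialect)
  stopifnot(all(c("track_id", "frame", "t", "x", "y") %in% names(tracks)))
  out <- if (dialect == "spot_table_csv") {
    o <- data.frame(TRACK_ID = tracks$track_id, FRAME = tracks$frame,
                    POSITION_T = tracks$t, POSITION_X = tracks$x,
                    POSITION_Y = tracks$y)
    if ("z" %in% names(tracks)) o$POSITION_Z <- tracks$z
    o
  } else as.data.frame(tracks[, intersect(c("track_id", "frame", "t", "x",
                                            "y", "z"), names(tracks))])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
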