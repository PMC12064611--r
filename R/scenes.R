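#' Scene tables
#'
#' A scene is a labeled time interval selecting the task-relevant part of a
#' recording (footage before/after the task, or particular behaviors of
#' interest). Intervals are half-open `[start_ms, end_ms)` in milliseconds,
#' so adjacent scenes compose without double-counting boundary frames.
#'
#' @param start_ms,end_ms Interval bounds in ms (`0 <= start < end`).
#' @param description Label per interval.
#' @return A `scene_table` tibble.
#' @examples
#' scene_table(c(0, 60000), c(30000, 90000), c("warmup", "task"))
#' @export
scene_table <- function(start_ms, end_ms, description = "") {
  tb <- tibble(start_ms = as.double(start_ms),
               end_ms = as.double(end_ms),
               description = as.character(description))
  problems <- scene_problems(tb)
  if (length(problems)) {
    stop_fbbc(paste0("Invalid scene table:\n",
                     paste("-", problems, collapse = "\n")),
              "fbbc_validation_error")
  }
  class(tb) <- c("scene_table", class(tibble()))
  tb
}

scene_problems <- function(tb) {
  problems <- character()
  bad <- which(is.na(tb$start_ms) | is.na(tb$end_ms))
  if (length(bad)) {
    problems <- c(problems,
                  sprintf("row %d: non-numeric or missing bound", bad))
  }
  bad <- which(!is.na(tb$start_ms) & tb$start_ms < 0)
  if (length(bad)) {
    problems <- c(problems, sprintf("row %d: start_ms < 0", bad))
  }
  bad <- which(!is.na(tb$start_ms) & !is.na(tb$end_ms) &
               tb$start_ms >= tb$end_ms)
  if (length(bad)) {
    problems <- c(problems, sprintf("row %d: start_ms >= end_ms", bad))
  }
  problems
}

#' Read or write a scene table CSV
#'
#' CSV with header `start_ms,end_ms,description`. Malformed rows (negative
#' or non-numeric times, `start >= end`) raise a validation error naming the
#' row.
#'
#' @param path CSV path.
#' @param table A `scene_table`.
#' @return `read_scene_table()` returns the `scene_table`;
#'   `write_scene_table()` returns `path` invisibly.
#' @export
read_scene_table <- function(path) {
  df <- readr::read_csv(path, col_types = "ddc")
  if (!all(c("start_ms", "end_ms", "description") %in% names(df))) {
    stop_fbbc(sprintf("'%s' lacks the start_ms,end_ms,description header.", path),
              "fbbc_format_error")
  }
  df$description[is.na(df$description)] <- ""
  scene_table(df$start_ms, df$end_ms, df$description)
}

#' @rdname read_scene_table
#' @export
write_scene_table <- function(table, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(table)[, c("start_ms", "end_ms", "description")],
                   path)
  invisible(path)
}

#' Restrict a track or feature series to scenes
#'
#' Keeps rows whose timestamp falls into at least one scene interval
#' (`start <= t < end`); overlapping scenes count a row once. Row order is
#' preserved, and the operation is idempotent.
#'
#' @param x A `track_series` or `feature_series`.
#' @param scenes A non-empty `scene_table`.
#' @return The same type as `x`, restricted to the scenes.
#' @export
filter_by_scenes <- function(x, scenes) {
  if (!inherits(scenes, "scene_table") || nrow(scenes) == 0L) {
    stop_fbbc("`scenes` must be a non-empty scene_table.", "fbbc_argument_error")
  }
  t_ms <- if (is_track_series(x)) {
    track_time_ms(x)
  } else if (is_feature_series(x)) {
    x$time_ms
  } else {
    stop_fbbc("`x` must be a track_series or feature_series.",
              "fbbc_argument_error")
  }
  keep <- rep(FALSE, length(t_ms))
  for (i in seq_len(nrow(scenes))) {
    keep <- keep | (t_ms >= scenes$start_ms[i] & t_ms < scenes$end_ms[i])
  }
  restore_attrs(x[keep, , drop = FALSE], x)
}
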