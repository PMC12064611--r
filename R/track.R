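#' Build a keypoint track
#'
#' A track is the per-frame, per-person, per-keypoint record of image
#' coordinates produced by a pose-estimation backend: one row per
#' `(frame, person, keypoint)` with `x`, `y` in pixels (image convention:
#' origin top-left, y increases downward) and a detection `confidence` in
#' \[0, 1\] (or `NA` when the backend reports none). Missing detections are
#' kept as `NA` coordinates, never zero-filled.
#'
#' @param data A data frame with columns `frame`, `person`, `keypoint`, `x`,
#'   `y` and optionally `confidence`.
#' @param fps Frame rate of the source video (frames/second, > 0).
#' @param scheme Optional [keypoint_scheme()] describing the keypoints.
#' @param video_name Optional name of the source video.
#' @param frame_size Optional `c(width, height)` in pixels.
#' @return A `track_series`: a tibble sorted by `(frame, person, keypoint)`
#'   with the frame rate and scheme attached as attributes.
#' @examples
#' track_series(
#'   data.frame(frame = 0:1, person = 0, keypoint = 0, x = 1:2, y = 3:4),
#'   fps = 30
#' )
#' @export
track_series <- function(data, fps, scheme = NULL, video_name = "",
                         frame_size = NULL) {
  check_scalar_number(fps, "fps", min = 0, strict = TRUE)
  data <- as_tibble(data)
  needed <- c("frame", "person", "keypoint", "x", "y")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop_fbbc(paste0("Track data lacks column(s): ",
                     paste(missing_cols, collapse = ", "), "."),
              "fbbc_argument_error")
  }
  if (!"confidence" %in% names(data)) data$confidence <- NA_real_
  data <- data[, c(needed, "confidence")]
  data$frame <- as.integer(data$frame)
  data$person <- as.integer(data$person)
  data$keypoint <- as.integer(data$keypoint)
  data$x <- as.double(data$x)
  data$y <- as.double(data$y)
  data$confidence <- as.double(data$confidence)

  tr <- new_track_series(data, fps = fps, scheme = scheme,
                         video_name = video_name, frame_size = frame_size)
  rep <- validate_track(tr, scheme = scheme)
  if (nrow(rep)) {
    stop_fbbc(paste0("Invalid track:\n",
                     paste("-", rep$message, collapse = "\n")),
              "fbbc_track_error")
  }
  tr
}

# low-level constructor: no validation, used internally and by tests that
# need to build deliberately broken tracks
new_track_series <- function(data, fps, scheme = NULL, video_name = "",
                             frame_size = NULL) {
  data <- arrange(as_tibble(data), .data$frame, .data$person, .data$keypoint)
  structure(
    data,
    fps = as.double(fps),
    scheme = scheme,
    video_name = as.character(video_name),
    frame_size = frame_size,
    class = c("track_series", class(tibble())))
}

is_track_series <- function(x) inherits(x, "track_series")

#' @export
print.track_series <- function(x, ...) {
  cat(sprintf("<track_series: %d rows, %d frame(s), %d person(s), fps %.6g%s>\n",
              nrow(x), dplyr::n_distinct(x$frame), dplyr::n_distinct(x$person),
              attr(x, "fps"),
              if (nzchar(attr(x, "video_name"))) paste0(", video '", attr(x, "video_name"), "'") else ""))
  NextMethod()
}

#' Frame rate of a track, feature series or timeline
#' @param x An object carrying an `fps` attribute.
#' @return Frames per second as a double.
#' @export
fps <- function(x) {
  out <- attr(x, "fps")
  if (is.null(out)) stop_fbbc("Object carries no frame rate.", "fbbc_argument_error")
  out
}

#' Timestamps of track frames
#'
#' Frame timestamps are defined as `frame / fps * 1000` milliseconds.
#'
#' @param track A `track_series`.
#' @return Numeric vector of per-row timestamps (ms).
#' @export
track_time_ms <- function(track) {
  track$frame / fps(track) * 1000
}

#' Validate a track against its invariants
#'
#' Checks the structural invariants of a track — unique
#' `(frame, person, keypoint)` keys, non-negative frames, positive frame
#' rate, finite-or-missing coordinates, confidence in \[0, 1\] — and, when a
#' scheme is given, that every keypoint id belongs to it. Violations are
#' reported, not thrown, so the function can be used to triage suspect files.
#'
#' @param track A `track_series` (possibly invalid).
#' @param scheme Optional [keypoint_scheme()]; defaults to the track's own.
#' @return A tibble with columns `check` and `message`, one row per
#'   violation; zero rows iff all invariants hold.
#' @export
validate_track <- function(track, scheme = NULL) {
  scheme <- scheme %||% attr(track, "scheme")
  bad <- list()
  note <- function(check, message) {
    bad[[length(bad) + 1L]] <<- tibble(check = check, message = message)
  }

  fps_val <- attr(track, "fps")
  if (is.null(fps_val) || !is.numeric(fps_val) || length(fps_val) != 1L ||
      is.na(fps_val) || fps_val <= 0) {
    note("fps", "fps must be a single number > 0")
  }
  dup <- duplicated(track[, c("frame", "person", "keypoint")])
  if (any(dup)) {
    note("duplicate_key",
         sprintf("%d duplicated (frame, person, keypoint) triple(s)", sum(dup)))
  }
  if (any(track$frame < 0, na.rm = TRUE) || anyNA(track$frame)) {
    note("frame_index", "frame indices must be non-negative integers")
  }
  nonfinite <- function(v) !is.na(v) & !is.finite(v)
  if (any(nonfinite(track$x)) || any(nonfinite(track$y))) {
    note("coordinates", "x/y must be finite numbers or NA (missing)")
  }
  conf <- track$confidence
  if (any(!is.na(conf) & (conf < 0 | conf > 1))) {
    note("confidence", "confidence must lie in [0, 1] or be NA")
  }
  if (!is.null(scheme)) {
    alien <- setdiff(unique(track$keypoint), scheme_ids(scheme))
    if (length(alien)) {
      note("scheme", sprintf("keypoint id(s) outside scheme '%s': %s",
                             scheme$scheme_name,
                             paste(alien, collapse = ", ")))
    }
  }
  if (length(bad)) bind_rows(bad) else tibble(check = character(), message = character())
}

#' Restrict a track to one person
#'
#' @param track A `track_series`.
#' @param person_id Person id to keep.
#' @return A `track_series` with only that person's rows; metadata unchanged.
#' @export
select_person <- function(track, person_id) {
  person_id <- check_count(person_id, "person_id", min = 0L)
  avail <- sort(unique(track$person))
  if (!person_id %in% avail) {
    stop_fbbc(sprintf("Person %d not in track; available person id(s): %s.",
                      person_id, paste(avail, collapse = ", ")),
              "fbbc_lookup_error")
  }
  restore_attrs(track[track$person == person_id, , drop = FALSE], track)
}

#' Mask low-confidence detections
#'
#' Ingest keeps every detection; this explicit filter marks the coordinates of
#' detections below a confidence threshold as missing (`NA`), so downstream
#' features propagate the missingness instead of using unreliable positions.
#' Rows with `NA` confidence are left untouched.
#'
#' @param track A `track_series`.
#' @param threshold Confidence below which coordinates are masked.
#' @return A `track_series` with masked coordinates.
#' @export
filter_confidence <- function(track, threshold) {
  check_scalar_number(threshold, "threshold", min = 0)
  low <- !is.na(track$confidence) & track$confidence < threshold
  track$x[low] <- NA_real_
  track$y[low] <- NA_real_
  track
}
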