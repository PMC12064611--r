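#' Feature series
#'
#' A feature series is a tibble of named numeric time-series columns derived
#' from a track: one row per frame (`frame` unique and strictly increasing,
#' `time_ms = frame / fps * 1000`), then one column per feature. Units depend
#' on the feature: px for positions and distances, px/s for speeds, px^2 for
#' dot and cross products, unitless after normalization. A provenance record
#' (source, operations applied) rides along as an attribute.
#'
#' @param data Data frame with `frame`, `time_ms` and feature columns.
#' @param fps Frame rate (frames/second).
#' @param provenance Optional list describing how the series was derived.
#' @return A `feature_series` tibble.
#' @export
feature_series <- function(data, fps, provenance = list()) {
  check_scalar_number(fps, "fps", min = 0, strict = TRUE)
  data <- as_tibble(data)
  if (!all(c("frame", "time_ms") %in% names(data))) {
    stop_fbbc("A feature series needs `frame` and `time_ms` columns.",
              "fbbc_argument_error")
  }
  if (anyDuplicated(data$frame) || is.unsorted(data$frame, strictly = TRUE)) {
    stop_fbbc("`frame` must be unique and strictly increasing.",
              "fbbc_argument_error")
  }
  if (anyDuplicated(names(data))) {
    stop_fbbc("Feature column names must be unique.", "fbbc_argument_error")
  }
  structure(data,
            fps = as.double(fps),
            provenance = provenance,
            class = c("feature_series", class(tibble())))
}

is_feature_series <- function(x) inherits(x, "feature_series")

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series: %d frame(s), %d feature column(s), fps %.6g>\n",
              nrow(x), length(feature_columns(x)), attr(x, "fps")))
  NextMethod()
}

#' Names of the feature columns of a feature series
#' @param series A `feature_series`.
#' @return Character vector (everything except `frame` and `time_ms`).
#' @export
feature_columns <- function(series) {
  setdiff(names(series), c("frame", "time_ms"))
}

#' Provenance record of a derived object
#' @param x A `feature_series`, `embedding2d` or pipeline result.
#' @return The provenance list.
#' @export
provenance <- function(x) attr(x, "provenance")

# ---------------------------------------------------------------------------
# per-keypoint coordinate access

# wide per-frame coordinates for the requested keypoints; frames = all frames
# present in the track, NA where a keypoint was not detected
kp_coords <- function(track, ids) {
  if (dplyr::n_distinct(track$person) > 1L) {
    stop_fbbc("Track holds several persons; use select_person() first.",
              "fbbc_argument_error")
  }
  present <- unique(track$keypoint)
  alien <- setdiff(ids, present)
  if (length(alien)) {
    stop_fbbc(sprintf("Keypoint id(s) not in track: %s (track has: %s).",
                      paste(alien, collapse = ", "),
                      paste(sort(present), collapse = ", ")),
              "fbbc_lookup_error")
  }
  frames <- sort(unique(track$frame))
  out <- list(frames = frames)
  for (id in ids) {
    sub <- track[track$keypoint == id, , drop = FALSE]
    ri <- match(frames, sub$frame)
    out[[paste0("x", id)]] <- sub$x[ri]
    out[[paste0("y", id)]] <- sub$y[ri]
  }
  out
}

feature_frame <- function(track, frames, values, name, op, ids) {
  feature_series(
    tibble(frame = frames, time_ms = frames / fps(track) * 1000,
           !!name := values),
    fps = fps(track),
    provenance = list(source = attr(track, "video_name"),
                      ops = list(list(op = op, ids = ids, name = name)))
  )
}

# ---------------------------------------------------------------------------
# elementary features

#' Raw coordinate of one keypoint over time
#'
#' @param track A single-person `track_series`.
#' @param keypoint_id Keypoint id.
#' @param axis `"x"` or `"y"` (image convention, y down).
#' @param name Output column name.
#' @return A one-column `feature_series` in pixels; missing coordinates stay
#'   missing.
#' @export
position_series <- function(track, keypoint_id, axis = c("x", "y"),
                            name = NULL) {
  axis <- match.arg(axis)
  co <- kp_coords(track, keypoint_id)
  name <- name %||% sprintf("%s_%d", axis, keypoint_id)
  vals <- co[[paste0(axis, keypoint_id)]]
  feature_frame(track, co$frames, vals, name,
                op = paste0("position_", axis), ids = keypoint_id)
}

#' Instantaneous speed of one keypoint
#'
#' Backward difference: the Euclidean displacement from the previous retained
#' frame divided by the elapsed time, in px/s. The first frame has no
#' predecessor and is missing; a missing coordinate at either end of a step
#' makes that step missing.
#'
#' @inheritParams position_series
#' @return A one-column `feature_series` in px/s.
#' @export
speed_series <- function(track, keypoint_id, name = NULL) {
  co <- kp_coords(track, keypoint_id)
  if (length(co$frames) < 2L) {
    stop_fbbc("Speed needs at least 2 frames.", "fbbc_degenerate_input")
  }
  x <- co[[paste0("x", keypoint_id)]]
  y <- co[[paste0("y", keypoint_id)]]
  dt <- diff(co$frames) / fps(track)            # seconds between retained frames
  sp <- c(NA_real_, sqrt(diff(x)^2 + diff(y)^2) / dt)
  name <- name %||% sprintf("speed_%d", keypoint_id)
  feature_frame(track, co$frames, sp, name, op = "speed", ids = keypoint_id)
}

#' Distance between two keypoints
#'
#' @inheritParams position_series
#' @param id_a,id_b Keypoint ids.
#' @return A one-column `feature_series` in px.
#' @export
distance_series <- function(track, id_a, id_b, name = NULL) {
  co <- kp_coords(track, unique(c(id_a, id_b)))
  d <- sqrt((co[[paste0("x", id_a)]] - co[[paste0("x", id_b)]])^2 +
            (co[[paste0("y", id_a)]] - co[[paste0("y", id_b)]])^2)
  name <- name %||% sprintf("dist_%d_%d", id_a, id_b)
  feature_frame(track, co$frames, d, name, op = "distance", ids = c(id_a, id_b))
}

#' Dot product of two keypoint vectors
#'
#' Per frame, the scalar product of the vectors from `id_origin` to `id_a`
#' and from `id_origin` to `id_b`, in px^2. Degenerate geometry (coincident
#' points) gives 0 rather than an error: transient keypoint overlap is common
#' in real tracks.
#'
#' @inheritParams position_series
#' @param id_origin,id_a,id_b Keypoint ids forming the two vectors.
#' @return A one-column `feature_series` in px^2.
#' @export
dot_product_series <- function(track, id_origin, id_a, id_b, name = NULL) {
  co <- kp_coords(track, unique(c(id_origin, id_a, id_b)))
  ux <- co[[paste0("x", id_a)]] - co[[paste0("x", id_origin)]]
  uy <- co[[paste0("y", id_a)]] - co[[paste0("y", id_origin)]]
  vx <- co[[paste0("x", id_b)]] - co[[paste0("x", id_origin)]]
  vy <- co[[paste0("y", id_b)]] - co[[paste0("y", id_origin)]]
  name <- name %||% sprintf("dot_%d_%d_%d", id_origin, id_a, id_b)
  feature_frame(track, co$frames, ux * vx + uy * vy, name,
                op = "dot_product", ids = c(id_origin, id_a, id_b))
}

#' Cross product of two keypoint vectors
#'
#' Per frame, the 2-D scalar cross product `u_x v_y - u_y v_x` of the vectors
#' `u` from `id_origin` to `id_a` and `v` from `id_origin` to `id_b`,
#' evaluated on raw image coordinates, in px^2. Because image coordinates are
#' y-down (origin top-left), the sign follows a left-handed convention: the
#' value is positive when `v` lies clockwise of `u` on screen. The sign
#' therefore encodes the relative orientation of three keypoints, which is
#' what makes it a useful posture feature. Values are reported raw (not
#' normalized by vector lengths); normalization belongs to the mix/norm
#' stage.
#'
#' @inheritParams dot_product_series
#' @return A one-column `feature_series` in px^2.
#' @export
cross_product_series <- function(track, id_origin, id_a, id_b, name = NULL) {
  co <- kp_coords(track, unique(c(id_origin, id_a, id_b)))
  ux <- co[[paste0("x", id_a)]] - co[[paste0("x", id_origin)]]
  uy <- co[[paste0("y", id_a)]] - co[[paste0("y", id_origin)]]
  vx <- co[[paste0("x", id_b)]] - co[[paste0("x", id_origin)]]
  vy <- co[[paste0("y", id_b)]] - co[[paste0("y", id_origin)]]
  name <- name %||% sprintf("cross_%d_%d_%d", id_origin, id_a, id_b)
  feature_frame(track, co$frames, ux * vy - uy * vx, name,
                op = "cross_product", ids = c(id_origin, id_a, id_b))
}

# ---------------------------------------------------------------------------
# feature-file container

#' Write and read feature files
#'
#' Feature series are stored in the same columnar binary container as tracks
#' (Feather v2, metadata included), conventionally under
#' `<video_dir>/calc/<subfolder>/`; [write_features_csv()] writes the
#' plain-text mirror (`frame,time_ms,<feature columns>`).
#'
#' @param series A `feature_series`.
#' @param path Destination file.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns the `feature_series`.
#' @export
write_features <- function(series, path) {
  if (!is_feature_series(series)) {
    stop_fbbc("`series` must be a feature_series.", "fbbc_argument_error")
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  arrow::write_feather(series, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) {
    stop_fbbc(sprintf("Feature file not found: '%s'.", path), "fbbc_io_error")
  }
  out <- tryCatch(
    arrow::read_feather(path),
    error = function(e) {
      stop_fbbc(sprintf("'%s' is not a readable feature container: %s",
                        path, conditionMessage(e)),
                "fbbc_format_error")
    }
  )
  if (!is_feature_series(out)) {
    stop_fbbc(sprintf("'%s' does not contain a feature_series.", path),
              "fbbc_format_error")
  }
  out
}

#' @rdname write_features
#' @export
write_features_csv <- function(series, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(series), path)
  invisible(path)
}
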