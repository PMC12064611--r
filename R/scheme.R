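#' Define a keypoint scheme
#'
#' A keypoint scheme names the landmarks a pose-estimation model reports and
#' fixes the integer id of each one, so that feature recipes can refer to
#' keypoints by id. Optionally a skeleton (pairs of ids) can be attached for
#' plotting.
#'
#' @param scheme_name Name of the scheme (e.g. `"halpe26_upper"`).
#' @param ids Integer vector of keypoint ids (unique, non-negative).
#' @param labels Character vector of keypoint labels, same length as `ids`.
#' @param skeleton Optional two-column matrix or data frame of id pairs.
#' @return A `keypoint_scheme` object: a list with `scheme_name`, a
#'   `keypoints` tibble (`id`, `label`) and `skeleton`.
#' @examples
#' keypoint_scheme("toy", ids = c(0, 1), labels = c("head", "tail"))
#' @export
keypoint_scheme <- function(scheme_name, ids, labels, skeleton = NULL) {
  ids <- vapply(ids, check_count, integer(1), name = "ids", min = 0L)
  if (anyDuplicated(ids)) {
    stop_fbbc("Keypoint ids must be unique within a scheme.", "fbbc_scheme_error")
  }
  if (length(labels) != length(ids)) {
    stop_fbbc("`ids` and `labels` must have the same length.", "fbbc_scheme_error")
  }
  if (!is.null(skeleton)) {
    skeleton <- as.matrix(skeleton)
    storage.mode(skeleton) <- "integer"
    if (ncol(skeleton) != 2L || !all(skeleton %in% ids)) {
      stop_fbbc("`skeleton` must be pairs of ids present in the scheme.",
                "fbbc_scheme_error")
    }
  }
  structure(
    list(
      scheme_name = as.character(scheme_name),
      keypoints = tibble(id = as.integer(ids), label = as.character(labels)),
      skeleton = skeleton
    ),
    class = "keypoint_scheme"
  )
}

#' @export
print.keypoint_scheme <- function(x, ...) {
  cat(sprintf("<keypoint_scheme '%s': %d keypoints>\n",
              x$scheme_name, nrow(x$keypoints)))
  print(x$keypoints, n = Inf)
  invisible(x)
}

#' Built-in Halpe26 upper-body subset
#'
#' The six upper-body landmarks of the Halpe26 scheme used throughout the
#' worked examples: left/right shoulder (5, 6), right elbow (8), left/right
#' hand (9, 10) and neck (18). Ids follow the Halpe26 numbering so tracks from
#' an RTMPose-Halpe26 backend can be used directly.
#'
#' @return A [keypoint_scheme()].
#' @examples
#' halpe26_upper()
#' @export
halpe26_upper <- function() {
  keypoint_scheme(
    "halpe26_upper",
    ids = c(5L, 6L, 8L, 9L, 10L, 18L),
    labels = c("left_shoulder", "right_shoulder", "right_elbow",
               "left_hand", "right_hand", "neck"),
    skeleton = rbind(c(18L, 5L), c(18L, 6L), c(6L, 8L), c(8L, 10L), c(5L, 9L))
  )
}

scheme_ids <- function(scheme) {
  if (is.null(scheme)) integer() else scheme$keypoints$id
}
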