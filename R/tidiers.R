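#' Tidy an embedding
#' @param x An `embedding2d`.
#' @param ... Ignored.
#' @return A plain tibble `frame`, `u`, `v`.
#' @export
tidy.embedding2d <- function(x, ...) {
  as_tibble(x)[, c("frame", "u", "v")]
}

#' @rdname tidy.embedding2d
#' @export
glance.embedding2d <- function(x, ...) {
  p <- attr(x, "params")
  tibble(n_points = nrow(x), n_neighbors = p$n_neighbors,
         min_dist = p$min_dist, thin_step = p$thin_step,
         random_seed = p$random_seed)
}

#' Tidy a cluster assignment
#' @param x A `cluster_assignment`.
#' @param ... Ignored.
#' @return Tibble `frame`, `cluster_id`, `code` (NA when unassigned).
#' @export
tidy.cluster_assignment <- function(x, ...) {
  tb <- cluster_table(x)
  tibble(frame = x$frame, cluster_id = x$cluster_id,
         code = tb$name[match(x$cluster_id, tb$cluster_id)])
}

#' Tidy a behavior timeline
#' @param x A `behavior_timeline`.
#' @param ... Ignored.
#' @return The interval view (see [timeline_intervals()]).
#' @export
tidy.behavior_timeline <- function(x, ...) timeline_intervals(x)

#' @rdname tidy.behavior_timeline
#' @export
glance.behavior_timeline <- function(x, ...) {
  active <- x$code != "NONE"
  tibble(
    n_frames = nrow(x),
    n_codes = dplyr::n_distinct(x$code[active]),
    coded_fraction = mean(active),
    duration_s = (max(x$frame) - min(x$frame) + 1L) / fps(x)
  )
}

#' Per-stage row counts of a pipeline run
#' @param x An `fbbc_run`.
#' @param ... Ignored.
#' @return Tibble `stage`, `rows`.
#' @export
tidy.fbbc_run <- function(x, ...) {
  tibble(stage = names(x$counts),
         rows = unlist(x$counts, use.names = FALSE))
}

#' @rdname tidy.fbbc_run
#' @export
glance.fbbc_run <- function(x, ...) {
  tibble(
    track_rows = x$counts$track_rows,
    feature_rows = x$counts$feature_rows,
    feature_columns = x$counts$feature_columns,
    embedded_points = x$counts$embedded_points,
    clusters = x$counts$clusters,
    coded_fraction = mean(x$timeline$code != "NONE"),
    seed = x$config$seed
  )
}
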