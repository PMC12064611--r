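#' Cluster assignments over an embedding
#'
#' An assignment maps each embedded point (identified by its source frame) to
#' a cluster id, or to `NA` for unassigned points, together with a cluster
#' table (`cluster_id`, `name`). Assignments are produced manually with
#' [assign_by_pick()] or programmatically with [auto_cluster()], and turned
#' into a behavior timeline with [build_timeline()].
#'
#' @param embedding An `embedding2d` whose points are being labeled.
#' @param clusters A data frame with `cluster_id` (small integers) and
#'   unique `name`s.
#' @return A `cluster_assignment`: tibble `frame`, `cluster_id` (NA =
#'   unassigned) with the cluster table attached.
#' @export
cluster_assignment <- function(embedding, clusters) {
  clusters <- as_tibble(clusters)
  if (!all(c("cluster_id", "name") %in% names(clusters))) {
    stop_fbbc("`clusters` needs columns cluster_id and name.",
              "fbbc_argument_error")
  }
  if (anyDuplicated(clusters$name) || anyDuplicated(clusters$cluster_id)) {
    stop_fbbc("Cluster ids and names must be unique.", "fbbc_argument_error")
  }
  clusters$cluster_id <- as.integer(clusters$cluster_id)
  clusters$name <- as.character(clusters$name)
  structure(
    tibble(frame = embedding$frame, cluster_id = NA_integer_),
    clusters = clusters,
    class = c("cluster_assignment", class(tibble()))
  )
}

#' Cluster table of an assignment
#' @param assignment A `cluster_assignment`.
#' @return Tibble with `cluster_id`, `name`.
#' @export
cluster_table <- function(assignment) attr(assignment, "clusters")

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment: %d point(s), %d assigned, %d cluster(s)>\n",
              nrow(x), sum(!is.na(x$cluster_id)), nrow(cluster_table(x))))
  NextMethod()
}

#' Label embedding points around a picked location
#'
#' Headless counterpart of clicking on the scatter plot: every embedding
#' point within `picker_range` (Euclidean distance in embedding coordinate
#' units) of the picked location is assigned to `cluster_id`, overwriting
#' any previous label — the semantics of interactive reassignment. Note the
#' radius is measured in embedding data units, not screen pixels, since there
#' is no screen here.
#'
#' @param assignment A `cluster_assignment`.
#' @param embedding The `embedding2d` the assignment was built for.
#' @param pick `c(u, v)` location of the pick.
#' @param picker_range Radius around the pick, in embedding units (> 0).
#' @param cluster_id Cluster to assign; must exist in the cluster table.
#' @return The updated `cluster_assignment`.
#' @export
assign_by_pick <- function(assignment, embedding, pick, picker_range,
                           cluster_id) {
  check_scalar_number(picker_range, "picker_range", min = 0, strict = TRUE)
  cluster_id <- as.integer(cluster_id)
  tb <- cluster_table(assignment)
  if (!cluster_id %in% tb$cluster_id) {
    stop_fbbc(sprintf("Cluster id %d not in cluster table (have: %s).",
                      cluster_id, paste(tb$cluster_id, collapse = ", ")),
              "fbbc_lookup_error")
  }
  if (length(pick) != 2L || anyNA(pick)) {
    stop_fbbc("`pick` must be c(u, v).", "fbbc_argument_error")
  }
  d <- sqrt((embedding$u - pick[1])^2 + (embedding$v - pick[2])^2)
  assignment$cluster_id[d <= picker_range] <- cluster_id
  assignment
}

#' Cluster an embedding programmatically
#'
#' Stand-in for manual scatter-plot clustering, so pipelines run headless and
#' reproducibly. Two modes:
#'
#' * `k` given: k-means on the embedding coordinates (deterministic under
#'   `seed`); every point is labeled.
#' * `k = NULL` (automatic): connectivity-based grouping. Single-linkage
#'   merge heights are scanned for the largest relative gap, the dendrogram
#'   is cut there, and groups smaller than `min_size` points are treated as
#'   sparse noise and left unassigned. Well-separated blobs — the situation
#'   thinning and normalization aim to produce — yield one cluster per blob
#'   with no tuning.
#'
#' Cluster ids are 0-based, ordered by first occurrence along the frame
#' sequence, with default names `c0`, `c1`, ...
#'
#' @param embedding An `embedding2d`.
#' @param k Number of clusters, or `NULL` for automatic.
#' @param min_size Minimum cluster size in automatic mode (default
#'   `max(5, 1%)` of points).
#' @param max_k Largest cluster count considered in automatic mode.
#' @param gap_ratio Minimum ratio between consecutive single-linkage merge
#'   heights for a split to count as a real gap.
#' @param seed Seed for the k-means mode.
#' @return A fully labeled `cluster_assignment` (automatic mode may leave
#'   sparse points unassigned).
#' @export
auto_cluster <- function(embedding, k = NULL, min_size = NULL, max_k = 15L,
                         gap_ratio = 2, seed = 42L) {
  n <- nrow(embedding)
  if (n < 1L) stop_fbbc("Empty embedding.", "fbbc_degenerate_input")
  pts <- cbind(embedding$u, embedding$v)

  if (!is.null(k)) {
    k <- check_count(k, "k", min = 1L)
    if (k > n) {
      stop_fbbc(sprintf("k = %d exceeds the %d embedded point(s).", k, n),
                "fbbc_argument_error")
    }
    raw <- if (k == 1L) {
      rep(1L, n)
    } else {
      with_local_seed(seed, kmeans(pts, centers = k, nstart = 10L,
                                   iter.max = 100L)$cluster)
    }
  } else {
    raw <- gap_cluster(pts, max_k = max_k, gap_ratio = gap_ratio)
    min_size <- min_size %||% max(5L, ceiling(n / 100))
    sizes <- table(raw)
    small <- as.integer(names(sizes)[sizes < min_size])
    raw[raw %in% small] <- NA_integer_
  }

  # renumber 0..K-1 by first occurrence so labels are deterministic
  first_seen <- unique(raw[!is.na(raw)])
  ids <- match(raw, first_seen) - 1L
  kk <- length(first_seen)
  clusters <- tibble(cluster_id = seq_len(kk) - 1L,
                     name = paste0("c", seq_len(kk) - 1L))
  out <- cluster_assignment(embedding, clusters)
  out$cluster_id <- ids
  out
}

# single-linkage gap heuristic: heights h_1 <= ... <= h_{n-1}; cutting into k
# clusters removes the top k-1 merges, so a real k-cluster structure shows as
# a large jump from h_{n-k} to h_{n-k+1}
gap_cluster <- function(pts, max_k, gap_ratio) {
  n <- nrow(pts)
  if (n == 1L) return(1L)
  hc <- hclust(dist(pts), method = "single")
  h <- hc$height
  kmax <- min(max_k, n - 1L)
  eps <- max(h) * 1e-12 + .Machine$double.eps
  ratios <- vapply(2:max(2L, kmax), function(k) {
    h[n - k + 1L] / max(h[n - k], eps)
  }, numeric(1))
  best <- which.max(ratios) + 1L
  k <- if (max(ratios) >= gap_ratio) best else 1L
  cutree(hc, k = k)
}

#' Expand a cluster assignment into a per-frame behavior timeline
#'
#' The behavior-coding output: one code per frame over a full frame range.
#' Because clustering runs on thinned rows, labels must be propagated across
#' the gaps; each coded point labels frames from its own source frame up to
#' (not including) the next retained source frame (hold-forward). Frames
#' before the first retained frame, and frames whose point is unassigned,
#' get the code `"NONE"`.
#'
#' @param assignment A `cluster_assignment` (its `frame` column holds the
#'   retained source frames).
#' @param full_range `c(first, last)` frame range the timeline must cover.
#' @param fps Frame rate, for timestamps.
#' @return A `behavior_timeline`: tibble `frame`, `time_ms`, `code`.
#' @export
build_timeline <- function(assignment, full_range, fps) {
  if (!inherits(assignment, "cluster_assignment") || nrow(assignment) == 0L) {
    stop_fbbc("`assignment` must be a non-empty cluster_assignment.",
              "fbbc_degenerate_input")
  }
  check_scalar_number(fps, "fps", min = 0, strict = TRUE)
  full_range <- as.integer(full_range)
  if (length(full_range) != 2L || full_range[1] > full_range[2]) {
    stop_fbbc("`full_range` must be c(first, last) with first <= last.",
              "fbbc_argument_error")
  }
  src <- assignment$frame
  if (any(src < full_range[1]) || any(src > full_range[2])) {
    stop_fbbc("Assignment frames fall outside `full_range`.",
              "fbbc_argument_error")
  }
  tb <- cluster_table(assignment)
  code_of <- setNames(tb$name, as.character(tb$cluster_id))

  frames <- seq(full_range[1], full_range[2])
  # index of the latest source frame <= each frame (0 = before the first)
  idx <- findInterval(frames, sort(src))
  ord <- order(src)
  codes <- rep("NONE", length(frames))
  has <- idx > 0L
  cid <- assignment$cluster_id[ord][idx[has]]
  codes[has] <- ifelse(is.na(cid), "NONE", code_of[as.character(cid)])

  structure(
    tibble(frame = frames, time_ms = frames / fps * 1000, code = codes),
    fps = as.double(fps),
    clusters = tb,
    class = c("behavior_timeline", class(tibble()))
  )
}

#' @export
print.behavior_timeline <- function(x, ...) {
  cat(sprintf("<behavior_timeline: frames %d-%d, %d code(s)%s>\n",
              min(x$frame), max(x$frame),
              dplyr::n_distinct(x$code[x$code != "NONE"]),
              if (any(x$code == "NONE")) " (+NONE)" else ""))
  NextMethod()
}

#' Run-length interval view of a timeline
#'
#' Collapses consecutive frames with the same code into half-open intervals
#' `[start_ms, end_ms)`. [intervals_to_timeline()] reverses the operation
#' losslessly.
#'
#' @param timeline A `behavior_timeline`.
#' @return Tibble `code`, `start_ms`, `end_ms`.
#' @export
timeline_intervals <- function(timeline) {
  fps_v <- fps(timeline)
  r <- rle(timeline$code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(
    code = r$values,
    start_ms = timeline$frame[starts] / fps_v * 1000,
    end_ms = (timeline$frame[ends] + 1L) / fps_v * 1000
  )
}

#' @rdname timeline_intervals
#' @param intervals Tibble `code`, `start_ms`, `end_ms` (contiguous,
#'   non-overlapping, as produced by [timeline_intervals()]).
#' @param fps Frame rate of the original timeline.
#' @return A `behavior_timeline`.
#' @export
intervals_to_timeline <- function(intervals, fps) {
  check_scalar_number(fps, "fps", min = 0, strict = TRUE)
  first <- as.integer(round(min(intervals$start_ms) * fps / 1000))
  last <- as.integer(round(max(intervals$end_ms) * fps / 1000)) - 1L
  frames <- seq(first, last)
  t_ms <- frames / fps * 1000
  codes <- rep(NA_character_, length(frames))
  for (i in seq_len(nrow(intervals))) {
    hit <- t_ms >= intervals$start_ms[i] - 1e-6 &
      t_ms < intervals$end_ms[i] - 1e-6
    codes[hit] <- intervals$code[i]
  }
  structure(
    tibble(frame = frames, time_ms = t_ms, code = codes),
    fps = as.double(fps),
    class = c("behavior_timeline", class(tibble()))
  )
}

#' Export a timeline to CSV
#'
#' Writes the per-frame view (`frame,time_ms,code`) and, optionally, the
#' run-length interval view (`code,start_ms,end_ms`).
#'
#' @param timeline A `behavior_timeline`.
#' @param path Per-frame CSV destination.
#' @param intervals_path Optional interval CSV destination.
#' @return `path`, invisibly.
#' @export
export_timeline <- function(timeline, path, intervals_path = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(timeline)[, c("frame", "time_ms", "code")], path)
  if (!is.null(intervals_path)) {
    readr::write_csv(timeline_intervals(timeline), intervals_path)
  }
  invisible(path)
}

#' Read a per-frame timeline CSV
#' @param path CSV written by [export_timeline()].
#' @param fps Frame rate to attach.
#' @return A `behavior_timeline`.
#' @export
read_timeline <- function(path, fps) {
  df <- readr::read_csv(path, col_types = "idc")
  structure(as_tibble(df), fps = as.double(fps),
            class = c("behavior_timeline", class(tibble())))
}
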