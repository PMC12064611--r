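#' Thin a feature series
#'
#' Retains every `step`-th row (positions 0, step, 2*step, ... of the row
#' sequence). Thinning before embedding suppresses transitional frames —
#' intermediate postures between one posture and the next — which tends to
#' produce better-separated scatter plots. At 29.97 fps a step of 5 retains
#' one row per ~0.17 s.
#'
#' @param series A `feature_series`.
#' @param step Positive integer step (1 = keep everything).
#' @return The thinned `feature_series`; `step` is recorded in provenance.
#' @export
thin_features <- function(series, step) {
  step <- check_count(step, "step", min = 1L)
  keep <- seq(1L, nrow(series), by = step)
  out <- restore_attrs(series[keep, , drop = FALSE], series)
  prov <- provenance(out)
  prov$thin_step <- step
  attr(out, "provenance") <- prov
  out
}

#' Time between retained rows after thinning
#'
#' @param step Thinning step.
#' @param fps Frame rate (frames/second).
#' @return Seconds between consecutive retained rows (`step / fps`).
#' @examples
#' thin_interval_s(5, 29.97) # ~0.17 s
#' @export
thin_interval_s <- function(step, fps) {
  step <- check_count(step, "step", min = 1L)
  check_scalar_number(fps, "fps", min = 0, strict = TRUE)
  step / fps
}

#' Embedding parameters
#'
#' The two UMAP parameters that matter most are `n_neighbors` (size of the
#' local neighborhood; larger values favour global structure) and `min_dist`
#' (how tightly points pack in the embedding). In practice, well-separated
#' scatter plots are usually obtained with `n_neighbors` of 20 or 50 and
#' `min_dist` of 0.1; exploring a few values is recommended, so neither is
#' switched silently.
#'
#' @param n_neighbors Neighborhood size (>= 2).
#' @param min_dist Minimum embedding distance, in `[0, 1)`.
#' @param thin_step Thinning step recorded for provenance (thinning itself is
#'   [thin_features()]).
#' @param random_seed Seed for the embedding; fixed by default so published
#'   runs are reproducible.
#' @param feature_columns Columns to embed (default: all feature columns).
#' @return An `embed_params` list.
#' @export
embed_params <- function(n_neighbors = 20L, min_dist = 0.1, thin_step = 1L,
                         random_seed = 42L, feature_columns = NULL) {
  n_neighbors <- check_count(n_neighbors, "n_neighbors", min = 2L)
  check_scalar_number(min_dist, "min_dist", min = 0)
  if (min_dist >= 1) {
    stop_fbbc("`min_dist` must be in [0, 1).", "fbbc_argument_error")
  }
  thin_step <- check_count(thin_step, "thin_step", min = 1L)
  random_seed <- check_count(random_seed, "random_seed", min = -.Machine$integer.max)
  structure(
    list(n_neighbors = n_neighbors, min_dist = min_dist, thin_step = thin_step,
         random_seed = random_seed, feature_columns = feature_columns),
    class = "embed_params"
  )
}

#' Embed feature rows in two dimensions with UMAP
#'
#' Projects the (typically thinned and normalized) feature rows into a 2-D
#' embedding with uniform manifold approximation and projection. UMAP
#' preserves local neighborhood structure, so frames with similar posture
#' features land close together; clusters in the scatter plot are candidate
#' behavior codes. The embedding is always 2-D. Rows with any missing value
#' in the selected columns are dropped (with an informational count) before
#' embedding — distance computations need complete vectors — and are excluded
#' from `source_frames`. With a fixed seed the embedding is exactly
#' reproducible.
#'
#' @param series A `feature_series`.
#' @param params An [embed_params()].
#' @return An `embedding2d`: a tibble `frame`, `u`, `v` with the parameters
#'   and provenance attached.
#' @export
embed_features <- function(series, params = embed_params()) {
  if (!inherits(params, "embed_params")) {
    stop_fbbc("`params` must come from embed_params().", "fbbc_argument_error")
  }
  cols <- params$feature_columns %||% feature_columns(series)
  missing_cols <- setdiff(cols, names(series))
  if (length(missing_cols)) {
    stop_fbbc(paste0("Unknown feature column(s): ",
                     paste(missing_cols, collapse = ", "), "."),
              "fbbc_lookup_error")
  }
  if (!length(cols)) {
    stop_fbbc("No feature columns to embed.", "fbbc_degenerate_input")
  }
  mat <- as.matrix(as_tibble(series)[, cols, drop = FALSE])
  if (!is.numeric(mat)) {
    stop_fbbc("Selected feature columns must be numeric.", "fbbc_type_error")
  }
  complete <- stats::complete.cases(mat)
  if (any(!complete)) {
    inform(sprintf("embed_features: dropped %d row(s) with missing values.",
                   sum(!complete)))
  }
  mat <- mat[complete, , drop = FALSE]
  frames <- series$frame[complete]
  if (nrow(mat) < params$n_neighbors + 1L) {
    stop_fbbc(sprintf(
      "UMAP with n_neighbors = %d needs at least %d complete rows; got %d.",
      params$n_neighbors, params$n_neighbors + 1L, nrow(mat)),
      "fbbc_degenerate_input")
  }

  coords <- with_local_seed(params$random_seed, {
    uwot::umap(mat,
               n_neighbors = params$n_neighbors,
               min_dist = params$min_dist,
               n_components = 2L,
               n_threads = 1L, n_sgd_threads = 0L,
               verbose = FALSE)
  })
  out <- tibble(frame = frames, u = coords[, 1], v = coords[, 2])
  structure(out,
            fps = attr(series, "fps"),
            params = params,
            provenance = c(provenance(series) %||% list(),
                           list(embedded_columns = cols,
                                dropped_incomplete = sum(!complete))),
            class = c("embedding2d", class(tibble())))
}

# run code under a given seed without clobbering the caller's RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_embedding2d <- function(x) inherits(x, "embedding2d")

#' @export
print.embedding2d <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<embedding2d: %d point(s), n_neighbors %d, min_dist %g, seed %d>\n",
              nrow(x), p$n_neighbors, p$min_dist, p$random_seed))
  NextMethod()
}

#' Write or read an embedding
#'
#' CSV with columns `frame,u,v`, plus a JSON sidecar
#' (`<path>.provenance.json`) holding the parameters, seed, embedded columns
#' and thinning step so a published embedding can be reproduced.
#'
#' @param embedding An `embedding2d`.
#' @param path CSV destination.
#' @return `write_embedding()` returns `path` invisibly; `read_embedding()`
#'   returns the `embedding2d`.
#' @export
write_embedding <- function(embedding, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(embedding)[, c("frame", "u", "v")], path)
  side <- list(
    params = unclass(attr(embedding, "params")),
    provenance = provenance(embedding),
    fps = attr(embedding, "fps")
  )
  jsonlite::write_json(side, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  df <- readr::read_csv(path, col_types = "idd")
  side_path <- paste0(path, ".provenance.json")
  params <- embed_params()
  fps <- NULL
  prov <- list()
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    pp <- side$params
    params <- embed_params(pp$n_neighbors, pp$min_dist, pp$thin_step,
                           pp$random_seed,
                           feature_columns = pp$feature_columns)
    fps <- side$fps
    prov <- side$provenance
  }
  structure(as_tibble(df), fps = fps, params = params, provenance = prov,
            class = c("embedding2d", class(tibble())))
}
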