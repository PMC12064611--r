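# fixtures are built in code: random-walk tracks, fixed-geometry tracks and
# tiny feature series used across test files

toy_scheme <- function(ids = 0:2) {
  keypoint_scheme("toy", ids = ids, labels = paste0("kp", ids))
}

# random-walk track: one person, `ids` keypoints, optional missingness
random_track <- function(n_frames = 20, ids = 0:2, fps = 10, seed = 1,
                         persons = 0L, na_frac = 0) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    grid <- expand.grid(frame = seq_len(n_frames) - 1L, person = persons,
                        keypoint = ids)
    n <- nrow(grid)
    x <- cumsum(rnorm(n)) + 100
    y <- cumsum(rnorm(n)) + 100
    conf <- runif(n)
    if (na_frac > 0) {
      drop <- sample.int(n, ceiling(na_frac * n))
      x[drop] <- NA_real_
      y[drop] <- NA_real_
    }
    track_series(
      data.frame(grid, x = x, y = y, confidence = conf),
      fps = fps, scheme = NULL, video_name = "fixture"
    )
  })
}

# track with every keypoint fixed at a given position across n frames;
# positions = named list id -> c(x, y)
fixed_track <- function(positions, n_frames = 10, fps = 10) {
  rows <- lapply(names(positions), function(id) {
    data.frame(frame = seq_len(n_frames) - 1L, person = 0L,
               keypoint = as.integer(id),
               x = positions[[id]][1], y = positions[[id]][2],
               confidence = 1)
  })
  track_series(do.call(rbind, rows), fps = fps)
}

# track whose 3 keypoints (0 = origin, 1 = a, 2 = b) take arbitrary per-frame
# coordinates given as n x 6 matrix (xo, yo, xa, ya, xb, yb)
triple_track <- function(coords, fps = 10) {
  n <- nrow(coords)
  track_series(
    data.frame(
      frame = rep(seq_len(n) - 1L, 3),
      person = 0L,
      keypoint = rep(0:2, each = n),
      x = c(coords[, 1], coords[, 3], coords[, 5]),
      y = c(coords[, 2], coords[, 4], coords[, 6]),
      confidence = 1
    ),
    fps = fps
  )
}

tiny_features <- function(values, fps = 10, name = "f") {
  n <- length(values)
  dat <- tibble::tibble(frame = seq_len(n) - 1L,
                        time_ms = (seq_len(n) - 1L) / fps * 1000)
  dat[[name]] <- values
  feature_series(dat, fps = fps)
}

expect_track_equal <- function(a, b) {
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "fps"), attr(b, "fps"))
  expect_identical(attr(a, "video_name"), attr(b, "video_name"))
  expect_equal(attr(a, "scheme"), attr(b, "scheme"))
}

# small embedding stand-in for coding tests (no UMAP involved)
fake_embedding <- function(u, v, frames = seq_along(u) - 1L) {
  structure(tibble::tibble(frame = as.integer(frames), u = u, v = v),
            fps = 10, params = embed_params(),
            class = c("embedding2d", class(tibble::tibble())))
}

run_python <- function(code) {
  res <- suppressWarnings(system2("python", stdout = TRUE, stderr = TRUE,
                                  input = code))
  status <- attr(res, "status") %||% 0L
  if (status != 0) stop("python helper failed:\n", paste(res, collapse = "\n"))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# columns only, no classes or provenance attributes
plain_df <- function(x) as.data.frame(as.list(tibble::as_tibble(x)))
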