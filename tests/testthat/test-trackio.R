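test_that("track constructor enforces the key and value invariants", {
  tr <- random_track(n_frames = 5, ids = 0:1)
  expect_s3_class(tr, "track_series")
  expect_identical(nrow(tr), 10L)

  base <- data.frame(frame = c(0L, 0L), person = 0L, keypoint = c(1L, 1L),
                     x = 1, y = 2)
  expect_error(track_series(base, fps = 10), class = "fbbc_track_error")
  expect_error(track_series(base[1, ], fps = 0), class = "fbbc_argument_error")
  bad <- data.frame(frame = 0L, person = 0L, keypoint = 0L, x = Inf, y = 0)
  expect_error(track_series(bad, fps = 10), class = "fbbc_track_error")
})

test_that("validate_track reports violations without throwing", {
  ok <- random_track(n_frames = 5, ids = c(5L, 6L))
  expect_identical(nrow(validate_track(ok, halpe26_upper())), 0L)

  alien <- random_track(n_frames = 3, ids = c(5L, 99L))
  rep <- validate_track(alien, halpe26_upper())
  expect_identical(rep$check, "scheme")
  expect_match(rep$message, "99")

  dup <- new_track_series(
    data.frame(frame = c(0L, 0L), person = 0L, keypoint = 0L,
               x = c(1, 2), y = c(1, 2), confidence = NA_real_),
    fps = 10)
  expect_identical(validate_track(dup)$check, "duplicate_key")

  neg_fps <- new_track_series(
    data.frame(frame = 0L, person = 0L, keypoint = 0L, x = 1, y = 1,
               confidence = NA_real_), fps = -1)
  expect_true("fps" %in% validate_track(neg_fps)$check)
})

test_that("select_person subsets one person and partitions the track", {
  one <- random_track(n_frames = 4, ids = 0:1)
  expect_track_equal(select_person(one, 0), one)

  two <- random_track(n_frames = 6, ids = 0:1, persons = 0:1)
  p0 <- select_person(two, 0)
  expect_identical(nrow(p0), nrow(two) %/% 2L)
  expect_error(select_person(two, 7), class = "fbbc_lookup_error")
  expect_match(tryCatch(select_person(two, 7), error = conditionMessage), "0, 1")

  parts <- lapply(sort(unique(two$person)), function(p) {
    as.data.frame(select_person(two, p))
  })
  expect_identical(
    dplyr::arrange(do.call(rbind, parts), frame, person, keypoint),
    as.data.frame(two))
})

test_that("native container round-trips randomized tracks exactly", {
  for (i in 1:100) {
    tr <- random_track(n_frames = sample(1:15, 1), ids = sort(sample(0:25, 3)),
                       seed = i, na_frac = if (i %% 3 == 0) 0.2 else 0)
    path <- withr::local_tempfile(fileext = ".track")
    write_track(tr, path)
    expect_track_equal(read_track(path), tr)
  }
})

test_that("container round trip preserves metadata, missingness and emptiness", {
  tr <- random_track(n_frames = 8, ids = c(5L, 6L), na_frac = 0.3)
  attr(tr, "scheme") <- halpe26_upper()
  attr(tr, "frame_size") <- c(640L, 480L)
  path <- withr::local_tempfile(fileext = ".track")
  write_track(tr, path)
  back <- read_track(path)
  expect_track_equal(back, tr)
  expect_identical(attr(back, "frame_size"), c(640L, 480L))
  expect_identical(is.na(back$x), is.na(tr$x))
  expect_false(any(back$x[is.na(tr$x)] %in% 0))

  empty <- new_track_series(
    data.frame(frame = integer(), person = integer(), keypoint = integer(),
               x = double(), y = double(), confidence = double()),
    fps = 25, video_name = "empty")
  write_track(empty, path)
  back <- read_track(path)
  expect_identical(nrow(back), 0L)
  expect_identical(attr(back, "fps"), 25)
  expect_identical(attr(back, "video_name"), "empty")
})

test_that("unreadable or foreign files raise format errors naming the path", {
  expect_error(read_track("/nonexistent/t.track"), class = "fbbc_io_error")
  junk <- withr::local_tempfile(fileext = ".track")
  writeLines("not a container", junk)
  err <- tryCatch(read_track(junk), error = identity)
  expect_s3_class(err, "fbbc_format_error")
  expect_match(conditionMessage(err), basename(junk), fixed = TRUE)
})

test_that("CSV mirror stores frame, timestamp and coordinates faithfully", {
  tr <- random_track(n_frames = 10, ids = 0:1, fps = 29.97)
  path <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(tr, path)
  df <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(df, c("frame", "time_ms", "person", "keypoint", "x", "y", "conf"))
  expect_equal(df$time_ms, df$frame / 29.97 * 1000)
  back <- read_track_csv(path, fps = 29.97)
  expect_equal(back$x, tr$x, tolerance = 1e-12)
})

test_that("the folder layout puts tracks under trk/ and features under calc/", {
  expect_identical(track_path("study/task1.mp4"),
                   file.path("study", "trk", "task1.track"))
  expect_identical(calc_dir("study/task1.mp4", "arm"),
                   file.path("study", "calc", "arm"))
})
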