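# The DeepLabCut dialect: three-level scorer/bodyparts/coords hierarchy in
# pandas-flavoured HDF5. pandas itself (via the preinstalled python) acts as
# the independent fixture writer / reader.

write_pandas_dlc <- function(path, format = "fixed", levels = 3L,
                             likelihood = TRUE) {
  coords <- if (likelihood) '["x","y","likelihood"]' else '["x","y"]'
  cols <- if (levels == 3L) {
    sprintf('pd.MultiIndex.from_product([["scorer1"],["nose","ear"],%s],
             names=["scorer","bodyparts","coords"])', coords)
  } else {
    sprintf('pd.MultiIndex.from_product([["nose","ear"],%s],
             names=["bodyparts","coords"])', coords)
  }
  n_col <- if (likelihood) 6L else 4L
  run_python(sprintf('
import pandas as pd, numpy as np
cols = %s
vals = np.arange(%d, dtype=float).reshape(3, %d) / 20.0
df = pd.DataFrame(vals, columns=cols)
df.to_hdf(%s, key="df_with_missing", mode="w", format="%s")
', cols, 3L * n_col, n_col, deparse(path), format))
  matrix(seq_len(3L * n_col) - 1L, nrow = 3L, byrow = TRUE) / 20.0
}

test_that("pandas-written fixtures are read back value-exact, both layouts", {
  for (fmt in c("fixed", "table")) {
    path <- withr::local_tempfile(fileext = ".h5")
    vals <- write_pandas_dlc(path, format = fmt)
    tr <- read_dlc_keypoints(path, fps = 10)
    expect_identical(sort(unique(tr$keypoint)), c(0L, 1L))  # nose, ear in order
    # column layout: nose x,y,likelihood then ear x,y,likelihood
    nose <- tr[tr$keypoint == 0L, ]
    ear <- tr[tr$keypoint == 1L, ]
    expect_identical(nose$x, vals[, 1])
    expect_identical(nose$y, vals[, 2])
    expect_identical(nose$confidence, vals[, 3])
    expect_identical(ear$x, vals[, 4])
    expect_identical(ear$confidence, vals[, 6])
  }
})

test_that("missing likelihood columns yield missing confidence, not zeros", {
  path <- withr::local_tempfile(fileext = ".h5")
  write_pandas_dlc(path, likelihood = FALSE)
  tr <- read_dlc_keypoints(path, fps = 10)
  expect_true(all(is.na(tr$confidence)))
  expect_false(anyNA(tr$x))
})

test_that("a two-level hierarchy is rejected as a dialect error", {
  path <- withr::local_tempfile(fileext = ".h5")
  write_pandas_dlc(path, levels = 2L)
  expect_error(read_dlc_keypoints(path, fps = 10), class = "fbbc_dialect_error")
})

test_that("fps and file preconditions are enforced", {
  path <- withr::local_tempfile(fileext = ".h5")
  write_pandas_dlc(path)
  expect_error(read_dlc_keypoints(path, fps = 0), class = "fbbc_argument_error")
  expect_error(read_dlc_keypoints("/no/such/file.h5", fps = 10),
               class = "fbbc_io_error")
  junk <- withr::local_tempfile(fileext = ".h5")
  writeLines("junk", junk)
  expect_error(read_dlc_keypoints(junk, fps = 10), class = "fbbc_format_error")
})

test_that("writer and reader are mutual inverses, with missingness intact", {
  sim <- simulate_track(desk_task_spec(duration_s = 0.5, seed = 3))
  tr <- sim$track
  tr$x[c(3, 17)] <- NA_real_
  tr$y[c(3, 17)] <- NA_real_
  path <- withr::local_tempfile(fileext = ".h5")
  write_dlc_keypoints(tr, path)
  map <- setNames(attr(tr, "scheme")$keypoints$id, attr(tr, "scheme")$keypoints$label)
  back <- read_dlc_keypoints(path, fps = 29.97, name_map = map)
  expect_identical(back$x, tr$x)
  expect_identical(back$y, tr$y)
  expect_identical(back$confidence, tr$confidence)
  expect_identical(back$keypoint, tr$keypoint)
})

test_that("files written from R are readable by pandas with the same values", {
  pos <- list(`0` = c(10.5, 20.25), `1` = c(-3.5, 7.75))
  tr <- fixed_track(pos, n_frames = 4)
  path <- withr::local_tempfile(fileext = ".h5")
  write_dlc_keypoints(tr, path, scorer = "testsuite")
  out <- run_python(sprintf('
import warnings; warnings.filterwarnings("ignore")
import pandas as pd
df = pd.read_hdf(%s)
assert df.columns.nlevels == 3
assert list(df.columns.names) == ["scorer", "bodyparts", "coords"]
print(df.shape[0], df.shape[1])
print(float(df[("testsuite", "kp_0", "x")].iloc[0]))
print(float(df[("testsuite", "kp_1", "y")].iloc[3]))
', deparse(path)))
  out <- out[out != ""]
  expect_identical(out[1], "4 6")
  expect_identical(as.numeric(out[2]), 10.5)
  expect_identical(as.numeric(out[3]), 7.75)
})

test_that("bodypart ids default to order of appearance and honor a name map", {
  path <- withr::local_tempfile(fileext = ".h5")
  write_pandas_dlc(path)
  tr <- read_dlc_keypoints(path, fps = 10)
  expect_identical(attr(tr, "bodypart_map"), c(nose = 0L, ear = 1L))
  tr2 <- read_dlc_keypoints(path, fps = 10,
                            name_map = c(nose = 30L, ear = 31L))
  expect_identical(sort(unique(tr2$keypoint)), c(30L, 31L))
  expect_error(
    read_dlc_keypoints(path, fps = 10, name_map = c(nose = 0L)),
    class = "fbbc_argument_error")
})
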