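test_that("position series extract raw coordinates, missing included", {
  tr <- fixed_track(list(`0` = c(3, 4)), n_frames = 10)
  expect_equal(position_series(tr, 0, "x")$x_0, rep(3, 10))
  expect_equal(position_series(tr, 0, "y")$y_0, rep(4, 10))

  rw <- random_track(n_frames = 30, ids = 0:1, na_frac = 0.2, seed = 4)
  ps <- position_series(rw, 1, "x")
  direct <- rw$x[rw$keypoint == 1L][match(ps$frame, rw$frame[rw$keypoint == 1L])]
  expect_identical(ps$x_1, direct)
  expect_error(position_series(rw, 9), class = "fbbc_lookup_error")
})

test_that("speed is the backward-difference displacement rate", {
  still <- fixed_track(list(`0` = c(5, 5)), n_frames = 6)
  sp <- speed_series(still, 0)
  expect_true(is.na(sp$speed_0[1]))
  expect_equal(sp$speed_0[-1], rep(0, 5))

  # +2 px in x per frame at 10 fps -> 20 px/s
  mv <- track_series(
    data.frame(frame = 0:9, person = 0L, keypoint = 0L,
               x = 2 * (0:9), y = 1),
    fps = 10)
  expect_equal(speed_series(mv, 0)$speed_0[-1], rep(20, 9))

  rw <- random_track(n_frames = 50, ids = 0L, fps = 29.97, seed = 9)
  sp <- speed_series(rw, 0)$speed_0
  x <- rw$x; y <- rw$y
  oracle <- c(NA, vapply(2:50, function(i) {
    sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2) * 29.97
  }, numeric(1)))
  expect_equal(sp, oracle, tolerance = 1e-12)

  single <- track_series(
    data.frame(frame = 0L, person = 0L, keypoint = 0L, x = 1, y = 1),
    fps = 10)
  expect_error(speed_series(single, 0), class = "fbbc_degenerate_input")
})

test_that("speed of a time-reversed walk mirrors the forward walk", {
  rw <- random_track(n_frames = 40, ids = 0L, seed = 11)
  fwd <- speed_series(rw, 0)$speed_0
  rev_tr <- track_series(
    data.frame(frame = max(rw$frame) - rw$frame, person = 0L, keypoint = 0L,
               x = rw$x, y = rw$y),
    fps = 10)
  bwd <- speed_series(rev_tr, 0)$speed_0
  # step between frames i-1 and i appears reversed as step n-i+1
  expect_equal(bwd[-1], rev(fwd[-1]), tolerance = 1e-12)
})

test_that("distance matches the direct Euclidean formula", {
  tr <- fixed_track(list(`0` = c(0, 0), `1` = c(3, 4)), n_frames = 5)
  expect_equal(distance_series(tr, 0, 1)$dist_0_1, rep(5, 5))
  expect_equal(distance_series(tr, 0, 0)$dist_0_0, rep(0, 5))

  set.seed(21)
  coords <- matrix(rnorm(100 * 6, sd = 50), ncol = 6)
  tt <- triple_track(coords)
  d <- distance_series(tt, 0, 2)$dist_0_2
  oracle <- sqrt((coords[, 1] - coords[, 5])^2 + (coords[, 2] - coords[, 6])^2)
  expect_equal(d, oracle, tolerance = 1e-12)
})

test_that("dot product matches the expansion u_x v_x + u_y v_y", {
  tr <- fixed_track(list(`0` = c(0, 0), `1` = c(1, 0), `2` = c(0, 1)),
                    n_frames = 3)
  expect_equal(dot_product_series(tr, 0, 1, 2)$dot_0_1_2, rep(0, 3))
  tr2 <- fixed_track(list(`0` = c(0, 0), `1` = c(2, 0), `2` = c(3, 0)),
                     n_frames = 3)
  expect_equal(dot_product_series(tr2, 0, 1, 2)$dot_0_1_2, rep(6, 3))

  set.seed(22)
  coords <- matrix(rnorm(200 * 6, sd = 30), ncol = 6)
  tt <- triple_track(coords)
  dp <- dot_product_series(tt, 0, 1, 2)$dot_0_1_2
  ux <- coords[, 3] - coords[, 1]; uy <- coords[, 4] - coords[, 2]
  vx <- coords[, 5] - coords[, 1]; vy <- coords[, 6] - coords[, 2]
  expect_equal(dp, ux * vx + uy * vy, tolerance = 1e-12)
})

test_that("cross product equals the shoelace determinant on 1000 random triples", {
  tr <- fixed_track(list(`0` = c(0, 0), `1` = c(1, 1), `2` = c(2, 2)),
                    n_frames = 3)
  expect_equal(cross_product_series(tr, 0, 1, 2)$cross_0_1_2, rep(0, 3))
  unit <- fixed_track(list(`0` = c(0, 0), `1` = c(1, 0), `2` = c(0, 1)),
                      n_frames = 2)
  expect_equal(cross_product_series(unit, 0, 1, 2)$cross_0_1_2, rep(1, 2))

  set.seed(23)
  coords <- matrix(rnorm(1000 * 6, sd = 100), ncol = 6)
  tt <- triple_track(coords)
  cp <- cross_product_series(tt, 0, 1, 2)$cross_0_1_2
  # independent oracle: twice the signed triangle area, shoelace arrangement
  shoelace <- coords[, 1] * (coords[, 4] - coords[, 6]) +
    coords[, 3] * (coords[, 6] - coords[, 2]) +
    coords[, 5] * (coords[, 2] - coords[, 4])
  expect_equal(cp, shoelace, tolerance = 1e-9)
})

test_that("cross/dot/distance obey antisymmetry, translation invariance and Lagrange", {
  set.seed(24)
  coords <- matrix(rnorm(300 * 6, sd = 80), ncol = 6)
  tt <- triple_track(coords)
  cp_ab <- cross_product_series(tt, 0, 1, 2)$cross_0_1_2
  cp_ba <- cross_product_series(tt, 0, 2, 1)$cross_0_2_1
  expect_equal(cp_ab, -cp_ba, tolerance = 1e-12)

  shifted <- triple_track(coords + matrix(rep(c(37, -12), 3 * 300),
                                          ncol = 6, byrow = TRUE))
  expect_equal(cross_product_series(shifted, 0, 1, 2)$cross_0_1_2, cp_ab,
               tolerance = 1e-9)
  expect_equal(dot_product_series(shifted, 0, 1, 2)$dot_0_1_2,
               dot_product_series(tt, 0, 1, 2)$dot_0_1_2, tolerance = 1e-9)
  expect_equal(distance_series(shifted, 0, 2)$dist_0_2,
               distance_series(tt, 0, 2)$dist_0_2, tolerance = 1e-9)

  dp <- dot_product_series(tt, 0, 1, 2)$dot_0_1_2
  u2 <- (coords[, 3] - coords[, 1])^2 + (coords[, 4] - coords[, 2])^2
  v2 <- (coords[, 5] - coords[, 1])^2 + (coords[, 6] - coords[, 2])^2
  expect_equal(cp_ab^2 + dp^2, u2 * v2, tolerance = 1e-9)
})

test_that("features touching a missing coordinate are missing, never imputed", {
  coords <- matrix(rnorm(20 * 6), ncol = 6)
  tt <- triple_track(coords)
  tt$x[tt$frame == 5 & tt$keypoint == 1] <- NA_real_
  expect_true(is.na(cross_product_series(tt, 0, 1, 2)$cross_0_1_2[6]))
  expect_true(is.na(dot_product_series(tt, 0, 1, 2)$dot_0_1_2[6]))
  expect_true(is.na(position_series(tt, 1, "x")$x_1[6]))
  sp <- speed_series(tt, 1)$speed_1
  expect_true(all(is.na(sp[c(6, 7)])))  # steps into and out of the gap
  expect_false(anyNA(sp[c(2:5, 8:20)]))
})

test_that("recipes validate arity and evaluate column-by-column", {
  expect_error(feature_spec("cross_product", c(1, 2), "bad"),
               class = "fbbc_recipe_error")
  expect_error(feature_spec("speed", c(1, 2), "bad"), class = "fbbc_recipe_error")
  expect_error(
    feature_recipe(feature_spec("speed", 1, "s"), feature_spec("speed", 2, "s")),
    class = "fbbc_recipe_error")

  sim <- simulate_track(desk_task_spec(duration_s = 0.5, seed = 5))
  four <- apply_recipe(sim$track, "right_arm_cross4")
  expect_identical(feature_columns(four),
                   c("shoulder_left", "hand", "shoulder_right", "elbow"))

  empty <- apply_recipe(sim$track, feature_recipe())
  expect_identical(feature_columns(empty), character())
  expect_identical(nrow(empty), dplyr::n_distinct(sim$track$frame))

  five <- apply_recipe(sim$track, "desk_task")
  expect_identical(length(feature_columns(five)), 5L)
  expect_identical(five$neck_x,
                   position_series(sim$track, 18, "x")$x_18)
  expect_identical(five$shoulder_left,
                   cross_product_series(sim$track, 5, 10, 6)$cross_5_10_6)

  bad <- feature_recipe(feature_spec("position_x", 77, "ghost"))
  err <- tryCatch(apply_recipe(sim$track, bad), error = identity)
  expect_s3_class(err, "fbbc_recipe_error")
  expect_match(conditionMessage(err), "ghost")
})

test_that("feature files round-trip through the container", {
  sim <- simulate_track(desk_task_spec(duration_s = 0.5, seed = 6))
  fs <- apply_recipe(sim$track, "desk_task")
  path <- withr::local_tempfile(fileext = ".feather")
  write_features(fs, path)
  back <- read_features(path)
  expect_identical(as.data.frame(back), as.data.frame(fs))
  expect_identical(attr(back, "fps"), attr(fs, "fps"))
  expect_equal(provenance(back), provenance(fs))
})
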