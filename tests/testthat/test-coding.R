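two_cluster_table <- function() {
  tibble::tibble(cluster_id = 0:1, name = c("alpha", "beta"))
}

test_that("picker assignment labels exactly the points within the radius", {
  emb <- fake_embedding(u = c(0, 0.1, 5, 5.2, 9), v = c(0, 0, 5, 5, 9))
  asg <- cluster_assignment(emb, two_cluster_table())

  far <- assign_by_pick(asg, emb, pick = c(100, 100), picker_range = 1,
                        cluster_id = 0)
  expect_true(all(is.na(far$cluster_id)))

  one <- assign_by_pick(asg, emb, pick = c(9, 9), picker_range = 0.01,
                        cluster_id = 1)
  expect_identical(which(!is.na(one$cluster_id)), 5L)

  set.seed(71)
  emb2 <- fake_embedding(u = runif(300, 0, 10), v = runif(300, 0, 10))
  asg2 <- cluster_assignment(emb2, two_cluster_table())
  for (i in 1:5) {
    pick <- runif(2, 0, 10); r <- runif(1, 0.5, 3)
    asg2 <- assign_by_pick(asg2, emb2, pick, r, cluster_id = i %% 2)
    inside <- sqrt((emb2$u - pick[1])^2 + (emb2$v - pick[2])^2) <= r
    expect_true(all(asg2$cluster_id[inside] == i %% 2))
  }
  expect_error(assign_by_pick(asg, emb, c(0, 0), 1, cluster_id = 9),
               class = "fbbc_lookup_error")
})

test_that("later picks overwrite earlier ones", {
  emb <- fake_embedding(u = c(0, 1), v = c(0, 0))
  asg <- cluster_assignment(emb, two_cluster_table())
  asg <- assign_by_pick(asg, emb, c(0.5, 0), 2, cluster_id = 0)
  asg <- assign_by_pick(asg, emb, c(1, 0), 0.5, cluster_id = 1)
  expect_identical(asg$cluster_id, c(0L, 1L))
})

test_that("k-means mode partitions disjoint discs by membership", {
  set.seed(72)
  th <- runif(120, 0, 2 * pi); r <- sqrt(runif(120))
  centers <- rep(c(0, 20), each = 60)
  emb <- fake_embedding(u = centers + r * cos(th), v = r * sin(th))
  truth <- rep(0:1, each = 60)

  asg <- auto_cluster(emb, k = 2)
  expect_identical(nrow(cluster_table(asg)), 2L)
  expect_false(anyNA(asg$cluster_id))
  expect_true(all(table(asg$cluster_id, truth) %in% c(0L, 60L)))

  all_one <- auto_cluster(emb, k = 1)
  expect_identical(unique(all_one$cluster_id), 0L)
  expect_error(auto_cluster(emb, k = 500), class = "fbbc_argument_error")
})

test_that("automatic mode finds the cluster count from connectivity gaps", {
  set.seed(73)
  blob <- function(cx, cy, n = 50) cbind(cx + rnorm(n, sd = 0.3),
                                         cy + rnorm(n, sd = 0.3))
  pts <- rbind(blob(0, 0), blob(10, 0), blob(5, 8))
  emb <- fake_embedding(u = pts[, 1], v = pts[, 2])
  asg <- auto_cluster(emb)
  expect_identical(nrow(cluster_table(asg)), 3L)
  truth <- rep(1:3, each = 50)
  expect_gte(mclust::adjustedRandIndex(asg$cluster_id, truth), 0.99)

  lone <- fake_embedding(u = rnorm(80, sd = 0.5), v = rnorm(80, sd = 0.5))
  expect_identical(nrow(cluster_table(auto_cluster(lone))), 1L)
})

test_that("a 5-regime synthetic embedding is recovered with high ARI", {
  sim <- simulate_track(desk_task_spec(seed = 12, duration_s = 60))
  fs <- minmax_normalize(apply_recipe(sim$track, "desk_task"))
  th <- thin_features(fs, 5)
  emb <- embed_features(th, embed_params(n_neighbors = 20, random_seed = 12))
  asg <- auto_cluster(emb)
  truth <- sim$ethogram$regime_id[match(emb$frame, sim$ethogram$frame)]
  expect_gte(mclust::adjustedRandIndex(asg$cluster_id, truth), 0.9)
})

test_that("hold-forward expansion covers each frame exactly once", {
  emb <- fake_embedding(u = 1:3, v = 1:3, frames = c(0L, 5L, 10L))
  asg <- cluster_assignment(emb, two_cluster_table())
  asg$cluster_id <- c(0L, 0L, 1L)
  tl <- build_timeline(asg, full_range = c(0, 14), fps = 10)
  expect_identical(tl$frame, 0:14)
  expect_identical(tl$code, c(rep("alpha", 10), rep("beta", 5)))

  # thin step 1: timeline equals the per-point labels
  emb1 <- fake_embedding(u = 1:4, v = 1:4, frames = 0:3)
  a1 <- cluster_assignment(emb1, two_cluster_table())
  a1$cluster_id <- c(0L, 1L, 1L, 0L)
  t1 <- build_timeline(a1, full_range = c(0, 3), fps = 10)
  expect_identical(t1$code, c("alpha", "beta", "beta", "alpha"))

  # frames before the first source frame and unassigned points get NONE
  emb2 <- fake_embedding(u = 1:2, v = 1:2, frames = c(3L, 6L))
  a2 <- cluster_assignment(emb2, two_cluster_table())
  a2$cluster_id <- c(0L, NA)
  t2 <- build_timeline(a2, full_range = c(0, 9), fps = 10)
  expect_identical(t2$code, c(rep("NONE", 3), rep("alpha", 3), rep("NONE", 4)))

  expect_error(build_timeline(a2[0, ], full_range = c(0, 5), fps = 10),
               class = "fbbc_degenerate_input")
  expect_error(build_timeline(a2, full_range = c(4, 5), fps = 10),
               class = "fbbc_argument_error")
})

test_that("random assignments match a brute-force per-frame scan", {
  set.seed(74)
  for (rep in 1:10) {
    src <- sort(sample(0:60, 12))
    emb <- fake_embedding(u = rnorm(12), v = rnorm(12), frames = src)
    asg <- cluster_assignment(emb, two_cluster_table())
    asg$cluster_id <- sample(c(0L, 1L, NA), 12, replace = TRUE)
    tl <- build_timeline(asg, full_range = c(0, 70), fps = 10)
    expect_identical(nrow(tl), 71L)
    expect_identical(anyDuplicated(tl$frame), 0L)

    oracle <- vapply(0:70, function(f) {
      prior <- src[src <= f]
      if (!length(prior)) return("NONE")
      cid <- asg$cluster_id[which(src == max(prior))]
      if (is.na(cid)) "NONE" else c("alpha", "beta")[cid + 1]
    }, character(1))
    expect_identical(tl$code, oracle)
  }
})

test_that("interval and per-frame exports convert without loss", {
  const <- structure(
    tibble::tibble(frame = 0:9, time_ms = (0:9) * 100, code = "alpha"),
    fps = 10, class = c("behavior_timeline", class(tibble::tibble())))
  iv <- timeline_intervals(const)
  expect_identical(nrow(iv), 1L)
  expect_equal(iv$end_ms - iv$start_ms, 1000)

  alt <- structure(
    tibble::tibble(frame = 0:9, time_ms = (0:9) * 100,
                   code = rep(c("a", "b"), 5)),
    fps = 10, class = c("behavior_timeline", class(tibble::tibble())))
  expect_identical(nrow(timeline_intervals(alt)), 10L)

  set.seed(75)
  rnd <- structure(
    tibble::tibble(frame = 0:99, time_ms = (0:99) / 29.97 * 1000,
                   code = sample(c("a", "b", "NONE"), 100, replace = TRUE)),
    fps = 29.97, class = c("behavior_timeline", class(tibble::tibble())))
  back <- intervals_to_timeline(timeline_intervals(rnd), fps = 29.97)
  expect_identical(back$frame, rnd$frame)
  expect_identical(back$code, rnd$code)
})

test_that("timeline CSV exports round-trip", {
  tl <- structure(
    tibble::tibble(frame = 0:19, time_ms = (0:19) * 100,
                   code = rep(c("a", "a", "b", "NONE"), 5)),
    fps = 10, class = c("behavior_timeline", class(tibble::tibble())))
  path <- withr::local_tempfile(fileext = ".csv")
  ivpath <- withr::local_tempfile(fileext = ".csv")
  export_timeline(tl, path, ivpath)
  back <- read_timeline(path, fps = 10)
  expect_identical(back$code, tl$code)
  iv <- readr::read_csv(ivpath, show_col_types = FALSE)
  dec <- intervals_to_timeline(iv, fps = 10)
  expect_identical(dec$code, tl$code)
})
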