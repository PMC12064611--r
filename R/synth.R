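#' Specify a synthetic posture-regime track
#'
#' The simulator emulates multi-keypoint upper-body tracks with
#' regime-switching postures: a first-order Markov chain over K posture
#' regimes sampled per frame, each regime a template of mean keypoint
#' positions, with independent Gaussian jitter on every coordinate. Because
#' the ground-truth regime sequence is returned alongside the track, every
#' downstream stage — featurization, embedding, clustering, timeline — can be
#' tested without any video data.
#'
#' @param scheme A [keypoint_scheme()]; every regime must define all its
#'   keypoints.
#' @param regimes Named list of templates; each template is a data frame
#'   with columns `keypoint`, `x`, `y`.
#' @param transition K x K row-stochastic matrix (rows sum to 1 within
#'   1e-12), in the order of `regimes`.
#' @param noise_sd Gaussian jitter standard deviation, px (>= 0).
#' @param fps Frame rate, frames/second.
#' @param duration_s Duration, seconds.
#' @param seed Integer seed; the simulation is bit-reproducible from it.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(scheme, regimes, transition, noise_sd, fps,
                           duration_s, seed = 1L) {
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  check_scalar_number(fps, "fps", min = 0, strict = TRUE)
  check_scalar_number(duration_s, "duration_s", min = 0, strict = TRUE)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  K <- length(regimes)
  if (is.null(names(regimes)) || anyDuplicated(names(regimes))) {
    stop_fbbc("`regimes` must be a uniquely named list.", "fbbc_validation_error")
  }
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(K, K))) {
    stop_fbbc(sprintf("`transition` must be %d x %d.", K, K),
              "fbbc_validation_error")
  }
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-12)) {
    stop_fbbc("`transition` rows must be non-negative and sum to 1 (within 1e-12).",
              "fbbc_validation_error")
  }
  ids <- scheme_ids(scheme)
  regimes <- purrr::map(regimes, function(tpl) {
    tpl <- as_tibble(tpl)
    if (!all(c("keypoint", "x", "y") %in% names(tpl)) ||
        !setequal(tpl$keypoint, ids)) {
      stop_fbbc("Every regime template must define x, y for every scheme keypoint.",
                "fbbc_validation_error")
    }
    tpl[match(ids, tpl$keypoint), c("keypoint", "x", "y")]
  })
  structure(
    list(scheme = scheme, regimes = regimes, transition = transition,
         noise_sd = as.double(noise_sd), fps = as.double(fps),
         duration_s = as.double(duration_s), seed = seed),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec: %d regime(s) [%s], %d keypoint(s), fps %.6g, %gs, noise_sd %g px, seed %d>\n",
    length(x$regimes), paste(names(x$regimes), collapse = ", "),
    nrow(x$regimes[[1]]), x$fps, x$duration_s, x$noise_sd, x$seed))
  invisible(x)
}

#' Default desk-task specification
#'
#' Five posture regimes over the Halpe26 upper-body subset (keypoints 5, 6,
#' 8, 9, 10, 18) qualitatively mimicking a seated manipulation task filmed at
#' 29.97 fps: reaching to the left side, raising the hand while resting on
#' the elbow, putting the hand near the face, reaching to the right side, and
#' using the left hand (the right arm adopting its characteristic rest
#' posture). Templates live in a nominal 640 x 480 frame (image coordinates,
#' y down). Regimes persist with probability `stay_prob` per frame and
#' otherwise switch uniformly, giving a mean dwell of
#' `1 / (1 - stay_prob)` frames (~2.2 s at the default).
#'
#' @param noise_sd Keypoint jitter, px.
#' @param fps Frame rate.
#' @param duration_s Duration, seconds.
#' @param stay_prob Per-frame probability of staying in the current regime.
#' @param seed Simulation seed.
#' @return A [synthetic_spec()].
#' @export
desk_task_spec <- function(noise_sd = 3, fps = 29.97, duration_s = 120,
                           stay_prob = 0.985, seed = 1L) {
  check_scalar_number(stay_prob, "stay_prob", min = 0)
  if (stay_prob >= 1) {
    stop_fbbc("`stay_prob` must be < 1 so regimes can switch.",
              "fbbc_argument_error")
  }
  tpl <- function(kp5, kp6, kp8, kp9, kp10, kp18) {
    tibble(
      keypoint = c(5L, 6L, 8L, 9L, 10L, 18L),
      x = c(kp5[1], kp6[1], kp8[1], kp9[1], kp10[1], kp18[1]),
      y = c(kp5[2], kp6[2], kp8[2], kp9[2], kp10[2], kp18[2])
    )
  }
  regimes <- list(
    left_side = tpl(kp5 = c(310, 200), kp6 = c(190, 200), kp8 = c(170, 260),
                    kp9 = c(330, 300), kp10 = c(90, 280), kp18 = c(250, 180)),
    up_hand = tpl(kp5 = c(380, 200), kp6 = c(260, 200), kp8 = c(250, 270),
                  kp9 = c(380, 300), kp10 = c(260, 160), kp18 = c(320, 180)),
    near_face = tpl(kp5 = c(380, 200), kp6 = c(260, 200), kp8 = c(230, 260),
                    kp9 = c(380, 300), kp10 = c(300, 190), kp18 = c(320, 180)),
    right_side = tpl(kp5 = c(450, 200), kp6 = c(330, 200), kp8 = c(400, 250),
                     kp9 = c(440, 310), kp10 = c(520, 280), kp18 = c(390, 180)),
    use_left_hand = tpl(kp5 = c(380, 200), kp6 = c(260, 200), kp8 = c(240, 290),
                        kp9 = c(450, 320), kp10 = c(250, 340), kp18 = c(320, 185))
  )
  K <- length(regimes)
  transition <- matrix((1 - stay_prob) / (K - 1), K, K)
  diag(transition) <- stay_prob
  synthetic_spec(halpe26_upper(), regimes, transition,
                 noise_sd = noise_sd, fps = fps, duration_s = duration_s,
                 seed = seed)
}

#' Simulate a track with known posture regimes
#'
#' Samples the regime chain (starting in the first regime) and adds
#' independent Gaussian jitter to every template coordinate. Confidence is
#' set to 1 for all synthetic detections. The same seed always yields a
#' bit-identical track and label sequence.
#'
#' @param spec A [synthetic_spec()].
#' @param person_id Person id for the generated rows.
#' @return A list: `track` (a `track_series` with `frame_size` 640 x 480 for
#'   the default templates) and `ethogram`, the ground truth — a tibble
#'   `frame`, `regime_id` (0-based), `regime` (name).
#' @export
simulate_track <- function(spec, person_id = 0L) {
  if (!inherits(spec, "synthetic_spec")) {
    stop_fbbc("`spec` must come from synthetic_spec().", "fbbc_argument_error")
  }
  n_frames <- max(2L, as.integer(floor(spec$fps * spec$duration_s)))
  K <- length(spec$regimes)
  ids <- spec$regimes[[1]]$keypoint
  n_kp <- length(ids)

  sim <- with_local_seed(spec$seed, {
    states <- integer(n_frames)
    states[1] <- 1L
    if (n_frames > 1L) {
      u <- runif(n_frames - 1L)
      cum <- t(apply(spec$transition, 1L, cumsum))
      for (t in 2:n_frames) {
        states[t] <- as.integer(findInterval(u[t - 1L], cum[states[t - 1L], ],
                                             left.open = TRUE)) + 1L
      }
    }
    jitter_x <- matrix(rnorm(n_frames * n_kp, sd = spec$noise_sd), n_frames, n_kp)
    jitter_y <- matrix(rnorm(n_frames * n_kp, sd = spec$noise_sd), n_frames, n_kp)
    list(states = states, jx = jitter_x, jy = jitter_y)
  })

  tpl_x <- vapply(spec$regimes, function(r) r$x, numeric(n_kp))
  tpl_y <- vapply(spec$regimes, function(r) r$y, numeric(n_kp))
  x <- t(tpl_x[, sim$states, drop = FALSE]) + sim$jx  # frames x keypoints
  y <- t(tpl_y[, sim$states, drop = FALSE]) + sim$jy

  rows <- tibble(
    frame = rep(seq_len(n_frames) - 1L, times = n_kp),
    person = as.integer(person_id),
    keypoint = rep(ids, each = n_frames),
    x = as.vector(x),
    y = as.vector(y),
    confidence = 1
  )
  track <- track_series(rows, fps = spec$fps, scheme = spec$scheme,
                        video_name = "synthetic", frame_size = c(640L, 480L))
  ethogram <- tibble(
    frame = seq_len(n_frames) - 1L,
    regime_id = sim$states - 1L,
    regime = names(spec$regimes)[sim$states]
  )
  list(track = track, ethogram = ethogram)
}

#' Write a ground-truth ethogram CSV
#' @param ethogram Tibble `frame`, `regime_id`, `regime` from
#'   [simulate_track()].
#' @param path CSV destination.
#' @export
write_ethogram <- function(ethogram, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(ethogram, path)
  invisible(path)
}

#' Frames near a regime transition
#'
#' Hold-forward label propagation cannot be exact around regime switches, so
#' agreement between a coded timeline and the ground truth is conventionally
#' measured excluding a window of frames around each transition.
#'
#' @param ethogram Ground-truth ethogram from [simulate_track()].
#' @param window Half-width of the exclusion window in frames.
#' @return Logical vector, `TRUE` for frames within `window` frames of a
#'   regime change.
#' @export
near_transition <- function(ethogram, window) {
  window <- check_count(window, "window", min = 0L)
  switches <- which(diff(ethogram$regime_id) != 0L)  # switch between i and i+1
  near <- rep(FALSE, nrow(ethogram))
  if (window == 0L) return(near)
  for (s in switches) {
    lo <- max(1L, s - window + 1L)
    hi <- min(nrow(ethogram), s + window)
    near[lo:hi] <- TRUE
  }
  near
}

#' Agreement between a coded timeline and a ground-truth ethogram
#'
#' Cluster codes are arbitrary names, so codes are first matched one-to-one
#' to regimes greedily by overlap count on the evaluated frames; agreement is
#' the fraction of those frames whose matched code equals the true regime.
#' Frames within `exclude_window` frames of a regime transition are excluded
#' (see [near_transition()]), as are frames the ethogram does not cover.
#'
#' @param timeline A `behavior_timeline`.
#' @param ethogram Ground-truth ethogram from [simulate_track()].
#' @param exclude_window Half-width of the transition exclusion window,
#'   frames.
#' @return A list: `agreement` (fraction in \[0, 1\]), `n_frames` evaluated,
#'   and the `mapping` tibble (`code` -> `regime`).
#' @export
timeline_agreement <- function(timeline, ethogram, exclude_window = 0L) {
  keep <- !near_transition(ethogram, window = exclude_window)
  truth <- ethogram$regime[keep]
  pred <- timeline$code[match(ethogram$frame[keep], timeline$frame)]
  ok <- !is.na(pred)
  truth <- truth[ok]; pred <- pred[ok]
  if (!length(truth)) {
    stop_fbbc("No overlapping frames to compare.", "fbbc_degenerate_input")
  }
  tab <- table(pred, truth)
  mapping <- tibble(code = character(), regime = character())
  m <- as.matrix(tab)
  while (nrow(m) && ncol(m) && max(m) > 0) {
    ij <- which(m == max(m), arr.ind = TRUE)[1, ]
    mapping <- bind_rows(mapping, tibble(code = rownames(m)[ij[1]],
                                         regime = colnames(m)[ij[2]]))
    m <- m[-ij[1], -ij[2], drop = FALSE]
  }
  matched <- mapping$regime[match(pred, mapping$code)]
  list(agreement = mean(!is.na(matched) & matched == truth),
       n_frames = length(truth),
       mapping = mapping)
}
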