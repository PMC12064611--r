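#' Build a feature recipe
#'
#' A recipe is an ordered list of feature specifications that is applied to a
#' track in one call. Each spec names an operation, the keypoint ids it takes
#' (1 for positions and speed, 2 for distance, 3 — origin, a, b — for dot and
#' cross products) and the output column name.
#'
#' @param ... Specs created with [feature_spec()], or a single list of them.
#' @return A `feature_recipe`.
#' @examples
#' feature_recipe(
#'   feature_spec("position_x", 18, name = "neck_x"),
#'   feature_spec("cross_product", c(5, 10, 6), name = "shoulder_left")
#' )
#' @export
feature_recipe <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1]], "feature_spec") &&
      is.list(specs[[1]])) {
    specs <- specs[[1]]
  }
  specs <- purrr::map(specs, as_feature_spec)
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop_fbbc(sprintf("Duplicate output name(s) in recipe: %s.",
                      paste(unique(nm[duplicated(nm)]), collapse = ", ")),
              "fbbc_recipe_error")
  }
  structure(specs, class = "feature_recipe")
}

recipe_arity <- c(position_x = 1L, position_y = 1L, speed = 1L,
                  distance = 2L, dot_product = 3L, cross_product = 3L)

#' @rdname feature_recipe
#' @param op One of `"position_x"`, `"position_y"`, `"speed"`, `"distance"`,
#'   `"dot_product"`, `"cross_product"`.
#' @param ids Keypoint ids, in the arity and order the operation expects
#'   (dot/cross: origin, a, b).
#' @param name Output column name.
#' @export
feature_spec <- function(op, ids, name) {
  op <- as.character(op)
  if (!op %in% names(recipe_arity)) {
    stop_fbbc(sprintf("Unknown feature op '%s'.", op), "fbbc_recipe_error")
  }
  ids <- as.integer(ids)
  if (length(ids) != recipe_arity[[op]] || anyNA(ids)) {
    stop_fbbc(sprintf("Spec '%s': op '%s' takes %d keypoint id(s), got %d.",
                      name, op, recipe_arity[[op]], length(ids)),
              "fbbc_recipe_error")
  }
  structure(list(op = op, ids = ids, name = as.character(name)),
            class = "feature_spec")
}

as_feature_spec <- function(x) {
  if (inherits(x, "feature_spec")) return(x)
  if (is.list(x) && all(c("op", "ids", "name") %in% names(x))) {
    return(feature_spec(x$op, x$ids, x$name))
  }
  stop_fbbc("Recipe entries must be feature_spec objects.", "fbbc_recipe_error")
}

#' @export
print.feature_recipe <- function(x, ...) {
  cat(sprintf("<feature_recipe: %d feature(s)>\n", length(x)))
  for (s in x) {
    cat(sprintf("  %-18s %-13s ids = %s\n", s$name, s$op,
                paste(s$ids, collapse = ", ")))
  }
  invisible(x)
}

#' Built-in feature recipes
#'
#' * `"right_arm_cross4"` — the four cross products that characterise the
#'   posture of the right arm from keypoints 5 (left shoulder), 6 (right
#'   shoulder), 8 (right elbow) and 10 (right hand): with `V[i,j]` the vector
#'   from keypoint i to keypoint j,
#'   `shoulder_left = V[5,10] x V[5,6]`, `hand = V[10,8] x V[10,5]`,
#'   `shoulder_right = V[6,5] x V[6,8]`, `elbow = V[8,6] x V[8,10]`.
#' * `"neck_x"` — the x-coordinate of the neck (keypoint 18), tracking
#'   left-right movement of the upper body.
#' * `"desk_task"` — `neck_x` followed by the four cross products: the
#'   five-column feature set used for coding a seated desk task.
#'
#' @param name Preset name.
#' @return A [feature_recipe()].
#' @export
recipe_preset <- function(name = c("right_arm_cross4", "neck_x", "desk_task")) {
  name <- match.arg(name)
  cross4 <- list(
    feature_spec("cross_product", c(5L, 10L, 6L), name = "shoulder_left"),
    feature_spec("cross_product", c(10L, 8L, 5L), name = "hand"),
    feature_spec("cross_product", c(6L, 5L, 8L), name = "shoulder_right"),
    feature_spec("cross_product", c(8L, 6L, 10L), name = "elbow")
  )
  neck <- list(feature_spec("position_x", 18L, name = "neck_x"))
  switch(name,
    right_arm_cross4 = feature_recipe(cross4),
    neck_x = feature_recipe(neck),
    desk_task = feature_recipe(c(neck, cross4))
  )
}

#' Apply a recipe to a track
#'
#' Evaluates every spec of the recipe against the track and binds the results
#' into one feature series, one column per spec, in recipe order.
#'
#' @param track A single-person `track_series`.
#' @param recipe A [feature_recipe()] or preset name for [recipe_preset()].
#' @return A `feature_series` with one column per spec.
#' @export
apply_recipe <- function(track, recipe) {
  if (is.character(recipe)) recipe <- recipe_preset(recipe)
  if (!inherits(recipe, "feature_recipe")) {
    stop_fbbc("`recipe` must be a feature_recipe or a preset name.",
              "fbbc_recipe_error")
  }
  frames <- sort(unique(track$frame))
  out <- tibble(frame = frames, time_ms = frames / fps(track) * 1000)
  ops <- list()
  for (s in recipe) {
    col <- tryCatch(
      switch(s$op,
        position_x = position_series(track, s$ids[1], "x", name = s$name),
        position_y = position_series(track, s$ids[1], "y", name = s$name),
        speed = speed_series(track, s$ids[1], name = s$name),
        distance = distance_series(track, s$ids[1], s$ids[2], name = s$name),
        dot_product = dot_product_series(track, s$ids[1], s$ids[2], s$ids[3],
                                         name = s$name),
        cross_product = cross_product_series(track, s$ids[1], s$ids[2], s$ids[3],
                                             name = s$name)
      ),
      fbbc_error = function(e) {
        stop_fbbc(sprintf("Recipe spec '%s' (%s of %s) failed: %s",
                          s$name, s$op, paste(s$ids, collapse = ","),
                          conditionMessage(e)),
                  "fbbc_recipe_error")
      }
    )
    out[[s$name]] <- col[[s$name]]
    ops <- c(ops, list(list(op = s$op, ids = s$ids, name = s$name)))
  }
  feature_series(out, fps = fps(track),
                 provenance = list(source = attr(track, "video_name"),
                                   ops = ops))
}
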