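#' Configure an end-to-end coding run
#'
#' Declares every decision of the workflow — input, scheme, scenes, feature
#' recipe, normalization, thinning, embedding parameters, clustering mode,
#' output folder — in one object, so a run is a pure function of
#' (input files, config, seed) and can be reproduced byte-identically.
#'
#' @param input Input description, one of:
#'   `list(kind = "track", path = ...)`,
#'   `list(kind = "dlc", path = ..., fps = ..., person = 0)`, or
#'   `list(kind = "simulate", spec = synthetic_spec)` (default: the desk-task
#'   spec).
#' @param scheme A [keypoint_scheme()] or built-in scheme name
#'   (`"halpe26_upper"`).
#' @param person Person id to analyse.
#' @param scenes Optional `scene_table` or scene CSV path.
#' @param recipe A [feature_recipe()] or preset name.
#' @param normalize Min-max normalize the features before embedding?
#' @param thin_step Thinning step before embedding.
#' @param n_neighbors,min_dist UMAP parameters (see [embed_params()]).
#' @param seed Seed for the embedding and clustering.
#' @param cluster Clustering mode: `list(mode = "auto")` (automatic cluster
#'   count), `list(mode = "auto_k", k = 5)`, or
#'   `list(mode = "picks", picks = <pick-script tibble or CSV path>)`. A pick
#'   script has columns `u`, `v`, `radius`, `cluster` and replays manual
#'   scatter-plot clustering headlessly.
#' @param output_dir Directory all artifacts are written into.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = list(kind = "simulate"),
                            scheme = "halpe26_upper",
                            person = 0L,
                            scenes = NULL,
                            recipe = "desk_task",
                            normalize = TRUE,
                            thin_step = 5L,
                            n_neighbors = 20L,
                            min_dist = 0.1,
                            seed = 42L,
                            cluster = list(mode = "auto"),
                            output_dir = tempfile("fbbc_run_")) {
  if (is.character(scheme)) {
    scheme <- switch(scheme,
      halpe26_upper = halpe26_upper(),
      stop_fbbc(sprintf("Unknown scheme '%s'.", scheme), "fbbc_config_error"))
  }
  if (!is.list(input) || is.null(input$kind) ||
      !input$kind %in% c("track", "dlc", "simulate")) {
    stop_fbbc("`input$kind` must be 'track', 'dlc' or 'simulate'.",
              "fbbc_config_error")
  }
  if (input$kind %in% c("track", "dlc")) {
    if (is.null(input$path) || !file.exists(input$path)) {
      stop_fbbc(sprintf("Input file not found: '%s'.",
                        input$path %||% "<missing>"),
                "fbbc_config_error")
    }
    if (input$kind == "dlc" && is.null(input$fps)) {
      stop_fbbc("DLC input needs `input$fps` (the dialect stores no frame rate).",
                "fbbc_config_error")
    }
  }
  if (input$kind == "simulate" && is.null(input$spec)) {
    input$spec <- desk_task_spec(seed = seed)
  }
  if (is.character(scenes)) scenes <- read_scene_table(scenes)
  if (is.character(recipe)) recipe <- recipe_preset(recipe)
  if (!is.null(cluster$picks) && is.character(cluster$picks)) {
    cluster$picks <- readr::read_csv(cluster$picks, show_col_types = FALSE)
  }
  cluster$mode <- cluster$mode %||% "auto"
  if (!cluster$mode %in% c("auto", "auto_k", "picks")) {
    stop_fbbc("`cluster$mode` must be 'auto', 'auto_k' or 'picks'.",
              "fbbc_config_error")
  }
  if (cluster$mode == "auto_k") check_count(cluster$k, "cluster$k", min = 1L)
  structure(
    list(input = input, scheme = scheme, person = check_count(person, "person", 0L),
         scenes = scenes, recipe = recipe, normalize = isTRUE(normalize),
         thin_step = check_count(thin_step, "thin_step"),
         n_neighbors = check_count(n_neighbors, "n_neighbors", 2L),
         min_dist = min_dist,
         seed = check_count(seed, "seed", min = -.Machine$integer.max),
         cluster = cluster, output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `input.kind: simulate`
#' accepts the desk-task generator knobs (`noise_sd`, `fps`, `duration_s`,
#' `stay_prob`) inline.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- y$input %||% list(kind = "simulate")
  if (identical(input$kind, "simulate")) {
    knobs <- input[intersect(names(input),
                             c("noise_sd", "fps", "duration_s", "stay_prob", "seed"))]
    input <- list(kind = "simulate",
                  spec = do.call(desk_task_spec, knobs))
  }
  recipe <- y$recipe %||% "desk_task"
  if (is.list(recipe)) recipe <- feature_recipe(recipe)
  args <- list(
    input = input, recipe = recipe,
    scheme = y$scheme %||% "halpe26_upper",
    person = y$person %||% 0L,
    scenes = y$scenes,
    normalize = y$normalize %||% TRUE,
    thin_step = y$thin_step %||% 5L,
    n_neighbors = y$n_neighbors %||% 20L,
    min_dist = y$min_dist %||% 0.1,
    seed = y$seed %||% 42L,
    cluster = y$cluster %||% list(mode = "auto")
  )
  if (!is.null(y$output_dir)) args$output_dir <- y$output_dir
  do.call(pipeline_config, args)
}

resolved_config_list <- function(config) {
  input <- config$input
  input_desc <- switch(input$kind,
    simulate = {
      s <- input$spec
      list(kind = "simulate", regimes = names(s$regimes), noise_sd = s$noise_sd,
           fps = s$fps, duration_s = s$duration_s, seed = s$seed)
    },
    list(kind = input$kind, path = input$path, fps = input$fps,
         person = input$person)
  )
  list(
    input = input_desc,
    scheme = config$scheme$scheme_name,
    person = config$person,
    scenes = if (!is.null(config$scenes)) {
      lapply(seq_len(nrow(config$scenes)), function(i) as.list(config$scenes[i, ]))
    },
    recipe = lapply(unclass(config$recipe), function(s) {
      list(op = s$op, ids = s$ids, name = s$name)
    }),
    normalize = config$normalize,
    thin_step = config$thin_step,
    n_neighbors = config$n_neighbors,
    min_dist = config$min_dist,
    seed = config$seed,
    cluster = config$cluster[setdiff(names(config$cluster), "picks")]
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_fbbc(sprintf("Pipeline stage '%s' failed: %s",
                      stage, conditionMessage(e)),
              "fbbc_pipeline_error")
  })
}

#' Run the full coding workflow
#'
#' Executes ingest, optional scene filtering, featurization, mix/norm,
#' thinning, 2-D embedding, clustering and timeline expansion, writing every
#' intermediate artifact (track container + CSV mirror, feature file + CSV,
#' embedding + provenance sidecar, cluster table, per-frame and interval
#' timelines, a resolved copy of the configuration) into
#' `config$output_dir`. The run report records row counts at every stage.
#'
#' @param config A [pipeline_config()].
#' @return An `fbbc_run` object: list with `config`, `counts` (per-stage row
#'   counts), `files` (paths written), `track`, `features`, `embedding`,
#'   `assignment`, `timeline` and, for simulated input, the ground-truth
#'   `ethogram`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_fbbc("`config` must come from pipeline_config().", "fbbc_config_error")
  }
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  counts <- list()

  ethogram <- NULL
  inp <- config$input
  if (inp$kind == "simulate") {
    sim <- run_stage("ingest", simulate_track(inp$spec, person_id = config$person))
    ethogram <- sim$ethogram
    files$ethogram <- file.path(out_dir, "ethogram.csv")
    write_ethogram(ethogram, files$ethogram)
    track <- sim$track
  } else {
    track <- run_stage("ingest", switch(inp$kind,
      track = read_track(inp$path),
      dlc = read_dlc_keypoints(inp$path, fps = inp$fps,
                               person_id = inp$person %||% config$person,
                               scheme = config$scheme)
    ))
  }
  track <- run_stage("select_person", select_person(track, config$person))
  counts$track_rows <- nrow(track)
  files$track <- file.path(out_dir, "trk", "input.track")
  write_track(track, files$track)
  files$track_csv <- file.path(out_dir, "trk", "input.csv")
  write_track_csv(track, files$track_csv)

  if (!is.null(config$scenes)) {
    track <- run_stage("scenes", filter_by_scenes(track, config$scenes))
    counts$track_rows_in_scenes <- nrow(track)
  }

  feats <- run_stage("featurize", apply_recipe(track, config$recipe))
  counts$feature_rows <- nrow(feats)
  counts$feature_columns <- length(feature_columns(feats))

  if (config$normalize) {
    feats <- run_stage("normalize", minmax_normalize(feats))
  }
  files$features <- file.path(out_dir, "calc", "features", "features.feather")
  write_features(feats, files$features)
  files$features_csv <- file.path(out_dir, "calc", "features", "features.csv")
  write_features_csv(feats, files$features_csv)

  thinned <- run_stage("thin", thin_features(feats, config$thin_step))
  counts$thinned_rows <- nrow(thinned)

  params <- embed_params(n_neighbors = config$n_neighbors,
                         min_dist = config$min_dist,
                         thin_step = config$thin_step,
                         random_seed = config$seed)
  embedding <- run_stage("embed", embed_features(thinned, params))
  counts$embedded_points <- nrow(embedding)
  files$embedding <- file.path(out_dir, "embedding.csv")
  write_embedding(embedding, files$embedding)

  assignment <- run_stage("cluster", {
    cl <- config$cluster
    switch(cl$mode,
      auto = auto_cluster(embedding, k = NULL, seed = config$seed),
      auto_k = auto_cluster(embedding, k = cl$k, seed = config$seed),
      picks = {
        picks <- as_tibble(cl$picks)
        clusters <- tibble(name = unique(as.character(picks$cluster)))
        clusters$cluster_id <- seq_len(nrow(clusters)) - 1L
        asg <- cluster_assignment(embedding, clusters)
        for (i in seq_len(nrow(picks))) {
          asg <- assign_by_pick(
            asg, embedding, pick = c(picks$u[i], picks$v[i]),
            picker_range = picks$radius[i],
            cluster_id = clusters$cluster_id[match(as.character(picks$cluster[i]),
                                                   clusters$name)])
        }
        asg
      }
    )
  })
  counts$clusters <- nrow(cluster_table(assignment))
  counts$assigned_points <- sum(!is.na(assignment$cluster_id))
  files$clusters <- file.path(out_dir, "clusters.csv")
  readr::write_csv(cluster_table(assignment), files$clusters)

  timeline <- run_stage("timeline", {
    build_timeline(assignment,
                   full_range = c(min(track$frame), max(track$frame)),
                   fps = fps(track))
  })
  counts$timeline_frames <- nrow(timeline)
  files$timeline <- file.path(out_dir, "timeline.csv")
  files$intervals <- file.path(out_dir, "intervals.csv")
  export_timeline(timeline, files$timeline, files$intervals)

  files$config <- file.path(out_dir, "config_resolved.yaml")
  yaml::write_yaml(resolved_config_list(config), files$config)

  structure(
    list(config = config, counts = counts, files = files,
         track = track, features = feats, thinned = thinned,
         embedding = embedding, assignment = assignment, timeline = timeline,
         ethogram = ethogram),
    class = "fbbc_run"
  )
}

#' @export
print.fbbc_run <- function(x, ...) {
  cat("<fbbc_run>\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  }
  cat(sprintf("  output: %s\n", x$config$output_dir))
  invisible(x)
}
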