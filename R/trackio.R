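#' Write and read the native track container
#'
#' Tracks are stored one file per video in a columnar binary container
#' (Apache Arrow Feather v2) that round-trips coordinates bit-exactly,
#' preserves missingness and carries the track metadata (frame rate, video
#' name, frame size, keypoint scheme). A plain-text CSV mirror can always be
#' written alongside for inspection with [write_track_csv()].
#'
#' @param track A valid `track_series`.
#' @param path Destination file (conventionally `<video_dir>/trk/<stem>.track`,
#'   see [track_path()]).
#' @return `write_track()` returns `path` invisibly; `read_track()` returns
#'   the `track_series`.
#' @seealso [track_path()] for the folder layout.
#' @export
write_track <- function(track, path) {
  if (!is_track_series(track)) {
    stop_fbbc("`track` must be a track_series.", "fbbc_argument_error")
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  arrow::write_feather(track, path)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  if (!file.exists(path)) {
    stop_fbbc(sprintf("Track file not found: '%s'.", path), "fbbc_io_error")
  }
  out <- tryCatch(
    arrow::read_feather(path),
    error = function(e) {
      stop_fbbc(sprintf("'%s' is not a readable track container: %s",
                        path, conditionMessage(e)),
                "fbbc_format_error")
    }
  )
  if (!is_track_series(out)) {
    stop_fbbc(sprintf("'%s' does not contain a track_series.", path),
              "fbbc_format_error")
  }
  out
}

#' CSV mirror of a track
#'
#' Human-readable mirror of the native container with columns
#' `frame,time_ms,person,keypoint,x,y,conf`.
#'
#' @inheritParams write_track
#' @export
write_track_csv <- function(track, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- tibble(
    frame = track$frame,
    time_ms = track_time_ms(track),
    person = track$person,
    keypoint = track$keypoint,
    x = track$x,
    y = track$y,
    conf = track$confidence
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_track_csv
#' @param fps Frame rate to attach (the CSV mirror stores timestamps, not fps
#'   metadata; supply the original rate).
#' @param scheme Optional [keypoint_scheme()].
#' @export
read_track_csv <- function(path, fps, scheme = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  track_series(
    tibble(frame = df$frame, person = df$person, keypoint = df$keypoint,
           x = df$x, y = df$y, confidence = df$conf),
    fps = fps, scheme = scheme
  )
}

#' Conventional file layout around a video
#'
#' Tracks live in a `trk` folder next to the video; feature files live in
#' user-named subfolders of a sibling `calc` folder.
#'
#' @param video_path Path to the video file (the file need not exist).
#' @param calc_subfolder Subfolder name for derived feature files.
#' @return `track_path()`: the `<dir>/trk/<stem>.track` path;
#'   `calc_dir()`: the `<dir>/calc/<subfolder>` directory.
#' @examples
#' track_path("study/task1.mp4")
#' calc_dir("study/task1.mp4", "arm_features")
#' @export
track_path <- function(video_path) {
  stem <- tools::file_path_sans_ext(basename(video_path))
  file.path(dirname(video_path), "trk", paste0(stem, ".track"))
}

#' @rdname track_path
#' @export
calc_dir <- function(video_path, calc_subfolder) {
  file.path(dirname(video_path), "calc", calc_subfolder)
}

# ---------------------------------------------------------------------------
# DeepLabCut HDF5 dialect
#
# DLC stores one pandas DataFrame per file with a three-level column
# MultiIndex (scorer / bodyparts / coords) and coords in {x, y, likelihood}.
# pandas writes either the "fixed" layout (axis0_level*/axis0_label* string
# tables plus a block0_values matrix) or the "table" layout (a compound
# `table` dataset whose column tuples are pickled, protocol 0, into the
# `values_block_0_kind` attribute). Both are supported read-side; the writer
# emits the fixed layout.

#' Read DeepLabCut keypoint output
#'
#' Parses a DeepLabCut `.h5` keypoint file (three-level column hierarchy
#' scorer/bodyparts/coords) into a track. The dialect does not store a frame
#' rate, so `fps` must be supplied. Bodyparts carry names, not ids: ids are
#' assigned 0..n-1 in order of appearance unless `name_map` (a named integer
#' vector, `label -> id`) says otherwise. A missing `likelihood` column yields
#' `NA` confidence.
#'
#' @param path Path to the `.h5` file.
#' @param fps Frame rate of the source video (> 0).
#' @param person_id Person id to assign to all rows (DLC single-animal files
#'   carry one individual).
#' @param name_map Optional named integer vector mapping bodypart labels to
#'   keypoint ids.
#' @param scheme Optional [keypoint_scheme()] to attach.
#' @return A `track_series`. The bodypart-to-id mapping used is attached as
#'   attribute `bodypart_map`.
#' @export
read_dlc_keypoints <- function(path, fps, person_id = 0L, name_map = NULL,
                               scheme = NULL) {
  check_scalar_number(fps, "fps", min = 0, strict = TRUE)
  person_id <- check_count(person_id, "person_id", min = 0L)
  if (!file.exists(path)) {
    stop_fbbc(sprintf("DeepLabCut file not found: '%s'.", path), "fbbc_io_error")
  }
  listing <- tryCatch(
    rhdf5::h5ls(path),
    error = function(e) {
      stop_fbbc(sprintf("'%s' is not a readable HDF5 file: %s",
                        path, conditionMessage(e)),
                "fbbc_format_error")
    }
  )
  groups <- unique(listing$group[listing$group != "/"])
  key <- sub("^/", "", groups[1] %||% NA_character_)
  if (is.na(key)) {
    stop_fbbc(sprintf("'%s' contains no data group.", path), "fbbc_format_error")
  }
  in_group <- listing$name[listing$group == paste0("/", key)]

  if ("block0_values" %in% in_group) {
    parsed <- read_pandas_fixed(path, key)
  } else if ("table" %in% in_group) {
    parsed <- read_pandas_table(path, key)
  } else {
    stop_fbbc(sprintf("'%s' is not in a recognised pandas HDF5 layout.", path),
              "fbbc_format_error")
  }
  cols <- parsed$columns  # list of character tuples, in column order
  depth <- unique(lengths(cols))
  if (length(depth) != 1L || depth != 3L) {
    stop_fbbc(sprintf(
      "'%s': expected a 3-level column hierarchy (scorer/bodyparts/coords), got %s levels.",
      path, paste(depth, collapse = "/")), "fbbc_dialect_error")
  }
  bodyparts <- vapply(cols, `[[`, character(1), 2L)
  coords <- vapply(cols, `[[`, character(1), 3L)
  if (!all(coords %in% c("x", "y", "likelihood"))) {
    stop_fbbc(sprintf("'%s': unexpected coordinate name(s): %s.", path,
                      paste(setdiff(unique(coords), c("x", "y", "likelihood")),
                            collapse = ", ")),
              "fbbc_dialect_error")
  }

  parts <- unique(bodyparts)
  if (is.null(name_map)) {
    id_of <- setNames(seq_along(parts) - 1L, parts)
  } else {
    missing_parts <- setdiff(parts, names(name_map))
    if (length(missing_parts)) {
      stop_fbbc(paste0("name_map lacks bodypart(s): ",
                       paste(missing_parts, collapse = ", "), "."),
                "fbbc_argument_error")
    }
    id_of <- vapply(name_map, as.integer, integer(1))[parts]
  }

  values <- parsed$values  # rows x cols
  n_frames <- nrow(values)
  pull <- function(part, coord) {
    j <- which(bodyparts == part & coords == coord)
    if (length(j) == 1L) values[, j] else rep(NA_real_, n_frames)
  }
  per_part <- purrr::map(parts, function(p) {
    tibble(
      frame = seq_len(n_frames) - 1L,
      person = person_id,
      keypoint = id_of[[p]],
      x = pull(p, "x"),
      y = pull(p, "y"),
      confidence = pull(p, "likelihood")
    )
  })
  tr <- track_series(bind_rows(per_part), fps = fps, scheme = scheme,
                     video_name = tools::file_path_sans_ext(basename(path)))
  attr(tr, "bodypart_map") <- id_of
  tr
}

read_pandas_fixed <- function(path, key) {
  g <- rhdf5::h5read(path, key)
  n_levels <- sum(grepl("^block0_items_level", names(g)))
  if (n_levels > 0L) {
    levels <- lapply(seq_len(n_levels) - 1L,
                     function(i) as.character(g[[paste0("block0_items_level", i)]]))
    labels <- lapply(seq_len(n_levels) - 1L,
                     function(i) as.integer(g[[paste0("block0_items_label", i)]]))
    n_cols <- length(labels[[1]])
    columns <- lapply(seq_len(n_cols), function(j) {
      vapply(seq_len(n_levels),
             function(l) levels[[l]][labels[[l]][j] + 1L], character(1))
    })
  } else {
    # flat (single-level) columns
    columns <- as.list(as.character(g$block0_items))
  }
  values <- t(as.matrix(g$block0_values))  # rhdf5 reads column-major: cols x rows
  list(columns = columns, values = values)
}

read_pandas_table <- function(path, key) {
  tab <- rhdf5::h5read(path, paste0(key, "/table"), compoundAsDataFrame = FALSE)
  at <- rhdf5::h5readAttributes(path, paste0(key, "/table"))
  kind <- at$values_block_0_kind
  if (is.null(kind)) {
    stop_fbbc(sprintf("'%s': table layout without column metadata.", path),
              "fbbc_format_error")
  }
  columns <- parse_pickle0_tuples(kind)
  values <- t(as.matrix(tab$values_block_0))
  list(columns = columns, values = values)
}

# Minimal reader for the restricted pickle protocol-0 streams pandas writes
# for a list of column tuples: handles list/tuple marks, unicode strings
# (V...), memo put/get (p/g) and appends (a). Nothing else appears in these
# attributes.
parse_pickle0_tuples <- function(text) {
  # newlines terminate opcodes WITH arguments (V/S/I/p/g); the argument-less
  # opcodes ( l a t . can be glued together on one "line" (e.g. "a(g1")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  stack <- list()
  memo <- list()
  out <- list()
  push <- function(v) stack[[length(stack) + 1L]] <<- v
  pop <- function() {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <<- NULL
    top
  }
  pop_to_mark <- function() {
    items <- list()
    while (length(stack)) {
      top <- pop()
      if (identical(top, quote(mark))) break
      items <- c(list(top), items)
    }
    items
  }
  for (ln in lines) {
    while (nzchar(ln)) {
      op <- substr(ln, 1L, 1L)
      arg <- substring(ln, 2L)
      if (op %in% c("V", "S", "I", "p", "g")) {
        switch(op,
          "V" = push(arg),
          "S" = push(gsub("^'|'$", "", arg)),
          "I" = push(as.integer(arg)),
          "p" = { memo[[arg]] <- stack[[length(stack)]] },
          "g" = push(memo[[arg]])
        )
        break  # argument consumed the rest of the line
      }
      switch(op,
        "(" = push(quote(mark)),
        "l" = { },       # list built via appends; its mark is already pushed
        "t" = push(unlist(pop_to_mark(), use.names = FALSE)),
        "a" = { out[[length(out) + 1L]] <- pop() },
        "." = { },
        { }              # anything else is noise for this restricted grammar
      )
      ln <- arg
    }
  }
  out
}

#' Write a track in the DeepLabCut HDF5 dialect
#'
#' Emits the pandas "fixed" layout with a scorer/bodyparts/coords column
#' hierarchy, readable both by [read_dlc_keypoints()] and by
#' `pandas.read_hdf()`. Bodypart labels come from the track's scheme when
#' present, else `kp_<id>`. Only one person can be written per file.
#'
#' @param track A `track_series` with a single person.
#' @param path Destination `.h5` path.
#' @param scorer Scorer name for the first column level.
#' @param key HDF5 group name (DLC convention: `df_with_missing`).
#' @param likelihood Write the likelihood (confidence) columns? Set `FALSE`
#'   to emulate files that carry only x/y.
#' @return `path`, invisibly.
#' @export
write_dlc_keypoints <- function(track, path, scorer = "fbbc",
                                key = "df_with_missing", likelihood = TRUE) {
  if (dplyr::n_distinct(track$person) > 1L) {
    stop_fbbc("DLC files hold one individual; use select_person() first.",
              "fbbc_argument_error")
  }
  scheme <- attr(track, "scheme")
  kps <- sort(unique(track$keypoint))
  label_of <- setNames(paste0("kp_", kps), as.character(kps))
  if (!is.null(scheme)) {
    hit <- match(kps, scheme$keypoints$id)
    label_of[!is.na(hit)] <- scheme$keypoints$label[hit[!is.na(hit)]]
  }
  frames <- sort(unique(track$frame))
  coord_names <- if (likelihood) c("x", "y", "likelihood") else c("x", "y")

  # dense frame x column matrix, NA where a keypoint is absent in a frame
  wide <- matrix(NA_real_, nrow = length(frames),
                 ncol = length(kps) * length(coord_names))
  col_tuples <- list()
  j <- 0L
  for (kp in kps) {
    sub <- track[track$keypoint == kp, , drop = FALSE]
    ri <- match(sub$frame, frames)
    for (coord in coord_names) {
      j <- j + 1L
      col_tuples[[j]] <- c(scorer, label_of[[as.character(kp)]], coord)
      v <- switch(coord, x = sub$x, y = sub$y, likelihood = sub$confidence)
      wide[ri, j] <- v
    }
  }

  level0 <- scorer
  level1 <- sort(unique(vapply(col_tuples, `[[`, character(1), 2L)))
  level2 <- sort(unique(vapply(col_tuples, `[[`, character(1), 3L)))
  lab <- function(levels, vals) as.integer(match(vals, levels) - 1L)
  label0 <- lab(level0, vapply(col_tuples, `[[`, character(1), 1L))
  label1 <- lab(level1, vapply(col_tuples, `[[`, character(1), 2L))
  label2 <- lab(level2, vapply(col_tuples, `[[`, character(1), 3L))

  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, key)
  wr <- function(name, value) rhdf5::h5write(value, path, paste0(key, "/", name))
  wr("axis0_level0", level0); wr("axis0_level1", level1); wr("axis0_level2", level2)
  wr("axis0_label0", label0); wr("axis0_label1", label1); wr("axis0_label2", label2)
  wr("block0_items_level0", level0); wr("block0_items_level1", level1)
  wr("block0_items_level2", level2)
  wr("block0_items_label0", label0); wr("block0_items_label1", label1)
  wr("block0_items_label2", label2)
  wr("axis1", as.integer(frames))
  # a pandas-written block reads back through rhdf5 as a (n_cols, n_rows)
  # matrix, so write the transpose to reproduce the layout byte-for-byte
  wr("block0_values", t(wide))

  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, key)
  wattr <- function(id, name, value) {
    # pytables only decodes string attributes written with the UTF-8 cset;
    # variable-length avoids a trailing NUL in the stored value
    rhdf5::h5writeAttribute(value, id, name, asScalar = TRUE,
                            encoding = if (is.character(value)) "UTF-8",
                            variableLengthString = is.character(value))
  }
  wattr(gid, "pandas_type", "frame")
  wattr(gid, "pandas_version", "0.15.2")
  wattr(gid, "encoding", "UTF-8")
  wattr(gid, "errors", "strict")
  wattr(gid, "ndim", 2L)
  wattr(gid, "nblocks", 1L)
  wattr(gid, "axis0_variety", "multi")
  wattr(gid, "axis1_variety", "regular")
  wattr(gid, "axis0_nlevels", 3L)
  wattr(gid, "block0_items_nlevels", 3L)
  wattr(gid, "block0_items_variety", "multi")
  rhdf5::H5Gclose(gid)
  for (lvl in 0:2) {
    for (base in c("axis0", "block0_items")) {
      did <- rhdf5::H5Dopen(fid, paste0(key, "/", base, "_level", lvl))
      wattr(did, "kind", "string")
      wattr(did, "name", c("scorer", "bodyparts", "coords")[lvl + 1L])
      rhdf5::H5Dclose(did)
    }
  }
  did <- rhdf5::H5Dopen(fid, paste0(key, "/axis1"))
  wattr(did, "kind", "integer")
  rhdf5::H5Dclose(did)
  did <- rhdf5::H5Dopen(fid, paste0(key, "/block0_values"))
  wattr(did, "transposed", 1L)
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  invisible(path)
}
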