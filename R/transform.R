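#' Concatenate feature series
#'
#' Places the columns of several feature series side by side, aligned on
#' `frame` by intersection: frames present in only some inputs are dropped
#' (with an informational count), because scene filtering or thinning
#' legitimately desynchronizes series. Column names must not collide.
#'
#' @param ... Feature series, or a single list of them.
#' @return A `feature_series` with all input columns.
#' @export
concat_features <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1L && !is_feature_series(inputs[[1]])) {
    inputs <- inputs[[1]]
  }
  if (!length(inputs)) {
    stop_fbbc("Need at least one feature series.", "fbbc_argument_error")
  }
  if (!all(vapply(inputs, is_feature_series, logical(1)))) {
    stop_fbbc("All inputs must be feature_series.", "fbbc_argument_error")
  }
  if (length(inputs) == 1L) return(inputs[[1]])

  all_cols <- unlist(lapply(inputs, feature_columns))
  if (anyDuplicated(all_cols)) {
    stop_fbbc(sprintf("Duplicate feature column(s) across inputs: %s.",
                      paste(unique(all_cols[duplicated(all_cols)]),
                            collapse = ", ")),
              "fbbc_naming_error")
  }
  frames <- Reduce(intersect, lapply(inputs, function(s) s$frame))
  if (!length(frames)) {
    stop_fbbc("Inputs share no frames; nothing to concatenate.",
              "fbbc_degenerate_input")
  }
  frames <- sort(frames)
  dropped <- sum(vapply(inputs, nrow, integer(1))) - length(frames) * length(inputs)
  if (dropped > 0) {
    inform(sprintf("concat_features: dropped %d row(s) outside the common frame set.",
                   dropped))
  }
  out <- inputs[[1]][match(frames, inputs[[1]]$frame), c("frame", "time_ms")]
  for (s in inputs) {
    out[feature_columns(s)] <-
      s[match(frames, s$frame), feature_columns(s), drop = FALSE]
  }
  feature_series(out, fps = attr(inputs[[1]], "fps"),
                 provenance = list(
                   op = "concat",
                   inputs = lapply(inputs, provenance),
                   dropped_rows = max(dropped, 0)))
}

#' Min-max normalize feature columns
#'
#' Maps each selected column independently onto \[0, 1\] by
#' `(x - min) / (max - min)` over its non-missing values, so that features
#' with very different ranges (pixel coordinates vs px^2 cross products)
#' contribute comparably to the embedding. Missing values stay missing.
#' A constant column has no range and is mapped to all zeros (with a
#' warning) rather than NaN, so it cannot poison the embedding input.
#'
#' @param series A `feature_series`.
#' @param columns Columns to normalize (default: all feature columns).
#' @return The normalized `feature_series`.
#' @export
minmax_normalize <- function(series, columns = NULL) {
  columns <- columns %||% feature_columns(series)
  missing_cols <- setdiff(columns, names(series))
  if (length(missing_cols)) {
    stop_fbbc(paste0("Unknown column(s): ", paste(missing_cols, collapse = ", "), "."),
              "fbbc_lookup_error")
  }
  for (cl in columns) {
    v <- series[[cl]]
    rng <- suppressWarnings(range(v, na.rm = TRUE))
    if (!is.finite(rng[1])) next  # all-missing column: leave as is
    if (rng[1] == rng[2]) {
      warn(sprintf("minmax_normalize: column '%s' is constant; mapped to 0.", cl))
      series[[cl]] <- ifelse(is.na(v), NA_real_, 0)
    } else {
      series[[cl]] <- (v - rng[1]) / (rng[2] - rng[1])
    }
  }
  prov <- provenance(series)
  prov$normalized <- union(prov$normalized, columns)
  attr(series, "provenance") <- prov
  series
}

#' Binarize a feature column
#'
#' Values at or above the threshold become 1, values below become 0
#' (`x >= threshold -> 1`); missing stays missing.
#'
#' @param series A `feature_series`.
#' @param column Column name.
#' @param threshold Threshold value.
#' @return The `feature_series` with the column binarized in place.
#' @export
binarize <- function(series, column, threshold) {
  if (!column %in% names(series)) {
    stop_fbbc(sprintf("Unknown column '%s'.", column), "fbbc_lookup_error")
  }
  check_scalar_number(threshold, "threshold")
  v <- series[[column]]
  series[[column]] <- ifelse(is.na(v), NA_real_, as.double(v >= threshold))
  series
}

#' Element-wise arithmetic between two feature columns
#'
#' Appends `a <op> b` as a new column. Division by zero yields missing (with
#' an informational count); missing operands propagate.
#'
#' @param series A `feature_series`.
#' @param column_a,column_b Operand column names.
#' @param op `"add"`, `"subtract"`, `"multiply"` or `"divide"`.
#' @param out Name of the appended column.
#' @return The `feature_series` with the extra column.
#' @export
feature_arithmetic <- function(series, column_a, column_b,
                               op = c("add", "subtract", "multiply", "divide"),
                               out) {
  op <- match.arg(op)
  for (cl in c(column_a, column_b)) {
    if (!cl %in% names(series)) {
      stop_fbbc(sprintf("Unknown column '%s'.", cl), "fbbc_lookup_error")
    }
  }
  if (out %in% names(series)) {
    stop_fbbc(sprintf("Output column '%s' already exists.", out),
              "fbbc_naming_error")
  }
  a <- series[[column_a]]
  b <- series[[column_b]]
  v <- switch(op,
    add = a + b,
    subtract = a - b,
    multiply = a * b,
    divide = {
      zero <- !is.na(b) & b == 0
      if (any(zero)) {
        inform(sprintf("feature_arithmetic: %d division(s) by zero set to missing.",
                       sum(zero)))
      }
      r <- a / b
      r[zero] <- NA_real_
      r
    }
  )
  series[[out]] <- v
  series
}
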