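#' Dwell-density map of a keypoint
#'
#' Where did a keypoint spend its time? A Gaussian product-kernel density of
#' the keypoint's (x, y) observations, evaluated at the centers of a regular
#' grid over the frame (or data) extent. High values mark locations where the
#' keypoint dwelt; overlaying the map on a video frame visualises e.g. how an
#' upper body shifted side to side during a task. The grid is scaled so the
#' discrete bin-weighted sum approximates 1 when the grid covers the mass of
#' the distribution.
#'
#' @param track A single-person `track_series`.
#' @param keypoint_id Keypoint id.
#' @param grid `c(width_bins, height_bins)`.
#' @param bandwidth Kernel standard deviation in px; a scalar or `c(bx, by)`.
#'   Default: Silverman-style rule per axis ([stats::bw.nrd0()]).
#' @param extent Optional `c(xmin, xmax, ymin, ymax)`. Defaults to the
#'   track's `frame_size` when known, else the data range padded by 4
#'   bandwidths.
#' @return A `kde_dwell` list: bin centers `x`, `y`, density matrix `z`
#'   (rows follow `x`, columns follow `y`), `bandwidth`, number of
#'   observations `n` and the bin area.
#' @export
kde_dwell <- function(track, keypoint_id, grid = c(64L, 48L),
                      bandwidth = NULL, extent = NULL) {
  co <- kp_coords(track, keypoint_id)
  x <- co[[paste0("x", keypoint_id)]]
  y <- co[[paste0("y", keypoint_id)]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) {
    stop_fbbc("KDE needs at least 2 non-missing observations.",
              "fbbc_degenerate_input")
  }
  grid <- c(check_count(grid[1], "grid[1]"), check_count(grid[2], "grid[2]"))
  if (is.null(bandwidth)) {
    bandwidth <- c(bw.nrd0(x), bw.nrd0(y))
    # bw.nrd0 degenerates to 0 on constant data; fall back to 1 px
    bandwidth[bandwidth <= 0] <- 1
  }
  bandwidth <- rep(as.double(bandwidth), length.out = 2L)
  if (any(bandwidth <= 0)) {
    stop_fbbc("`bandwidth` must be > 0.", "fbbc_argument_error")
  }
  if (is.null(extent)) {
    fs <- attr(track, "frame_size")
    extent <- if (!is.null(fs)) {
      c(0, fs[1], 0, fs[2])
    } else {
      c(range(x) + c(-4, 4) * bandwidth[1],
        range(y) + c(-4, 4) * bandwidth[2])
    }
  }
  cx <- seq(extent[1], extent[2], length.out = grid[1] + 1L)
  cy <- seq(extent[3], extent[4], length.out = grid[2] + 1L)
  bin_area <- diff(cx[1:2]) * diff(cy[1:2])
  cx <- (cx[-1] + cx[-length(cx)]) / 2
  cy <- (cy[-1] + cy[-length(cy)]) / 2

  # mixture of n Gaussian product kernels, evaluated as an outer product of
  # the per-axis kernel matrices: z = Kx %*% t(Ky) / n
  kx <- outer(cx, x, function(c, m) dnorm(c, mean = m, sd = bandwidth[1]))
  ky <- outer(cy, y, function(c, m) dnorm(c, mean = m, sd = bandwidth[2]))
  z <- kx %*% t(ky) / length(x)

  structure(
    list(x = cx, y = cy, z = z, bandwidth = bandwidth, n = length(x),
         bin_area = bin_area, keypoint = keypoint_id),
    class = "kde_dwell"
  )
}

#' @export
print.kde_dwell <- function(x, ...) {
  cat(sprintf(
    "<kde_dwell: keypoint %d, %d x %d grid, bandwidth (%.3g, %.3g) px, n = %d>\n",
    x$keypoint, length(x$x), length(x$y), x$bandwidth[1], x$bandwidth[2], x$n))
  invisible(x)
}
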