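#' Sliding-window grid over a genomic region
#'
#' Builds the half-open sliding windows used by all window-based sweep
#' statistics. Coordinates are 0-based base pairs; a window is
#' `[start, start + width)`. The number of windows is
#' `floor((L - width) / step) + 1`, so a 600-kb region scanned with 100-kb
#' windows advancing in 10-kb steps yields 51 windows.
#'
#' @param region_length Region length L in bp.
#' @param width Window width in bp; must satisfy `0 < width <= L`.
#' @param step Step size in bp; must be positive.
#'
#' @return An object of class `window_grid`: a list with `region_length`,
#'   `width`, `step`, and a two-column matrix `windows` (`start`, `end`).
#' @examples
#' wg <- make_windows(600000, 100000, 10000)
#' nrow(wg$windows)  # 51
#' @export
make_windows <- function(region_length, width, step) {
  stopifnot(length(region_length) == 1, length(width) == 1, length(step) == 1)
  if (!(width > 0 && width <= region_length)) {
    stop("window width must satisfy 0 < width <= region_length")
  }
  if (step <= 0) stop("step must be positive")
  n <- floor((region_length - width) / step) + 1
  start <- (seq_len(n) - 1) * step
  windows <- cbind(start = start, end = start + width)
  structure(
    list(region_length = region_length, width = width, step = step,
         windows = windows),
    class = "window_grid"
  )
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("window_grid: %d windows of %g bp (step %g) over [0, %g)\n",
              nrow(x$windows), x$width, x$step, x$region_length))
  invisible(x)
}

#' @export
length.window_grid <- function(x) nrow(x$windows)

# Index of the window (row of grid$windows) each position falls into is not
# unique under overlapping windows; helper returns logical membership matrix
# windows x positions. Used internally by per-window statistics.
window_membership <- function(grid, positions) {
  w <- grid$windows
  outer(w[, "start"], positions, "<=") & outer(w[, "end"], positions, ">")
}
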