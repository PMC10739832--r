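#' Normalized time grid for movement curves
#'
#' Movement cycles are compared on a common grid of equally spaced
#' normalized-time points (percent of movement).  The conventional grid in
#' human-movement analysis has 101 frames, numbered 0 to 100, covering the
#' start and end of the cycle.
#'
#' @param n_frames Number of equally spaced frames, at least 2.
#' @param t_min,t_max Endpoints of the normalized-time domain.
#'
#' @return An object of class `frame_grid`: a list with `n_frames`, `t_min`,
#'   `t_max` and the vector of grid `points`.
#' @examples
#' frame_grid()
#' frame_grid(51)
#' @export
frame_grid <- function(n_frames = 101, t_min = 0, t_max = n_frames - 1) {
  if (!is.numeric(n_frames) || length(n_frames) != 1L || n_frames < 2 ||
      n_frames != round(n_frames)) {
    abort("`n_frames` must be a single integer >= 2.")
  }
  if (t_max <= t_min) abort("`t_max` must exceed `t_min`.")
  structure(
    list(
      n_frames = as.integer(n_frames),
      t_min = as.numeric(t_min),
      t_max = as.numeric(t_max),
      points = seq(t_min, t_max, length.out = n_frames)
    ),
    class = "frame_grid"
  )
}

#' @export
print.frame_grid <- function(x, ...) {
  cat(sprintf("<frame_grid> %d frames on [%g, %g]\n", x$n_frames, x$t_min, x$t_max))
  invisible(x)
}

is_frame_grid <- function(x) inherits(x, "frame_grid")

# Infer the grid from a long table's 0-based `frame` column.
grid_from_frames <- function(frames) {
  frames <- sort(unique(as.integer(frames)))
  n <- max(frames) + 1L
  if (!identical(frames, 0:(n - 1L))) {
    abort("`frame` values must form a complete 0..(n_frames-1) range.")
  }
  frame_grid(n)
}
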