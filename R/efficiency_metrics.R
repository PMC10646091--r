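# Temporal and spatial navigation efficiency: latency, path length/error,
# surface coverage, presence-probability grids.

#' Latency to the final location
#'
#' Trial duration in seconds: last timestamp minus first (trial onset to the
#' button press fixing the final location).
#'
#' @param traj a [trial_trajectory()].
#' @return seconds, non-negative.
#' @export
latency <- function(traj) {
  traj$t[length(traj$t)] - traj$t[1]
}

#' Traveled path length
#'
#' Sum of Euclidean segment lengths along the sampled polyline.
#'
#' @param xy n x 2 position matrix, or a [trial_trajectory()].
#' @return meters.
#' @export
path_length <- function(xy) {
  if (inherits(xy, "trial_trajectory")) xy <- positions(xy)
  xy <- rbind(xy)
  if (nrow(xy) < 2) stop("need at least 2 points")
  sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
}

#' Path error (percent excess path length)
#'
#' Percentage by which the traveled path exceeds the ideal path, the straight
#' segment from the start to the final location:
#' `100 * (actual - ideal) / ideal`. Ranges from 0 (straight path) upward.
#' Degenerate trials whose start coincides with the final location (ideal
#' length below `tol`) yield `NA` rather than infinity.
#'
#' @param traj a [trial_trajectory()].
#' @param tol minimum ideal path length in meters.
#' @return percent, or `NA` for degenerate trials.
#' @export
path_error <- function(traj, tol = 1e-6) {
  xy <- positions(traj)
  ideal <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
  if (ideal < tol) {
    warning("start and final location coincide; path error undefined")
    return(NA_real_)
  }
  100 * (path_length(xy) - ideal) / ideal
}

#' Surface coverage (percent of arena area)
#'
#' Bounding-box estimate of the arena surface visited:
#' `100 * pi * |x_min - x_max| * |y_min - y_max| / (pi * radius^2)`,
#' using the full bounding-box widths. Because full widths (not semi-axes)
#' enter the numerator, a trajectory spanning the whole bounding square
#' evaluates to 400; the conventional inscribed-ellipse variant with
#' semi-axes (maximum 100 for that square) is available with
#' `semi_axes = TRUE`.
#'
#' @param traj a [trial_trajectory()].
#' @param arena an [arena_config()].
#' @param semi_axes use half-widths (ellipse semi-axes) instead of the
#'   default full widths.
#' @return percent (may exceed 100 in the default form).
#' @export
surface_coverage <- function(traj, arena = arena_config(), semi_axes = FALSE) {
  w <- abs(min(traj$x) - max(traj$x))
  h <- abs(min(traj$y) - max(traj$y))
  if (semi_axes) { w <- w / 2; h <- h / 2 }
  100 * (pi * w * h) / (pi * arena$radius^2)
}

#' Presence-probability map
#'
#' For each cell of the `grid_n` x `grid_n` grid over the arena's bounding
#' square, the fraction of trials whose path passed through the cell. A cell
#' counts as visited when any position sample falls inside it; at 60-90 Hz
#' and walking speed (1.4 m/s) consecutive samples cannot skip a cell.
#'
#' @param trials list of [trial_trajectory()] objects (or of
#'   `list(meta=, trajectory=)` pairs).
#' @param arena an [arena_config()].
#' @return an object of class `presence_map`: list with `grid`
#'   (probabilities in `[0, 1]`) and `bounds`.
#' @export
presence_map <- function(trials, arena = arena_config()) {
  if (length(trials) < 1) stop("need at least one trial")
  trials <- lapply(trials, function(tr) {
    if (inherits(tr, "trial_trajectory")) tr else tr$trajectory
  })
  acc <- matrix(0, arena$grid_n, arena$grid_n)
  for (tr in trials) acc <- acc + cells_visited(tr, arena)
  structure(
    list(grid = acc / length(trials),
         bounds = c(-arena$radius, arena$radius)),
    class = "presence_map")
}
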