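# Navigation-strategy measures: search accuracy (average distance to the
# final location), landmark use (idPhi), and path replication (rotation-
# aligned, normalized DTW trajectory distance).

#' Average distance to the final location
#'
#' Search-accuracy measure: the mean over all samples of the Euclidean
#' distance to the trial's final location. Low values indicate a focused
#' search near the eventual response; high values diffuse or remote search.
#'
#' @param traj a [trial_trajectory()].
#' @param arena an [arena_config()], used only when `normalize = TRUE`.
#' @param normalize divide by the arena diameter (dimensionless output).
#' @return meters (or dimensionless).
#' @export
avg_distance_to_final <- function(traj, arena = arena_config(),
                                  normalize = FALSE) {
  fin <- final_location(traj)
  d <- mean(sqrt((traj$x - fin[1])^2 + (traj$y - fin[2])^2))
  if (normalize) d <- d / (2 * arena$radius)
  d
}

#' Initial angular velocity (idPhi)
#'
#' Landmark-use measure: the mean absolute per-sample yaw change over the
#' initial time window of the trial (default 5 s), computed on the unwrapped,
#' low-pass filtered yaw channel. Higher values reflect more lateral head
#' rotation, i.e. more intense visual exploration of the surrounding
#' landmarks; the statistic is the classic idPhi index of vicarious
#' trial-and-error.
#'
#' The raw unit is radians per sample step (the sum of absolute differences
#' divided by their count), which depends on the sampling rate;
#' `per_second = TRUE` multiplies by the sampling rate for a rate-independent
#' rad/s variant.
#'
#' @param traj a [trial_trajectory()].
#' @param arena an [arena_config()] providing window length and filter cutoff.
#' @param preprocess unwrap and low-pass filter the yaw channel first
#'   (set `FALSE` if the trajectory already carries preprocessed yaw).
#' @param per_second report radians per second instead of per sample step.
#' @return non-negative scalar; `NA` when the window holds fewer than two
#'   samples. Attribute `window_truncated` flags trials shorter than the
#'   window.
#' @export
initial_angular_velocity <- function(traj, arena = arena_config(),
                                     preprocess = TRUE, per_second = FALSE) {
  yaw <- if (preprocess) preprocess_yaw(traj, arena) else traj$yaw
  keep <- traj$t < traj$t[1] + arena$idphi_window
  truncated <- all(keep)
  yw <- yaw[keep]
  if (length(yw) < 2) return(structure(NA_real_, window_truncated = truncated))
  v <- mean(abs(diff(yw)))
  if (per_second) v <- v * traj$sampling_rate
  structure(v, window_truncated = truncated)
}

#' Dynamic time warping with squared-Euclidean local cost
#'
#' Classic dynamic-programming DTW between two 2-D point sequences: local
#' cost is the squared Euclidean distance, steps are `{(1,0), (0,1), (1,1)}`
#' with unit weights, and the alignment spans both sequences end to end. The
#' accumulated cost is the minimum over all admissible warping paths.
#'
#' @param a,b n x 2 position matrices or [trial_trajectory()] objects.
#' @param keep_path also compute and return the optimal warping path
#'   (requires the full `m` x `n` cost matrix; disable for long
#'   trajectories when only the cost is needed).
#' @return an object of class `dtw_result`: list with `cost`, `path`
#'   (L x 2 matrix of 1-based index pairs, or `NULL`), `m`, `n`, and
#'   `normalized_distance = sqrt(cost / max(m, n))`.
#' @examples
#' a <- cbind(c(0, 2), c(0, 0))
#' b <- cbind(c(0, 1, 2), c(0, 0, 0))
#' dtw_squared(a, b)$cost  # 1
#' @export
dtw_squared <- function(a, b, keep_path = TRUE) {
  a <- as_xy(a); b <- as_xy(b)
  if (nrow(a) < 1 || nrow(b) < 1) stop("empty input sequence")
  if (keep_path) {
    res <- .dtw_path_cpp(a, b)
    cost <- res$cost; path <- res$path
  } else {
    cost <- .dtw_cost_cpp(a, b)
    path <- NULL
  }
  structure(
    list(cost = cost, path = path, m = nrow(a), n = nrow(b),
         normalized_distance = sqrt(cost / max(nrow(a), nrow(b)))),
    class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> cost %.4f over %d x %d, normalized %.4f\n",
              x$cost, x$m, x$n, x$normalized_distance))
  invisible(x)
}

as_xy <- function(p) {
  if (inherits(p, "trial_trajectory")) return(positions(p))
  p <- rbind(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2) stop("point sequences must be n x 2")
  p
}

#' Trajectory distance (path replication measure)
#'
#' Rotation-aligned, length-normalized DTW distance between the last learning
#' trajectory of a block and a probe trajectory. Each trajectory is first
#' rotated about the arena center by the angle that maps its first sample
#' onto the canonical ray (angle 0, radius preserved) — this removes the
#' designed probe-start rotation — and the distance is then
#' `sqrt(dtw_cost / max(m, n))`, the accumulated squared-Euclidean DTW cost
#' divided by the minimal admissible warping-path length. A probe identical
#' to the learning path up to a rotation about the center scores 0; low
#' values indicate egocentric route replay.
#'
#' @param last_learning,probe [trial_trajectory()] objects (or n x 2
#'   matrices). Both must start strictly off-center.
#' @param arena an [arena_config()].
#' @return non-negative normalized distance.
#' @export
trajectory_distance <- function(last_learning, probe,
                                arena = arena_config()) {
  a <- align_to_canonical_ray(as_xy(last_learning), arena, "learning")
  b <- align_to_canonical_ray(as_xy(probe), arena, "probe")
  cost <- .dtw_cost_cpp(a, b)
  sqrt(cost / max(nrow(a), nrow(b)))
}

align_to_canonical_ray <- function(xy, arena, label) {
  v <- xy[1, ] - arena$center
  if (sqrt(sum(v^2)) < 1e-9)
    stop(sprintf("%s trajectory starts at the arena center; ", label),
         "rotation alignment is undefined")
  rotate_points(xy, -atan2(v[2], v[1]), center = arena$center)
}
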