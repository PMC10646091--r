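# Shared fixtures and independent oracles for the test suite.

# Straight-line trajectory between two points.
make_line_traj <- function(from = c(-3, 0), to = c(1, 1), n = 50, fs = 60,
                           yaw = NULL) {
  tt <- (seq_len(n) - 1) / fs
  x <- seq(from[1], to[1], length.out = n)
  y <- seq(from[2], to[2], length.out = n)
  if (is.null(yaw)) yaw <- rep(atan2(to[2] - from[2], to[1] - from[1]), n)
  trial_trajectory(tt, x, y, yaw, sampling_rate = fs)
}

# Trajectory through an explicit list of waypoints (one sample each).
make_poly_traj <- function(xy, fs = 60, yaw = NULL) {
  n <- nrow(xy)
  if (is.null(yaw)) yaw <- rep(0, n)
  trial_trajectory((seq_len(n) - 1) / fs, xy[, 1], xy[, 2], yaw,
                   sampling_rate = fs)
}

rand_unit_quat <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

# Rotation matrix from a unit quaternion (w, x, y, z), right-handed.
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Yaw of a rotation matrix about the +z axis: heading of the rotated +x axis.
yaw_from_matrix <- function(M) atan2(M[2, 1], M[1, 1])

# Exhaustive DTW oracle: enumerate every admissible warping path.
dtw_enumerate <- function(a, b) {
  m <- nrow(a); n <- nrow(b)
  cost <- function(i, j) sum((a[i, ] - b[j, ])^2)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + cost(i, j)
    if (i == m && j == n) {
      best <<- min(best, acc)
      return(invisible(NULL))
    }
    if (i < m) walk(i + 1, j, acc)
    if (j < n) walk(i, j + 1, acc)
    if (i < m && j < n) walk(i + 1, j + 1, acc)
    invisible(NULL)
  }
  walk(1, 1, 0)
  best
}

# Independent top-down memoized DTW recursion (distinct code path from the
# package's bottom-up C++ dynamic program).
dtw_memo <- function(a, b) {
  m <- nrow(a); n <- nrow(b)
  memo <- matrix(NA_real_, m, n)
  cost <- function(i, j) sum((a[i, ] - b[j, ])^2)
  rec <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- if (i == 1 && j == 1) {
      cost(1, 1)
    } else {
      best <- Inf
      if (i > 1) best <- min(best, rec(i - 1, j))
      if (j > 1) best <- min(best, rec(i, j - 1))
      if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
      best + cost(i, j)
    }
    memo[i, j] <<- v
    v
  }
  rec(m, n)
}

test_arena <- function(...) arena_config(...)

# Random point well inside the arena (for target/response draws).
runif_target <- function(arena) {
  repeat {
    p <- stats::runif(2, -arena$radius, arena$radius)
    if (sqrt(sum(p^2)) < 0.95 * arena$radius) return(p)
  }
}

positions_of <- function(traj) cbind(traj$x, traj$y)

# Independent rotation alignment onto the canonical ray (arena center at 0).
align_oracle <- function(xy) {
  ang <- atan2(xy[1, 2], xy[1, 1])
  rotate_pts(xy, -ang)
}

rotate_pts <- function(xy, ang) {
  cbind(cos(ang) * xy[, 1] - sin(ang) * xy[, 2],
        sin(ang) * xy[, 1] + cos(ang) * xy[, 2])
}

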