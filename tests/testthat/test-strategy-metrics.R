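arena <- test_arena()

test_that("average distance to the final location is the per-sample mean", {
  still <- make_poly_traj(matrix(rep(c(1, 1), 5), 5, 2, byrow = TRUE))
  expect_equal(avg_distance_to_final(still), 0)

  # samples at distances 3, 1 and 0 from the final location
  tr <- make_poly_traj(rbind(c(-3, 0), c(-1, 0), c(0, 0)))
  expect_equal(avg_distance_to_final(tr), (3 + 1 + 0) / 3)

  set.seed(14)
  xy <- matrix(stats::rnorm(60, sd = 0.9), 30, 2)
  tr <- make_poly_traj(xy)
  fin <- xy[30, ]
  oracle <- mean(apply(xy, 1, function(p) sqrt(sum((p - fin)^2))))
  expect_equal(avg_distance_to_final(tr), oracle, tolerance = 1e-12)
  expect_equal(avg_distance_to_final(tr, arena, normalize = TRUE),
               oracle / 7.6)
})

test_that("idPhi is the mean absolute yaw change in the initial window", {
  n <- 400
  const <- make_line_traj(c(-3, 0), c(1, 0), n = n, yaw = rep(1.2, n))
  expect_equal(as.numeric(initial_angular_velocity(const, arena,
                                                   preprocess = FALSE)), 0)

  ramp <- make_line_traj(c(-3, 0), c(1, 0), n = n,
                         yaw = 0.1 * (seq_len(n) - 1))
  expect_equal(as.numeric(initial_angular_velocity(ramp, arena,
                                                   preprocess = FALSE)), 0.1)

  # only samples within the first five seconds enter
  fs <- 60
  yaw <- c(0.05 * seq_len(5 * fs), rep(0.05 * 5 * fs, 5 * fs))
  tr <- trial_trajectory((seq_along(yaw) - 1) / fs, seq_along(yaw) * 1e-3,
                         rep(0, length(yaw)), yaw, fs)
  v <- initial_angular_velocity(tr, arena, preprocess = FALSE)
  expect_equal(as.numeric(v), 0.05)
  expect_false(attr(v, "window_truncated"))

  # sinusoidal yaw against a brute-force differencing oracle
  tt <- (0:(5 * fs)) / fs
  syaw <- 0.8 * sin(2 * pi * 1 * tt)
  tr <- trial_trajectory(tt, tt * 0.1, rep(0, length(tt)), syaw, fs)
  oracle <- mean(abs(diff(syaw[tt < 5])))
  expect_equal(as.numeric(initial_angular_velocity(tr, arena,
                                                   preprocess = FALSE)),
               oracle, tolerance = 1e-12)

  # per-second variant scales by the sampling rate
  expect_equal(as.numeric(initial_angular_velocity(tr, arena,
                                                   preprocess = FALSE,
                                                   per_second = TRUE)),
               oracle * fs, tolerance = 1e-12)
})

test_that("DTW solves the textbook cases", {
  ident <- matrix(stats::rnorm(20), 10, 2)
  r <- dtw_squared(ident, ident)
  expect_equal(r$cost, 0)
  expect_equal(r$path, cbind(1:10, 1:10))
  expect_equal(r$normalized_distance, 0)

  r <- dtw_squared(rbind(c(0, 0), c(2, 0)), rbind(c(0, 0), c(1, 0), c(2, 0)))
  expect_equal(r$cost, 1)  # exhaustive enumeration gives 1 for this pair
  expect_equal(r$normalized_distance, sqrt(1 / 3))

  # single point vs k points: every pairing is forced
  a <- rbind(c(0.5, -0.5))
  b <- matrix(stats::rnorm(10), 5, 2)
  forced <- sum(apply(b, 1, function(p) sum((p - a)^2)))
  expect_equal(dtw_squared(a, b)$cost, forced)
  expect_error(dtw_squared(a[0, , drop = FALSE], b), "empty")
})

test_that("DTW equals exhaustive path enumeration and is symmetric", {
  set.seed(77)
  for (k in 1:60) {
    m <- sample(1:5, 1); n <- sample(1:5, 1)
    a <- matrix(stats::rnorm(2 * m), m, 2)
    b <- matrix(stats::rnorm(2 * n), n, 2)
    expect_equal(dtw_squared(a, b)$cost, dtw_enumerate(a, b),
                 tolerance = 1e-12)
    expect_equal(dtw_squared(a, b)$cost, dtw_squared(b, a)$cost,
                 tolerance = 1e-12)
  }
})

test_that("DTW warping paths are admissible and trace the reported cost", {
  set.seed(78)
  for (k in 1:20) {
    m <- sample(2:9, 1); n <- sample(2:9, 1)
    a <- matrix(stats::rnorm(2 * m), m, 2)
    b <- matrix(stats::rnorm(2 * n), n, 2)
    r <- dtw_squared(a, b)
    p <- r$path
    expect_equal(p[1, ], c(1, 1))
    expect_equal(p[nrow(p), ], c(m, n))
    steps <- diff(p)
    expect_true(all(steps %in% 0:1) && all(rowSums(steps) >= 1))
    expect_gte(nrow(p), max(m, n))
    traced <- sum(vapply(seq_len(nrow(p)), function(i)
      sum((a[p[i, 1], ] - b[p[i, 2], ])^2), numeric(1)))
    expect_equal(traced, r$cost, tolerance = 1e-9)
  }
})

test_that("trajectory distance removes rotations about the center", {
  learn <- make_line_traj(c(-3.7, 0), c(1.2, 0.8), n = 120)
  expect_equal(trajectory_distance(learn, learn, arena), 0, tolerance = 1e-9)

  for (ang in c(90, 180, 270)) {
    xy <- rotate_pts(positions_of(learn), ang * pi / 180)
    probe <- make_poly_traj(xy)
    expect_equal(trajectory_distance(learn, probe, arena), 0,
                 tolerance = 1e-9)
  }

  # invariance to a global rotation of BOTH trajectories
  probe <- make_line_traj(c(0, -3.7), c(1.0, 1.0), n = 95)
  d0 <- trajectory_distance(learn, probe, arena)
  expect_gt(d0, 0)
  gl <- 0.7
  d1 <- trajectory_distance(make_poly_traj(rotate_pts(positions_of(learn), gl)),
                            make_poly_traj(rotate_pts(positions_of(probe), gl)),
                            arena)
  expect_equal(d1, d0, tolerance = 1e-9)

  centered <- make_poly_traj(rbind(c(0, 0), c(1, 0)))
  expect_error(trajectory_distance(centered, probe, arena), "center")
})

test_that("trajectory distance matches the brute-force DTW oracle on short paths", {
  # straight learning path from (r, 0) to the target vs the allocentric
  # shortcut from the 180-degree-rotated start, resampled to <= 12 points
  tgt <- c(1.0, 0.9)
  learn <- make_line_traj(c(3.7, 0), tgt, n = 10)
  probe <- make_line_traj(c(-3.7, 0), tgt, n = 12)
  a <- align_oracle(positions_of(learn))
  b <- align_oracle(positions_of(probe))
  want <- sqrt(dtw_memo(a, b) / max(nrow(a), nrow(b)))
  expect_equal(trajectory_distance(learn, probe, arena), want,
               tolerance = 1e-12)
})
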