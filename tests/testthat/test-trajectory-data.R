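arena <- test_arena()

test_that("trajectory construction rejects invariant violations", {
  tt <- (0:9) / 60
  expect_error(trial_trajectory(tt, 1:9, 1:10, rep(0, 10), 60),
               "equal length")
  expect_error(trial_trajectory(0, 0, 0, 0, 60), "at least 2")
  bad_t <- c(0, 1, 1, 2) / 60
  expect_error(trial_trajectory(bad_t, 1:4, 1:4, rep(0, 4), 60),
               "strictly increasing")
  expect_error(trial_trajectory(tt, rep(10, 10), rep(0, 10), rep(0, 10), 60,
                                arena = arena),
               "outside arena wall")
  expect_error(trial_trajectory(tt, rep(0, 10), rep(0, 10), rep(0, 10), -1),
               "sampling_rate")
})

test_that("trial metadata enforces the probe-rotation and design rules", {
  tgt <- c(1, 1); fin <- c(0.5, 0.5)
  expect_error(trial_meta("p", "control", "stationary", 1, "probe", 1, 0,
                          NA, tgt, fin, arena = arena), "probe_rotation")
  expect_error(trial_meta("p", "control", "stationary", 1, "learning", 1, 0,
                          90, tgt, fin, arena = arena), "must be NA")
  expect_error(trial_meta("p", "control", "stationary", 1, "probe", 1, 17,
                          90, tgt, fin, arena = arena), "start_angle")
  expect_error(trial_meta("p", "control", "stationary", 1, "probe", 1, 0,
                          90, c(5, 5), fin, arena = arena), "outside")
  m <- trial_meta("p", "MTLR", "mobile", 2, "probe", 3, 120, 180, tgt, fin,
                  sampling_rate = 90, arena = arena)
  expect_s3_class(m, "trial_meta")
  expect_equal(m$probe_rotation, 180)
})

test_that("sessions round-trip through the CSV dialect to machine precision", {
  design <- generate_design(arena, seed = 11)
  sess <- simulate_block(design[[1]], agent_spec(seed = 4), arena, seed = 8,
                         participant = "P01")
  td <- withr::local_tempdir()
  tf <- file.path(td, "s_trajectories.csv")
  mf <- file.path(td, "s_meta.csv")
  write_session(sess, tf, mf)
  back <- read_session(tf, mf, arena)
  expect_length(back, length(sess))
  for (i in seq_along(sess)) {
    expect_identical(back[[i]]$trajectory$x, sess[[i]]$trajectory$x)
    expect_identical(back[[i]]$trajectory$t, sess[[i]]$trajectory$t)
    expect_identical(back[[i]]$trajectory$yaw, sess[[i]]$trajectory$yaw)
    expect_identical(back[[i]]$meta$target_location,
                     sess[[i]]$meta$target_location)
    expect_identical(back[[i]]$meta$final_location,
                     final_location(back[[i]]$trajectory))
  }
})

test_that("loader errors name the offending trial", {
  design <- generate_design(arena, seed = 11)
  sess <- simulate_block(design[[1]], agent_spec(seed = 4), arena, seed = 8,
                         participant = "P07")[1:2]
  td <- withr::local_tempdir()
  tf <- file.path(td, "t.csv"); mf <- file.path(td, "m.csv")
  write_session(sess, tf, mf)
  raw <- readLines(tf)
  # duplicate a timestamp inside trial 1
  raw[3] <- raw[2]
  writeLines(raw, tf)
  expect_error(read_session(tf, mf, arena), "P07/stationary/1/learning/1")
})

test_that("quaternion orientation columns are converted on load", {
  td <- withr::local_tempdir()
  n <- 5
  traj <- data.frame(participant = "p", setup = "stationary", block = 1,
                     trial_type = "learning", trial_index = 1,
                     t = (0:(n - 1)) / 60, x = seq(0, 1, length.out = n),
                     y = 0, qw = 1, qx = 0, qy = 0, qz = 0)
  meta <- data.frame(participant = "p", group = "control",
                     setup = "stationary", block = 1,
                     trial_type = "learning", trial_index = 1,
                     start_angle = 0, probe_rotation = NA,
                     target_x = 1, target_y = 1, sampling_rate = 60)
  write.csv(traj, file.path(td, "q_trajectories.csv"), row.names = FALSE)
  write.csv(meta, file.path(td, "q_meta.csv"), row.names = FALSE)
  sess <- read_session(file.path(td, "q_trajectories.csv"),
                       file.path(td, "q_meta.csv"), arena)
  expect_equal(sess[[1]]$trajectory$yaw, rep(0, n))
})

test_that("metric tables keep missing values as empty cells and round-trip", {
  rec <- data.frame(participant = "p", trial_type = "learning",
                    memory_score = NA_real_, latency = 12.3456789012345678,
                    trajectory_distance = NA_real_)
  td <- withr::local_tempdir()
  out <- file.path(td, "metrics.csv")
  write_metrics(rec, out)
  lines <- readLines(out)
  expect_length(lines, 2)                     # header + one data row
  expect_match(lines[2], ",,", fixed = TRUE)  # NA written as empty, not 0
  back <- read_metrics(out)
  expect_identical(back$latency, rec$latency)
  expect_true(is.na(back$trajectory_distance))
  expect_error(write_metrics(rec[0, ], out), "non-empty")
})
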