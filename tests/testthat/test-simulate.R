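arena <- test_arena()

test_that("designs satisfy the task geometry", {
  for (s in c(1, 42, 999)) {
    d <- generate_design(arena, seed = s)
    expect_length(d, 6)
    expect_setequal(vapply(d, `[[`, numeric(1), "start_angle"),
                    seq(0, 300, by = 60))
    for (e in d) {
      expect_setequal(e$probe_rotations, c(0, 90, 180, 270))
      expect_gte(e$target_distance, 0.2 * arena$radius)  # 0.76 m
      expect_lte(e$target_distance, 0.8 * arena$radius)  # 3.04 m
      # target on a quadrant center axis relative to the start
      rel <- (atan2(e$target[2], e$target[1]) * 180 / pi - e$start_angle) %% 360
      expect_true(min(abs(rel - c(45, 135, 225, 315))) < 1e-9)
    }
  }
  expect_identical(generate_design(arena, 5), generate_design(arena, 5))
})

test_that("blocks hold 3 learning + 4 probe trials and respect the wall", {
  d <- generate_design(arena, seed = 2)
  blk <- simulate_block(d[[3]], agent_spec(seed = 9), arena, seed = 17)
  expect_length(blk, 7)
  types <- vapply(blk, function(tr) tr$meta$trial_type, character(1))
  expect_equal(types, c(rep("learning", 3), rep("probe", 4)))
  rots <- vapply(blk[4:7], function(tr) tr$meta$probe_rotation, numeric(1))
  expect_setequal(rots, c(0, 90, 180, 270))
  for (tr in blk) {
    expect_silent(validate_trajectory(tr$trajectory, arena))
    expect_equal(tr$meta$final_location, positions_of(tr$trajectory)[
      length(tr$trajectory$x), ])
  }
})

test_that("a noiseless direct agent navigates optimally", {
  d <- generate_design(arena, seed = 3)
  ag <- agent_spec(goal_noise_sigma = 0, heading_noise_sigma = 0,
                   scan_duration = 0, seed = 1)
  blk <- simulate_block(d[[1]], ag, arena, seed = 1)
  for (tr in blk[4:7]) {
    expect_lt(suppressWarnings(path_error(tr$trajectory)), 1)
    expect_equal(memory_score(tr$meta$final_location, d[[1]]$target, arena,
                              seed = 5)$score, 100)
  }
})

test_that("egocentric replay reflects the learned final through the center", {
  d <- generate_design(arena, seed = 4)
  e <- d[[2]]
  ag <- agent_spec("path_replication", goal_noise_sigma = 0,
                   heading_noise_sigma = 0, scan_duration = 0, seed = 2)
  learn <- simulate_trial(e, "learning", agent = ag, arena = arena)
  probe <- simulate_trial(e, "probe", 180, agent = ag, arena = arena,
                          learned = learn$trajectory)
  expect_equal(probe$meta$final_location, -learn$meta$final_location,
               tolerance = 1e-6)
  # geometry oracle: the reflected endpoint is biased away from the target
  expect_lt(memory_score_analytic(probe$meta$final_location, e$target, arena),
            50)
  expect_error(simulate_trial(e, "probe", 90, ag, arena, learned = NULL),
               "no learning trajectory")
})

test_that("random search covers more surface than direct navigation", {
  d <- generate_design(arena, seed = 6)
  wins <- 0
  for (k in 1:20) {
    dir <- simulate_trial(d[[1]], "probe", 90,
                          agent_spec("direct", seed = 100 + k), arena)
    rs <- simulate_trial(d[[1]], "probe", 90,
                         agent_spec("random_search", max_duration = 15,
                                    seed = 100 + k), arena)
    wins <- wins + (surface_coverage(rs$trajectory, arena) >
                      surface_coverage(dir$trajectory, arena))
  }
  expect_equal(wins, 20)
})

test_that("cohorts are deterministic and correctly sized", {
  co1 <- simulate_cohort(c(MTLR = 1, control = 2), seed = 31)
  expect_length(co1$sessions, 6)          # 3 participants x 2 setups
  expect_equal(unname(vapply(co1$sessions, length, integer(1))),
               rep(42L, 6))               # 6 blocks x 7 trials
  expect_equal(co1$participants$group, c("MTLR", "control", "control"))
  fs <- vapply(co1$sessions[["P01.mobile"]], function(tr)
    tr$trajectory$sampling_rate, numeric(1))
  expect_true(all(fs == 90))

  co2 <- simulate_cohort(c(MTLR = 1, control = 2), seed = 31)
  expect_identical(
    lapply(co1$sessions, function(s) lapply(s, function(tr) tr$trajectory)),
    lapply(co2$sessions, function(s) lapply(s, function(tr) tr$trajectory)))
})

test_that("group effects shift agent parameters per group and setup", {
  fx <- list(MTLR.stationary = list(goal_noise_sigma = 2.0))
  ag <- adjust_agent(agent_spec(), fx$MTLR.stationary)
  expect_equal(ag$goal_noise_sigma, 2.0)
  expect_equal(ag$speed, 1.4)
})
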