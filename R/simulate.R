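# Synthetic navigator simulator: experiment designs, single-trial agent
# policies, and whole cohorts in the 2-group x 2-setup structure of the task.

#' Generate a reproducible experiment design
#'
#' Six blocks, one per start axis (0, 60, ..., 300 degrees, randomly ordered).
#' Each block's target lies on one of the quadrant center axes relative to
#' its start (relative angle -135, -45, +45 or +135 degrees) at a center
#' distance drawn uniformly from `[0.2, 0.8] * radius`, and carries a random
#' permutation of the four probe-start rotations (0, 90, 180, 270 degrees).
#' Each block comprises 3 learning and 4 probe trials.
#'
#' @param arena an [arena_config()].
#' @param seed integer seed; identical seeds give identical designs.
#' @return an object of class `experiment_design`: list of 6 block entries,
#'   each with `block`, `start_angle` (deg), `target` (x, y),
#'   `target_distance` (m), `probe_rotations` (deg).
#' @export
generate_design <- function(arena = arena_config(), seed = 1L) {
  with_seed(seed, {
    starts <- sample(seq(0, 300, by = 60))
    lapply(seq_along(starts), function(i) {
      rel <- sample(c(-135, -45, 45, 135), 1)
      d <- stats::runif(1, 0.2, 0.8) * arena$radius
      ang <- deg2rad(starts[i] + rel)
      list(block = i,
           start_angle = starts[i],
           target = arena$center + d * c(cos(ang), sin(ang)),
           target_distance = d,
           probe_rotations = sample(c(0, 90, 180, 270)))
    })
  })
}

#' Synthetic navigator parameters
#'
#' @param strategy navigation policy: `"direct"` (scan, then head for the
#'   remembered goal), `"random_search"` (correlated random walk, specular
#'   reflection at the wall), or `"path_replication"` (egocentric replay of
#'   the block's last learning path).
#' @param goal_noise_sigma SD (meters) of the Gaussian error on the
#'   remembered target location.
#' @param heading_noise_sigma SD (radians per step) of heading perturbations.
#' @param scan_duration seconds of in-place rotation at trial onset
#'   (landmark scanning).
#' @param scan_rate scan rotation rate, radians/s (default 50 deg/s, the
#'   stationary setup's rotation speed, used for both setups).
#' @param speed translation speed, m/s (task value 1.4).
#' @param capture_radius distance (m) at which a learning-trial target is
#'   registered as found (task value 0.8).
#' @param sampling_rate Hz; 60 (stationary) or 90 (mobile).
#' @param max_duration trial timeout in seconds.
#' @param seed integer seed for the agent's random stream.
#' @return an object of class `agent_spec`.
#' @export
agent_spec <- function(strategy = c("direct", "random_search",
                                    "path_replication"),
                       goal_noise_sigma = 0.6, heading_noise_sigma = 0.05,
                       scan_duration = 2, scan_rate = deg2rad(50),
                       speed = 1.4, capture_radius = 0.8,
                       sampling_rate = 60, max_duration = 30, seed = 1L) {
  strategy <- match.arg(strategy)
  if (speed <= 0) stop("speed must be > 0")
  if (capture_radius <= 0) stop("capture_radius must be > 0")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  structure(
    list(strategy = strategy, goal_noise_sigma = goal_noise_sigma,
         heading_noise_sigma = heading_noise_sigma,
         scan_duration = scan_duration, scan_rate = scan_rate, speed = speed,
         capture_radius = capture_radius, sampling_rate = sampling_rate,
         max_duration = max_duration, seed = as.integer(seed)),
    class = "agent_spec")
}

#' @export
print.agent_spec <- function(x, ...) {
  cat(sprintf("<agent_spec> %s, goal sd %.2f m, %.0f Hz, seed %d\n",
              x$strategy, x$goal_noise_sigma, x$sampling_rate, x$seed))
  invisible(x)
}

# Override fields of an agent_spec with a named list of adjustments.
adjust_agent <- function(agent, adjustments) {
  if (is.null(adjustments)) return(agent)
  for (nm in names(adjustments)) agent[[nm]] <- adjustments[[nm]]
  agent
}

# Keep a position strictly inside the wall.
clip_to_arena <- function(p, arena, margin = 1e-3) {
  v <- p - arena$center
  r <- sqrt(sum(v^2))
  lim <- arena$radius - margin
  if (r > lim) p <- arena$center + v * (lim / r)
  p
}

#' Simulate a single trial
#'
#' Runs one agent policy through one trial of a design block. Direct agents
#' scan in place for `scan_duration` (yaw sweeping at `scan_rate`), then walk
#' toward their goal estimate (the true target on learning trials, where the
#' object becomes visible when approached; the target plus Gaussian goal
#' noise on probes) with per-step heading noise. Learning trials end when the
#' agent is within `capture_radius` of the target; probe trials end with the
#' final sample placed at the goal estimate (the button press at the
#' remembered location). Random-search agents run a correlated random walk
#' with specular reflection at the wall. Path-replication agents replay the
#' supplied learning trajectory egocentrically — the displacement sequence is
#' reproduced relative to the rotated start's facing direction, i.e. without
#' compensating for the probe rotation.
#'
#' @param entry a design block entry from [generate_design()].
#' @param trial_type `"learning"` or `"probe"`.
#' @param probe_rotation probe start rotation in degrees (`NA` for learning).
#' @param agent an [agent_spec()].
#' @param arena an [arena_config()].
#' @param learned the block's stored learning [trial_trajectory()], required
#'   by `path_replication` probes.
#' @param participant,group,trial_index metadata fields.
#' @return `list(meta = trial_meta, trajectory = trial_trajectory)`.
#' @export
simulate_trial <- function(entry, trial_type = c("learning", "probe"),
                           probe_rotation = NA, agent = agent_spec(),
                           arena = arena_config(), learned = NULL,
                           participant = "sim", group = "control",
                           trial_index = 1L) {
  trial_type <- match.arg(trial_type)
  is_probe <- trial_type == "probe"
  if (is_probe && (is.na(probe_rotation) ||
                   !probe_rotation %in% c(0, 90, 180, 270)))
    stop("probe trials need probe_rotation in {0, 90, 180, 270}")
  strategy <- agent$strategy
  if (strategy == "path_replication" && is_probe && is.null(learned))
    stop("path replication requested but no learning trajectory available ",
         "in this block")
  # route must be learned before it can be replayed
  if (strategy == "path_replication" && !is_probe) strategy <- "direct"

  fs <- agent$sampling_rate
  dt <- 1 / fs
  rot <- if (is_probe) probe_rotation else 0
  start_ang <- deg2rad(entry$start_angle + rot)
  start <- arena$center + (arena$radius - 0.05) * c(cos(start_ang),
                                                    sin(start_ang))
  heading0 <- start_ang + pi  # face the arena center

  sim <- with_seed(agent$seed, switch(
    strategy,
    direct = sim_direct(entry, is_probe, start, heading0, agent, arena, dt),
    random_search = sim_random_search(entry, is_probe, start, heading0,
                                      agent, arena, dt),
    path_replication = sim_replication(learned, rot, arena)))

  traj <- trial_trajectory(seq(0, by = dt, length.out = nrow(sim$xy)),
                           sim$xy[, 1], sim$xy[, 2], sim$yaw,
                           sampling_rate = fs, arena = arena)
  meta <- trial_meta(participant, group,
                     setup = if (fs >= 75) "mobile" else "stationary",
                     block = entry$block, trial_type = trial_type,
                     trial_index = trial_index,
                     start_angle = entry$start_angle,
                     probe_rotation = if (is_probe) probe_rotation else NA,
                     target_location = entry$target,
                     final_location = final_location(traj),
                     sampling_rate = fs, arena = arena)
  list(meta = meta, trajectory = traj)
}

sim_direct <- function(entry, is_probe, start, heading0, agent, arena, dt) {
  goal <- if (is_probe) {
    clip_to_arena(entry$target + stats::rnorm(2, 0, agent$goal_noise_sigma),
                  arena)
  } else entry$target
  xy <- rbind(start); yaw <- heading0
  max_turn <- agent$scan_rate * dt   # rotation is rate-limited throughout
  # in-place landmark scan: triangular sweep out and back, no yaw jump
  n_scan <- round(agent$scan_duration / dt)
  if (n_scan > 0) {
    sweep_dir <- sample(c(-1, 1), 1)
    half <- ceiling(n_scan / 2)
    for (k in seq_len(n_scan)) {
      xy <- rbind(xy, start)
      excursion <- if (k <= half) k else n_scan - k
      yaw <- c(yaw, heading0 + sweep_dir * agent$scan_rate * dt * excursion)
    }
  }
  pos <- start
  step <- agent$speed * dt
  n_max <- ceiling(agent$max_duration / dt)
  cur_yaw <- yaw[length(yaw)]
  repeat {
    d <- goal - pos
    dist <- sqrt(sum(d^2))
    if (!is_probe && sqrt(sum((entry$target - pos)^2)) < agent$capture_radius)
      break
    if (is_probe && dist <= step) {
      xy <- rbind(xy, goal)
      yaw <- c(yaw, cur_yaw)
      break
    }
    if (nrow(xy) >= n_max) break
    h <- atan2(d[2], d[1]) + stats::rnorm(1, 0, agent$heading_noise_sigma)
    # recorded view direction turns toward the movement bearing at the
    # rate-limited rotation speed
    delta <- wrap_angles(h - cur_yaw)
    cur_yaw <- cur_yaw + sign(delta) * min(abs(delta), max_turn)
    pos <- clip_to_arena(pos + step * c(cos(h), sin(h)), arena)
    xy <- rbind(xy, pos)
    yaw <- c(yaw, cur_yaw)
  }
  if (nrow(xy) < 2) { xy <- rbind(xy, pos); yaw <- c(yaw, yaw[1]) }
  list(xy = xy, yaw = yaw)
}

sim_random_search <- function(entry, is_probe, start, heading0, agent, arena,
                              dt) {
  # correlated random walk; turn SD floored so search actually wanders
  turn_sd <- max(agent$heading_noise_sigma, 0.05)
  step <- agent$speed * dt
  n_max <- ceiling(agent$max_duration / dt)
  xy <- matrix(NA_real_, n_max + 1, 2)
  yaw <- numeric(n_max + 1)
  xy[1, ] <- start; yaw[1] <- heading0
  pos <- start; h <- heading0
  n <- 1
  while (n <= n_max) {
    if (!is_probe && sqrt(sum((entry$target - pos)^2)) < agent$capture_radius)
      break
    h <- h + stats::rnorm(1, 0, turn_sd)
    cand <- pos + step * c(cos(h), sin(h))
    v <- cand - arena$center
    if (sqrt(sum(v^2)) > arena$radius - 1e-3) {
      # specular reflection: mirror the velocity across the wall tangent
      nrm <- (pos - arena$center) / sqrt(sum((pos - arena$center)^2))
      vel <- c(cos(h), sin(h))
      vel <- vel - 2 * sum(vel * nrm) * nrm
      h <- atan2(vel[2], vel[1])
      cand <- clip_to_arena(pos + step * c(cos(h), sin(h)), arena)
    }
    pos <- cand
    n <- n + 1
    xy[n, ] <- pos
    yaw[n] <- h
  }
  if (n < 2) { xy[2, ] <- xy[1, ]; yaw[2] <- yaw[1]; n <- 2 }
  list(xy = xy[seq_len(n), , drop = FALSE], yaw = yaw[seq_len(n)])
}

sim_replication <- function(learned, rot_deg, arena) {
  rot <- deg2rad(rot_deg)
  xy <- rotate_points(positions(learned), rot, center = arena$center)
  xy <- t(apply(xy, 1, clip_to_arena, arena = arena))
  list(xy = xy, yaw = learned$yaw + rot)
}

#' Simulate one block (3 learning + 4 probe trials)
#'
#' Each trial draws its own random substream derived from `seed`, emulating
#' the disorientation task's decorrelation of consecutive trials. For
#' path-replication agents, learning trials run the direct policy and probes
#' replay the third learning trajectory.
#'
#' @inheritParams simulate_trial
#' @param seed integer seed for the block.
#' @return list of 7 `list(meta=, trajectory=)` trials.
#' @export
simulate_block <- function(entry, agent = agent_spec(),
                           arena = arena_config(), seed = 1L,
                           participant = "sim", group = "control") {
  trials <- vector("list", 7)
  learned <- NULL
  for (i in 1:3) {
    ag <- agent
    ag$seed <- derive_seed(seed, entry$block, "learning", i)
    trials[[i]] <- simulate_trial(entry, "learning", agent = ag, arena = arena,
                                  participant = participant, group = group,
                                  trial_index = i)
    learned <- trials[[i]]$trajectory
  }
  for (i in 1:4) {
    ag <- agent
    ag$seed <- derive_seed(seed, entry$block, "probe", i)
    trials[[3 + i]] <- simulate_trial(entry, "probe",
                                      probe_rotation = entry$probe_rotations[i],
                                      agent = ag, arena = arena,
                                      learned = learned,
                                      participant = participant, group = group,
                                      trial_index = i)
  }
  trials
}

#' Simulate a full session (6 blocks, block order permuted)
#'
#' @inheritParams simulate_block
#' @param design an [generate_design()] result.
#' @param setup `"stationary"` (60 Hz) or `"mobile"` (90 Hz); overrides the
#'   agent's sampling rate.
#' @return flat list of 42 trials.
#' @export
simulate_session <- function(design, agent = agent_spec(),
                             arena = arena_config(), seed = 1L,
                             participant = "sim", group = "control",
                             setup = c("stationary", "mobile")) {
  setup <- match.arg(setup)
  agent$sampling_rate <- if (setup == "mobile") 90 else 60
  order <- with_seed(derive_seed(seed, participant, setup, "order"),
                     sample(seq_along(design)))
  out <- list()
  for (b in order) {
    out <- c(out, simulate_block(design[[b]], agent, arena,
                                 seed = derive_seed(seed, participant, setup,
                                                    "block", b),
                                 participant = participant, group = group))
  }
  out
}

#' Simulate a cohort in the 2-group x 2-setup design
#'
#' Generates `n_per_group` agents per group, runs each through both setups
#' (6 blocks x 7 trials each) over a single shared experiment design, and —
#' when `out_dir` is given — writes each participant-setup session in the
#' package's trajectory/metadata CSV dialect plus a participants table and a
#' run manifest. Output is deterministic given `seed`.
#'
#' @param n_per_group named counts, e.g. `c(MTLR = 10, control = 20)`.
#' @param group_effects named list of [agent_spec()] field overrides keyed
#'   by `"<group>.<setup>"` (e.g. `MTLR.stationary`), expressing group-by-
#'   setup differences such as higher goal noise.
#' @param seed integer master seed.
#' @param arena an [arena_config()].
#' @param base_agent template [agent_spec()].
#' @param out_dir output directory (created if needed); `NULL` keeps the
#'   sessions in memory only.
#' @return invisibly, a list with `sessions` (list of trial lists),
#'   `participants` (covariate data.frame), `design`, and `files` (written
#'   paths, if any).
#' @export
simulate_cohort <- function(n_per_group = c(MTLR = 10, control = 20),
                            group_effects = NULL, seed = 1L,
                            arena = arena_config(),
                            base_agent = agent_spec(), out_dir = NULL) {
  design <- generate_design(arena, seed = derive_seed(seed, "design"))
  groups <- rep(names(n_per_group), n_per_group)
  n <- length(groups)
  participants <- with_seed(derive_seed(seed, "covariates"), data.frame(
    participant = sprintf("P%02d", seq_len(n)),
    group = groups,
    session_order = rep_len(c("stationary_first", "mobile_first"), n),
    sex = rep_len(c("f", "m"), n),
    age = sample(22:61, n, replace = TRUE),
    education = sample(12:20, n, replace = TRUE),
    stringsAsFactors = FALSE))

  sessions <- list()
  files <- character()
  for (i in seq_len(n)) {
    pid <- participants$participant[i]
    grp <- participants$group[i]
    for (setup in c("stationary", "mobile")) {
      agent <- adjust_agent(base_agent,
                            group_effects[[paste(grp, setup, sep = ".")]])
      sess <- simulate_session(design, agent, arena,
                               seed = derive_seed(seed, pid, setup),
                               participant = pid, group = grp, setup = setup)
      sessions[[paste(pid, setup, sep = ".")]] <- sess
      if (!is.null(out_dir)) {
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        tf <- file.path(out_dir, sprintf("%s_%s_trajectories.csv", pid, setup))
        mf <- file.path(out_dir, sprintf("%s_%s_meta.csv", pid, setup))
        write_session(sess, tf, mf)
        files <- c(files, tf, mf)
      }
    }
  }
  if (!is.null(out_dir)) {
    pf <- file.path(out_dir, "participants.csv")
    write_tidy_csv(participants, pf)
    manifest <- list(seed = seed, n_per_group = as.list(n_per_group),
                     arena = unclass(arena),
                     group_effects = group_effects,
                     files = basename(files))
    jf <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, jf, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, pf, jf)
  }
  invisible(list(sessions = sessions, participants = participants,
                 design = design, files = files))
}
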