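#' Single-trial navigation trajectory
#'
#' Container for one trial's time series: timestamps in seconds, arena-centered
#' Cartesian positions in meters, and yaw in radians (counterclockwise from
#' +x). Validated on construction.
#'
#' @param timestamps numeric vector, strictly increasing, seconds.
#' @param x,y numeric vectors of positions (meters).
#' @param yaw numeric vector of yaw angles (radians).
#' @param sampling_rate nominal sampling rate in Hz (60 stationary, 90 mobile).
#' @param arena optional [arena_config()]; if given, positions are checked to
#'   lie within `radius + tol` of the center.
#' @param tol wall tolerance in meters for the containment check.
#' @return an object of class `trial_trajectory` with elements
#'   `t`, `x`, `y`, `yaw`, `sampling_rate`.
#' @export
trial_trajectory <- function(timestamps, x, y, yaw, sampling_rate,
                             arena = NULL, tol = 1e-3) {
  n <- length(timestamps)
  if (n < 2) stop("trajectory needs at least 2 samples")
  if (length(x) != n || length(y) != n || length(yaw) != n)
    stop("timestamps, x, y and yaw must have equal length")
  if (any(!is.finite(timestamps)) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in trajectory channels")
  if (any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  obj <- structure(
    list(t = as.numeric(timestamps), x = as.numeric(x), y = as.numeric(y),
         yaw = as.numeric(yaw), sampling_rate = as.numeric(sampling_rate)),
    class = "trial_trajectory")
  if (!is.null(arena)) validate_trajectory(obj, arena, tol = tol)
  obj
}

#' Validate a trajectory against the arena wall
#'
#' @param traj a `trial_trajectory`.
#' @inheritParams trial_trajectory
#' @return `traj`, invisibly; errors on violation.
#' @export
validate_trajectory <- function(traj, arena, tol = 1e-3) {
  stopifnot(inherits(traj, "trial_trajectory"), inherits(arena, "arena_config"))
  r <- sqrt((traj$x - arena$center[1])^2 + (traj$y - arena$center[2])^2)
  bad <- which(r > arena$radius + tol)
  if (length(bad))
    stop(sprintf("position outside arena wall at sample %d (r = %.4f m)",
                 bad[1], r[bad[1]]))
  invisible(traj)
}

#' @export
print.trial_trajectory <- function(x, ...) {
  cat(sprintf("<trial_trajectory> %d samples, %.2f s at %g Hz\n",
              length(x$t), x$t[length(x$t)] - x$t[1], x$sampling_rate))
  invisible(x)
}

positions <- function(traj) cbind(traj$x, traj$y)

final_location <- function(traj) c(traj$x[length(traj$x)], traj$y[length(traj$y)])

#' Trial metadata
#'
#' Identifiers and design variables for one trial. `final_location` must equal
#' the last trajectory sample; `probe_rotation` is required for probe trials
#' and must be absent otherwise.
#'
#' @param participant participant identifier (character).
#' @param group group label, `"MTLR"` or `"control"`.
#' @param setup `"stationary"` or `"mobile"`.
#' @param block block number 1-6.
#' @param trial_type `"learning"`, `"probe"` or `"baseline"`.
#' @param trial_index trial index within block.
#' @param start_angle start axis in degrees, one of 0, 60, ..., 300.
#' @param probe_rotation probe start rotation in degrees (0/90/180/270);
#'   `NA` for non-probe trials.
#' @param target_location numeric length-2, target (x, y).
#' @param final_location numeric length-2, response location (last sample).
#' @param sampling_rate nominal Hz.
#' @param arena optional [arena_config()] for the target-containment check.
#' @return an object of class `trial_meta`.
#' @export
trial_meta <- function(participant, group, setup, block, trial_type,
                       trial_index, start_angle, probe_rotation = NA,
                       target_location, final_location, sampling_rate = 60,
                       arena = NULL) {
  trial_type <- match.arg(trial_type, c("learning", "probe", "baseline"))
  setup <- match.arg(setup, c("stationary", "mobile"))
  if (trial_type == "probe") {
    if (is.na(probe_rotation) || !probe_rotation %in% c(0, 90, 180, 270))
      stop("probe trials require probe_rotation in {0, 90, 180, 270}")
  } else if (!is.na(probe_rotation)) {
    stop("probe_rotation must be NA for non-probe trials")
  }
  if (!start_angle %in% c(0, 60, 120, 180, 240, 300))
    stop("start_angle must be one of 0, 60, ..., 300 degrees")
  if (!is.null(arena)) {
    d <- sqrt(sum((target_location - arena$center)^2))
    if (d >= arena$radius) stop("target location lies outside the arena")
  }
  structure(
    list(participant = as.character(participant), group = as.character(group),
         setup = setup, block = as.integer(block), trial_type = trial_type,
         trial_index = as.integer(trial_index),
         start_angle = as.numeric(start_angle),
         probe_rotation = as.numeric(probe_rotation),
         target_location = as.numeric(target_location),
         final_location = as.numeric(final_location),
         sampling_rate = as.numeric(sampling_rate)),
    class = "trial_meta")
}

trial_key <- function(participant, setup, block, trial_type, trial_index) {
  paste(participant, setup, block, trial_type, trial_index, sep = "/")
}

#' Read a recorded session from trajectory and metadata files
#'
#' The trajectory file is a long CSV with columns
#' `participant,setup,block,trial_type,trial_index,t,x,y` plus either a `yaw`
#' column (radians) or quaternion columns `qw,qx,qy,qz` (converted on load via
#' [quaternion_to_yaw()]). The metadata file has one row per trial with columns
#' `participant,group,setup,block,trial_type,trial_index,start_angle,`
#' `probe_rotation,target_x,target_y,sampling_rate`.
#'
#' @param trajectory_file,meta_file file paths.
#' @param arena an [arena_config()].
#' @param axis_map optional 2x2 matrix applied to raw `(x, y)` rows, the
#'   escape hatch for recordings whose ground-plane axes differ from the
#'   package convention (arena-centered, y up the page). Default identity.
#' @param axis_convention quaternion axis convention passed to
#'   [quaternion_to_yaw()] when orientation is stored as quaternions.
#' @param wall_tol wall tolerance in meters.
#' @return a list of trials, each a list with elements `meta` (`trial_meta`)
#'   and `trajectory` (`trial_trajectory`).
#' @export
read_session <- function(trajectory_file, meta_file, arena,
                         axis_map = NULL, axis_convention = "z_up",
                         wall_tol = 1e-3) {
  traj <- read_tidy_csv(trajectory_file)
  meta <- read_tidy_csv(meta_file)
  need_t <- c("participant", "setup", "block", "trial_type", "trial_index",
              "t", "x", "y")
  miss <- setdiff(need_t, names(traj))
  if (length(miss))
    stop("trajectory file missing columns: ", paste(miss, collapse = ", "))
  has_yaw <- "yaw" %in% names(traj)
  has_quat <- all(c("qw", "qx", "qy", "qz") %in% names(traj))
  if (!has_yaw && !has_quat)
    stop("trajectory file needs a `yaw` column or `qw,qx,qy,qz` columns")
  need_m <- c("participant", "group", "setup", "block", "trial_type",
              "trial_index", "start_angle", "target_x", "target_y",
              "sampling_rate")
  miss <- setdiff(need_m, names(meta))
  if (length(miss))
    stop("metadata file missing columns: ", paste(miss, collapse = ", "))
  if (!"probe_rotation" %in% names(meta)) meta$probe_rotation <- NA_real_

  if (!is.null(axis_map)) {
    stopifnot(is.matrix(axis_map), all(dim(axis_map) == 2))
    xy <- as.matrix(traj[, c("x", "y")]) %*% t(axis_map)
    traj$x <- xy[, 1]; traj$y <- xy[, 2]
  }

  keys <- trial_key(traj$participant, traj$setup, traj$block,
                    traj$trial_type, traj$trial_index)
  mkeys <- trial_key(meta$participant, meta$setup, meta$block,
                     meta$trial_type, meta$trial_index)
  if (anyDuplicated(mkeys)) stop("duplicate trial rows in metadata file")
  out <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    rows <- which(keys == mkeys[i])
    if (!length(rows))
      stop(sprintf("trial %s: no trajectory rows found", mkeys[i]))
    sub <- traj[rows, , drop = FALSE]
    if (any(diff(sub$t) <= 0)) {
      bad <- rows[which(diff(sub$t) <= 0)[1] + 1]
      stop(sprintf("trial %s: non-increasing timestamp at row %d",
                   mkeys[i], bad))
    }
    yaw <- if (has_yaw && !all(is.na(sub$yaw))) {
      sub$yaw
    } else {
      quaternion_to_yaw(cbind(sub$qw, sub$qx, sub$qy, sub$qz),
                        axis_convention = axis_convention)
    }
    tt <- tryCatch(
      trial_trajectory(sub$t, sub$x, sub$y, yaw,
                       sampling_rate = meta$sampling_rate[i],
                       arena = arena, tol = wall_tol),
      error = function(e) stop(sprintf("trial %s: %s", mkeys[i],
                                       conditionMessage(e)), call. = FALSE))
    tm <- trial_meta(meta$participant[i], meta$group[i], meta$setup[i],
                     meta$block[i], meta$trial_type[i], meta$trial_index[i],
                     meta$start_angle[i], meta$probe_rotation[i],
                     c(meta$target_x[i], meta$target_y[i]),
                     final_location(tt),
                     sampling_rate = meta$sampling_rate[i], arena = arena)
    out[[i]] <- list(meta = tm, trajectory = tt)
  }
  out
}

#' Write a session to the package's trajectory/metadata CSV dialect
#'
#' Inverse of [read_session()]; numeric fields round-trip to machine
#' precision.
#'
#' @param session list of `list(meta=, trajectory=)` trials.
#' @param trajectory_file,meta_file output paths.
#' @return invisibly, `c(trajectory_file, meta_file)`.
#' @export
write_session <- function(session, trajectory_file, meta_file) {
  stopifnot(length(session) >= 1)
  tlist <- lapply(session, function(tr) {
    m <- tr$meta; y <- tr$trajectory
    data.frame(participant = m$participant, setup = m$setup, block = m$block,
               trial_type = m$trial_type, trial_index = m$trial_index,
               t = y$t, x = y$x, y = y$y, yaw = y$yaw,
               stringsAsFactors = FALSE)
  })
  mlist <- lapply(session, function(tr) {
    m <- tr$meta
    data.frame(participant = m$participant, group = m$group, setup = m$setup,
               block = m$block, trial_type = m$trial_type,
               trial_index = m$trial_index, start_angle = m$start_angle,
               probe_rotation = m$probe_rotation,
               target_x = m$target_location[1], target_y = m$target_location[2],
               final_x = m$final_location[1], final_y = m$final_location[2],
               sampling_rate = m$sampling_rate, stringsAsFactors = FALSE)
  })
  write_tidy_csv(do.call(rbind, tlist), trajectory_file)
  write_tidy_csv(do.call(rbind, mlist), meta_file)
  invisible(c(trajectory_file, meta_file))
}

#' Write or read a tidy per-trial metrics table
#'
#' One row per trial; missing metrics (e.g. `trajectory_distance` on learning
#' trials) are written as empty fields, never as zero, and the table
#' round-trips losslessly.
#'
#' @param records data.frame of per-trial metric records
#'   (see [run_pipeline()]).
#' @param out output path.
#' @return `write_metrics()` returns `out` invisibly; `read_metrics()` the
#'   data.frame.
#' @export
write_metrics <- function(records, out) {
  if (!is.data.frame(records) || nrow(records) < 1)
    stop("`records` must be a non-empty data.frame")
  write_tidy_csv(records, out)
  invisible(out)
}

#' @rdname write_metrics
#' @param path path of a file written by [write_metrics()].
#' @export
read_metrics <- function(path) read_tidy_csv(path)
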