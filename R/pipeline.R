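# End-to-end orchestration: per-trial metric records, block-level scatter,
# participant and group x setup summaries, and the analysis-ready long table.

metric_columns <- c("memory_score", "latency", "path_length", "path_error",
                    "surface_coverage", "avg_distance_to_final", "idphi",
                    "trajectory_distance")

#' Compute all metrics for one trial
#'
#' Learning trials receive latency, path length, path error, surface
#' coverage, average distance to the final location, and idPhi; probe trials
#' additionally the memory score and — when the block's last learning
#' trajectory is supplied — the trajectory distance.
#'
#' @param meta a [trial_meta()].
#' @param traj the matching [trial_trajectory()].
#' @param arena an [arena_config()].
#' @param last_learning the block's last learning [trial_trajectory()], or
#'   `NULL`.
#' @param seed integer seed for the memory-score reference draw.
#' @return one-row data.frame (a metric record).
#' @export
compute_trial_metrics <- function(meta, traj, arena = arena_config(),
                                  last_learning = NULL, seed = 1L) {
  is_probe <- meta$trial_type == "probe"
  ms <- if (is_probe) {
    memory_score(meta$final_location, meta$target_location, arena,
                 seed = seed)$score
  } else NA_real_
  td <- if (is_probe && !is.null(last_learning)) {
    trajectory_distance(last_learning, traj, arena)
  } else NA_real_
  pe <- suppressWarnings(path_error(traj))
  data.frame(
    participant = meta$participant, group = meta$group, setup = meta$setup,
    block = meta$block, trial_type = meta$trial_type,
    trial_index = meta$trial_index, start_angle = meta$start_angle,
    probe_rotation = meta$probe_rotation,
    target_x = meta$target_location[1], target_y = meta$target_location[2],
    final_x = meta$final_location[1], final_y = meta$final_location[2],
    memory_score = ms,
    latency = latency(traj),
    path_length = path_length(traj),
    path_error = pe,
    surface_coverage = surface_coverage(traj, arena),
    avg_distance_to_final = avg_distance_to_final(traj),
    idphi = as.numeric(initial_angular_velocity(traj, arena)),
    trajectory_distance = td,
    stringsAsFactors = FALSE)
}

#' Run the full metrics pipeline
#'
#' Takes recorded or simulated sessions, computes one metric record per
#' trial (probes are scored against the block's last learning trial), the
#' per-block scatter of final locations, and the group x setup summary
#' table. All randomness (the memory-score reference draws) derives from
#' `seed` per trial, so reruns are identical.
#'
#' @param input either a directory containing `*_trajectories.csv` /
#'   `*_meta.csv` session pairs (as written by [simulate_cohort()] or
#'   [write_session()]), a single session (list of `list(meta=, trajectory=)`
#'   trials), or a list of such sessions.
#' @param arena an [arena_config()].
#' @param out_dir optional output directory; writes `metrics.csv`,
#'   `scatter.csv`, `summary.csv` and `manifest.json`.
#' @param seed integer master seed for memory-score reference draws.
#' @return list with `metrics` (per-trial records), `scatter` (per
#'   participant x setup x block), `summary` (see [aggregate_summary()]).
#' @export
run_pipeline <- function(input, arena = arena_config(), out_dir = NULL,
                         seed = 1L) {
  sessions <- load_sessions(input, arena)
  records <- list()
  scat <- list()
  for (sess in sessions) {
    blocks <- split(sess, vapply(sess, function(tr)
      paste(tr$meta$setup, tr$meta$block), character(1)))
    for (blk in blocks) {
      types <- vapply(blk, function(tr) tr$meta$trial_type, character(1))
      idx <- vapply(blk, function(tr) tr$meta$trial_index, integer(1))
      learn <- blk[types == "learning"]
      last_learning <- if (length(learn)) {
        learn[[which.max(idx[types == "learning"])]]$trajectory
      } else NULL
      finals <- list()
      for (tr in blk) {
        m <- tr$meta
        rec <- compute_trial_metrics(
          m, tr$trajectory, arena, last_learning = last_learning,
          seed = derive_seed(seed, m$participant, m$setup, m$block,
                             m$trial_type, m$trial_index))
        records[[length(records) + 1]] <- rec
        if (m$trial_type == "probe")
          finals[[length(finals) + 1]] <- m$final_location
      }
      if (length(finals)) {
        m <- blk[[1]]$meta
        scat[[length(scat) + 1]] <- data.frame(
          participant = m$participant, group = m$group, setup = m$setup,
          block = m$block, n_probes = length(finals),
          scatter = final_location_scatter(do.call(rbind, finals), arena,
                                           allow_partial = TRUE),
          stringsAsFactors = FALSE)
      }
    }
  }
  metrics <- do.call(rbind, records)
  scatter <- if (length(scat)) do.call(rbind, scat) else NULL
  summary <- aggregate_summary(metrics)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_metrics(metrics, file.path(out_dir, "metrics.csv"))
    if (!is.null(scatter))
      write_tidy_csv(scatter, file.path(out_dir, "scatter.csv"))
    write_tidy_csv(summary, file.path(out_dir, "summary.csv"))
    jsonlite::write_json(
      list(seed = seed, arena = unclass(arena),
           n_trials = nrow(metrics),
           n_participants = length(unique(metrics$participant))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  list(metrics = metrics, scatter = scatter, summary = summary)
}

load_sessions <- function(input, arena) {
  if (is.character(input)) {
    mfiles <- list.files(input, pattern = "_meta\\.csv$", full.names = TRUE)
    if (!length(mfiles)) stop("no *_meta.csv session files found in ", input)
    return(lapply(mfiles, function(mf) {
      tf <- sub("_meta\\.csv$", "_trajectories.csv", mf)
      if (!file.exists(tf)) stop("missing trajectory file for ", mf)
      read_session(tf, mf, arena)
    }))
  }
  if (is.list(input)) {
    if (length(input) && !is.null(input[[1]]$meta)) return(list(input))
    return(input)
  }
  stop("`input` must be a directory path, a session, or a list of sessions")
}

#' Group x setup summary table
#'
#' Aggregates trial records in two stages, matching how repeated-measures
#' designs are reported: trial values are first averaged within participant
#' (per group, setup, and trial type), then summarized across participants
#' as mean, SEM (`sd / sqrt(n)`), and participant count `n`.
#'
#' @param metrics per-trial metric records from [run_pipeline()].
#' @param pooled if `TRUE`, skip the participant-mean stage and pool all
#'   trials directly.
#' @return long data.frame with columns `group`, `setup`, `trial_type`,
#'   `metric`, `mean`, `sem`, `n`.
#' @export
aggregate_summary <- function(metrics, pooled = FALSE) {
  out <- list()
  for (m in intersect(metric_columns, names(metrics))) {
    d <- metrics[!is.na(metrics[[m]]),
                 c("participant", "group", "setup", "trial_type", m)]
    if (!nrow(d)) next
    unit <- if (pooled) d else
      stats::aggregate(d[[m]],
                       by = d[c("participant", "group", "setup", "trial_type")],
                       FUN = mean)
    vcol <- if (pooled) m else "x"
    agg <- stats::aggregate(unit[[vcol]],
                            by = unit[c("group", "setup", "trial_type")],
                            FUN = function(v) c(mean = mean(v),
                                                sd = stats::sd(v),
                                                n = length(v)))
    res <- data.frame(agg[c("group", "setup", "trial_type")],
                      metric = m,
                      mean = agg$x[, "mean"],
                      sem = agg$x[, "sd"] / sqrt(agg$x[, "n"]),
                      n = agg$x[, "n"],
                      stringsAsFactors = FALSE)
    out[[m]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Analysis-ready long table for mixed-model fitting
#'
#' One row per participant x setup x metric (the participant's mean over all
#' trials where the metric is defined), with design and covariate columns,
#' suitable for external linear mixed-model fitting. Rows whose metric is
#' entirely missing for a participant-setup cell are omitted.
#'
#' Optionally applies the conventional log-transform rule for heavily
#' non-normal metrics: a metric is log-transformed when its skewness falls
#' outside `[-2, 2]` or its excess kurtosis outside `[-7, 7]` (only when all
#' values are positive); the `transformed` column records this.
#'
#' @param metrics per-trial records from [run_pipeline()].
#' @param participants optional covariate data.frame (as produced by
#'   [simulate_cohort()]) with columns `participant`, `session_order`,
#'   `sex`, `age`, `education`.
#' @param log_transform apply the skewness/kurtosis log rule.
#' @return long data.frame with columns `participant`, `group`, `setup`,
#'   `metric`, `value`, `transformed`, plus covariates when supplied.
#' @export
export_model_table <- function(metrics, participants = NULL,
                               log_transform = FALSE) {
  if (!is.data.frame(metrics) || !nrow(metrics)) stop("empty metrics table")
  rows <- list()
  for (m in intersect(metric_columns, names(metrics))) {
    d <- metrics[!is.na(metrics[[m]]),
                 c("participant", "group", "setup", m)]
    if (!nrow(d)) next
    agg <- stats::aggregate(d[[m]], by = d[c("participant", "group", "setup")],
                            FUN = mean)
    vals <- agg$x
    transformed <- FALSE
    if (log_transform && all(vals > 0)) {
      sk <- sample_skewness(vals); ku <- sample_excess_kurtosis(vals)
      if (!is.na(sk) && (abs(sk) > 2 || abs(ku) > 7)) {
        vals <- log(vals)
        transformed <- TRUE
      }
    }
    rows[[m]] <- data.frame(agg[c("participant", "group", "setup")],
                            metric = m, value = vals,
                            transformed = transformed,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(participants)) {
    out <- merge(out, participants[setdiff(names(participants), "group")],
                 by = "participant", sort = FALSE)
  }
  out[order(out$metric, out$participant, out$setup), , drop = FALSE]
}

sample_skewness <- function(x) {
  n <- length(x); if (n < 3) return(NA_real_)
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

sample_excess_kurtosis <- function(x) {
  n <- length(x); if (n < 4) return(NA_real_)
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2 - 3
}
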