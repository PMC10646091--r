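# Spatial memory performance: Monte-Carlo percent-rank memory score, its
# closed-form oracle, response scatter, and final-location grid maps.

#' Monte-Carlo memory score of a probe response
#'
#' Percent rank of the response-to-target distance against uniformly sampled
#' arena locations: `n_reference` points are drawn uniformly over the arena
#' disk (radius `R * sqrt(u)`, angle uniform) and the score is
#' `100 - 100 * (# reference points strictly closer to the target than the
#' final location) / n_reference`. 100 means perfect recall, 50 chance-level
#' responding, below 50 a systematic bias away from the target. Reference
#' points at exactly the response distance do not count against the score
#' (strict inequality).
#'
#' @param final numeric length-2, response (final) location.
#' @param target numeric length-2, target location, strictly inside the arena.
#' @param arena an [arena_config()]; supplies radius, center and
#'   `n_reference_points`.
#' @param seed integer seed for the reference draw; the result is
#'   deterministic given the seed. Use [derive_seed()] for per-trial streams.
#' @param n_reference optional override of `arena$n_reference_points`.
#' @return an object of class `memory_score_result`: list with `score`
#'   (percent), `response_distance` (m), `n_reference`, `seed`.
#' @examples
#' arena <- arena_config()
#' memory_score(c(1, 1), c(1, 1), arena, seed = 1)$score  # 100
#' @export
memory_score <- function(final, target, arena = arena_config(), seed = 1L,
                         n_reference = arena$n_reference_points) {
  stopifnot(length(final) == 2, length(target) == 2)
  if (n_reference < 1) stop("n_reference must be >= 1")
  R <- arena$radius
  d_t <- sqrt(sum((target - arena$center)^2))
  if (d_t >= R) stop("target must lie strictly inside the arena")
  d_f <- sqrt(sum((final - arena$center)^2))
  if (d_f > R + 1e-6) stop("final location lies outside the arena")
  resp <- sqrt(sum((final - target)^2))
  ref <- with_seed(seed, runif_disk(n_reference, arena$center, R))
  dref <- sqrt((ref[, 1] - target[1])^2 + (ref[, 2] - target[2])^2)
  closer <- sum(dref < resp)
  structure(
    list(score = 100 - 100 * closer / n_reference,
         response_distance = resp,
         n_reference = as.integer(n_reference),
         seed = as.integer(seed)),
    class = "memory_score_result")
}

#' @export
print.memory_score_result <- function(x, ...) {
  cat(sprintf("<memory_score> %.1f%% (response %.3f m from target, n = %d)\n",
              x$score, x$response_distance, x$n_reference))
  invisible(x)
}

#' Closed-form memory score (circle-intersection oracle)
#'
#' Exact value the Monte-Carlo score estimates: the fraction of the arena disk
#' strictly closer to the target than the response is the area of the disk of
#' radius `|final - target|` centered on the target, intersected with the
#' arena disk, divided by `pi R^2`. The score is `100 * (1 - that fraction)`.
#'
#' @inheritParams memory_score
#' @return score in percent.
#' @export
memory_score_analytic <- function(final, target, arena = arena_config()) {
  R <- arena$radius
  D <- sqrt(sum((target - arena$center)^2))
  if (D >= R) stop("target must lie strictly inside the arena")
  r <- sqrt(sum((final - target)^2))
  a_int <- circle_intersection_area(R, r, D)
  100 * (1 - a_int / (pi * R^2))
}

# Area of intersection of two disks with radii R and r whose centers are
# distance D apart (standard lens formula with containment limits).
circle_intersection_area <- function(R, r, D) {
  if (r <= 0) return(0)
  if (D + r <= R) return(pi * r^2)   # response disk inside arena
  if (D + R <= r) return(pi * R^2)   # arena inside response disk
  # clamp acos arguments against roundoff at the tangency boundaries
  a1 <- (D^2 + r^2 - R^2) / (2 * D * r)
  a2 <- (D^2 + R^2 - r^2) / (2 * D * R)
  a1 <- min(1, max(-1, a1)); a2 <- min(1, max(-1, a2))
  tri <- (-D + r + R) * (D + r - R) * (D - r + R) * (D + r + R)
  r^2 * acos(a1) + R^2 * acos(a2) - 0.5 * sqrt(max(0, tri))
}

#' Scatter of final locations
#'
#' Spatial precision of a block's probe responses: the mean of all pairwise
#' Euclidean distances among the final locations (six distances for the four
#' probes of a block). Smaller values mean more consistent responses.
#'
#' @param finals n x 2 matrix of final locations (normally n = 4).
#' @param arena an [arena_config()], used only when `normalize = TRUE`.
#' @param normalize divide by the arena diameter, yielding a dimensionless
#'   relative scatter.
#' @param allow_partial accept 2-3 points (averaging over the available
#'   `choose(n, 2)` pairs) instead of requiring exactly 4.
#' @return mean pairwise distance (meters, or dimensionless when normalized);
#'   `NA` when fewer than 2 points are available.
#' @examples
#' final_location_scatter(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
#' @export
final_location_scatter <- function(finals, arena = arena_config(),
                                   normalize = FALSE, allow_partial = FALSE) {
  finals <- rbind(finals)
  finals <- finals[stats::complete.cases(finals), , drop = FALSE]
  n <- nrow(finals)
  if (n < 2) return(NA_real_)
  if (n != 4 && !allow_partial)
    stop("expected exactly 4 final locations (set allow_partial = TRUE)")
  d <- stats::dist(finals)
  s <- mean(d)
  if (normalize) s <- s / (2 * arena$radius)
  s
}

#' Final-location percentage map
#'
#' Bins final response locations into the `grid_n` x `grid_n` grid covering
#' the bounding square `[-R, R]^2` of the arena; each cell holds the
#' percentage of responses falling in it (cells sum to 100).
#'
#' @param finals n x 2 matrix of final locations, or a session list of
#'   `list(meta=, trajectory=)` trials (probe trials' final locations are
#'   used).
#' @param arena an [arena_config()].
#' @return an object of class `final_location_map`: list with `grid`
#'   (percent matrix, rows = x bins, columns = y bins) and `bounds`.
#' @export
final_location_map <- function(finals, arena = arena_config()) {
  if (is.list(finals) && !is.data.frame(finals) && !is.matrix(finals)) {
    finals <- do.call(rbind, lapply(finals, function(tr) {
      if (tr$meta$trial_type == "probe") tr$meta$final_location else NULL
    }))
  }
  finals <- rbind(finals)
  if (nrow(finals) < 1) stop("need at least one final location")
  g <- bin_counts(finals[, 1], finals[, 2], arena)
  structure(
    list(grid = 100 * g / nrow(finals),
         bounds = c(-arena$radius, arena$radius)),
    class = "final_location_map")
}

# Count points per cell of the grid over [-R, R]^2 (arena-centered).
bin_counts <- function(x, y, arena) {
  R <- arena$radius; n <- arena$grid_n
  ix <- pmin(pmax(floor((x - arena$center[1] + R) / (2 * R) * n) + 1, 1), n)
  iy <- pmin(pmax(floor((y - arena$center[2] + R) / (2 * R) * n) + 1, 1), n)
  g <- matrix(0, n, n)
  for (k in seq_along(ix)) g[ix[k], iy[k]] <- g[ix[k], iy[k]] + 1
  g
}

# Which cells does a trajectory visit (binary matrix)?
cells_visited <- function(traj, arena) {
  bin_counts(traj$x, traj$y, arena) > 0
}

#' Export a grid map as a CSV matrix
#'
#' @param map a `final_location_map` or `presence_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  utils::write.table(map$grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
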