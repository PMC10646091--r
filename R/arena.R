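#' Arena configuration
#'
#' Geometry of the circular arena and the parameters shared by the trajectory
#' metrics: the grid resolution used for presence/final-location maps, the
#' number of uniform reference points behind the Monte-Carlo memory score,
#' the initial time window of the idPhi statistic, and the yaw low-pass
#' cutoff.
#'
#' @param center numeric length-2, arena center in (virtual) meters.
#' @param radius arena radius in meters; the task arena is 3.8 m.
#' @param grid_n cells per axis of the square grid covering `[-R, R]^2`.
#' @param n_reference_points uniform reference locations drawn per memory
#'   score evaluation.
#' @param idphi_window initial time window (seconds) for
#'   [initial_angular_velocity()].
#' @param filter_cutoff yaw low-pass cutoff frequency in Hz.
#' @return an object of class `arena_config`.
#' @examples
#' arena <- arena_config()
#' arena$radius
#' @export
arena_config <- function(center = c(0, 0), radius = 3.8, grid_n = 20L,
                         n_reference_points = 1000L, idphi_window = 5,
                         filter_cutoff = 6) {
  stopifnot(is.numeric(center), length(center) == 2, all(is.finite(center)))
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("`radius` must be a single positive number")
  if (grid_n < 1) stop("`grid_n` must be >= 1")
  if (n_reference_points < 1) stop("`n_reference_points` must be >= 1")
  if (idphi_window <= 0) stop("`idphi_window` must be > 0")
  structure(
    list(center = as.numeric(center), radius = as.numeric(radius),
         grid_n = as.integer(grid_n),
         n_reference_points = as.integer(n_reference_points),
         idphi_window = as.numeric(idphi_window),
         filter_cutoff = as.numeric(filter_cutoff)),
    class = "arena_config")
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf("<arena_config> center=(%.2f, %.2f) radius=%.2f m, %dx%d grid,\n",
              x$center[1], x$center[2], x$radius, x$grid_n, x$grid_n))
  cat(sprintf("  %d reference points, idPhi window %.1f s, %.1f Hz cutoff\n",
              x$n_reference_points, x$idphi_window, x$filter_cutoff))
  invisible(x)
}

#' Read or write an arena configuration as YAML
#'
#' @param path file path.
#' @return `read_arena_config()` returns an `arena_config`;
#'   `write_arena_config()` returns `path` invisibly.
#' @export
read_arena_config <- function(path) {
  y <- yaml::read_yaml(path)
  arena_config(center = unlist(y$center %||% c(0, 0)),
               radius = y$radius %||% 3.8,
               grid_n = y$grid_n %||% 20L,
               n_reference_points = y$n_reference_points %||% 1000L,
               idphi_window = y$idphi_window %||% 5,
               filter_cutoff = y$filter_cutoff %||% 6)
}

#' @rdname read_arena_config
#' @param arena an `arena_config`.
#' @export
write_arena_config <- function(arena, path) {
  stopifnot(inherits(arena, "arena_config"))
  yaml::write_yaml(unclass(arena), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
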