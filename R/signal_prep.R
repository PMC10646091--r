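# Orientation preprocessing: quaternion -> yaw, unwrapping, zero-phase
# low-pass filtering. Yaw is the only Euler channel any downstream metric
# consumes, so no full Euler-triplet extraction is attempted.

#' Extract yaw from unit quaternions
#'
#' Converts rotation quaternions to the heading (yaw) angle in radians,
#' counterclockwise-positive when viewed from above, in `(-pi, pi]`.
#' For `z_up` (right-handed, z vertical):
#' `yaw = atan2(2(wz + xy), 1 - 2(y^2 + z^2))`. For `unity_y_up`
#' (left-handed, y vertical, as recorded by Unity engines) the rotation about
#' the vertical y axis is extracted and negated so that counterclockwise from
#' above stays positive.
#'
#' @param q numeric vector `c(w, x, y, z)` or an n x 4 matrix of quaternion
#'   rows. Quaternions are normalized; zero-norm rows are an error.
#' @param axis_convention `"z_up"` or `"unity_y_up"`.
#' @return yaw angle(s) in radians in `(-pi, pi]`.
#' @examples
#' quaternion_to_yaw(c(1, 0, 0, 0))                      # identity -> 0
#' quaternion_to_yaw(c(cos(pi / 4), 0, 0, sin(pi / 4)))  # quarter turn -> pi/2
#' @export
quaternion_to_yaw <- function(q, axis_convention = c("z_up", "unity_y_up")) {
  axis_convention <- match.arg(axis_convention)
  q <- rbind(q)
  if (ncol(q) != 4) stop("quaternions must have 4 components (w, x, y, z)")
  nrm <- sqrt(rowSums(q^2))
  if (any(nrm < 1e-12)) stop("zero-norm quaternion cannot be normalized")
  q <- q / nrm
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  yaw <- switch(axis_convention,
    z_up = atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2)),
    unity_y_up = -atan2(2 * (w * y + x * z), 1 - 2 * (y^2 + z^2)))
  # atan2 returns [-pi, pi]; fold -pi onto +pi for the (-pi, pi] convention
  yaw[yaw <= -pi] <- yaw[yaw <= -pi] + 2 * pi
  if (nrow(q) == 1) yaw <- yaw[[1]]
  yaw
}

#' Unwrap a yaw angle sequence
#'
#' Removes 2*pi discontinuities so that consecutive differences lie in
#' `(-pi, pi]`; the first element is unchanged and the output equals the input
#' modulo 2*pi elementwise.
#'
#' @param yaw numeric vector of angles in radians.
#' @return unwrapped angles.
#' @examples
#' unwrap_angles(c(3.0, -3.0))  # second element becomes -3 + 2*pi
#' @export
unwrap_angles <- function(yaw) {
  if (length(yaw) < 1) stop("need at least one angle")
  if (length(yaw) == 1) return(yaw)
  d <- diff(yaw)
  # map each increment into (-pi, pi]
  d <- d - 2 * pi * ceiling((d - pi) / (2 * pi))
  c(yaw[1], yaw[1] + cumsum(d))
}

# Inverse of unwrapping: wrap angles into (-pi, pi].
wrap_angles <- function(yaw) {
  yaw - 2 * pi * ceiling((yaw - pi) / (2 * pi))
}

#' Zero-phase low-pass filter for unwrapped yaw
#'
#' 4th-order Butterworth applied forward and backward
#' (`signal::filtfilt()`), so the magnitude response is squared and the phase
#' response is zero — rotation-onset timing feeding idPhi is unbiased. The
#' signal is extended at both ends by odd (point-) reflection over one
#' warm-up length before filtering to suppress edge transients.
#'
#' If `sampling_rate <= 2 * cutoff` the filter is not realizable and the
#' input is returned unchanged with a warning and attribute
#' `filtered = FALSE`; likewise for sequences shorter than the warm-up
#' length.
#'
#' @param yaw numeric vector of unwrapped yaw angles (radians).
#' @param sampling_rate sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz (default 6).
#' @param order filter order (default 4).
#' @return filtered sequence, same length, with attribute `filtered`.
#' @export
lowpass_yaw <- function(yaw, sampling_rate, cutoff = 6, order = 4) {
  n <- length(yaw)
  if (sampling_rate <= 2 * cutoff) {
    warning(sprintf(
      "sampling rate %g Hz cannot resolve a %g Hz cutoff; returning unfiltered",
      sampling_rate, cutoff))
    return(structure(yaw, filtered = FALSE))
  }
  padlen <- ceiling(3 * sampling_rate / cutoff)
  if (n <= padlen + 1) {
    warning("sequence shorter than filter warm-up; returning unfiltered")
    return(structure(yaw, filtered = FALSE))
  }
  bf <- signal::butter(order, cutoff / (sampling_rate / 2), type = "low")
  # the endpoint-to-endpoint linear trend is DC-like (below any realizable
  # cutoff); pass it through untouched and filter only the residual, which
  # makes constant/linear inputs exact and suppresses edge transients
  trend <- seq(yaw[1], yaw[n], length.out = n)
  resid <- yaw - trend
  front <- 2 * resid[1] - resid[(padlen + 1):2]
  back <- 2 * resid[n] - resid[(n - 1):(n - padlen)]
  out <- signal::filtfilt(bf, c(front, resid, back))
  structure(trend + out[(padlen + 1):(padlen + n)], filtered = TRUE)
}

#' Full yaw preprocessing chain
#'
#' Unwraps, then low-pass filters the yaw channel of a trial, in that order.
#'
#' @param traj a [trial_trajectory()].
#' @param arena an [arena_config()] providing the filter cutoff.
#' @return numeric vector of preprocessed yaw.
#' @export
preprocess_yaw <- function(traj, arena = arena_config()) {
  suppressWarnings(
    lowpass_yaw(unwrap_angles(traj$yaw), traj$sampling_rate,
                cutoff = arena$filter_cutoff))
}
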