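#' Wrap angles into [0, 2*pi)
#'
#' @param x numeric vector of angles in radians.
#' @return angles mapped into `[0, 2*pi)`.
#' @export
wrap_angle <- function(x) {
  x %% (2 * pi)
}

#' Map angle differences into (-pi, pi]
#'
#' Frame-to-frame differences of a wrapped angle series contain apparent
#' jumps of magnitude > pi whenever the angle crosses the 0/2*pi seam; those
#' are wrap artifacts, not real motion, and are re-mapped onto the short arc.
#'
#' @param d numeric vector of raw angle differences (radians).
#' @return differences mapped into `(-pi, pi]`.
#' @export
wrap_diff <- function(d) {
  out <- ((d + pi) %% (2 * pi)) - pi
  out[out == -pi] <- pi
  out
}

# circular absolute difference between two angles, in [0, pi]
circ_dist <- function(a, b) {
  abs(wrap_diff(a - b))
}

# extract a bare numeric spike-time vector from a spike_train or numeric input
spike_times <- function(spikes) {
  if (inherits(spikes, "spike_train")) spikes$times else as.numeric(spikes)
}

# session duration implied by a kinematics frame grid (frames are left edges)
session_duration <- function(kin) {
  dt <- attr(kin, "dt")
  kin$t[nrow(kin)] - kin$t[1] + dt
}

# a statistic that could not be computed, with a machine-readable reason code
absent_stat <- function(reason) {
  structure(list(value = NA_real_, reason = reason), class = "absent_stat")
}

is_absent <- function(x) inherits(x, "absent_stat")
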