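#' Construct a tracking trace
#'
#' A tracking trace holds the LED position digitised from the overhead
#' camera: one row per video frame, timestamps in seconds, coordinates in cm.
#'
#' @param t numeric vector of frame timestamps (s), strictly increasing.
#' @param x,y LED coordinates (cm), finite.
#' @return a `tracking_trace` data frame with columns `t`, `x`, `y`.
#' @export
tracking_trace <- function(t, x, y) {
  stopifnot(length(t) == length(x), length(t) == length(y))
  if (length(t) == 0L) stop("empty tracking trace")
  if (any(diff(t) <= 0)) stop("tracking timestamps must be strictly increasing")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite LED coordinates")
  structure(data.frame(t = t, x = x, y = y),
            class = c("tracking_trace", "data.frame"))
}

#' Boxcar-smooth LED coordinates
#'
#' Centred rectangular (boxcar) moving average of the x and y coordinates,
#' window `window_s` seconds (default 600 ms). At the edges the window is
#' truncated to the available frames so the output stays on the frame grid.
#'
#' @param trace a [tracking_trace()].
#' @param window_s smoothing window length in seconds, > 0.
#' @return a `tracking_trace` with smoothed `x`, `y`; timestamps unchanged.
#' @export
smooth_coordinates <- function(trace, window_s = 0.6) {
  stopifnot(window_s > 0)
  n <- nrow(trace)
  if (n == 0L) stop("empty tracking trace")
  dt <- stats::median(diff(trace$t))
  half <- floor(window_s / 2 / dt + 1e-9)
  runmean_trunc <- function(v) {
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  tracking_trace(trace$t, runmean_trunc(trace$x), runmean_trunc(trace$y))
}

# Kasa algebraic least-squares circle fit: minimises sum((x-a)^2+(y-b)^2-r^2)^2
# linearised as x^2+y^2 = 2a*x + 2b*y + c. Closed form and deterministic.
fit_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  qrA <- qr(A)
  if (qrA$rank < 3L) stop("degenerate trajectory: collinear or constant LED positions")
  beta <- qr.coef(qrA, b)
  r2 <- beta[3] + beta[1]^2 + beta[2]^2
  if (!is.finite(r2) || r2 <= .Machine$double.eps) {
    stop("degenerate trajectory: zero-radius circle fit")
  }
  list(cx = unname(beta[1]), cy = unname(beta[2]), radius = sqrt(r2))
}

#' Extract the head-direction angle from a smoothed trace
#'
#' The rotation centre is estimated by an algebraic least-squares circle fit
#' to the LED positions; the head angle is the polar angle of the LED about
#' that centre (plus a fixed, configurable offset between LED angle and the
#' animal's sagittal plane, which only rotates tuning curves). The unwrapped
#' angle accumulates continuity by mapping successive differences into
#' `(-pi, pi]`.
#'
#' @param trace a smoothed [tracking_trace()] with at least 10 frames.
#' @param offset_rad fixed LED-to-head angular offset (radians), default 0.
#' @return a `kinematics` data frame with columns `t`, `theta`,
#'   `theta_unwrapped`, carrying the fitted centre/radius and frame interval
#'   as attributes `center`, `led_radius_cm`, `dt`.
#' @export
compute_head_angle <- function(trace, offset_rad = 0) {
  if (nrow(trace) < 10L) stop("need at least 10 frames to fit the rotation centre")
  fit <- fit_circle(trace$x, trace$y)
  theta <- wrap_angle(atan2(trace$y - fit$cy, trace$x - fit$cx) + offset_rad)
  dth <- wrap_diff(diff(theta))
  unwrapped <- theta[1] + c(0, cumsum(dth))
  kin <- data.frame(t = trace$t, x = trace$x, y = trace$y,
                    theta = theta, theta_unwrapped = unwrapped)
  structure(kin,
            class = c("kinematics", "data.frame"),
            center = c(cx = fit$cx, cy = fit$cy),
            led_radius_cm = fit$radius,
            dt = stats::median(diff(trace$t)))
}

#' Angular velocity and acceleration by finite differences
#'
#' `omega[i] = (theta_unwrapped[i+1] - theta_unwrapped[i]) / dt` with the
#' last value repeated so the series stays on the frame grid; `alpha` is the
#' same forward difference of `omega`. Differences are taken on the
#' unwrapped angle, so crossing the 0/2*pi seam produces no spurious spikes.
#'
#' @param kin a `kinematics` frame with `theta_unwrapped` present.
#' @return `kin` with columns `omega` (rad/s) and `alpha` (rad/s^2) added.
#' @export
compute_angular_velocity <- function(kin) {
  n <- nrow(kin)
  if (n < 3L) stop("need at least 3 frames for velocity and acceleration")
  fwd_diff <- function(v) {
    d <- diff(v) / diff(kin$t)
    c(d, d[n - 1L])
  }
  kin$omega <- fwd_diff(kin$theta_unwrapped)
  kin$alpha <- fwd_diff(kin$omega)
  kin
}

#' Linear speed and movement mask
#'
#' Linear LED speed from frame-to-frame displacement of the (smoothed)
#' coordinates; a frame is "moving" when the linear speed exceeds the
#' cutoff (default 1 cm/s). Rest and rotation epochs partition the session;
#' downstream analyses keep only spikes falling in moving frames.
#'
#' @param kin a `kinematics` frame with coordinates and `omega` present.
#' @param cutoff_cm_s linear speed cutoff separating rest from rotation (cm/s).
#' @return `kin` with columns `lin_speed` (cm/s) and logical `moving` added.
#' @export
movement_mask <- function(kin, cutoff_cm_s = 1.0) {
  n <- nrow(kin)
  disp <- sqrt(diff(kin$x)^2 + diff(kin$y)^2) / diff(kin$t)
  kin$lin_speed <- c(disp, disp[n - 1L])
  kin$moving <- kin$lin_speed > cutoff_cm_s
  attr(kin, "cutoff_cm_s") <- cutoff_cm_s
  kin
}

#' Count rotation-direction inversions
#'
#' An inversion is a sign change of the difference between two consecutive
#' head angles. Raw differences with magnitude > pi are 0/2*pi wrap
#' artifacts and are first re-mapped into `(-pi, pi]`; near-zero differences
#' (|d| < `eps`, rest chatter) do not toggle the sign state.
#'
#' @param kin a `kinematics` frame with `theta` present.
#' @param eps dead-band below which a difference is treated as rest (rad).
#' @return integer count of direction reversals.
#' @export
count_inversions <- function(kin, eps = 1e-4) {
  d <- wrap_diff(diff(kin$theta))
  s <- sign(d[abs(d) > eps])
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

#' Session-level kinematic summary
#'
#' Mean absolute angular speed over movement frames, mean acceleration over
#' positive-alpha movement frames, mean deceleration over negative-alpha
#' movement frames, inversion count, and the movement/rest time partition.
#' Speed fields are reported as `NA` when no movement frames exist.
#'
#' @param kin a fully populated `kinematics` frame.
#' @param alpha_eps accelerations with `|alpha|` below this (rad/s^2) are
#'   classified as zero rather than positive or negative; guards the sign
#'   split against floating-point residue on constant-speed segments.
#' @return a list of class `session_kinematics_summary`.
#' @export
summarize_kinematics <- function(kin, alpha_eps = 1e-9) {
  dt <- attr(kin, "dt")
  mov <- kin$moving
  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  out <- list(
    mean_angular_speed = mean_or_na(abs(kin$omega[mov])),
    mean_accel = mean_or_na(kin$alpha[mov & kin$alpha > alpha_eps]),
    mean_decel = mean_or_na(kin$alpha[mov & kin$alpha < -alpha_eps]),
    n_inversions = count_inversions(kin),
    movement_time = sum(mov) * dt,
    rest_time = sum(!mov) * dt
  )
  structure(out, class = "session_kinematics_summary")
}

#' Full kinematics pipeline from raw tracking
#'
#' Convenience wrapper: boxcar smoothing, circle fit and head angle, angular
#' velocity/acceleration, linear speed and movement mask.
#'
#' @param trace a raw [tracking_trace()].
#' @param window_s boxcar window (s).
#' @param cutoff_cm_s movement cutoff (cm/s).
#' @param offset_rad LED-to-head angular offset (rad).
#' @return a fully populated `kinematics` data frame.
#' @export
compute_kinematics <- function(trace, window_s = 0.6, cutoff_cm_s = 1.0,
                               offset_rad = 0) {
  sm <- smooth_coordinates(trace, window_s = window_s)
  kin <- compute_head_angle(sm, offset_rad = offset_rad)
  kin <- compute_angular_velocity(kin)
  movement_mask(kin, cutoff_cm_s = cutoff_cm_s)
}
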