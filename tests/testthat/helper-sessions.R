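# shared session fixtures, generated once per test run and cached

.session_cache <- new.env(parent = emptyenv())

# kinematics of a generated passive-rotation session at the default
# study conditions (300 s, 25 Hz, 6 inversions, 1.1 rad/s, 20% rest)
demo_kin <- function(duration_s = 300, seed = 11, n_inversions = 6,
                     rest_fraction = 0.2) {
  key <- sprintf("kin_%g_%d_%d_%g", duration_s, seed, n_inversions,
                 rest_fraction)
  if (is.null(.session_cache[[key]])) {
    sp <- session_spec(duration_s = duration_s, seed = seed,
                       n_inversions = n_inversions,
                       rest_fraction = rest_fraction)
    tr <- generate_rotation_trajectory(sp)
    .session_cache[[key]] <- compute_kinematics(tr)
  }
  .session_cache[[key]]
}

# hand-built kinematics frame (bypasses tracking) for exact-value tests:
# theta given directly, everything else derived, movement mask as supplied
manual_kin <- function(theta_unwrapped, dt = 0.04, moving = TRUE,
                       radius = 10) {
  n <- length(theta_unwrapped)
  t <- (seq_len(n) - 1L) * dt
  kin <- data.frame(
    t = t,
    x = 50 + radius * cos(theta_unwrapped),
    y = 50 + radius * sin(theta_unwrapped),
    theta = theta_unwrapped %% (2 * pi),
    theta_unwrapped = theta_unwrapped)
  kin <- structure(kin, class = c("kinematics", "data.frame"), dt = dt)
  kin <- compute_angular_velocity(kin)
  kin$lin_speed <- abs(kin$omega) * radius
  kin$moving <- rep_len(moving, n)
  kin
}

# uniform constant-speed sweep visiting all 36 bins equally
uniform_sweep_kin <- function(n_rev = 2, dt = 0.04, omega0 = 2 * pi / 36) {
  n <- round(n_rev * 2 * pi / (omega0 * dt))
  manual_kin(omega0 * (seq_len(n) - 1L) * dt, dt = dt)
}
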