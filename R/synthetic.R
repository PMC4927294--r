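#' Specification of a synthetic passive-rotation session
#'
#' Encodes the study conditions a generated session should emulate: total
#' duration, video frame rate, LED lever-arm radius, number of rotation
#' direction reversals, target angular speed and acceleration of the
#' platform, and the fraction of the session spent at rest.
#'
#' @param duration_s session duration (s), > 0.
#' @param frame_rate_hz tracking camera frame rate (frames/s), default 25.
#' @param led_radius_cm distance of the LED from the rotation centre (cm).
#' @param n_inversions number of rotation-direction reversals, >= 0.
#' @param target_angular_speed_rad_s plateau angular speed (rad/s).
#' @param target_accel_rad_s2 ramp acceleration magnitude (rad/s^2).
#' @param rest_fraction fraction of the session spent at rest, in [0, 1].
#' @param seed integer RNG seed making the schedule reproducible.
#' @return a validated list of class `session_spec`.
#' @export
session_spec <- function(duration_s = 300, frame_rate_hz = 25,
                         led_radius_cm = 10, n_inversions = 6,
                         target_angular_speed_rad_s = 1.1,
                         target_accel_rad_s2 = 1.3,
                         rest_fraction = 0.2, seed = 1L) {
  stopifnot(duration_s > 0, frame_rate_hz > 0, led_radius_cm > 0,
            n_inversions >= 0, target_angular_speed_rad_s > 0,
            target_accel_rad_s2 > 0,
            rest_fraction >= 0, rest_fraction <= 1)
  structure(list(duration_s = duration_s, frame_rate_hz = frame_rate_hz,
                 led_radius_cm = led_radius_cm,
                 n_inversions = as.integer(n_inversions),
                 target_angular_speed_rad_s = target_angular_speed_rad_s,
                 target_accel_rad_s2 = target_accel_rad_s2,
                 rest_fraction = rest_fraction, seed = as.integer(seed)),
            class = "session_spec")
}

#' Specification of a synthetic cell's firing model
#'
#' Parameters of the inhomogeneous-Poisson intensity used to emulate the
#' firing classes seen under passive rotation: von Mises head-direction
#' tuning (concentration `kappa` about `preferred_dir_rad`), sinusoidal
#' theta modulation (`theta_freq_hz`, `theta_depth`), and a linear gain on
#' absolute angular speed (`speed_gain`, Hz per rad/s, floored so the
#' intensity never goes negative).
#'
#' @param base_rate_hz mean firing rate (Hz), >= 0.
#' @param kappa von Mises concentration, >= 0 (0 = untuned).
#' @param preferred_dir_rad preferred head direction (rad).
#' @param theta_freq_hz theta modulation frequency (Hz) or `NA` for none.
#' @param theta_depth modulation depth in [0, 1].
#' @param speed_gain signed rate gain (Hz per rad/s of |angular velocity|).
#' @param refractory_ms absolute refractory period enforced by deletion (ms).
#' @param celltype_label `"principal"` or `"fs"` (selects waveform template).
#' @param seed integer RNG seed.
#' @return a validated list of class `cell_spec`.
#' @export
cell_spec <- function(base_rate_hz = 5, kappa = 0, preferred_dir_rad = 0,
                      theta_freq_hz = NA_real_, theta_depth = 0,
                      speed_gain = 0, refractory_ms = 2,
                      celltype_label = c("principal", "fs"), seed = 1L) {
  celltype_label <- match.arg(celltype_label)
  stopifnot(base_rate_hz >= 0, kappa >= 0,
            theta_depth >= 0, theta_depth <= 1, refractory_ms >= 0)
  if (!is.na(theta_freq_hz)) stopifnot(theta_freq_hz > 0)
  structure(list(base_rate_hz = base_rate_hz, kappa = kappa,
                 preferred_dir_rad = wrap_angle(preferred_dir_rad),
                 theta_freq_hz = theta_freq_hz, theta_depth = theta_depth,
                 speed_gain = speed_gain, refractory_ms = refractory_ms,
                 celltype_label = celltype_label, seed = as.integer(seed)),
            class = "cell_spec")
}

#' Generate a passive-rotation LED trajectory
#'
#' Builds a deterministic rotation schedule: `n_inversions + 1` rotation
#' epochs of alternating direction, each a trapezoidal speed profile that
#' ramps at the target acceleration up to the target angular speed, with
#' whole-block rest epochs interleaved so that rest totals approximately
#' `rest_fraction` of the session. Epoch durations are jittered (seeded) so
#' sessions are not metronomic. The LED rides a circle of radius
#' `led_radius_cm` about a fixed centre.
#'
#' @param spec a [session_spec()].
#' @param center_cm numeric length-2 rotation centre (cm).
#' @return a [tracking_trace()] on an exact `1/frame_rate_hz` grid, with the
#'   true unwrapped angle series attached as attribute `theta_true`.
#' @export
generate_rotation_trajectory <- function(spec, center_cm = c(50, 50)) {
  stopifnot(inherits(spec, "session_spec"))
  dt <- 1 / spec$frame_rate_hz
  n <- round(spec$duration_s * spec$frame_rate_hz)
  t <- (seq_len(n) - 1L) * dt

  v <- spec$target_angular_speed_rad_s
  a <- spec$target_accel_rad_s2
  n_rot <- spec$n_inversions + 1L
  move_time <- spec$duration_s * (1 - spec$rest_fraction)
  rest_time <- spec$duration_s - move_time
  # each epoch must at least fit its acceleration + deceleration ramp
  if (move_time / n_rot < 2 * v / a) {
    stop("impossible schedule: too many inversions for the duration at the ",
         "target speed and acceleration")
  }

  set.seed(spec$seed)
  w_mov <- stats::runif(n_rot, 0.8, 1.2)
  mov_len <- move_time * w_mov / sum(w_mov)
  # rest blocks sit between epochs and at both ends (n_rot + 1 slots)
  w_rest <- stats::runif(n_rot + 1L, 0.5, 1.5)
  rest_len <- if (rest_time > 0) rest_time * w_rest / sum(w_rest) else
    rep(0, n_rot + 1L)
  start_dir <- sample(c(-1, 1), 1L)

  # piecewise angular-speed profile evaluated at frame midpoints-of-interval
  omega_of <- function(tau, L, dir) {
    t_r <- min(v / a, L / 2)
    v_pk <- a * t_r
    s <- ifelse(tau < t_r, a * tau,
                ifelse(tau > L - t_r, a * (L - tau), v_pk))
    dir * pmax(s, 0)
  }
  omega <- numeric(n)
  cursor <- rest_len[1L]
  dir <- start_dir
  for (k in seq_len(n_rot)) {
    L <- mov_len[k]
    in_epoch <- t >= cursor & t < cursor + L
    omega[in_epoch] <- omega_of(t[in_epoch] - cursor, L, dir)
    cursor <- cursor + L + rest_len[k + 1L]
    dir <- -dir
  }

  theta0 <- stats::runif(1, 0, 2 * pi)
  theta <- theta0 + cumsum(c(0, omega[-n] * dt))
  x <- center_cm[1] + spec$led_radius_cm * cos(theta)
  y <- center_cm[2] + spec$led_radius_cm * sin(theta)
  tr <- tracking_trace(t, x, y)
  attr(tr, "theta_true") <- theta
  attr(tr, "omega_true") <- omega
  attr(tr, "spec") <- spec
  tr
}

#' Simulate a spike train on a kinematics frame grid
#'
#' Inhomogeneous-Poisson spike generation by thinning. The intensity is
#' `lambda(t) = base * exp(kappa*cos(theta(t) - pd)) / I0(kappa) *
#' (1 + depth*cos(2*pi*f*t)) * max(0, 1 + gain*|omega(t)| / base)`, with
#' `theta`, `omega` piecewise-constant on the frame grid and the theta-phase
#' factor evaluated in continuous time. The thinning bound is the product of
#' the factor maxima (`base * exp(kappa)/I0(kappa) * (1+depth) *
#' max(speed factor)`); candidates are drawn homogeneously at that bound and
#' accepted with probability `lambda/bound`. An absolute refractory period
#' is then enforced by deleting any spike closer than `refractory_ms` to its
#' accepted predecessor.
#'
#' @param kin a populated `kinematics` data frame (needs `theta`, `omega`).
#' @param cell a [cell_spec()].
#' @return a `spike_train`: list with sorted strictly-increasing `times`
#'   (s), `duration_s`, and the generating `cell` spec.
#' @export
generate_spike_train <- function(kin, cell) {
  stopifnot(inherits(cell, "cell_spec"), nrow(kin) >= 2L)
  dt <- attr(kin, "dt")
  T_end <- session_duration(kin)
  t0 <- kin$t[1]
  if (cell$base_rate_hz == 0) {
    return(structure(list(times = numeric(0), duration_s = T_end, cell = cell),
                     class = "spike_train"))
  }
  i0 <- besselI(cell$kappa, 0)
  speed_fac_frames <- pmax(0, 1 + cell$speed_gain * abs(kin$omega) / cell$base_rate_hz)
  depth <- if (is.na(cell$theta_freq_hz)) 0 else cell$theta_depth
  bound <- cell$base_rate_hz * exp(cell$kappa) / i0 * (1 + depth) *
    max(speed_fac_frames)
  if (!is.finite(bound)) stop("non-finite thinning bound for the spike intensity")
  if (bound == 0) {
    return(structure(list(times = numeric(0), duration_s = T_end, cell = cell),
                     class = "spike_train"))
  }
  set.seed(cell$seed)
  n_cand <- stats::rpois(1, bound * T_end)
  cand <- sort(stats::runif(n_cand, 0, T_end))
  frame <- pmin(pmax(findInterval(cand, kin$t - t0 + 0), 1L), nrow(kin))
  lam <- cell$base_rate_hz *
    exp(cell$kappa * cos(kin$theta[frame] - cell$preferred_dir_rad)) / i0 *
    speed_fac_frames[frame]
  if (depth > 0) {
    lam <- lam * (1 + depth * cos(2 * pi * cell$theta_freq_hz * cand))
  }
  keep <- stats::runif(n_cand) < lam / bound
  times <- cand[keep]
  # absolute refractory by deletion
  if (length(times) > 1L && cell$refractory_ms > 0) {
    refr <- cell$refractory_ms / 1000
    ok <- logical(length(times))
    last <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - last >= refr) {
        ok[i] <- TRUE
        last <- times[i]
      }
    }
    times <- times[ok]
  }
  structure(list(times = times + t0, duration_s = T_end, cell = cell),
            class = "spike_train")
}

# waveform template geometry per cell class (ms); raised-cosine lobes, so
# the positive-lobe half-width is exactly pos_ms/2 and peak-to-trough is
# (pos_ms + neg_ms)/2
waveform_params <- function(celltype_label) {
  switch(celltype_label,
         principal = list(pos_ms = 0.6, neg_ms = 1.0, neg_amp = 0.5),
         fs = list(pos_ms = 0.2, neg_ms = 0.3, neg_amp = 0.4),
         stop("unknown celltype_label: ", celltype_label))
}

#' Generate a synthetic extracellular spike waveform
#'
#' Biphasic template sampled at 20 kHz: a positive raised-cosine lobe of
#' duration `pos_ms` followed by a negative raised-cosine lobe of duration
#' `neg_ms` and relative amplitude `neg_amp`, preceded by a flat baseline
#' occupying the first quarter of the snippet. Geometry is closed-form: the
#' half-width of the positive lobe is `pos_ms/2` and the peak-to-trough time
#' is `(pos_ms + neg_ms)/2`. The fast-spiking template is narrower than the
#' principal-cell template.
#'
#' @param cell a [cell_spec()]; `celltype_label` selects the template.
#' @param sampling_rate_hz waveform sampling rate (Hz), default 20000.
#' @param n_samples snippet length in samples, default 64.
#' @param amplitude_uv positive-peak amplitude (arbitrary units).
#' @param noise_sd additive Gaussian noise SD (same units), default 0.
#' @param params optional override of the template geometry (list with
#'   `pos_ms`, `neg_ms`, `neg_amp`).
#' @return a `waveform`: list with `samples`, `sampling_rate_hz`,
#'   `alignment` (index of the peak sample).
#' @export
generate_waveform <- function(cell, sampling_rate_hz = 20000, n_samples = 64,
                              amplitude_uv = 100, noise_sd = 0, params = NULL) {
  stopifnot(inherits(cell, "cell_spec"))
  p <- if (is.null(params)) waveform_params(cell$celltype_label) else params
  dt_ms <- 1000 / sampling_rate_hz
  onset <- floor(n_samples / 4)          # baseline occupies first quarter
  tt <- (seq_len(n_samples) - 1L - onset) * dt_ms   # ms relative to lobe onset
  v <- numeric(n_samples)
  pos <- tt >= 0 & tt <= p$pos_ms
  v[pos] <- amplitude_uv * 0.5 * (1 - cos(2 * pi * tt[pos] / p$pos_ms))
  neg <- tt > p$pos_ms & tt <= p$pos_ms + p$neg_ms
  v[neg] <- -p$neg_amp * amplitude_uv * 0.5 *
    (1 - cos(2 * pi * (tt[neg] - p$pos_ms) / p$neg_ms))
  if (noise_sd > 0) {
    set.seed(cell$seed)
    v <- v + stats::rnorm(n_samples, 0, noise_sd)
  }
  structure(list(samples = v, sampling_rate_hz = sampling_rate_hz,
                 alignment = which.max(v)),
            class = "waveform")
}

#' Simulate a complete session: trajectory, kinematics, spikes, waveforms
#'
#' @param sspec a [session_spec()].
#' @param cell_specs list of [cell_spec()] objects (one per cell).
#' @param window_s,cutoff_cm_s kinematics parameters passed through.
#' @return list with `tracking`, `kin`, `spikes` (list of `spike_train`),
#'   `waveforms` (list of `waveform`), and the input specs.
#' @export
simulate_session <- function(sspec, cell_specs, window_s = 0.6,
                             cutoff_cm_s = 1.0) {
  tracking <- generate_rotation_trajectory(sspec)
  kin <- compute_kinematics(tracking, window_s = window_s,
                            cutoff_cm_s = cutoff_cm_s)
  spikes <- lapply(cell_specs, function(cs) generate_spike_train(kin, cs))
  waveforms <- lapply(cell_specs, generate_waveform)
  list(tracking = tracking, kin = kin, spikes = spikes,
       waveforms = waveforms, session_spec = sspec, cell_specs = cell_specs)
}

#' Write a simulated session to plain-text files
#'
#' Tracking as `tracking.csv` (`t_s,x_cm,y_cm`), one `spikes_<id>.csv` per
#' cell (one timestamp per row, column `t_s`), waveforms as a CSV matrix
#' (snippets x samples), and a JSON manifest echoing every path, seed and
#' parameter (including the smoothing-then-masking processing order).
#'
#' @param session result of [simulate_session()].
#' @param dir output directory (created if absent).
#' @return path of the manifest file, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr_path <- file.path(dir, "tracking.csv")
  utils::write.csv(
    data.frame(t_s = session$tracking$t, x_cm = session$tracking$x,
               y_cm = session$tracking$y),
    tr_path, row.names = FALSE)
  spike_paths <- character(length(session$spikes))
  for (i in seq_along(session$spikes)) {
    spike_paths[i] <- file.path(dir, sprintf("spikes_cell%02d.csv", i))
    utils::write.csv(data.frame(t_s = session$spikes[[i]]$times),
                     spike_paths[i], row.names = FALSE)
  }
  wf_path <- file.path(dir, "waveforms.csv")
  wf_mat <- do.call(rbind, lapply(session$waveforms, function(w) w$samples))
  utils::write.table(wf_mat, wf_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  manifest <- list(
    tracking = basename(tr_path),
    spikes = basename(spike_paths),
    waveforms = basename(wf_path),
    session_spec = unclass(session$session_spec),
    cell_specs = lapply(session$cell_specs, unclass),
    processing_order = "smooth_then_mask"
  )
  man_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(man_path)
}

#' Read a tracking CSV (`t_s,x_cm,y_cm`) written by [write_session()]
#' @param path CSV file path.
#' @return a [tracking_trace()].
#' @export
read_tracking_csv <- function(path) {
  d <- utils::read.csv(path)
  tracking_trace(d$t_s, d$x_cm, d$y_cm)
}

#' Read a spike-time CSV (one timestamp per row, column `t_s`)
#' @param path CSV file path.
#' @return numeric vector of spike times (s).
#' @export
read_spikes_csv <- function(path) {
  utils::read.csv(path)$t_s
}
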