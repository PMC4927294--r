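#' Instantaneous firing rate on the tracking frame grid
#'
#' Spike count per 40 ms video frame divided by the frame duration, aligned
#' one-to-one with the kinematics frames. No smoothing is applied.
#'
#' @param spikes a `spike_train` or numeric spike-time vector (s).
#' @param kin a populated `kinematics` data frame.
#' @return numeric rate series (Hz), one value per frame.
#' @export
instantaneous_rate <- function(spikes, kin) {
  st <- spike_times(spikes)
  dt <- attr(kin, "dt")
  n <- nrow(kin)
  idx <- findInterval(st - kin$t[1], (seq_len(n) - 1L) * dt)
  idx <- idx[idx >= 1L & idx <= n]
  tabulate(idx, nbins = n) / dt
}

#' Angular-speed score
#'
#' Pearson's product-moment correlation between the instantaneous firing
#' rate and the animal's instantaneous angular speed, over movement frames
#' only. Speed is unsigned (`|omega|`) by default because platform rotation
#' is bidirectional; the signed-omega correlation is attached as attribute
#' `signed_score`.
#'
#' @param rate frame-aligned rate series from [instantaneous_rate()].
#' @param kin a populated `kinematics` data frame.
#' @return Pearson r in [-1, 1], or an `absent_stat` with reason
#'   `"zero_variance"` when either series is constant over movement.
#' @export
speed_score <- function(rate, kin) {
  mov <- kin$moving
  if (sum(mov) < 2L) return(absent_stat("zero_variance"))
  r <- rate[mov]
  w <- abs(kin$omega[mov])
  if (stats::sd(r) == 0 || stats::sd(w) == 0) {
    return(absent_stat("zero_variance"))
  }
  score <- stats::cor(r, w)
  signed <- if (stats::sd(kin$omega[mov]) > 0) stats::cor(r, kin$omega[mov])
            else NA_real_
  attr(score, "signed_score") <- signed
  score
}

#' Whole-train time-shift shuffle test for speed modulation
#'
#' Rigid circular time-shift of the entire spike train per permutation (the
#' same null scheme as the HD shuffle); the speed score is recomputed
#' against the unshifted kinematics. Significance at the null 95th
#' percentile, p-value with the add-one correction.
#'
#' @inheritParams shuffle_test_hd
#' @return list with `observed`, `p_value`, `null_distribution`,
#'   `threshold`, `is_speed_modulated`; or an `absent_stat` when the
#'   observed score is undefined.
#' @export
shuffle_test_speed <- function(spikes, kin, n_perm = 1000, min_shift_s = 20,
                               seed = 1L) {
  st <- spike_times(spikes)
  observed <- speed_score(instantaneous_rate(st, kin), kin)
  if (is_absent(observed)) return(observed)
  T_end <- session_duration(kin)
  min_shift <- min(min_shift_s, T_end / 4)
  set.seed(seed)
  shifts <- stats::runif(n_perm, min_shift, T_end - min_shift)
  rel <- st - kin$t[1]
  null <- vapply(shifts, function(s) {
    sc <- speed_score(instantaneous_rate(((rel + s) %% T_end) + kin$t[1], kin),
                      kin)
    if (is_absent(sc)) 0 else as.numeric(sc)
  }, numeric(1))
  threshold <- stats::quantile(null, 0.95, names = FALSE)
  list(observed = as.numeric(observed),
       signed_score = attr(observed, "signed_score"),
       p_value = (1 + sum(null >= as.numeric(observed))) / (1 + n_perm),
       null_distribution = null,
       threshold = threshold,
       is_speed_modulated = as.numeric(observed) > threshold)
}

#' Firing rates during rest and during rotation
#'
#' Spike count divided by total duration within each class of the movement
#' mask. An empty epoch class yields an absent value with a reason code.
#'
#' @param spikes a `spike_train` or numeric spike-time vector (s).
#' @param kin a populated `kinematics` data frame.
#' @return list with `rate_rest_hz` and `rate_rotation_hz` (each numeric or
#'   an `absent_stat` with reason `"empty_epoch"`).
#' @export
rest_vs_rotation_rates <- function(spikes, kin) {
  st <- spike_times(spikes)
  dt <- attr(kin, "dt")
  n <- nrow(kin)
  idx <- findInterval(st - kin$t[1], (seq_len(n) - 1L) * dt)
  idx <- idx[idx >= 1L & idx <= n]
  rate_in <- function(mask) {
    dur <- sum(mask) * dt
    if (dur == 0) return(absent_stat("empty_epoch"))
    sum(mask[idx]) / dur
  }
  list(rate_rest_hz = rate_in(!kin$moving),
       rate_rotation_hz = rate_in(kin$moving))
}

#' Full per-cell speed-modulation analysis
#'
#' @inheritParams shuffle_test_speed
#' @return list of class `speed_result` combining the shuffle test output
#'   and the rest/rotation rates.
#' @export
analyze_speed <- function(spikes, kin, n_perm = 1000, min_shift_s = 20,
                          seed = 1L) {
  sh <- shuffle_test_speed(spikes, kin, n_perm = n_perm,
                           min_shift_s = min_shift_s, seed = seed)
  if (is_absent(sh)) return(sh)
  rates <- rest_vs_rotation_rates(spikes, kin)
  structure(c(sh, rates), class = "speed_result")
}
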