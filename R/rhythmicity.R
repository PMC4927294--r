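# internal: counts of positive pair lags in (0, max_lag], binned at bin_s,
# via a two-pointer sweep over the sorted train (O(n * pairs-per-window))
positive_lag_counts <- function(st, bin_s, max_lag_s) {
  n <- length(st)
  n_bins <- round(max_lag_s / bin_s)
  hi <- findInterval(st + max_lag_s + 1e-12, st)
  per <- hi - seq_len(n)
  if (sum(per) == 0) return(numeric(n_bins))
  i <- rep.int(seq_len(n), per)
  j <- i + sequence(per)
  d <- st[j] - st[i]
  d <- d[d > 0 & d <= max_lag_s + 1e-12]
  as.numeric(tabulate(pmin(ceiling(d / bin_s), n_bins), nbins = n_bins))
}

#' Spike-train autocorrelogram
#'
#' Histogram of all pairwise spike-time differences within `±max_lag_s`,
#' with 10 ms bins by default. Zero-lag self-pairs are excluded. If a
#' kinematics frame is supplied, only movement-period spikes enter.
#'
#' @param spikes a `spike_train` or numeric spike-time vector (s).
#' @param bin_s lag bin width (s), default 0.010.
#' @param max_lag_s maximum lag (s), default 0.5 (1 s window, so the
#'   spectrum resolves 1 Hz).
#' @param kin optional `kinematics` frame used to restrict to movement.
#' @return an `autocorrelogram`: list with symmetric `lags` (bin centres,
#'   s), `counts`, `bin_s`, `max_lag_s`, `n_spikes`.
#' @export
spike_autocorrelogram <- function(spikes, bin_s = 0.010, max_lag_s = 0.5,
                                  kin = NULL) {
  st <- sort(spike_times(spikes))
  if (!is.null(kin)) st <- movement_spikes(st, kin)
  if (length(st) < 2L) stop("need at least 2 spikes for an autocorrelogram")
  pos <- positive_lag_counts(st, bin_s, max_lag_s)
  n_bins <- length(pos)
  centers <- (seq_len(n_bins) - 0.5) * bin_s
  structure(list(lags = c(-rev(centers), centers),
                 counts = c(rev(pos), pos),
                 bin_s = bin_s, max_lag_s = max_lag_s,
                 n_spikes = length(st)),
            class = "autocorrelogram")
}

#' Theta index of an autocorrelogram
#'
#' The autocorrelogram (mean-subtracted to suppress the DC term, then
#' zero-padded by a factor `pad` for peak localisation) is Fourier
#' transformed; power is the squared magnitude. The peak frequency is the
#' power maximum within the theta band (4-12 Hz) and the theta index is the
#' mean power within 1 Hz of that peak divided by the mean power between
#' 1 and 50 Hz. Cells with 20 or fewer spikes are excluded with a reason
#' code rather than scored.
#'
#' @param acg an [spike_autocorrelogram()] result.
#' @param band_hz theta band searched for the peak, default `c(4, 12)`.
#' @param denom_hz band over which mean power normalises, default `c(1, 50)`.
#' @param pad zero-padding factor before the transform, default 4.
#' @param min_spikes inclusion threshold (strictly more required), default 20.
#' @param weak_threshold descriptive flag level: indices below it are
#'   reported as weakly rhythmic, default 5.
#' @return a `theta_result`: list with `theta_index`, `peak_freq_hz`,
#'   `is_weak` (index < `weak_threshold`), spectrum (`freq_hz`, `power`);
#'   or an `absent_stat` with reason `"too_few_spikes"`.
#' @export
theta_index <- function(acg, band_hz = c(4, 12), denom_hz = c(1, 50),
                        pad = 4, min_spikes = 20, weak_threshold = 5) {
  if (acg$n_spikes <= min_spikes) return(absent_stat("too_few_spikes"))
  y <- acg$counts - mean(acg$counts)
  n <- length(y) * pad
  p <- Mod(stats::fft(c(y, numeric(n - length(y)))))^2
  freq <- (seq_len(n) - 1L) / (n * acg$bin_s)
  half <- freq <= 1 / (2 * acg$bin_s)
  freq <- freq[half]
  p <- p[half]
  in_band <- freq >= band_hz[1] & freq <= band_hz[2]
  peak_freq <- freq[in_band][which.max(p[in_band])]
  num <- mean(p[freq >= peak_freq - 1 & freq <= peak_freq + 1])
  den <- mean(p[freq >= denom_hz[1] & freq <= denom_hz[2]])
  ti <- num / den
  structure(list(theta_index = ti, peak_freq_hz = peak_freq,
                 is_weak = ti < weak_threshold,
                 freq_hz = freq, power = p),
            class = "theta_result")
}

#' Per-spike time-shift shuffle test for theta rhythmicity
#'
#' Each permutation shifts every spike independently by its own uniform
#' random offset with wraparound over the session (destroying inter-spike
#' structure while preserving the spike count), then recomputes the theta
#' index. Significance at the null 95th percentile; the p-value carries the
#' add-one correction.
#'
#' @param spikes a `spike_train` or numeric spike-time vector (s).
#' @param duration_s session duration used for the wraparound (s); taken
#'   from a `spike_train` automatically.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param bin_s,max_lag_s autocorrelogram parameters.
#' @param min_spikes inclusion threshold passed to [theta_index()].
#' @return list with `observed` (a `theta_result`), `p_value`,
#'   `null_distribution`, `threshold`, `is_theta_rhythmic`; or an
#'   `absent_stat` when the cell has too few spikes.
#' @export
shuffle_test_theta <- function(spikes, duration_s = NULL, n_perm = 1000,
                               seed = 1L, bin_s = 0.010, max_lag_s = 0.5,
                               min_spikes = 20) {
  st <- sort(spike_times(spikes))
  if (is.null(duration_s)) {
    if (!inherits(spikes, "spike_train")) {
      stop("duration_s required when spikes is a bare vector")
    }
    duration_s <- spikes$duration_s
  }
  ti_of <- function(times) {
    theta_index(spike_autocorrelogram(times, bin_s = bin_s,
                                      max_lag_s = max_lag_s),
                min_spikes = min_spikes)
  }
  obs <- ti_of(st)
  if (is_absent(obs)) return(obs)
  set.seed(seed)
  n <- length(st)
  null <- vapply(seq_len(n_perm), function(k) {
    shifted <- sort((st + stats::runif(n, 0, duration_s)) %% duration_s)
    ti_of(shifted)$theta_index
  }, numeric(1))
  threshold <- stats::quantile(null, 0.95, names = FALSE)
  list(observed = obs,
       p_value = (1 + sum(null >= obs$theta_index)) / (1 + n_perm),
       null_distribution = null,
       threshold = threshold,
       is_theta_rhythmic = obs$theta_index > threshold)
}

# internal: spikes falling in movement-period frames
movement_spikes <- function(st, kin) {
  dt <- attr(kin, "dt")
  idx <- findInterval(st - kin$t[1], (seq_len(nrow(kin)) - 1L) * dt)
  st[idx >= 1L & idx <= nrow(kin) & kin$moving[pmax(idx, 1L)]]
}

#' Full per-cell theta-rhythmicity analysis
#'
#' Restricts to movement-period spikes, computes the autocorrelogram and
#' theta index, and runs the per-spike shuffle test.
#'
#' @param spikes a `spike_train` or numeric spike-time vector (s).
#' @param kin a populated `kinematics` data frame.
#' @param n_perm,seed shuffle parameters.
#' @param bin_s,max_lag_s,min_spikes passed to [shuffle_test_theta()].
#' @return the [shuffle_test_theta()] result (with `observed` inside), or
#'   an `absent_stat` with a reason code.
#' @export
analyze_theta <- function(spikes, kin, n_perm = 1000, seed = 1L,
                          bin_s = 0.010, max_lag_s = 0.5, min_spikes = 20) {
  st <- movement_spikes(sort(spike_times(spikes)), kin)
  if (length(st) < 2L) return(absent_stat("too_few_spikes"))
  shuffle_test_theta(st, duration_s = session_duration(kin),
                     n_perm = n_perm, seed = seed, bin_s = bin_s,
                     max_lag_s = max_lag_s, min_spikes = min_spikes)
}
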