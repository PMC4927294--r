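#' Average peak-aligned waveform snippets
#'
#' @param snippets a list of `waveform` objects or a numeric matrix
#'   (snippets in rows), all the same length and peak-aligned.
#' @param sampling_rate_hz sampling rate, used when `snippets` is a matrix.
#' @return a `waveform` holding the pointwise mean.
#' @export
average_waveform <- function(snippets, sampling_rate_hz = 20000) {
  if (is.list(snippets) && inherits(snippets[[1]], "waveform")) {
    lens <- vapply(snippets, function(w) length(w$samples), integer(1))
    if (length(unique(lens)) != 1L) stop("snippets have mismatched lengths")
    sampling_rate_hz <- snippets[[1]]$sampling_rate_hz
    m <- do.call(rbind, lapply(snippets, function(w) w$samples))
  } else {
    m <- as.matrix(snippets)
  }
  avg <- colMeans(m)
  structure(list(samples = avg, sampling_rate_hz = sampling_rate_hz,
                 alignment = which.max(avg)),
            class = "waveform")
}

# linear-interpolated crossing time (in samples, fractional) of level `lev`
# between samples k and k+1 of v
interp_crossing <- function(v, k, lev) {
  k + (lev - v[k]) / (v[k + 1L] - v[k])
}

#' Extract spike-shape features from a waveform
#'
#' Baseline is the mean of the first quarter of the snippet (pre-spike
#' segment). Features: `peak_to_trough_ms`, the time from the positive peak
#' to the subsequent minimum; `half_width_ms`, the width of the positive
#' peak at half its baseline-subtracted amplitude, with linear
#' interpolation between samples for sub-sample crossings; and
#' `negativity_amp`, the trough amplitude as a fraction of the peak
#' amplitude. Monophasic waveforms (no post-peak negativity) yield absent
#' trough-dependent features with a reason code.
#'
#' @param wf a `waveform`.
#' @param baseline_frac fraction of leading samples defining the baseline.
#' @return list of class `waveform_features` with `peak_to_trough_ms`,
#'   `half_width_ms`, `negativity_amp` (any of which may be an
#'   `absent_stat`).
#' @export
extract_features <- function(wf, baseline_frac = 0.25) {
  v <- wf$samples
  n <- length(v)
  dt_ms <- 1000 / wf$sampling_rate_hz
  baseline <- mean(v[seq_len(max(1L, floor(n * baseline_frac)))])
  u <- v - baseline
  pk <- which.max(u)
  amp <- u[pk]
  if (amp <= 0) stop("waveform has no identifiable positive peak")

  # half-width of the positive lobe at amp/2, sub-sample interpolated
  lev <- amp / 2
  left <- NA_real_
  if (pk > 1L) {
    for (k in seq.int(pk - 1L, 1L)) {
      if (u[k] < lev) { left <- interp_crossing(u, k, lev); break }
    }
  }
  right <- NA_real_
  if (pk < n) {
    for (k in seq.int(pk, n - 1L)) {
      if (u[k + 1L] < lev) { right <- interp_crossing(u, k, lev); break }
    }
  }
  half_width <- if (is.na(left) || is.na(right)) {
    absent_stat("no_half_crossing")
  } else {
    (right - left) * dt_ms
  }

  # trough after the peak
  post <- u[seq.int(pk, n)]
  tr_rel <- which.min(post)
  if (post[tr_rel] >= 0) {
    p2t <- absent_stat("monophasic")
    negativity <- absent_stat("monophasic")
  } else {
    p2t <- (tr_rel - 1L) * dt_ms
    negativity <- abs(post[tr_rel]) / amp
  }
  structure(list(peak_to_trough_ms = p2t, half_width_ms = half_width,
                 negativity_amp = negativity, peak_amp = amp,
                 baseline = baseline),
            class = "waveform_features")
}

#' Bursting index of a spike train
#'
#' Fraction of spikes whose preceding inter-spike interval is shorter than
#' `isi_threshold_ms` (default 6 ms). The first spike has no preceding
#' interval and contributes only to the denominator.
#'
#' @param spikes a `spike_train` or numeric spike-time vector (s).
#' @param isi_threshold_ms ISI threshold in milliseconds.
#' @return unitless index in [0, 1].
#' @export
bursting_index <- function(spikes, isi_threshold_ms = 6) {
  st <- sort(spike_times(spikes))
  if (length(st) == 0L) stop("empty spike train")
  if (length(st) == 1L) return(0)
  sum(diff(st) < isi_threshold_ms / 1000) / length(st)
}

#' Classify a cell as fast-spiking (FS)
#'
#' FS when the spike is narrow (peak-to-trough below `width_ms`) AND the
#' mean rate is high (above `rate_hz`). Thresholds default to 0.4 ms and
#' 5 Hz and are always echoed in the result so reports record the criteria
#' actually applied.
#'
#' @param features a `waveform_features` result.
#' @param mean_rate_hz the cell's mean firing rate (Hz).
#' @param width_ms peak-to-trough threshold (ms).
#' @param rate_hz rate threshold (Hz).
#' @return list with logical `is_fs` and the thresholds used.
#' @export
classify_fs <- function(features, mean_rate_hz, width_ms = 0.4, rate_hz = 5) {
  p2t <- features$peak_to_trough_ms
  is_fs <- !is_absent(p2t) && p2t < width_ms && mean_rate_hz > rate_hz
  list(is_fs = is_fs, width_threshold_ms = width_ms,
       rate_threshold_hz = rate_hz)
}
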