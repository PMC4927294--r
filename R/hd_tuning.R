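# internal: precompute everything the tuning curve and its shuffles reuse:
# per-frame bin assignment, movement mask, occupancy, frame grid geometry
tuning_frame_data <- function(kin, n_bins = 36) {
  dt <- attr(kin, "dt")
  bin_width <- 2 * pi / n_bins
  frame_bin <- pmin(floor(wrap_angle(kin$theta) / bin_width) + 1L, n_bins)
  occupancy <- as.numeric(tabulate(frame_bin[kin$moving], nbins = n_bins)) * dt
  list(n_bins = n_bins, dt = dt, frame_bin = frame_bin, moving = kin$moving,
       t0 = kin$t[1], n_frames = nrow(kin), occupancy = occupancy,
       bin_centers = (seq_len(n_bins) - 0.5) * bin_width)
}

# internal: spike counts per HD bin for given spike times (movement only)
spike_bin_counts <- function(st, fd) {
  idx <- findInterval(st - fd$t0, (seq_len(fd$n_frames) - 1L) * fd$dt)
  idx <- idx[idx >= 1L & idx <= fd$n_frames]
  idx <- idx[fd$moving[idx]]
  as.numeric(tabulate(fd$frame_bin[idx], nbins = fd$n_bins))
}

#' Head-direction tuning curve
#'
#' Occupancy-normalised firing rate in `n_bins` equal head-direction bins
#' (default 36 bins of 10 degrees). Each spike is assigned the head angle of
#' its containing video frame; occupancy is the summed frame duration per
#' bin. Only movement-period frames and spikes enter. Every bin must be
#' visited at least once during movement; violations raise an error listing
#' the empty bins rather than silently producing NaN rates.
#'
#' @param spikes a `spike_train` or numeric spike-time vector (s).
#' @param kin a populated `kinematics` data frame.
#' @param n_bins number of direction bins, default 36.
#' @return a `tuning_curve`: list with `bin_centers` (rad), `occupancy` (s),
#'   `spike_counts`, `rates` (Hz).
#' @export
compute_tuning_curve <- function(spikes, kin, n_bins = 36) {
  fd <- tuning_frame_data(kin, n_bins)
  empty <- which(fd$occupancy <= 0)
  if (length(empty)) {
    stop("unvisited head-direction bins during movement: ",
         paste(empty, collapse = ", "))
  }
  counts <- spike_bin_counts(spike_times(spikes), fd)
  structure(list(bin_centers = fd$bin_centers, occupancy = fd$occupancy,
                 spike_counts = counts, rates = counts / fd$occupancy),
            class = "tuning_curve")
}

#' HD index: mean resultant length of the tuning curve
#'
#' The Rayleigh vector of the binned tuning curve: each bin centre
#' contributes a unit vector weighted by its firing rate, and the index is
#' the length of the mean resultant,
#' `R = |sum_i r_i exp(1i*theta_i)| / sum_i r_i`, in [0, 1]. 0 for a flat
#' curve, 1 when all rate mass sits in one bin.
#'
#' @param curve a `tuning_curve`.
#' @return the HD index (unitless, in [0, 1]).
#' @export
hd_index <- function(curve) {
  r <- curve$rates
  if (any(r < 0)) stop("negative rates")
  tot <- sum(r)
  if (tot <= 0) stop("all-zero tuning curve: HD index undefined (silent cell)")
  Mod(sum(r * exp(1i * curve$bin_centers))) / tot
}

#' Preferred firing direction of a tuning curve
#'
#' Circular mean of the rate-weighted bin-centre vectors (the argument of
#' the same resultant that defines the HD index). The peak-rate bin centre
#' is attached as attribute `peak_bin_dir` for display ordering.
#'
#' @param curve a `tuning_curve`.
#' @return preferred direction in radians, `[0, 2*pi)`.
#' @export
preferred_direction <- function(curve) {
  tot <- sum(curve$rates)
  if (tot <= 0) stop("all-zero tuning curve: preferred direction undefined")
  pd <- wrap_angle(Arg(sum(curve$rates * exp(1i * curve$bin_centers))))
  attr(pd, "peak_bin_dir") <- curve$bin_centers[which.max(curve$rates)]
  pd
}

#' Whole-train time-shift shuffle test for HD tuning
#'
#' Each permutation rigidly shifts the entire spike sequence by one uniform
#' random offset (at least `min_shift_s` from either session edge) with
#' circular wraparound over the session, then recomputes the HD index
#' against the unshifted kinematics. The p-value is the add-one-corrected
#' fraction of null indices at least as large as the observed one,
#' `p = (1 + #{null >= obs}) / (1 + n_perm)`; a cell is classified HD when
#' its observed index exceeds the 95th percentile of its own null
#' distribution.
#'
#' @param spikes a `spike_train` or numeric spike-time vector (s).
#' @param kin a populated `kinematics` data frame.
#' @param n_perm number of permutations (default 1000).
#' @param min_shift_s minimum shift magnitude (s), clamped to a quarter of
#'   the session for short recordings.
#' @param seed RNG seed for the shift draws.
#' @param n_bins number of direction bins.
#' @return list with `observed`, `p_value`, `null_distribution`,
#'   `threshold` (null 95th percentile) and logical `is_hd`.
#' @export
shuffle_test_hd <- function(spikes, kin, n_perm = 1000, min_shift_s = 20,
                            seed = 1L, n_bins = 36) {
  st <- spike_times(spikes)
  if (length(st) == 0L) stop("cannot shuffle an empty spike train")
  if (n_perm < 100) warning("fewer than 100 permutations: p-value resolution is poor")
  fd <- tuning_frame_data(kin, n_bins)
  if (any(fd$occupancy <= 0)) {
    stop("unvisited head-direction bins during movement")
  }
  T_end <- fd$n_frames * fd$dt
  min_shift <- min(min_shift_s, T_end / 4)
  idx_of <- function(times) {
    counts <- spike_bin_counts(times, fd)
    tot <- sum(counts / fd$occupancy)
    if (tot <= 0) return(0)
    Mod(sum((counts / fd$occupancy) * exp(1i * fd$bin_centers))) / tot
  }
  observed <- idx_of(st)
  set.seed(seed)
  shifts <- stats::runif(n_perm, min_shift, T_end - min_shift)
  rel <- st - fd$t0
  null <- vapply(shifts,
                 function(s) idx_of(((rel + s) %% T_end) + fd$t0),
                 numeric(1))
  threshold <- stats::quantile(null, 0.95, names = FALSE)
  list(observed = observed,
       p_value = (1 + sum(null >= observed)) / (1 + n_perm),
       null_distribution = null,
       threshold = threshold,
       is_hd = observed > threshold)
}

#' Split-half stability of HD tuning
#'
#' Tuning curves are computed separately for the first and second half of
#' the recording time; stability is Pearson's linear correlation between
#' the two 36-bin rate vectors. Requires every bin to be sampled in each
#' half; otherwise (or when a half-curve has zero variance) an absent value
#' with a reason code is returned instead of a number.
#'
#' @param spikes a `spike_train` or numeric spike-time vector (s).
#' @param kin a populated `kinematics` data frame.
#' @param n_bins number of direction bins.
#' @return Pearson r, or an `absent_stat` with reason `"bin_coverage"` or
#'   `"zero_variance"`.
#' @export
split_half_stability <- function(spikes, kin, n_bins = 36) {
  st <- spike_times(spikes)
  n <- nrow(kin)
  half <- floor(n / 2)
  t_mid <- kin$t[half + 1L]
  halves <- list(seq_len(half), seq.int(half + 1L, n))
  rates <- vector("list", 2L)
  for (h in 1:2) {
    kin_h <- kin[halves[[h]], , drop = FALSE]
    attr(kin_h, "dt") <- attr(kin, "dt")
    st_h <- if (h == 1) st[st < t_mid] else st[st >= t_mid]
    fd <- tuning_frame_data(kin_h, n_bins)
    if (any(fd$occupancy <= 0)) return(absent_stat("bin_coverage"))
    rates[[h]] <- spike_bin_counts(st_h, fd) / fd$occupancy
  }
  if (stats::sd(rates[[1]]) == 0 || stats::sd(rates[[2]]) == 0) {
    return(absent_stat("zero_variance"))
  }
  stats::cor(rates[[1]], rates[[2]])
}

#' Classify a cell's head-direction tuning
#'
#' A cell is an HD cell when its HD index exceeds the 95th percentile of
#' its shuffle null; it is a "strong" HD cell when additionally the index
#' exceeds `strong_index` (default 0.8) and the shuffle p-value is below
#' `strong_p` (default 0.01).
#'
#' @param hd_index observed HD index.
#' @param p_value shuffle p-value.
#' @param null_threshold 95th percentile of the cell's null distribution.
#' @param strong_index,strong_p thresholds for the strong-HD criterion.
#' @return list with logicals `is_hd` and `is_strong_hd`.
#' @export
classify_hd <- function(hd_index, p_value, null_threshold,
                        strong_index = 0.8, strong_p = 0.01) {
  is_hd <- hd_index > null_threshold
  list(is_hd = is_hd,
       is_strong_hd = is_hd && hd_index > strong_index && p_value < strong_p)
}

#' Full per-cell head-direction analysis
#'
#' Tuning curve, HD index, shuffle significance, preferred direction, peak
#' and mean rates (movement-only and whole-session), split-half stability,
#' and classification flags.
#'
#' @inheritParams shuffle_test_hd
#' @param strong_index,strong_p strong-HD thresholds (see [classify_hd()]).
#' @return list of class `hd_result`.
#' @export
analyze_hd <- function(spikes, kin, n_perm = 1000, min_shift_s = 20,
                       seed = 1L, n_bins = 36,
                       strong_index = 0.8, strong_p = 0.01) {
  st <- spike_times(spikes)
  curve <- compute_tuning_curve(st, kin, n_bins)
  idx <- hd_index(curve)
  sh <- shuffle_test_hd(st, kin, n_perm = n_perm, min_shift_s = min_shift_s,
                        seed = seed, n_bins = n_bins)
  flags <- classify_hd(idx, sh$p_value, sh$threshold,
                       strong_index = strong_index, strong_p = strong_p)
  dt <- attr(kin, "dt")
  mov_time <- sum(kin$moving) * dt
  structure(list(
    curve = curve,
    hd_index = idx,
    p_value = sh$p_value,
    null_distribution = sh$null_distribution,
    preferred_dir = preferred_direction(curve),
    peak_rate = max(curve$rates),
    mean_rate = sum(curve$spike_counts) / mov_time,
    mean_rate_session = length(st) / session_duration(kin),
    stability_r = split_half_stability(st, kin, n_bins),
    is_hd = flags$is_hd,
    is_strong_hd = flags$is_strong_hd
  ), class = "hd_result")
}
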