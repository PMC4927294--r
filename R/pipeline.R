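#' Default analysis configuration
#'
#' Every threshold used anywhere in the pipeline, in one declarative list:
#' direction bins, coordinate smoothing window, movement cutoff, inversion
#' dead-band, autocorrelogram binning, theta bands, spike-count inclusion
#' threshold, bursting ISI threshold, permutation count, percentile
#' criterion, strong-HD thresholds, FS thresholds, minimum rigid shift.
#'
#' @return a named list of class `spikerot_config`.
#' @export
default_config <- function() {
  structure(list(
    n_bins = 36L,
    window_s = 0.6,
    cutoff_cm_s = 1.0,
    inversion_eps = 1e-4,
    acg_bin_s = 0.010,
    acg_max_lag_s = 0.5,
    theta_band_hz = c(4, 12),
    theta_denom_hz = c(1, 50),
    theta_min_spikes = 20L,
    theta_weak_threshold = 5,
    burst_isi_ms = 6,
    n_perm = 1000L,
    percentile = 0.95,
    strong_hd_index = 0.8,
    strong_hd_p = 0.01,
    fs_width_ms = 0.4,
    fs_rate_hz = 5,
    min_shift_s = 20,
    mc_correction = "none",
    offset_rad = 0
  ), class = "spikerot_config")
}

# value for the report table: unwrap absent_stat into NA + reason
report_value <- function(x) {
  if (is_absent(x)) list(value = NA_real_, reason = x$reason)
  else list(value = as.numeric(x), reason = NULL)
}

#' Analyse one cell against a session's kinematics
#'
#' Runs the head-direction, theta-rhythmicity, speed-modulation and
#' spike-feature analyses for a single cell and assembles a `cell_report`.
#' Statistics that cannot be computed (e.g. unvisited direction bins, too
#' few spikes, silent cell) are recorded as `NA` with a reason code; the
#' remaining fields are still populated.
#'
#' @param cell_id identifier string.
#' @param spikes a `spike_train` or numeric spike-time vector (s).
#' @param kin a populated `kinematics` data frame.
#' @param waveform optional `waveform` for shape features.
#' @param layer layer label (`"L2"`, `"L3"`, `"deep"`, `"unknown"`).
#' @param config a [default_config()]-style list.
#' @param seed RNG seed for the shuffles.
#' @return a list of class `cell_report`.
#' @export
analyze_cell <- function(cell_id, spikes, kin, waveform = NULL,
                         layer = "unknown", config = default_config(),
                         seed = 1L) {
  st <- sort(spike_times(spikes))
  dur <- session_duration(kin)
  mean_rate_session <- length(st) / dur
  mov_time <- sum(kin$moving) * attr(kin, "dt")
  mean_rate_mov <- length(movement_spikes(st, kin)) / mov_time

  hd <- tryCatch(
    analyze_hd(st, kin, n_perm = config$n_perm,
               min_shift_s = config$min_shift_s, seed = seed,
               n_bins = config$n_bins,
               strong_index = config$strong_hd_index,
               strong_p = config$strong_hd_p),
    error = function(e) absent_stat(conditionMessage(e)))

  theta <- tryCatch(
    analyze_theta(st, kin, n_perm = config$n_perm, seed = seed,
                  bin_s = config$acg_bin_s,
                  max_lag_s = config$acg_max_lag_s,
                  min_spikes = config$theta_min_spikes),
    error = function(e) absent_stat(conditionMessage(e)))

  speed <- tryCatch(
    analyze_speed(st, kin, n_perm = config$n_perm,
                  min_shift_s = config$min_shift_s, seed = seed),
    error = function(e) absent_stat(conditionMessage(e)))

  burst <- tryCatch(bursting_index(st, config$burst_isi_ms),
                    error = function(e) absent_stat(conditionMessage(e)))

  feats <- NULL
  fs <- NULL
  if (!is.null(waveform)) {
    feats <- tryCatch(extract_features(waveform),
                      error = function(e) absent_stat(conditionMessage(e)))
    if (!is_absent(feats)) {
      fs <- classify_fs(feats, mean_rate_session,
                        width_ms = config$fs_width_ms,
                        rate_hz = config$fs_rate_hz)
    }
  }

  structure(list(
    cell_id = cell_id, layer = layer,
    n_spikes = length(st),
    mean_rate_hz = mean_rate_session,
    mean_rate_movement_hz = mean_rate_mov,
    hd = hd, theta = theta, speed = speed,
    bursting_index = burst,
    waveform_features = feats,
    fs = fs,
    kinematics_summary = summarize_kinematics(kin),
    config = config, seed = seed
  ), class = "cell_report")
}

#' Run the full pipeline on a session's files
#'
#' Reads tracking and per-cell spike CSVs, computes kinematics, analyses
#' every cell (failing loudly per cell but continuing the session), and
#' returns the reports plus a manifest of parameters and seeds.
#'
#' @param tracking_file tracking CSV (`t_s,x_cm,y_cm`).
#' @param spike_files character vector of spike-time CSV paths, one per cell.
#' @param waveform_file optional waveform CSV matrix (one snippet per row).
#' @param layers optional character vector of layer labels per cell.
#' @param config a [default_config()]-style list.
#' @param seed base RNG seed; cell `i` uses `seed + i`.
#' @return list with `reports` (list of `cell_report`), `kin`, `manifest`.
#' @export
run_session <- function(tracking_file, spike_files, waveform_file = NULL,
                        layers = NULL, config = default_config(), seed = 1L) {
  trace <- read_tracking_csv(tracking_file)
  kin <- compute_kinematics(trace, window_s = config$window_s,
                            cutoff_cm_s = config$cutoff_cm_s,
                            offset_rad = config$offset_rad)
  wf_mat <- NULL
  if (!is.null(waveform_file)) {
    wf_mat <- as.matrix(utils::read.table(waveform_file, sep = ","))
  }
  if (is.null(layers)) layers <- rep("unknown", length(spike_files))
  reports <- vector("list", length(spike_files))
  for (i in seq_along(spike_files)) {
    st <- read_spikes_csv(spike_files[i])
    wf <- if (!is.null(wf_mat)) {
      structure(list(samples = as.numeric(wf_mat[i, ]),
                     sampling_rate_hz = 20000,
                     alignment = which.max(wf_mat[i, ])),
                class = "waveform")
    }
    reports[[i]] <- analyze_cell(
      cell_id = sprintf("cell%02d", i), spikes = st, kin = kin,
      waveform = wf, layer = layers[i], config = config, seed = seed + i)
  }
  manifest <- list(tracking_file = tracking_file,
                   spike_files = spike_files,
                   waveform_file = waveform_file,
                   config = unclass(config), seed = seed,
                   processing_order = "smooth_then_mask",
                   mc_correction = config$mc_correction)
  list(reports = reports, kin = kin, manifest = manifest)
}

#' Flatten cell reports into a one-row-per-cell table
#'
#' The session summary table: one row per cell with all scalar statistics
#' and classification flags; absent statistics appear as `NA` with their
#' reason in a matching `*_reason` column.
#'
#' @param reports list of `cell_report` objects.
#' @return a data frame.
#' @export
reports_table <- function(reports) {
  row_of <- function(rep) {
    g <- function(x, f) if (is_absent(x) || is.null(x)) NA_real_ else f(x)
    gr <- function(x) if (is_absent(x)) x$reason else NA_character_
    hd <- rep$hd
    th <- rep$theta
    sp <- rep$speed
    wf <- rep$waveform_features
    data.frame(
      cell_id = rep$cell_id, layer = rep$layer,
      n_spikes = rep$n_spikes,
      mean_rate_hz = rep$mean_rate_hz,
      mean_rate_movement_hz = rep$mean_rate_movement_hz,
      hd_index = g(hd, function(x) x$hd_index),
      hd_p = g(hd, function(x) x$p_value),
      preferred_dir_deg = g(hd, function(x) x$preferred_dir * 180 / pi),
      peak_rate_hz = g(hd, function(x) x$peak_rate),
      stability_r = if (is_absent(hd)) NA_real_ else
        (if (is_absent(hd$stability_r)) NA_real_ else hd$stability_r),
      is_hd = if (is_absent(hd)) NA else hd$is_hd,
      is_strong_hd = if (is_absent(hd)) NA else hd$is_strong_hd,
      hd_reason = gr(hd),
      theta_index = g(th, function(x) x$observed$theta_index),
      theta_peak_hz = g(th, function(x) x$observed$peak_freq_hz),
      theta_p = g(th, function(x) x$p_value),
      is_theta_rhythmic = if (is_absent(th)) NA else th$is_theta_rhythmic,
      theta_weak = if (is_absent(th)) NA else th$observed$is_weak,
      theta_reason = gr(th),
      speed_score = g(sp, function(x) x$observed),
      speed_p = g(sp, function(x) x$p_value),
      is_speed_modulated = if (is_absent(sp)) NA else sp$is_speed_modulated,
      rate_rest_hz = if (is_absent(sp)) NA_real_ else
        (if (is_absent(sp$rate_rest_hz)) NA_real_ else sp$rate_rest_hz),
      rate_rotation_hz = if (is_absent(sp)) NA_real_ else
        (if (is_absent(sp$rate_rotation_hz)) NA_real_ else sp$rate_rotation_hz),
      speed_reason = gr(sp),
      bursting_index = g(rep$bursting_index, as.numeric),
      half_width_ms = if (is.null(wf) || is_absent(wf)) NA_real_ else
        (if (is_absent(wf$half_width_ms)) NA_real_ else wf$half_width_ms),
      peak_to_trough_ms = if (is.null(wf) || is_absent(wf)) NA_real_ else
        (if (is_absent(wf$peak_to_trough_ms)) NA_real_ else wf$peak_to_trough_ms),
      negativity_amp = if (is.null(wf) || is_absent(wf)) NA_real_ else
        (if (is_absent(wf$negativity_amp)) NA_real_ else wf$negativity_amp),
      is_fs = if (is.null(rep$fs)) NA else rep$fs$is_fs,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(reports, row_of))
}

#' Write per-cell reports to deterministic JSON
#'
#' @param reports list of `cell_report` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cell_reports <- function(reports, path) {
  tab <- reports_table(reports)
  jsonlite::write_json(list(schema_version = "1.0", cells = tab),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = 12,
                       na = "null")
  invisible(path)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison
#'
#' Exact p for small untied samples, normal approximation with tie
#' correction otherwise (the switch is the stats::wilcox.test default:
#' exact when both groups have fewer than 50 observations and there are no
#' ties).
#'
#' @param group_a,group_b numeric vectors.
#' @param statistic_name label recorded in the result.
#' @return a `group_comparison` list with medians and the two-sided p.
#' @export
mann_whitney <- function(group_a, group_b, statistic_name = "statistic") {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  pooled <- c(group_a, group_b)
  if (length(unique(pooled)) == 1L) {
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(group_a, group_b, alternative = "two.sided")$p.value)
  }
  structure(list(test_name = "mann_whitney",
                 statistic_name = statistic_name,
                 groups = c("A", "B"),
                 median_a = stats::median(group_a),
                 median_b = stats::median(group_b),
                 p_value = p),
            class = "group_comparison")
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p by summing hypergeometric probabilities no larger than that
#' of the observed table.
#'
#' @param table a 2x2 matrix of non-negative integer counts.
#' @param statistic_name label recorded in the result.
#' @return a `group_comparison` list.
#' @export
fisher_exact <- function(table, statistic_name = "proportion") {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  p <- stats::fisher.test(table, alternative = "two.sided")$p.value
  structure(list(test_name = "fisher_exact",
                 statistic_name = statistic_name,
                 table = table,
                 p_value = p),
            class = "group_comparison")
}

#' Percentage helper for report composition tables
#'
#' @param k numerator count.
#' @param n denominator count, > 0.
#' @return `100 * k / n`.
#' @export
proportion_percent <- function(k, n) {
  stopifnot(n > 0, k >= 0)
  100 * k / n
}

#' Between-layer comparison set
#'
#' Reproduces the standard per-layer contrasts from a report table: HD
#' index (Mann-Whitney), proportion of HD cells (Fisher exact), theta
#' index, spike half-width and spike negativity (Mann-Whitney), with
#' per-group medians.
#'
#' @param table a [reports_table()] data frame with a `layer` column.
#' @param layers the two layer labels to compare, default `c("L2", "L3")`.
#' @return named list of `group_comparison` objects.
#' @export
layer_summary <- function(table, layers = c("L2", "L3")) {
  present <- intersect(layers, unique(table$layer))
  if (length(present) < 2L) stop("need at least two layers to compare")
  a <- table[table$layer == layers[1], , drop = FALSE]
  b <- table[table$layer == layers[2], , drop = FALSE]
  mw <- function(col) {
    va <- a[[col]][!is.na(a[[col]])]
    vb <- b[[col]][!is.na(b[[col]])]
    mann_whitney(va, vb, statistic_name = col)
  }
  hd_tab <- rbind(c(sum(a$is_hd, na.rm = TRUE), sum(!a$is_hd, na.rm = TRUE)),
                  c(sum(b$is_hd, na.rm = TRUE), sum(!b$is_hd, na.rm = TRUE)))
  list(hd_index = mw("hd_index"),
       pct_hd = fisher_exact(hd_tab, statistic_name = "pct_hd"),
       theta_index = mw("theta_index"),
       half_width_ms = mw("half_width_ms"),
       negativity_amp = mw("negativity_amp"))
}
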