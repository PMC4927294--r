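# independent mean-resultant-length oracle, real-arithmetic (no complex)
mrl_oracle <- function(rates, bins) {
  cx <- sum(rates * cos(bins))
  cy <- sum(rates * sin(bins))
  sqrt(cx^2 + cy^2) / sum(rates)
}

make_curve <- function(rates, n_bins = 36) {
  structure(list(bin_centers = (seq_len(n_bins) - 0.5) * 2 * pi / n_bins,
                 occupancy = rep(1, n_bins), spike_counts = rates,
                 rates = rates),
            class = "tuning_curve")
}

test_that("hd_index has its closed-form values on canonical curves", {
  expect_lt(hd_index(make_curve(rep(2.5, 36))), 1e-12)             # flat
  single <- rep(0, 36); single[7] <- 4
  expect_equal(hd_index(make_curve(single)), 1)                    # one bin
  opp <- rep(0, 36); opp[1] <- 3; opp[19] <- 3                     # 180 deg apart
  expect_lt(hd_index(make_curve(opp)), 1e-12)
  bins <- make_curve(rep(1, 36))$bin_centers
  cosine <- 1 + cos(bins - 1.234)
  expect_equal(hd_index(make_curve(cosine)), 0.5, tolerance = 1e-12)
})

test_that("hd_index agrees with the direct vector-sum oracle on random curves", {
  set.seed(17)
  bins <- make_curve(rep(1, 36))$bin_centers
  for (i in 1:200) {
    rates <- rgamma(36, shape = 0.7)
    expect_equal(hd_index(make_curve(rates)), mrl_oracle(rates, bins),
                 tolerance = 1e-12)
  }
})

test_that("hd_index is invariant to rate rescaling and bin-centre rotation", {
  set.seed(8)
  rates <- rexp(36)
  base <- hd_index(make_curve(rates))
  expect_equal(hd_index(make_curve(7.3 * rates)), base, tolerance = 1e-12)
  rotated <- make_curve(rates)
  rotated$bin_centers <- rotated$bin_centers + 0.9
  expect_equal(hd_index(rotated), base, tolerance = 1e-12)
})

test_that("hd_index rejects silent cells", {
  expect_error(hd_index(make_curve(rep(0, 36))), "silent")
})

test_that("tuning curve matches a per-bin counting oracle on a generated session", {
  kin <- demo_kin(duration_s = 300, seed = 11)
  st <- generate_spike_train(kin, cell_spec(base_rate_hz = 6, kappa = 2,
                                            preferred_dir_rad = 2, seed = 3))
  tc <- compute_tuning_curve(st, kin)
  # brute-force loop oracle: assign each spike/frame to its bin by hand
  dt <- attr(kin, "dt")
  width <- 2 * pi / 36
  occ <- counts <- numeric(36)
  for (i in seq_len(nrow(kin))) {
    if (kin$moving[i]) {
      b <- min(floor((kin$theta[i] %% (2 * pi)) / width) + 1, 36)
      occ[b] <- occ[b] + dt
    }
  }
  for (s in st$times) {
    fr <- floor((s - kin$t[1]) / dt) + 1
    if (fr >= 1 && fr <= nrow(kin) && kin$moving[fr]) {
      b <- min(floor((kin$theta[fr] %% (2 * pi)) / width) + 1, 36)
      counts[b] <- counts[b] + 1
    }
  }
  expect_equal(tc$occupancy, occ, tolerance = 1e-9)
  expect_equal(tc$spike_counts, counts)
  expect_equal(tc$rates, counts / occ, tolerance = 1e-9)
  expect_equal(sum(tc$occupancy), sum(kin$moving) * dt, tolerance = 1e-9)
})

test_that("uniform sweep with one spike per bin gives 1 Hz everywhere", {
  kin <- uniform_sweep_kin(n_rev = 1, dt = 0.04)   # 36 s, 1 s per bin
  width <- 2 * pi / 36
  spikes <- vapply(1:36, function(b) {
    kin$t[which(floor(kin$theta / width) + 1 == b)[1]] + 0.001
  }, numeric(1))
  tc <- compute_tuning_curve(spikes, kin)
  expect_equal(tc$rates, rep(1, 36), tolerance = 1e-9)
  expect_equal(sum(tc$occupancy), 36, tolerance = 1e-9)
})

test_that("no movement spikes yields an all-zero curve over full occupancy", {
  kin <- uniform_sweep_kin(n_rev = 1)
  tc <- compute_tuning_curve(numeric(0), kin)
  expect_equal(tc$rates, rep(0, 36))
  expect_equal(sum(tc$occupancy), 36, tolerance = 1e-9)
})

test_that("zero-occupancy bins are a reported precondition failure", {
  # half sweep only: bins 19..36 never visited
  kin <- manual_kin(seq(0, pi - 0.01, length.out = 500))
  expect_error(compute_tuning_curve(numeric(0), kin), "unvisited")
})

test_that("preferred direction matches the complex-argument oracle", {
  single <- rep(0, 36); single[10] <- 2   # bin centred at 95 degrees
  expect_equal(as.numeric(preferred_direction(make_curve(single))),
               (9.5) * 10 * pi / 180, tolerance = 1e-12)
  bins <- make_curve(rep(1, 36))$bin_centers
  cosine <- 1 + cos(bins - 2.8)
  expect_equal(as.numeric(preferred_direction(make_curve(cosine))), 2.8,
               tolerance = 1e-9)
  set.seed(4)
  two <- rep(0, 36); two[c(3, 8)] <- c(1.5, 0.5)
  oracle <- atan2(sum(two * sin(bins)), sum(two * cos(bins))) %% (2 * pi)
  expect_equal(as.numeric(preferred_direction(make_curve(two))), oracle,
               tolerance = 1e-12)
})

test_that("rigid shuffle preserves spike count and reproduces the observed index at shift 0", {
  kin <- demo_kin(duration_s = 300, seed = 11)
  st <- generate_spike_train(kin, cell_spec(base_rate_hz = 5, kappa = 3, seed = 6))
  tc <- compute_tuning_curve(st, kin)
  obs <- hd_index(tc)
  sh <- shuffle_test_hd(st, kin, n_perm = 150, seed = 2)
  expect_equal(sh$observed, obs, tolerance = 1e-12)
  # shift by a full session is the identity permutation
  T_end <- nrow(kin) * attr(kin, "dt")
  st0 <- (st$times %% T_end)
  expect_equal(hd_index(compute_tuning_curve(st0, kin)), obs, tolerance = 1e-12)
  expect_length(sh$null_distribution, 150L)
})

test_that("a strongly tuned cell is detected with small p for every seed", {
  kin <- demo_kin(duration_s = 300, seed = 11)
  for (s in 1:20) {
    st <- generate_spike_train(kin, cell_spec(base_rate_hz = 5, kappa = 4,
                                              preferred_dir_rad = s / 4,
                                              seed = 100 + s))
    sh <- shuffle_test_hd(st, kin, n_perm = 200, seed = s)
    expect_lt(sh$p_value, 0.05)
    expect_true(sh$is_hd)
  }
})

test_that("split-half stability is 1 for identical halves and -1 for mirrored halves", {
  # deterministic construction: a staircase that parks 25 frames at each
  # bin centre, repeated identically (plus one revolution) in each half
  width <- 2 * pi / 36
  stair <- rep((1:36 - 0.5) * width, each = 25)
  kin1 <- manual_kin(c(stair, stair + 2 * pi), dt = 0.04)
  half_T <- length(stair) * 0.04
  # mid-bin spike times, counts varying with the bin (b mod 4)
  first_t <- ((1:36 - 1) * 25 + 13 - 1) * 0.04 + 0.001
  spikes1 <- rep(first_t, times = (seq_len(36) %% 4L))
  spikes <- sort(c(spikes1, spikes1 + half_T))
  expect_equal(split_half_stability(spikes, kin1), 1, tolerance = 1e-9)
})

test_that("split-half stability on a stable simulated HD cell is high", {
  kin <- demo_kin(duration_s = 600, seed = 12, n_inversions = 10)
  rs <- vapply(1:25, function(s) {
    st <- generate_spike_train(kin, cell_spec(base_rate_hz = 5, kappa = 4,
                                              preferred_dir_rad = 1, seed = 400 + s))
    split_half_stability(st, kin)
  }, numeric(1))
  expect_gt(mean(rs), 0.7)
})

test_that("split-half returns reason codes instead of numbers when undefined", {
  # second half is all-rest: bins unsampled in that half
  u <- c(seq(0, 4 * pi, length.out = 500), rep(4 * pi, 500))
  kin <- manual_kin(u)
  kin <- movement_mask(kin)
  r <- split_half_stability(numeric(0), kin)
  expect_s3_class(r, "absent_stat")
  expect_equal(r$reason, "bin_coverage")
  # both halves covered, no spikes: zero variance
  kin2 <- uniform_sweep_kin(n_rev = 2)
  r2 <- split_half_stability(numeric(0), kin2)
  expect_equal(r2$reason, "zero_variance")
})

test_that("HD classification applies the percentile and strong criteria", {
  f <- classify_hd(0.9, 0.001, null_threshold = 0.3)
  expect_true(f$is_hd); expect_true(f$is_strong_hd)
  f2 <- classify_hd(0.9, 0.02, null_threshold = 0.3)
  expect_true(f2$is_hd); expect_false(f2$is_strong_hd)
  f3 <- classify_hd(0.95, 0.001, null_threshold = 0.96)
  expect_false(f3$is_hd); expect_false(f3$is_strong_hd)
})
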