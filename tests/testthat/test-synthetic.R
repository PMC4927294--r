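test_that("generated trajectory sits on an exact frame grid and a circle", {
  sp <- session_spec(duration_s = 60, frame_rate_hz = 25, seed = 3)
  tr <- generate_rotation_trajectory(sp)
  expect_equal(diff(tr$t), rep(0.040, nrow(tr) - 1L), tolerance = 1e-12)
  expect_equal(nrow(tr), 1500L)
  r <- sqrt((tr$x - 50)^2 + (tr$y - 50)^2)
  expect_equal(r, rep(sp$led_radius_cm, nrow(tr)), tolerance = 1e-9)
})

test_that("trajectory contains the scheduled number of direction reversals", {
  for (k in c(0L, 3L, 9L)) {
    sp <- session_spec(duration_s = 300, n_inversions = k, seed = 20 + k)
    tr <- generate_rotation_trajectory(sp)
    kin <- compute_kinematics(tr)
    expect_identical(count_inversions(kin), k)
  }
})

test_that("movement-frame angular speed approximates the target speed", {
  sp <- session_spec(duration_s = 300, target_angular_speed_rad_s = 1.1,
                     rest_fraction = 0.2, seed = 1)
  tr <- generate_rotation_trajectory(sp)
  kin <- compute_kinematics(tr)
  # independent finite-difference recomputation from the raw angles
  theta_true <- attr(tr, "theta_true")
  omega_fd <- diff(theta_true) / diff(tr$t)
  mov <- kin$moving[-nrow(kin)]
  expect_lt(abs(mean(abs(omega_fd[mov])) - 1.1) / 1.1, 0.15)
  expect_lt(abs(mean(abs(kin$omega[kin$moving])) - 1.1) / 1.1, 0.15)
})

test_that("rest epochs occupy approximately the requested fraction", {
  sp <- session_spec(duration_s = 300, rest_fraction = 0.25, seed = 5)
  kin <- compute_kinematics(generate_rotation_trajectory(sp))
  s <- summarize_kinematics(kin)
  expect_equal(s$rest_time / (s$rest_time + s$movement_time), 0.25,
               tolerance = 0.08)
})

test_that("an infeasible rotation schedule is rejected", {
  sp <- session_spec(duration_s = 20, n_inversions = 15, rest_fraction = 0.5,
                     seed = 1)
  expect_error(generate_rotation_trajectory(sp), "impossible schedule")
})

test_that("generator outputs are deterministic given the seed", {
  sp <- session_spec(duration_s = 60, seed = 42)
  tr1 <- generate_rotation_trajectory(sp)
  tr2 <- generate_rotation_trajectory(sp)
  expect_identical(tr1$x, tr2$x)
  kin <- compute_kinematics(tr1)
  cs <- cell_spec(base_rate_hz = 8, kappa = 2, seed = 9)
  expect_identical(generate_spike_train(kin, cs)$times,
                   generate_spike_train(kin, cs)$times)
  expect_identical(generate_waveform(cs)$samples,
                   generate_waveform(cs)$samples)
})

test_that("a zero-rate cell produces an empty train", {
  kin <- demo_kin(duration_s = 60, seed = 11)
  st <- generate_spike_train(kin, cell_spec(base_rate_hz = 0, seed = 1))
  expect_length(st$times, 0L)
})

test_that("no spike falls where the intensity is zero", {
  kin <- demo_kin(duration_s = 300, seed = 11)
  # strong negative speed gain zeroes the intensity whenever |omega| > 0.5
  cs <- cell_spec(base_rate_hz = 4, speed_gain = -8, seed = 2)
  st <- generate_spike_train(kin, cs)
  idx <- findInterval(st$times, kin$t)
  expect_true(all(abs(kin$omega[idx]) <= 0.5 + 1e-9))
  expect_gt(length(st$times), 0L)
})

test_that("an unmodulated cell fires at its base rate (Poisson count check)", {
  kin <- demo_kin(duration_s = 600, seed = 12, n_inversions = 10)
  cs <- cell_spec(base_rate_hz = 5, kappa = 0, theta_depth = 0,
                  speed_gain = 0, refractory_ms = 0, seed = 31)
  st <- generate_spike_train(kin, cs)
  expected <- 5 * 600
  se <- sqrt(expected)
  expect_lt(abs(length(st$times) - expected), 3 * se)
})

test_that("spike trains are sorted, strictly increasing, and respect the refractory period", {
  kin <- demo_kin(duration_s = 300, seed = 11)
  cs <- cell_spec(base_rate_hz = 30, kappa = 1, refractory_ms = 2, seed = 4)
  st <- generate_spike_train(kin, cs)$times
  expect_true(all(diff(st) > 0))
  expect_true(all(diff(st) >= 0.002 - 1e-12))
})

test_that("fs waveform is narrower than the principal waveform", {
  fs <- generate_waveform(cell_spec(celltype_label = "fs", seed = 1))
  pc <- generate_waveform(cell_spec(celltype_label = "principal", seed = 1))
  expect_lt(extract_features(fs)$peak_to_trough_ms,
            extract_features(pc)$peak_to_trough_ms)
  expect_length(fs$samples, 64L)
  expect_length(generate_waveform(cell_spec(seed = 1), n_samples = 96)$samples,
                96L)
})

test_that("noise-free waveform geometry matches the closed-form template", {
  # raised-cosine lobes: half-width = pos_ms/2, peak-to-trough = (pos+neg)/2
  pc <- extract_features(generate_waveform(cell_spec(celltype_label = "principal", seed = 1)))
  expect_equal(pc$half_width_ms, 0.3, tolerance = 1e-9)
  expect_equal(pc$peak_to_trough_ms, 0.8, tolerance = 1e-9)
  expect_equal(pc$negativity_amp, 0.5, tolerance = 1e-9)
  fs <- extract_features(generate_waveform(cell_spec(celltype_label = "fs", seed = 1)))
  expect_equal(fs$half_width_ms, 0.1, tolerance = 1e-9)
  expect_equal(fs$peak_to_trough_ms, 0.25, tolerance = 1e-9)
})

test_that("session files round-trip through CSV and a manifest is written", {
  dir <- withr::local_tempdir()
  sp <- session_spec(duration_s = 60, seed = 8, n_inversions = 2)
  cells <- list(cell_spec(base_rate_hz = 6, kappa = 3, seed = 1),
                cell_spec(base_rate_hz = 12, celltype_label = "fs", seed = 2))
  ses <- simulate_session(sp, cells)
  man <- write_session(ses, dir)
  expect_true(file.exists(man))
  tr2 <- read_tracking_csv(file.path(dir, "tracking.csv"))
  expect_equal(tr2$x, ses$tracking$x, tolerance = 1e-9)
  st2 <- read_spikes_csv(file.path(dir, "spikes_cell01.csv"))
  expect_equal(st2, ses$spikes[[1]]$times, tolerance = 1e-9)
  manifest <- jsonlite::read_json(man)
  expect_equal(manifest$session_spec$seed, 8L)
})
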