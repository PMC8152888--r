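tf500 <- build_target_frequencies()

test_that("synthetic EEG trials are deterministic and respect the mixing
           profile", {
  cfg <- synthetic_eeg_config(rate = 500, n_channels = 3L,
                              mixing = c(1, 0.5, 0.25), master_seed = 4L)
  ph <- participant_phases(tf500, 99L)
  a <- simulate_eeg_trial(cfg, "regular_to_degraded", ph, 7L, tf500)
  b <- simulate_eeg_trial(cfg, "regular_to_degraded", ph, 7L, tf500)
  expect_identical(a, b)
  expect_equal(dim(a), c(3L, round(58.4 * 500)))
  c2 <- simulate_eeg_trial(cfg, "regular_to_degraded", ph, 8L, tf500)
  expect_false(identical(a, c2))
  # zero noise: channels are exact scalings of each other
  cfg0 <- synthetic_eeg_config(rate = 500, n_channels = 3L,
                               mixing = c(1, 0.5, 0.25), noise_scale = 0)
  z <- simulate_eeg_trial(cfg0, "regular_to_degraded", ph, 7L, tf500)
  expect_equal(z[2, ], 0.5 * z[1, ], tolerance = 1e-12)
  expect_equal(z[3, ], 0.25 * z[1, ], tolerance = 1e-12)
  # padding region carries no deterministic signal
  expect_true(all(z[, 1:200] == 0))
  expect_error(simulate_eeg_trial(cfg, "regular_to_degraded", ph[1:3],
                                  7L, tf500), "phase")
})

test_that("a degraded-to-regular trial is the time reversal of its
           aligned-grid proto core", {
  cfg <- synthetic_eeg_config(rate = 500, n_channels = 1L, mixing = 1,
                              noise_scale = 0)
  ph <- participant_phases(tf500, 5L)
  reg <- simulate_eeg_trial(cfg, "regular_to_degraded", ph, 1L, tf500)
  deg <- simulate_eeg_trial(cfg, "degraded_to_regular", ph, 1L, tf500)
  core_r <- reg[1, 201:29000]
  core_d <- deg[1, 201:29000]
  expect_equal(core_d, rev(core_r), tolerance = 1e-12)
})

test_that("the null world recovers no direction difference and the flagged
           gain is recovered monotonically", {
  # small cohort: enough to see the structure, cheap enough for every run
  base <- list(n_participants = 4L, n_trials_per_direction = 4L,
               rate = 500, noise_scale = 0.5, master_seed = 31L)
  run <- function(gain) {
    cfg <- do.call(synthetic_eeg_config, c(base, context_gain = gain))
    d <- cohort_direction_difference(cfg, tf500)
    tapply(d$difference, d$segment_aligned, mean)
  }
  null <- run(1)
  expect_lt(max(abs(null)), 0.35)
  recovered <- vapply(c(1, 1.5, 2), function(g) run(g)[[4]], numeric(1))
  expect_true(all(diff(recovered) > 0)) # monotone in the injected gain
  expect_gt(recovered[3], 0.5)
})

test_that("synthetic tapping honours jitter, misses and period", {
  cfg <- synthetic_tap_config(base_period = 400, jitter_sd = 0, rate = 500)
  tr <- simulate_tapping_trial(cfg, seed = 3)
  d <- detect_taps(tr$samples, 500, threshold = 0.5)
  expect_equal(diff(d$times) * 1000, rep(400, length(d$times) - 1L),
               tolerance = 3)
  expect_equal(iti_error(d), 0, tolerance = 0.6)
  # same seed, same trial
  expect_identical(simulate_tapping_trial(cfg, seed = 3)$samples,
                   tr$samples)
  # all taps missed: empty train, silent sensor
  none <- simulate_tapping_trial(
    synthetic_tap_config(miss_prob = 1, rate = 500), seed = 1)
  expect_length(none$tap_times, 0L)
  expect_true(all(none$samples == 0))
})

test_that("per-segment phase resets barely move ITI-error but lower meter
           prominence", {
  rate <- 500
  n_rep <- 6L
  stats <- vapply(seq_len(n_rep), function(i) {
    steady <- simulate_tapping_trial(
      synthetic_tap_config(jitter_sd = 10, rate = rate), seed = 100 + i)
    reset <- simulate_tapping_trial(
      synthetic_tap_config(jitter_sd = 10, phase_reset_prob = 1,
                           rate = rate), seed = 100 + i)
    z_of <- function(tr) {
      r <- tapping_spectrum(list(tr$samples), "regular_to_degraded",
                            rate, tf500)
      mean(r$summary$meter_mean_z)
    }
    c(err_steady = iti_error(tr <- steady$tap_times),
      err_reset = iti_error(reset$tap_times),
      z_steady = z_of(steady), z_reset = z_of(reset))
  }, numeric(4))
  m <- rowMeans(stats)
  # ITI-error stays low under phase resets (phase-robust measure) ...
  expect_lt(m["err_reset"], m["err_steady"] + 5)
  expect_lt(m["err_reset"], 10)
  # ... while spectral meter prominence drops (phase-sensitive measure)
  # in every paired replicate
  expect_true(all(stats["z_reset", ] < stats["z_steady", ]))
  expect_lt(m["z_reset"], m["z_steady"] - 0.1)
})

test_that("cohort materialisation writes a complete, readable layout", {
  out <- withr::local_tempdir()
  cfg <- synthetic_eeg_config(n_participants = 2L,
                              n_trials_per_direction = 2L, rate = 500,
                              master_seed = 2L)
  tap <- synthetic_tap_config(rate = 500, seed = 2L)
  man <- simulate_cohort(out, cfg, tap, n_tap_trials = 2L)
  expect_true(file.exists(file.path(out, "eeg_manifest.tsv")))
  expect_true(file.exists(file.path(out, "tap_manifest.tsv")))
  expect_true(file.exists(file.path(out, "ground_truth.json")))
  m <- read_manifest(file.path(out, "eeg_manifest.tsv"))
  expect_equal(nrow(m), 2L * 4L)
  # every regular trial has a direction twin sharing the stimulus seed
  for (p in unique(m$participant)) {
    mp <- m[m$participant == p, ]
    expect_true(all(table(mp$seed) == 2L))
  }
  # recordings round-trip and cover the manifested epochs
  rec <- read_signals(file.path(out, m$path[1L]))
  expect_equal(rec$rate, 500)
  expect_gte(ncol(rec$data) / rec$rate, max(m$onset[m$participant == 1]) +
               58.4)
  # tapping WAVs are mono and readable
  tm <- read_manifest(file.path(out, "tap_manifest.tsv"))
  wav <- read_signals(file.path(out, tm$path[1L]), expect_mono = TRUE)
  expect_equal(nrow(wav$data), 1L)
  # empty cohort still writes valid manifests
  out2 <- withr::local_tempdir()
  cfg0 <- synthetic_eeg_config(n_participants = 0L)
  man0 <- simulate_cohort(out2, cfg0, NULL, n_tap_trials = 0L)
  expect_true(file.exists(file.path(out2, "ground_truth.json")))
})
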