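# rate 500 makes 14.4-s windows (7200 samples) and 200-ms events exact,
# with resolution exactly 1/14.4 Hz
rate <- 500

test_that("segmentation yields seven 50%-overlapping 14.4-s windows", {
  x <- matrix(rnorm(2 * round(57.6 * rate)), nrow = 2)
  seg <- segment_signal(x, rate)
  expect_length(seg$segments, 7L)
  expect_true(all(vapply(seg$segments, ncol, integer(1)) == 7200L))
  # segment k starts at k * hop
  x1 <- matrix(seq_len(round(57.6 * rate)), nrow = 1)
  seg1 <- segment_signal(x1, rate)
  for (k in 1:7)
    expect_equal(seg1$segments[[k]][1, 1], (k - 1) * 3600 + 1)
  # a 58.4-s trial with a 0.4-s offset also yields 7 segments
  x2 <- matrix(rnorm(round(58.4 * rate)), nrow = 1)
  expect_length(segment_signal(x2, rate, core_start_offset = 0.4)$segments,
                7L)
  expect_error(segment_signal(matrix(rnorm(10 * rate), 1), rate),
               "too short")
})

test_that("trial averaging preserves phase-locked signal and shrinks noise
           like 1/sqrt(N)", {
  n <- round(57.6 * rate)
  t <- (seq_len(n) - 1) / rate
  sig <- sin(2 * pi * 2.5 * t)
  n_trials <- 100L
  set.seed(99)
  trials <- lapply(seq_len(n_trials), function(i)
    segment_signal(sig + rnorm(n), rate))
  avg <- average_trials(trials)
  spec <- magnitude_spectrum(avg$segments[[1L]], rate)
  bin <- round(2.5 / spec$resolution) + 1L
  expect_equal(spec$amplitudes[bin, 1L], 1, tolerance = 0.05)
  # residual noise amplitude off the signal bin ~ single-trial / sqrt(N)
  single <- magnitude_spectrum(trials[[1L]]$segments[[1L]], rate)
  off <- setdiff(seq(10L, 3000L), bin + (-3:3))
  ratio <- mean(spec$amplitudes[off, 1L]) / mean(single$amplitudes[off, 1L])
  expect_gt(ratio, 1 / sqrt(n_trials) / 3)
  expect_lt(ratio, 3 / sqrt(n_trials))
  # averaging copies of one signal returns that signal
  same <- average_trials(list(trials[[1L]], trials[[1L]]))
  expect_equal(same$segments, trials[[1L]]$segments)
  expect_error(average_trials(list()), "no trials")
  short <- segment_signal(sig[1:40000], rate, n_segments = 5L)
  expect_error(average_trials(list(trials[[1L]], short)), "shape")
})

test_that("magnitude spectra use rectangular windows scaled to sinusoid
           amplitude", {
  n <- 7200L
  t <- (seq_len(n) - 1) / rate
  x <- 3 * cos(2 * pi * 2.5 * t + 0.7)
  spec <- magnitude_spectrum(x, rate)
  expect_equal(spec$resolution, 1 / 14.4)
  bin <- round(2.5 * 14.4) + 1L
  expect_equal(spec$amplitudes[bin, 1L], 3, tolerance = 1e-9)
  others <- spec$amplitudes[-bin, 1L]
  expect_lt(max(abs(others)), 1e-9)
  expect_true(all(magnitude_spectrum(rep(0, n), rate)$amplitudes == 0))
})

test_that("noise subtraction is linear, zeroes flat spectra and preserves
           isolated peaks", {
  fake_spec <- function(a) {
    structure(list(amplitudes = matrix(a, ncol = 1L),
                   frequencies = (seq_along(a) - 1L) / 14.4,
                   resolution = 1 / 14.4, noise_subtracted = FALSE,
                   rate = rate),
              class = "magnitude_spectrum")
  }
  # flat spectrum -> all zeros (including boundary bins)
  flat <- subtract_noise(fake_spec(rep(4.2, 50)))
  expect_true(all(abs(flat$amplitudes) < 1e-12))
  expect_true(flat$noise_subtracted)
  expect_error(subtract_noise(flat), "already")
  # isolated peak A at bin k on zero background
  a <- rep(0, 50); a[21] <- 7
  pk <- subtract_noise(fake_spec(a))$amplitudes[, 1]
  expect_equal(pk[21], 7)
  expect_equal(pk[19], -3.5)
  expect_equal(pk[23], -3.5)
  expect_true(all(pk[-c(19, 21, 23)] == 0))
  # peak on constant background: background cancels at the peak
  b <- rep(2, 50); b[21] <- 2 + 7
  expect_equal(subtract_noise(fake_spec(b))$amplitudes[21, 1], 7)
  # linearity
  set.seed(1)
  x <- runif(50); y <- runif(50)
  lin <- subtract_noise(fake_spec(2 * x + 3 * y))$amplitudes
  parts <- 2 * subtract_noise(fake_spec(x))$amplitudes +
    3 * subtract_noise(fake_spec(y))$amplitudes
  expect_equal(lin, parts, tolerance = 1e-12)
})

test_that("target-frequency set follows the harmonic-union rule", {
  tf <- build_target_frequencies()
  expect_equal(nrow(tf), 24L)
  expect_equal(sum(tf$rule == "exact_bin"), 16L)
  expect_true(any(abs(tf$frequency - 5 / 12) < 1e-9))   # 0.41667 Hz
  expect_true(any(abs(tf$frequency - 0.3125) < 1e-9))   # 5/16 Hz
  expect_equal(tf$frequency[tf$is_meter], c(1.25, 2.5, 5))
  expect_true(all(tf$frequency <= 5 + 1e-9))
  expect_false(any(duplicated(round(tf$frequency, 9))))
  # custom list hook
  tf21 <- build_target_frequencies(frequencies = tf$frequency[-c(1, 3, 5)])
  expect_equal(nrow(tf21), 21L)
  expect_error(build_target_frequencies(frequencies = c(1.25, 2.5)),
               "meter_subset")
})

test_that("amplitude extraction uses exact bins or the max of the two
           closest bins", {
  tf <- build_target_frequencies()
  n_bins <- 3601L
  a <- rep(0, n_bins)
  # 2.5 Hz -> bin 36 (0-based): inject and recover verbatim
  a[37] <- 1.5
  # 0.3125 Hz -> bins 4 and 5 (0-based): max rule
  a[5] <- 0.2; a[6] <- 0.9
  spec <- structure(list(amplitudes = matrix(a, ncol = 1L),
                         frequencies = (seq_len(n_bins) - 1L) / 14.4,
                         resolution = 1 / 14.4, noise_subtracted = TRUE,
                         rate = rate),
                    class = "magnitude_spectrum")
  amps <- extract_amplitudes(spec, tf)
  expect_equal(unname(amps[abs(tf$frequency - 2.5) < 1e-9]), 1.5)
  expect_equal(unname(amps[abs(tf$frequency - 0.3125) < 1e-9]), 0.9)
  expect_equal(tf$rule[abs(tf$frequency - 2.5) < 1e-9], "exact_bin")
  expect_equal(tf$rule[abs(tf$frequency - 0.3125) < 1e-9],
               "max_of_two_closest")
  # frequency above Nyquist errors
  low <- spec; low$frequencies <- low$frequencies[1:30]
  low$amplitudes <- low$amplitudes[1:30, , drop = FALSE]
  expect_error(extract_amplitudes(low, tf), "Nyquist")
  # multichannel spectra must be channel-averaged first
  two <- spec; two$amplitudes <- cbind(a, a)
  expect_error(extract_amplitudes(two, tf), "average")
})

test_that("z-scoring fixes the sample-SD convention and is
           scale-invariant", {
  toy_targets <- build_target_frequencies(frequencies = c(1.25, 2.5, 5),
                                          meter_subset = c(1.25, 2.5, 5))
  z <- zscore_amplitudes(c(1, 2, 3), toy_targets)
  expect_equal(unname(z$z), c(-1, 0, 1)) # sample (n-1) SD
  tf <- build_target_frequencies()
  set.seed(3)
  amps <- runif(24, 0.5, 2)
  zs <- zscore_amplitudes(amps, tf)
  expect_equal(mean(zs$z), 0, tolerance = 1e-12)
  expect_equal(sd(zs$z), 1, tolerance = 1e-12)
  # overall gain does not change z (relative, gain-free measure)
  zs_scaled <- zscore_amplitudes(17 * amps, tf)
  expect_equal(zs$z, zs_scaled$z, tolerance = 1e-12)
  expect_equal(zs$meter_mean_z, zs_scaled$meter_mean_z)
  # a single elevated frequency carries the only positive z
  flat <- rep(1, 24); flat[7] <- 2
  zf <- zscore_amplitudes(flat, tf)
  expect_equal(unname(which(zf$z > 0)), 7L)
  expect_error(zscore_amplitudes(rep(1, 24), tf), "variance")
})

test_that("periphery-vs-response difference has the documented sign
           convention", {
  tf <- build_target_frequencies()
  set.seed(8)
  amps <- runif(24, 0.8, 1.2)
  attr(amps, "noise_subtracted") <- TRUE
  za <- zscore_amplitudes(amps, tf)
  expect_equal(as.numeric(meter_z_difference(za, za)), 0)
  boosted <- amps
  boosted[tf$is_meter] <- boosted[tf$is_meter] * 2
  zb <- zscore_amplitudes(boosted, tf)
  expect_lt(as.numeric(meter_z_difference(za, zb)), 0)
  raw <- amps; attr(raw, "noise_subtracted") <- FALSE
  zraw <- zscore_amplitudes(raw, tf)
  expect_error(meter_z_difference(zraw, zb), "noise-subtracted")
  small <- build_target_frequencies(frequencies = c(1.25, 2.5, 5),
                                    meter_subset = c(1.25, 2.5, 5))
  zs <- zscore_amplitudes(c(1, 2, 3), small)
  expect_error(meter_z_difference(za, zs), "different")
})

test_that("the engine reproduces identical amplitudes for direction-matched
           segments of a sequence and its inversion", {
  s <- build_sequence(seed = 31)
  si <- invert_sequence(s)
  tf <- build_target_frequencies()
  env <- matrix(event_envelope(s, rate), nrow = 1L)
  env_i <- matrix(event_envelope(si, rate), nrow = 1L)
  res <- freqtag_analyze(list(env, env_i),
                         c("regular_to_degraded", "degraded_to_regular"),
                         rate, tf, origin = "envelope",
                         noise_subtract = TRUE)
  amp <- res$amplitudes
  for (seg in 1:7) {
    a_reg <- amp$amplitude[amp$direction == "regular_to_degraded" &
                             amp$segment_aligned == seg]
    a_deg <- amp$amplitude[amp$direction == "degraded_to_regular" &
                             amp$segment_aligned == seg]
    expect_equal(a_reg, a_deg, tolerance = 1e-9)
  }
  # raw and reversed segment bookkeeping
  deg <- res$summary[res$summary$direction == "degraded_to_regular", ]
  expect_equal(deg$segment_aligned, 8L - deg$segment)
})
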