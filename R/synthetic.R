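#' Configuration for synthetic EEG-like data
#'
#' Describes a virtual cohort whose ground truth is known exactly: each
#' trial is a sum of cosines at the target frequencies (stimulus-locked
#' harmonic responses) with per-(direction, segment) amplitudes, embedded
#' in 1/f^alpha background noise and mixed into a few channels. A context
#' effect is injected as a multiplicative gain `context_gain` on the
#' meter-subset amplitudes in the flagged (direction, segment) cells;
#' `context_gain = 1` reproduces the null world in which both sequence
#' directions are statistically identical. Cosine phases are drawn once per
#' participant and reused across trials, so time-domain trial averaging
#' preserves the deterministic component while cancelling the noise.
#'
#' @param n_participants number of virtual participants (default 16).
#' @param n_trials_per_direction trials per sequence direction (default 15).
#' @param rate sampling rate in samples/s (default 512).
#' @param base_amplitude amplitude of every target-frequency cosine
#'   (scalar, or one value per target frequency).
#' @param context_gain multiplicative gain >= 1 applied to meter-subset
#'   amplitudes in the flagged cells.
#' @param gain_direction direction of the flagged cells.
#' @param gain_segments raw segment indices (1..7) of the flagged cells.
#' @param noise_alpha exponent of the 1/f^alpha background noise.
#' @param noise_scale noise standard deviation relative to unit signal
#'   amplitude.
#' @param n_channels number of output channels.
#' @param mixing fixed channel mixing profile (length `n_channels`).
#' @param master_seed master integer seed.
#' @return an object of class `synthetic_eeg_config`.
#' @export
synthetic_eeg_config <- function(n_participants = 16L,
                                 n_trials_per_direction = 15L,
                                 rate = 512,
                                 base_amplitude = 1,
                                 context_gain = 1,
                                 gain_direction = "regular_to_degraded",
                                 gain_segments = 4L,
                                 noise_alpha = 1,
                                 noise_scale = 1,
                                 n_channels = 4L,
                                 mixing = NULL,
                                 master_seed = 1L) {
  stopifnot(context_gain >= 0, noise_scale >= 0, base_amplitude >= 0)
  if (is.null(mixing))
    mixing <- seq(1, 0.4, length.out = n_channels)
  stopifnot(length(mixing) == n_channels)
  structure(
    list(n_participants = as.integer(n_participants),
         n_trials_per_direction = as.integer(n_trials_per_direction),
         rate = rate, base_amplitude = base_amplitude,
         context_gain = context_gain, gain_direction = gain_direction,
         gain_segments = as.integer(gain_segments),
         noise_alpha = noise_alpha, noise_scale = noise_scale,
         n_channels = as.integer(n_channels), mixing = mixing,
         master_seed = as.integer(master_seed)),
    class = "synthetic_eeg_config"
  )
}

#' Per-participant cosine phases
#'
#' Random phases in `[0, 2*pi)`, one per target frequency, drawn from a
#' participant-specific stream and reused across all of that participant's
#' trials.
#'
#' @param targets a [build_target_frequencies()] set.
#' @param seed participant seed.
#' @return numeric vector of phases.
#' @export
participant_phases <- function(targets, seed) {
  with_sequence_rng(seed, stats::runif(nrow(targets), 0, 2 * pi))
}

# 1/f^alpha noise with unit SD, via spectral shaping of white noise;
# generated at a power-of-two length (fast FFT) and truncated to n
pink_noise <- function(n, alpha) {
  m <- stats::nextn(n, 2)
  white <- stats::rnorm(m)
  spec <- stats::fft(white)
  f <- c(1, seq_len(m - 1L)) # avoid dividing the DC bin by zero
  f <- pmin(f, m - f + 1)    # mirror for negative frequencies
  spec <- spec / f^(alpha / 2)
  spec[1L] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

#' Simulate one synthetic EEG trial
#'
#' Builds a 58.4-s multichannel trial: a 57.6-s core of target-frequency
#' cosines whose amplitudes follow the per-segment cells of `cfg`
#' (cross-faded between overlapping segments with triangular weights that
#' sum to one), mixed into channels by `cfg$mixing`, plus independent
#' 1/f^alpha noise per channel. The first and last 0.4 s (the padding
#' region dropped by epoching) contain noise only.
#'
#' Mirroring the stimulus design, a degraded-to-regular trial carries the
#' time reversal of the deterministic core built on the aligned segment
#' grid, so that raw segment `s` of a degraded-to-regular trial holds the
#' same spectral content as aligned segment `8 - s`; in the null world
#' (`context_gain = 1`, zero noise) direction-aligned segments are then
#' exactly identical in magnitude, as the inverted stimuli are in the real
#' experiment. `gain_segments` are therefore aligned segment indices.
#'
#' @param cfg a [synthetic_eeg_config()].
#' @param direction trial direction label.
#' @param phases per-frequency cosine phases (see [participant_phases()]).
#' @param trial_seed seed for the trial's noise.
#' @param targets a [build_target_frequencies()] set.
#' @return channels x samples matrix (58.4 s at `cfg$rate`).
#' @export
simulate_eeg_trial <- function(cfg, direction, phases, trial_seed,
                               targets = build_target_frequencies()) {
  stopifnot(inherits(cfg, "synthetic_eeg_config"))
  if (length(phases) != nrow(targets))
    stop("phase vector does not cover the target-frequency set")
  amp <- rep_len(cfg$base_amplitude, nrow(targets))
  rate <- cfg$rate
  n_core <- as.integer(round(57.6 * rate))
  n_pad <- as.integer(round(0.4 * rate))
  n_total <- 2L * n_pad + n_core
  n_win <- as.integer(round(14.4 * rate))
  core <- numeric(n_core)
  t_core <- (seq_len(n_core) - 1L) / rate
  for (s in 1:7) {
    a <- amp
    if (direction == cfg$gain_direction && s %in% cfg$gain_segments)
      a[targets$is_meter] <- a[targets$is_meter] * cfg$context_gain
    s0 <- as.integer(round((s - 1L) * 7.2 * rate)) # 0-based segment start
    idx <- s0 + seq_len(n_win)
    # triangular cross-fade; flat at the sequence edges so weights sum to 1
    u <- (seq_len(n_win) - 0.5) / n_win
    w <- 1 - abs(2 * u - 1)
    if (s == 1L) w[u <= 0.5] <- 1
    if (s == 7L) w[u >= 0.5] <- 1
    seg <- numeric(n_win)
    tt <- t_core[idx]
    for (k in seq_len(nrow(targets)))
      seg <- seg + a[k] * cos(2 * pi * targets$frequency[k] * tt +
                                phases[k])
    core[idx] <- core[idx] + w * seg
  }
  if (direction == "degraded_to_regular") core <- rev(core)
  full <- c(numeric(n_pad), core, numeric(n_pad))
  with_sequence_rng(trial_seed, {
    out <- matrix(NA_real_, cfg$n_channels, n_total)
    for (ch in seq_len(cfg$n_channels))
      out[ch, ] <- cfg$mixing[ch] * full +
        cfg$noise_scale * pink_noise(n_total, cfg$noise_alpha)
    out
  })
}

#' Simulate all trials of one virtual participant
#'
#' @param cfg a [synthetic_eeg_config()].
#' @param participant participant index (1-based).
#' @param targets a [build_target_frequencies()] set.
#' @return list with `epochs` (list of channels x samples matrices),
#'   `directions`, `trial_seeds` and `participant_seed`.
#' @export
simulate_eeg_participant <- function(cfg, participant,
                                     targets = build_target_frequencies()) {
  pseed <- derive_seed(cfg$master_seed, participant)
  phases <- participant_phases(targets, pseed)
  directions <- rep(c("regular_to_degraded", "degraded_to_regular"),
                    each = cfg$n_trials_per_direction)
  trial_seeds <- vapply(seq_along(directions), function(i)
    derive_seed(pseed, i), integer(1))
  epochs <- lapply(seq_along(directions), function(i)
    simulate_eeg_trial(cfg, directions[i], phases, trial_seeds[i],
                       targets))
  list(epochs = epochs, directions = directions,
       trial_seeds = trial_seeds, participant_seed = pseed)
}

#' Recover the direction difference in meter prominence from a synthetic
#' cohort
#'
#' Runs the full frequency-tagging pipeline over a simulated cohort and
#' returns, per participant and aligned segment, the difference in
#' meter-related mean z between the regular-to-degraded and the
#' degraded-to-regular direction (positive = more meter prominence in
#' regular-to-degraded). This is the parameter-recovery harness: with
#' `context_gain > 1` in a flagged cell the difference should be positive
#' in that (aligned) segment and near zero elsewhere; with
#' `context_gain = 1` it should be near zero everywhere.
#'
#' @param cfg a [synthetic_eeg_config()].
#' @param targets a [build_target_frequencies()] set.
#' @return data.frame with columns `participant`, `segment_aligned`,
#'   `difference`.
#' @export
cohort_direction_difference <- function(cfg,
                                        targets =
                                          build_target_frequencies()) {
  rows <- list()
  for (p in seq_len(cfg$n_participants)) {
    sim <- simulate_eeg_participant(cfg, p, targets)
    res <- freqtag_analyze(sim$epochs, sim$directions, cfg$rate, targets,
                           origin = "eeg", core_start_offset = 0.4)
    s <- res$summary
    reg <- s[s$direction == "regular_to_degraded", ]
    deg <- s[s$direction == "degraded_to_regular", ]
    m <- merge(reg[, c("segment_aligned", "meter_mean_z")],
               deg[, c("segment_aligned", "meter_mean_z")],
               by = "segment_aligned", suffixes = c("_reg", "_deg"))
    rows[[p]] <- data.frame(participant = p,
                            segment_aligned = m$segment_aligned,
                            difference = m$meter_mean_z_reg -
                              m$meter_mean_z_deg)
  }
  do.call(rbind, rows)
}

#' Configuration for synthetic tapping data
#'
#' A virtual tapper producing an impulse train at a base pulse period with
#' Gaussian motor jitter. At each 7.2-s segment boundary the tapper may
#' reset its phase (uniform shift within one period) or switch period
#' (between the base period and its double), each with a per-segment
#' Bernoulli probability; individual taps are missed with probability
#' `miss_prob`.
#'
#' @param base_period pulse period in ms (one of 200, 400, 600, 800, 1200).
#' @param jitter_sd Gaussian timing jitter SD in ms.
#' @param phase_reset_prob per-segment probability of a phase reset.
#' @param period_switch_prob per-segment probability of a period switch.
#' @param miss_prob probability that a tap is not executed.
#' @param rate sensor sampling rate in samples/s.
#' @param seed integer seed.
#' @return an object of class `synthetic_tap_config`.
#' @export
synthetic_tap_config <- function(base_period = 400, jitter_sd = 10,
                                 phase_reset_prob = 0,
                                 period_switch_prob = 0,
                                 miss_prob = 0, rate = 512, seed = 1L) {
  stopifnot(base_period %in% c(200, 400, 600, 800, 1200),
            jitter_sd >= 0,
            phase_reset_prob >= 0, phase_reset_prob <= 1,
            period_switch_prob >= 0, period_switch_prob <= 1,
            miss_prob >= 0, miss_prob <= 1)
  structure(
    list(base_period = base_period, jitter_sd = jitter_sd,
         phase_reset_prob = phase_reset_prob,
         period_switch_prob = period_switch_prob,
         miss_prob = miss_prob, rate = rate, seed = as.integer(seed)),
    class = "synthetic_tap_config"
  )
}

#' Simulate one synthetic tapping trial
#'
#' Generates a 58.4-s single-channel sensor signal: a brief damped pulse at
#' every executed tap. Tap times start 0.4 s into the trial (after the
#' padding sounds) and follow the jitter / phase-reset / period-switch /
#' miss process described in [synthetic_tap_config()].
#'
#' @param cfg a [synthetic_tap_config()].
#' @param seed optional seed overriding `cfg$seed`.
#' @return list with `samples` (numeric vector), `rate` and `tap_times`
#'   (the executed ground-truth tap times in seconds).
#' @export
simulate_tapping_trial <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_tap_config"))
  rate <- cfg$rate
  duration <- 58.4
  with_sequence_rng(seed, {
    period <- cfg$base_period / 1000
    t <- 0.4
    next_boundary <- 0.4 + 7.2
    taps <- numeric(0)
    while (t < duration - 0.4) {
      if (t >= next_boundary) {
        if (stats::runif(1) < cfg$phase_reset_prob)
          t <- t + stats::runif(1, 0, period)
        if (stats::runif(1) < cfg$period_switch_prob)
          period <- if (period == cfg$base_period / 1000)
            2 * cfg$base_period / 1000 else cfg$base_period / 1000
        next_boundary <- next_boundary + 7.2
        if (t >= duration - 0.4) break
      }
      jit <- if (cfg$jitter_sd > 0)
        stats::rnorm(1, 0, cfg$jitter_sd / 1000) else 0
      tap_t <- t + jit
      if (stats::runif(1) >= cfg$miss_prob &&
          tap_t >= 0 && tap_t < duration - 0.02)
        taps <- c(taps, tap_t)
      t <- t + period
    }
    taps <- sort(taps)
    n <- as.integer(round(duration * rate))
    samples <- numeric(n)
    # damped 20-ms pulse with a sharp attack
    n_pulse <- max(2L, as.integer(round(0.02 * rate)))
    pulse <- exp(-(seq_len(n_pulse) - 1L) / (0.005 * rate))
    for (tp in taps) {
      i0 <- as.integer(round(tp * rate)) + 1L
      idx <- i0 + seq_len(n_pulse) - 1L
      keep <- idx <= n
      samples[idx[keep]] <- samples[idx[keep]] + pulse[keep]
    }
    list(samples = samples, rate = rate, tap_times = taps)
  })
}

#' Write a synthetic cohort to disk
#'
#' Materialises a virtual experiment with the same file layout the analysis
#' tools consume: per-participant EEG recordings (columnar text or EDF)
#' with a trial manifest, per-trial tapping WAV files with their own
#' manifest, and a ground-truth JSON sidecar describing the generator
#' configuration.
#'
#' @param out_dir output directory (created if needed).
#' @param eeg_cfg a [synthetic_eeg_config()]; `NULL` skips the EEG part.
#' @param tap_cfg a [synthetic_tap_config()]; `NULL` skips the tapping
#'   part.
#' @param n_tap_trials tapping trials per direction.
#' @param eeg_format `"columnar"` or `"edf"`.
#' @param targets a [build_target_frequencies()] set.
#' @param gap gap between consecutive EEG trials in seconds.
#' @return invisibly, a list with the EEG and tapping manifests.
#' @export
simulate_cohort <- function(out_dir,
                            eeg_cfg = synthetic_eeg_config(),
                            tap_cfg = synthetic_tap_config(),
                            n_tap_trials = 5L,
                            eeg_format = c("columnar", "edf"),
                            targets = build_target_frequencies(),
                            gap = 1) {
  eeg_format <- match.arg(eeg_format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  eeg_manifest <- NULL
  tap_manifest <- NULL
  if (!is.null(eeg_cfg) && eeg_cfg$n_participants > 0L) {
    rows <- list()
    for (p in seq_len(eeg_cfg$n_participants)) {
      sim <- simulate_eeg_participant(eeg_cfg, p, targets)
      n_tr <- length(sim$epochs)
      n_ep <- if (n_tr > 0L) ncol(sim$epochs[[1L]]) else 0L
      gap_n <- as.integer(round(gap * eeg_cfg$rate))
      rec <- matrix(0, eeg_cfg$n_channels, n_tr * (n_ep + gap_n))
      onsets <- numeric(n_tr)
      for (i in seq_len(n_tr)) {
        s0 <- (i - 1L) * (n_ep + gap_n)
        rec[, s0 + seq_len(n_ep)] <- sim$epochs[[i]]
        onsets[i] <- s0 / eeg_cfg$rate
      }
      path <- file.path(out_dir, sprintf("eeg_p%02d.%s", p,
                        if (eeg_format == "edf") "edf" else "txt"))
      if (eeg_format == "edf")
        write_edf(rec, eeg_cfg$rate, path)
      else
        write_columnar(rec, eeg_cfg$rate, path)
      # the trial pair i shares one stimulus seed across directions
      stim <- derive_seed(sim$participant_seed,
                          1000L + (seq_len(n_tr) - 1L) %%
                            eeg_cfg$n_trials_per_direction)
      rows[[p]] <- data.frame(
        participant = p, session = "eeg", trial = seq_len(n_tr),
        direction = sim$directions, seed = stim, path = basename(path),
        onset = onsets)
    }
    eeg_manifest <- do.call(rbind, rows)
    utils::write.table(eeg_manifest,
                       file.path(out_dir, "eeg_manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(tap_cfg) && n_tap_trials > 0L) {
    rows <- list()
    k <- 0L
    for (i in seq_len(n_tap_trials)) {
      for (dir in c("regular_to_degraded", "degraded_to_regular")) {
        k <- k + 1L
        tr <- simulate_tapping_trial(tap_cfg, derive_seed(tap_cfg$seed, k))
        path <- file.path(out_dir, sprintf("tap_t%02d.wav", k))
        write_wav(tr$samples, tr$rate, path)
        rows[[k]] <- data.frame(participant = 1L, session = "tapping",
                                trial = k, direction = dir,
                                seed = derive_seed(tap_cfg$seed, i),
                                path = basename(path), onset = 0)
      }
    }
    tap_manifest <- do.call(rbind, rows)
    utils::write.table(tap_manifest,
                       file.path(out_dir, "tap_manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- list(eeg = if (!is.null(eeg_cfg)) unclass(eeg_cfg),
                tapping = if (!is.null(tap_cfg)) unclass(tap_cfg),
                target_frequencies = targets$frequency,
                meter_subset = targets$frequency[targets$is_meter])
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(eeg_manifest = eeg_manifest,
                 tap_manifest = tap_manifest))
}
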