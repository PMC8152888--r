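#' Preprocess a continuous EEG recording
#'
#' Zero-phase (forward-backward) Butterworth high-pass filtering at 0.1 Hz
#' (4th order by design; forward-backward application doubles the effective
#' order) to remove slow drifts, with optional integer-factor resampling and
#' pluggable hooks where artifact removal (ICA, channel interpolation)
#' would slot into a full pipeline. Hooks are no-ops by default.
#'
#' @param x channels x samples matrix (or vector for one channel).
#' @param rate sampling rate in samples/s.
#' @param highpass high-pass cutoff in Hz (default 0.1); `NULL` disables
#'   filtering.
#' @param order Butterworth filter order (default 4).
#' @param resample_to optional target rate; must divide `rate`.
#' @param hooks list of functions `f(x, rate)` returning a modified matrix,
#'   applied in order after filtering.
#' @return list with `data` (channels x samples) and `rate`.
#' @export
preprocess_eeg <- function(x, rate, highpass = 0.1, order = 4L,
                           resample_to = NULL, hooks = list()) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (!is.null(highpass)) {
    bf <- signal::butter(order, highpass / (rate / 2), type = "high")
    for (ch in seq_len(nrow(x)))
      x[ch, ] <- signal::filtfilt(bf, x[ch, ])
  }
  if (!is.null(resample_to)) {
    if (rate %% resample_to != 0)
      stop("resample_to must divide the original rate")
    q <- rate %/% resample_to
    x <- x[, seq(1L, ncol(x), by = q), drop = FALSE]
    rate <- resample_to
  }
  for (h in hooks) x <- h(x, rate)
  list(data = x, rate = rate)
}

#' Common-average rereferencing
#'
#' Subtracts the across-channel mean at every sample, so that the channel
#' sum is zero everywhere.
#'
#' @param x channels x samples matrix with at least 2 channels.
#' @return rereferenced matrix.
#' @export
rereference_common_average <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2L)
    stop("common-average reference requires at least 2 channels")
  sweep(x, 2L, colMeans(x), "-")
}

#' Cut stimulus-locked epochs out of a continuous recording
#'
#' Epochs start `offset` seconds after each trial onset (discarding the
#' padding sound events) and last `duration` seconds. The epoch grid is
#' aligned to the sample nearest to `onset + offset`; no sub-sample
#' interpolation is performed.
#'
#' @param x channels x samples matrix.
#' @param rate sampling rate in samples/s.
#' @param onsets trial-onset times in seconds.
#' @param duration epoch duration in seconds (default 57.6).
#' @param offset start offset relative to trial onset (default 0.4).
#' @return list of channels x samples matrices, one per onset.
#' @export
epoch_trials <- function(x, rate, onsets, duration = 57.6, offset = 0.4) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  n_ep <- as.integer(round(duration * rate))
  lapply(onsets, function(t0) {
    s0 <- as.integer(round((t0 + offset) * rate))
    if (s0 + n_ep > ncol(x))
      stop("epoch at onset ", t0, " s exceeds the recording (need ",
           (s0 + n_ep) / rate, " s, have ", ncol(x) / rate, " s)")
    x[, s0 + seq_len(n_ep), drop = FALSE]
  })
}

#' Full per-participant EEG analysis
#'
#' Orchestrates the pipeline for one participant: optional preprocessing,
#' epoching at 0.4 s past each trial onset, common-average rereferencing,
#' then the shared frequency-tagging engine (segmentation, per-direction
#' trial averaging, FFT, noise subtraction, channel averaging, target
#' extraction, z-scoring).
#'
#' Trials are paired across directions by their stimulus seed: excluding a
#' trial also drops its direction-matched twin, so the per-direction
#' averages always contain matched stimulus material. Unmatched manifest
#' rows are excluded with a warning.
#'
#' @param rec recording: list with `data` (channels x samples) and `rate`.
#' @param manifest data.frame with columns `trial`, `direction`
#'   (`"regular_to_degraded"` / `"degraded_to_regular"`), `onset`
#'   (seconds) and `seed` (stimulus seed shared by a trial pair).
#' @param targets a [build_target_frequencies()] set.
#' @param exclude trial ids to discard (their twins are discarded too).
#' @param preprocess apply [preprocess_eeg()] first (default TRUE).
#' @param epoch_offset epoch start relative to trial onset, seconds.
#' @param epoch_duration epoch duration, seconds.
#' @param ... passed to [freqtag_analyze()].
#' @return list with `amplitudes` and `summary` tables (see
#'   [freqtag_analyze()]) plus `dropped_trials`.
#' @export
run_participant <- function(rec, manifest,
                            targets = build_target_frequencies(),
                            exclude = integer(0),
                            preprocess = TRUE,
                            epoch_offset = 0.4, epoch_duration = 57.6,
                            ...) {
  stopifnot(is.data.frame(manifest),
            all(c("trial", "direction", "onset", "seed") %in%
                  names(manifest)))
  drop <- manifest$trial %in% exclude
  # a trial pair shares the stimulus seed; drop both members
  drop <- drop | manifest$seed %in% manifest$seed[drop]
  unmatched <- vapply(seq_len(nrow(manifest)), function(i)
    sum(manifest$seed == manifest$seed[i]) != 2L, logical(1))
  if (any(unmatched & !drop)) {
    warning("excluding unpaired trial(s): ",
            paste(manifest$trial[unmatched & !drop], collapse = ", "))
    drop <- drop | unmatched
  }
  kept <- manifest[!drop, , drop = FALSE]
  if (nrow(kept) == 0L) stop("no trials left after exclusion")
  x <- rec$data
  rate <- rec$rate
  if (preprocess) {
    pp <- preprocess_eeg(x, rate)
    x <- pp$data
    rate <- pp$rate
  }
  epochs <- epoch_trials(x, rate, kept$onset, duration = epoch_duration,
                         offset = epoch_offset)
  epochs <- lapply(epochs, rereference_common_average)
  res <- freqtag_analyze(epochs, kept$direction, rate, targets,
                         origin = "eeg", core_start_offset = 0, ...)
  res$dropped_trials <- manifest$trial[drop]
  res
}
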