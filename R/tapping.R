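#' Detect tap onsets in a continuous sensor signal
#'
#' A sample is a tap onset when (1) the amplitude is rising (strictly
#' positive first difference at the crossing sample), (2) the amplitude
#' crosses the threshold from below, and (3) at least `refractory` seconds
#' have passed since the previous detected onset. The threshold defaults to
#' 5 times the median absolute amplitude of the recording; both threshold
#' and refractory period are per-recording overridable.
#'
#' @param x numeric vector, single-channel sensor signal.
#' @param rate sampling rate in samples/s.
#' @param threshold detection threshold in signal units; `NULL` for the
#'   default.
#' @param refractory minimum gap between onsets in seconds (default 0.1).
#' @return an object of class `tap_onsets`: list with `times` (seconds,
#'   strictly increasing), `threshold`, `refractory`.
#' @export
detect_taps <- function(x, rate, threshold = NULL, refractory = 0.1) {
  stopifnot(is.numeric(x), refractory > 0)
  if (is.null(threshold)) {
    threshold <- 5 * stats::median(abs(x))
    # sparse noiseless signals have zero median amplitude; fall back to
    # half the peak
    if (threshold <= 0) threshold <- 0.5 * max(abs(x))
  }
  if (threshold <= 0)
    return(structure(list(times = numeric(0), threshold = threshold,
                          refractory = refractory),
                     class = "tap_onsets"))
  n <- length(x)
  rising <- c(FALSE, diff(x) > 0)
  crossing <- c(FALSE, x[-1L] >= threshold & x[-n] < threshold)
  cand <- which(rising & crossing)
  times <- numeric(0)
  last <- -Inf
  for (i in cand) {
    t <- (i - 1L) / rate
    if (t - last >= refractory) {
      times <- c(times, t)
      last <- t
    }
  }
  structure(list(times = times, threshold = threshold,
                 refractory = refractory),
            class = "tap_onsets")
}

#' @export
print.tap_onsets <- function(x, ...) {
  cat("Tap onsets:", length(x$times), "taps")
  if (length(x$times) > 1L)
    cat(", median ITI", round(stats::median(diff(x$times)) * 1000), "ms")
  cat(" (threshold", signif(x$threshold, 3), ", refractory",
      x$refractory, "s)\n")
  invisible(x)
}

#' Candidate meters for tapping classification
#'
#' The three simplest nested groupings of a 200-ms event grid by two or
#' three events: pulses at \{2,4\}, \{2,6\} and \{3,6\} events,
#' corresponding to nested periods \{200, 400, 800\},
#' \{200, 400, 1200\} and \{200, 600, 1200\} ms.
#'
#' @return named list of numeric period vectors (ms).
#' @export
meter_candidates <- function() {
  list("{2,4}" = c(200, 400, 800),
       "{2,6}" = c(200, 400, 1200),
       "{3,6}" = c(200, 600, 1200))
}

#' Match a median inter-tap interval against candidate meters
#'
#' For each candidate meter, the minimum percent difference between the
#' median ITI and the meter's nested periods,
#' `100 * |iti - P| / P`, is computed; the meter with the smallest
#' difference is the best match.
#'
#' @param median_iti median inter-tap interval in ms (> 0).
#' @param candidates named list of period vectors in ms (default
#'   [meter_candidates()]).
#' @return data.frame with columns `meter`, `pct_diff`, `closest_period`;
#'   the best-matching meter label is stored in attribute `best`.
#' @export
meter_match <- function(median_iti, candidates = meter_candidates()) {
  if (is.na(median_iti) || length(median_iti) != 1L)
    stop("median ITI is missing; no taps to classify")
  stopifnot(median_iti > 0)
  rows <- lapply(names(candidates), function(lab) {
    periods <- candidates[[lab]]
    d <- 100 * abs(median_iti - periods) / periods
    data.frame(meter = lab, pct_diff = min(d),
               closest_period = periods[which.min(d)])
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- out$meter[which.min(out$pct_diff)]
  out
}

#' ITI-error of tapping within an analysis window
#'
#' Mean percent deviation of the inter-tap intervals from the metric pulse
#' period the participant is tapping. ITIs longer than `max_iti` seconds
#' (pauses) are removed first; the pulse period is the one among `periods`
#' closest to the median of the remaining ITIs; the error is the mean over
#' ITIs of `100 * |iti - period| / period`. The measure is invariant to a
#' global time shift of the onsets (robust to tapping-phase changes) but
#' grows when the tapping period switches within the window.
#'
#' @param onsets a [detect_taps()] result or numeric vector of onset times
#'   in seconds.
#' @param window `c(start, end)` of the analysis window in seconds;
#'   `NULL` uses all onsets.
#' @param periods candidate pulse periods in ms (default the \{2,4\}-meter
#'   periods 200/400/800).
#' @param max_iti exclusion threshold for long ITIs in seconds (default 2).
#' @return percent error (scalar); `NA` with a message attribute when fewer
#'   than 2 taps fall in the window.
#' @export
iti_error <- function(onsets, window = NULL,
                      periods = c(200, 400, 800), max_iti = 2) {
  times <- if (inherits(onsets, "tap_onsets")) onsets$times else onsets
  if (!is.null(window))
    times <- times[times >= window[1L] & times < window[2L]]
  if (length(times) < 2L)
    return(structure(NA_real_, reason = "fewer than 2 taps in window"))
  itis <- diff(times) * 1000
  itis <- itis[itis <= max_iti * 1000]
  if (length(itis) == 0L)
    return(structure(NA_real_, reason = "no ITIs after pause exclusion"))
  med <- stats::median(itis)
  period <- periods[which.min(abs(med - periods))]
  mean(100 * abs(itis - period) / period)
}

#' Frequency-domain analysis of continuous tapping signals
#'
#' Routes continuous tapping-sensor signals through the shared
#' frequency-tagging engine (same segmentation, trial averaging, FFT, noise
#' subtraction, extraction and z-scoring as the EEG path), yielding the
#' meter-frequency prominence of the behavioural output. By default trials
#' are averaged in the time domain before the spectra are taken;
#' `freq_domain_average = TRUE` instead averages magnitude spectra across
#' trials (robust to trial-to-trial phase differences).
#'
#' @param signals list of numeric vectors (one continuous sensor signal per
#'   trial, including the 0.4-s padding region at the start).
#' @param directions direction label per trial.
#' @param rate sampling rate in samples/s.
#' @param targets a [build_target_frequencies()] set.
#' @param core_start_offset seconds to skip at the start of each trial
#'   (default 0.4, dropping the padding sounds).
#' @param freq_domain_average average across trials in the frequency domain
#'   instead of the time domain (default FALSE).
#' @param ... passed to [freqtag_analyze()].
#' @return as [freqtag_analyze()].
#' @export
tapping_spectrum <- function(signals, directions, rate,
                             targets = build_target_frequencies(),
                             core_start_offset = 0.4,
                             freq_domain_average = FALSE, ...) {
  epochs <- lapply(signals, function(s) matrix(s, nrow = 1L))
  if (!freq_domain_average)
    return(freqtag_analyze(epochs, directions, rate, targets,
                           origin = "tapping",
                           core_start_offset = core_start_offset, ...))
  # frequency-domain trial averaging: magnitude spectra per trial and
  # segment, averaged across trials before noise subtraction
  amp_rows <- list(); sum_rows <- list()
  n_segments <- 7L
  for (dir in unique(directions)) {
    idx <- which(directions == dir)
    segged <- lapply(epochs[idx], segment_signal, rate = rate,
                     core_start_offset = core_start_offset,
                     origin = "tapping")
    for (s in seq_len(n_segments)) {
      specs <- lapply(segged, function(sg)
        magnitude_spectrum(sg$segments[[s]], rate))
      spec <- specs[[1L]]
      if (length(specs) > 1L) {
        acc <- spec$amplitudes
        for (i in 2:length(specs)) acc <- acc + specs[[i]]$amplitudes
        spec$amplitudes <- acc / length(specs)
      }
      spec <- average_channels(subtract_noise(spec))
      amps <- extract_amplitudes(spec, targets)
      zs <- zscore_amplitudes(amps, targets)
      aligned <- if (dir == "degraded_to_regular")
        n_segments + 1L - s else s
      amp_rows[[length(amp_rows) + 1L]] <- data.frame(
        origin = "tapping", direction = dir, segment = s,
        segment_aligned = aligned, frequency = targets$frequency,
        amplitude = as.numeric(amps), z = as.numeric(zs$z),
        row.names = NULL)
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        origin = "tapping", direction = dir, segment = s,
        segment_aligned = aligned, meter_mean_z = zs$meter_mean_z,
        row.names = NULL)
    }
  }
  list(amplitudes = do.call(rbind, amp_rows),
       summary = do.call(rbind, sum_rows))
}
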