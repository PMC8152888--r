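#' Segment a continuous signal into overlapping analysis windows
#'
#' Cuts seven 14.4-s windows with 50% overlap (7.2-s hop) out of a
#' continuous multichannel signal, after skipping an initial offset (used
#' to drop the padding sound events at the start of a trial). Window and
#' hop lengths are rounded to the nearest sample.
#'
#' @param x numeric matrix (channels x samples) or vector (one channel).
#' @param rate sampling rate in samples/s.
#' @param core_start_offset offset in seconds from the start of `x` to the
#'   first analysed sample (default 0).
#' @param window window length in seconds (default 14.4).
#' @param hop hop between window starts in seconds (default 7.2).
#' @param n_segments number of windows (default 7).
#' @param origin label for the signal family (`"eeg"`, `"tapping"`,
#'   `"periphery"`, `"envelope"`).
#' @return an object of class `segmented_signal`: list with `segments` (list
#'   of channels x samples matrices), `rate`, `window`, `hop`, `origin`.
#' @export
segment_signal <- function(x, rate, core_start_offset = 0,
                           window = 14.4, hop = 7.2, n_segments = 7L,
                           origin = c("eeg", "tapping", "periphery",
                                      "envelope")) {
  origin <- match.arg(origin)
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  n_win <- as.integer(round(window * rate))
  off <- as.integer(round(core_start_offset * rate))
  starts <- off + vapply(seq_len(n_segments) - 1L,
                         function(k) as.integer(round(k * hop * rate)),
                         integer(1))
  needed <- starts[n_segments] + n_win
  if (ncol(x) < needed)
    stop("signal too short: need ", needed / rate, " s (", needed,
         " samples) from offset, have ", ncol(x) / rate, " s (",
         ncol(x), " samples)")
  segments <- lapply(starts, function(s0)
    x[, s0 + seq_len(n_win), drop = FALSE])
  structure(
    list(segments = segments, rate = rate, window = window, hop = hop,
         origin = origin),
    class = "segmented_signal"
  )
}

#' @export
print.segmented_signal <- function(x, ...) {
  cat("Segmented signal (", x$origin, "): ", length(x$segments),
      " windows of ", x$window, " s (", ncol(x$segments[[1L]]),
      " samples), hop ", x$hop, " s, ", nrow(x$segments[[1L]]),
      " channel(s)\n", sep = "")
  invisible(x)
}

#' Average segmented trials in the time domain
#'
#' Element-wise mean over a list of identically shaped [segment_signal()]
#' results. Time-domain averaging cancels activity that is not time-locked
#' to the stimulus while preserving phase-locked components.
#'
#' @param trials non-empty list of `segmented_signal` objects with equal
#'   shapes and rates.
#' @return a single `segmented_signal`.
#' @export
average_trials <- function(trials) {
  if (length(trials) == 0L) stop("no trials to average")
  ref <- trials[[1L]]
  for (tr in trials) {
    if (!identical(ref$rate, tr$rate) ||
        length(tr$segments) != length(ref$segments) ||
        !identical(dim(tr$segments[[1L]]), dim(ref$segments[[1L]])))
      stop("all trials must share segment shapes and sampling rate")
  }
  out <- ref
  for (s in seq_along(ref$segments)) {
    acc <- ref$segments[[s]]
    if (length(trials) > 1L)
      for (i in 2:length(trials)) acc <- acc + trials[[i]]$segments[[s]]
    out$segments[[s]] <- acc / length(trials)
  }
  out
}

#' FFT magnitude spectrum of a segment
#'
#' Per-channel discrete Fourier magnitudes with a rectangular window and no
#' zero padding, scaled to sinusoid amplitude: a unit-amplitude sinusoid at
#' an exact bin frequency yields 1 at that bin. Bins run from 0 Hz to the
#' Nyquist frequency; the resolution is 1/window-length.
#'
#' @param segment channels x samples matrix (or vector).
#' @param rate sampling rate in samples/s.
#' @return an object of class `magnitude_spectrum`: list with `amplitudes`
#'   (bins x channels matrix), `frequencies`, `resolution`,
#'   `noise_subtracted` flag and `rate`.
#' @export
magnitude_spectrum <- function(segment, rate) {
  if (is.vector(segment)) segment <- matrix(segment, nrow = 1L)
  n <- ncol(segment)
  n_bins <- n %/% 2L + 1L
  amps <- matrix(NA_real_, n_bins, nrow(segment))
  for (ch in seq_len(nrow(segment))) {
    m <- Mod(stats::fft(segment[ch, ]))[seq_len(n_bins)]
    m <- m / n * 2
    m[1L] <- m[1L] / 2
    if (n %% 2L == 0L) m[n_bins] <- m[n_bins] / 2
    amps[, ch] <- m
  }
  structure(
    list(amplitudes = amps,
         frequencies = (seq_len(n_bins) - 1L) * rate / n,
         resolution = rate / n,
         noise_subtracted = FALSE,
         rate = rate),
    class = "magnitude_spectrum"
  )
}

#' @export
print.magnitude_spectrum <- function(x, ...) {
  cat("Magnitude spectrum: ", nrow(x$amplitudes), " bins x ",
      ncol(x$amplitudes), " channel(s), resolution ",
      signif(x$resolution, 4), " Hz",
      if (x$noise_subtracted) ", noise-subtracted", "\n", sep = "")
  invisible(x)
}

#' @rdname plot_spectrum
#' @export
plot.magnitude_spectrum <- function(x, fmax = 6, ...) {
  keep <- x$frequencies <= fmax
  y <- rowMeans(x$amplitudes)[keep]
  graphics::plot(x$frequencies[keep], y, type = "h",
                 xlab = "Frequency (Hz)", ylab = "Amplitude",
                 main = if (x$noise_subtracted)
                   "Noise-subtracted magnitude spectrum"
                 else "Magnitude spectrum", ...)
  invisible(x)
}

#' Plot a magnitude spectrum
#'
#' Channel-averaged amplitudes up to `fmax` Hz.
#'
#' @param x a `magnitude_spectrum`.
#' @param fmax upper frequency limit for the plot, Hz.
#' @param ... passed to [graphics::plot()].
#' @name plot_spectrum
NULL

#' Second-neighbour-bin noise subtraction
#'
#' Removes smooth broadband background from a magnitude spectrum by
#' subtracting, at each frequency bin, the average amplitude of the second
#' neighbouring bin on either side:
#' `out[k] = in[k] - (in[k-2] + in[k+2]) / 2`.
#' Boundary bins with only one second neighbour available use that single
#' neighbour. The operation is linear and leaves an isolated narrow peak on
#' a flat background untouched at the peak bin. Output values may be
#' negative; the `noise_subtracted` flag is set and double subtraction is
#' refused.
#'
#' @param spec a [magnitude_spectrum()].
#' @return the noise-subtracted `magnitude_spectrum`.
#' @export
subtract_noise <- function(spec) {
  stopifnot(inherits(spec, "magnitude_spectrum"))
  if (spec$noise_subtracted)
    stop("spectrum is already noise-subtracted")
  a <- spec$amplitudes
  b <- nrow(a)
  if (b < 3L) stop("too few bins for noise subtraction")
  lower <- rbind(matrix(NA_real_, 2L, ncol(a)), a[seq_len(b - 2L), , drop = FALSE])
  upper <- rbind(a[-(1:2), , drop = FALSE], matrix(NA_real_, 2L, ncol(a)))
  noise <- matrix(NA_real_, b, ncol(a))
  both <- !is.na(lower) & !is.na(upper)
  noise[both] <- (lower[both] + upper[both]) / 2
  only_lo <- !is.na(lower) & is.na(upper)
  noise[only_lo] <- lower[only_lo]
  only_hi <- is.na(lower) & !is.na(upper)
  noise[only_hi] <- upper[only_hi]
  spec$amplitudes <- a - noise
  spec$noise_subtracted <- TRUE
  spec
}

#' Average a spectrum across channels
#'
#' @param spec a [magnitude_spectrum()].
#' @return the spectrum with a single channel holding the across-channel
#'   mean.
#' @export
average_channels <- function(spec) {
  stopifnot(inherits(spec, "magnitude_spectrum"))
  spec$amplitudes <- matrix(rowMeans(spec$amplitudes), ncol = 1L)
  spec
}

#' Build the target-frequency set
#'
#' The analysis frequencies are the harmonics of the possible event
#' groupings of the sequence: cycles of 12 events (5/12 Hz) and 16 events
#' (5/16 Hz) and all their harmonics up to the 5-Hz event rate,
#' deduplicated. The default union rule yields 24 frequencies of which 16
#' fall exactly on a bin at the 1/14.4-Hz resolution; a frequency is marked
#' `exact_bin` when `f / resolution` is an integer (tolerance 1e-9) and
#' `max_of_two_closest` otherwise. The meter-related subset is
#' \{1.25, 2.5, 5\} Hz: the event rate and its groupings by 2 and 4 events,
#' matching the meter used during sequence construction. A custom frequency
#' list can be supplied via `frequencies` (e.g. a curated 21-frequency set).
#'
#' @param event_rate event presentation rate in Hz (default 5).
#' @param cycles integer event-cycle lengths whose harmonics are analysed
#'   (default `c(12, 16)`).
#' @param resolution spectral resolution in Hz used to classify extraction
#'   rules (default `1/14.4`).
#' @param max_freq highest analysed frequency (default `event_rate`).
#' @param meter_subset meter-related frequencies in Hz.
#' @param frequencies optional explicit frequency vector overriding the
#'   union rule.
#' @return an object of class `target_frequencies`: data.frame with columns
#'   `frequency`, `rule` (`"exact_bin"` or `"max_of_two_closest"`) and
#'   `is_meter`, with the resolution stored as an attribute.
#' @export
build_target_frequencies <- function(event_rate = 5, cycles = c(12L, 16L),
                                     resolution = 1 / 14.4,
                                     max_freq = event_rate,
                                     meter_subset = c(1.25, 2.5, 5),
                                     frequencies = NULL) {
  tol <- 1e-9
  if (is.null(frequencies)) {
    freqs <- unlist(lapply(cycles, function(cyc)
      (seq_len(cyc) * event_rate) / cyc))
    freqs <- freqs[freqs <= max_freq + tol]
    freqs <- sort(freqs)
    freqs <- freqs[c(TRUE, diff(freqs) > tol)]
  } else {
    freqs <- sort(as.numeric(frequencies))
  }
  ratio <- freqs / resolution
  rule <- ifelse(abs(ratio - round(ratio)) < tol,
                 "exact_bin", "max_of_two_closest")
  is_meter <- vapply(freqs, function(f)
    any(abs(f - meter_subset) < tol), logical(1))
  if (!all(vapply(meter_subset, function(f)
    any(abs(freqs - f) < tol), logical(1))))
    stop("meter_subset must be contained in the frequency set")
  out <- data.frame(frequency = freqs, rule = rule, is_meter = is_meter)
  attr(out, "resolution") <- resolution
  class(out) <- c("target_frequencies", "data.frame")
  out
}

#' Extract amplitudes at the target frequencies
#'
#' For `exact_bin` frequencies the amplitude is read at the nearest bin
#' (`round(f / resolution)`); for `max_of_two_closest` frequencies it is the
#' maximum of the two bins bracketing the frequency. The spectrum must be
#' single-channel (average across channels first, see
#' [average_channels()]).
#'
#' @param spec a single-channel [magnitude_spectrum()].
#' @param targets a [build_target_frequencies()] set.
#' @return named numeric vector of amplitudes (names = frequencies), with
#'   the spectrum's `noise_subtracted` flag as attribute.
#' @export
extract_amplitudes <- function(spec, targets) {
  stopifnot(inherits(spec, "magnitude_spectrum"),
            inherits(targets, "target_frequencies"))
  if (ncol(spec$amplitudes) != 1L)
    stop("spectrum has ", ncol(spec$amplitudes),
         " channels; average across channels before extraction")
  nyq <- max(spec$frequencies)
  if (any(targets$frequency > nyq + 1e-9))
    stop("target frequency above the Nyquist frequency (", nyq, " Hz)")
  a <- spec$amplitudes[, 1L]
  res <- spec$resolution
  out <- vapply(seq_len(nrow(targets)), function(i) {
    ratio <- targets$frequency[i] / res
    if (targets$rule[i] == "exact_bin") {
      a[as.integer(round(ratio)) + 1L]
    } else {
      lo <- as.integer(floor(ratio)) + 1L
      hi <- as.integer(ceiling(ratio)) + 1L
      max(a[lo], a[hi])
    }
  }, numeric(1))
  names(out) <- format(targets$frequency, trim = TRUE)
  attr(out, "noise_subtracted") <- spec$noise_subtracted
  out
}

#' z-score amplitudes over the target-frequency set
#'
#' Standardizes the extracted amplitudes across the whole target set,
#' `z = (x - mean(x)) / sd(x)` with the sample (n-1) standard deviation,
#' and summarises the meter-related subset by its mean z. The z-scores have
#' mean 0 and SD 1 by construction and are invariant to overall spectrum
#' gain, which makes the meter prominence a relative, gain-free measure.
#'
#' @param amps named amplitude vector from [extract_amplitudes()] (or any
#'   numeric vector ordered as `targets`).
#' @param targets the [build_target_frequencies()] set the amplitudes were
#'   extracted with.
#' @return an object of class `zscore_summary`: list with `z` (named
#'   vector), `meter_mean_z`, `frequencies`, `meter_subset` and
#'   `noise_subtracted`.
#' @export
zscore_amplitudes <- function(amps, targets) {
  stopifnot(inherits(targets, "target_frequencies"))
  x <- as.numeric(amps)
  if (length(x) != nrow(targets))
    stop("amplitude vector length does not match the target set")
  if (length(unique(x)) < 2L || stats::sd(x) == 0)
    stop("zero variance across target frequencies; z-scores undefined")
  z <- (x - mean(x)) / stats::sd(x)
  names(z) <- format(targets$frequency, trim = TRUE)
  structure(
    list(z = z,
         meter_mean_z = mean(z[targets$is_meter]),
         frequencies = targets$frequency,
         meter_subset = targets$frequency[targets$is_meter],
         noise_subtracted = isTRUE(attr(amps, "noise_subtracted"))),
    class = "zscore_summary"
  )
}

#' @export
print.zscore_summary <- function(x, ...) {
  cat("z-scored amplitudes over", length(x$z), "target frequencies\n")
  cat("  meter subset {", paste(x$meter_subset, collapse = ", "),
      "} Hz: mean z =", round(x$meter_mean_z, 3), "\n")
  invisible(x)
}

#' Difference in meter-frequency prominence: periphery minus response
#'
#' Computes `periphery meter_mean_z - response meter_mean_z` for z-score
#' summaries built on the same target-frequency set. If the response were
#' fully explained by peripheral auditory processing the difference would
#' be zero; a response with selectively amplified meter frequencies yields
#' a negative difference under this sign convention.
#'
#' @param periphery_z `zscore_summary` from the cochlear-model path (must
#'   have been noise-subtracted before z-scoring, like the response path).
#' @param response_z `zscore_summary` from the EEG (or tapping) path.
#' @return scalar difference, with attribute `sign_convention`.
#' @export
meter_z_difference <- function(periphery_z, response_z) {
  stopifnot(inherits(periphery_z, "zscore_summary"),
            inherits(response_z, "zscore_summary"))
  if (length(periphery_z$frequencies) != length(response_z$frequencies) ||
      any(abs(periphery_z$frequencies - response_z$frequencies) > 1e-9))
    stop("z-score summaries built on different target-frequency sets")
  if (!periphery_z$noise_subtracted)
    stop("periphery spectrum must be noise-subtracted before z-scoring")
  structure(periphery_z$meter_mean_z - response_z$meter_mean_z,
            sign_convention = "periphery_minus_response")
}

#' Shared frequency-tagging analysis over epochs
#'
#' The engine behind the EEG, tapping and periphery paths: epochs are
#' segmented into seven overlapping windows, averaged across trials in the
#' time domain per (direction, segment) cell, transformed with FFT,
#' noise-subtracted per channel, averaged across channels, and reduced to
#' z-scored amplitudes at the target frequencies.
#'
#' For the degraded-to-regular direction the segment index is reported both
#' raw and reversed (`segment_aligned = 8 - segment`), so that rows with
#' equal `segment_aligned` always refer to identical stimulus-envelope
#' spectra across directions.
#'
#' @param epochs list of channels x samples matrices, one per trial.
#' @param directions character vector (one per epoch),
#'   `"regular_to_degraded"` or `"degraded_to_regular"`.
#' @param rate sampling rate in samples/s.
#' @param targets a [build_target_frequencies()] set (its resolution should
#'   match `window`).
#' @param origin signal family label, see [segment_signal()].
#' @param core_start_offset seconds to skip at each epoch start.
#' @param noise_subtract apply [subtract_noise()] (default TRUE).
#' @param window,hop,n_segments segmentation geometry in seconds.
#' @return list with `amplitudes` (long data.frame: origin, direction,
#'   segment, segment_aligned, frequency, amplitude, z) and `summary`
#'   (data.frame: origin, direction, segment, segment_aligned,
#'   meter_mean_z).
#' @export
freqtag_analyze <- function(epochs, directions, rate,
                            targets = build_target_frequencies(),
                            origin = c("eeg", "tapping", "periphery",
                                       "envelope"),
                            core_start_offset = 0,
                            noise_subtract = TRUE,
                            window = 14.4, hop = 7.2, n_segments = 7L) {
  origin <- match.arg(origin)
  stopifnot(length(epochs) == length(directions))
  amp_rows <- list()
  sum_rows <- list()
  for (dir in unique(directions)) {
    idx <- which(directions == dir)
    segged <- lapply(epochs[idx], segment_signal, rate = rate,
                     core_start_offset = core_start_offset,
                     window = window, hop = hop, n_segments = n_segments,
                     origin = origin)
    avg <- average_trials(segged)
    for (s in seq_along(avg$segments)) {
      spec <- magnitude_spectrum(avg$segments[[s]], rate)
      if (noise_subtract) spec <- subtract_noise(spec)
      spec <- average_channels(spec)
      amps <- extract_amplitudes(spec, targets)
      zs <- zscore_amplitudes(amps, targets)
      aligned <- if (dir == "degraded_to_regular")
        n_segments + 1L - s else s
      amp_rows[[length(amp_rows) + 1L]] <- data.frame(
        origin = origin, direction = dir, segment = s,
        segment_aligned = aligned,
        frequency = targets$frequency,
        amplitude = as.numeric(amps), z = as.numeric(zs$z),
        row.names = NULL)
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        origin = origin, direction = dir, segment = s,
        segment_aligned = aligned, meter_mean_z = zs$meter_mean_z,
        row.names = NULL)
    }
  }
  list(amplitudes = do.call(rbind, amp_rows),
       summary = do.call(rbind, sum_rows))
}
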