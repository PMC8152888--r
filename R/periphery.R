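#' Auditory periphery model configuration
#'
#' Settings for the cochlear front end: a gammatone filterbank with
#' ERB-spaced centre frequencies followed by a hair-cell transduction
#' stage. The default transduction (`"rca"`) is a simplified
#' rectify-compress-adapt stage: half-wave rectification, power-law
#' compression and a divisive adaptation loop. The reservoir hair-cell
#' model (`"meddis"`), implemented from the published constants, is
#' available behind this switch. The activation is downsampled to
#' `out_rate` (default 512 samples/s) so the periphery path feeds the same
#' spectral engine as the EEG.
#'
#' @param n_channels number of cochlear channels (default 100).
#' @param cf_min,cf_max centre-frequency range in Hz (default 50-8000,
#'   ERB-spaced).
#' @param haircell `"rca"` (default) or `"meddis"`.
#' @param out_rate activation sampling rate after decimation, samples/s.
#' @param compression power-law exponent of the `"rca"` stage.
#' @param adapt_strength divisive adaptation strength of the `"rca"` stage.
#' @param adapt_tau adaptation time constant in seconds.
#' @return an object of class `periphery_config`.
#' @export
periphery_config <- function(n_channels = 100L, cf_min = 50, cf_max = 8000,
                             haircell = c("rca", "meddis"),
                             out_rate = 512,
                             compression = 0.3, adapt_strength = 5,
                             adapt_tau = 0.075) {
  haircell <- match.arg(haircell)
  stopifnot(n_channels >= 1L, cf_min > 0, cf_max > cf_min)
  structure(
    list(n_channels = as.integer(n_channels), cf_min = cf_min,
         cf_max = cf_max, haircell = haircell, out_rate = out_rate,
         compression = compression, adapt_strength = adapt_strength,
         adapt_tau = adapt_tau),
    class = "periphery_config"
  )
}

#' ERB-spaced centre frequencies
#'
#' Centre frequencies spaced uniformly on the equivalent-rectangular-
#' bandwidth (ERB) scale between `low` and `high` Hz, returned ascending.
#'
#' @param n number of channels.
#' @param low,high frequency range in Hz.
#' @return numeric vector of length `n`, strictly increasing.
#' @export
erb_centre_frequencies <- function(n, low, high) {
  ear_q <- 9.26449
  min_bw <- 24.7
  cf <- -(ear_q * min_bw) +
    exp(seq_len(n) * (-log(high + ear_q * min_bw) +
                        log(low + ear_q * min_bw)) / n) *
    (high + ear_q * min_bw)
  sort(cf)
}

# digital gammatone coefficients (all-pole approximation, 4 cascaded
# second-order sections); one row per channel:
# a0 a11 a12 a13 a14 a2 b1 b2 gain
gammatone_coefs <- function(cf, fs) {
  t <- 1 / fs
  ear_q <- 9.26449
  min_bw <- 24.7
  erb <- cf / ear_q + min_bw
  b <- 1.019 * 2 * pi * erb
  a0 <- t
  a2 <- 0
  b1 <- -2 * cos(2 * cf * pi * t) / exp(b * t)
  b2 <- exp(-2 * b * t)
  sp <- sqrt(3 + 2^1.5)
  sm <- sqrt(3 - 2^1.5)
  a11 <- -(2 * t * cos(2 * cf * pi * t) / exp(b * t) +
             2 * sp * t * sin(2 * cf * pi * t) / exp(b * t)) / 2
  a12 <- -(2 * t * cos(2 * cf * pi * t) / exp(b * t) -
             2 * sp * t * sin(2 * cf * pi * t) / exp(b * t)) / 2
  a13 <- -(2 * t * cos(2 * cf * pi * t) / exp(b * t) +
             2 * sm * t * sin(2 * cf * pi * t) / exp(b * t)) / 2
  a14 <- -(2 * t * cos(2 * cf * pi * t) / exp(b * t) -
             2 * sm * t * sin(2 * cf * pi * t) / exp(b * t)) / 2
  z <- exp(4i * cf * pi * t)
  e <- exp(-(b * t) + 2i * cf * pi * t)
  cs <- cos(2 * cf * pi * t)
  sn <- sin(2 * cf * pi * t)
  gain <- abs(
    (-2 * z * t + 2 * e * t * (cs - sm * sn)) *
    (-2 * z * t + 2 * e * t * (cs + sm * sn)) *
    (-2 * z * t + 2 * e * t * (cs - sp * sn)) *
    (-2 * z * t + 2 * e * t * (cs + sp * sn)) /
    (-2 / exp(2 * b * t) - 2 * z + 2 * (1 + z) / exp(b * t))^4
  )
  cbind(a0 = rep(a0, length(cf)), a11 = a11, a12 = a12, a13 = a13,
        a14 = a14, a2 = rep(a2, length(cf)), b1 = b1, b2 = b2,
        gain = gain)
}

#' Peripheral auditory activation of a waveform
#'
#' Runs a stimulus waveform through the gammatone ERB filterbank and the
#' configured hair-cell stage, then block-averages the per-channel
#' activation down to `cfg$out_rate`. The result approximates the envelope-
#' following activation of the auditory nerve and is non-negative.
#'
#' @param wave a [render_audio()] waveform, or a list with `samples` and
#'   `rate`.
#' @param cfg a [periphery_config()].
#' @return an object of class `neural_activation`: list with `activations`
#'   (channels x time matrix), `rate` (= `cfg$out_rate`), `cf` (centre
#'   frequencies) and `config`.
#' @export
periphery_response <- function(wave, cfg = periphery_config()) {
  stopifnot(length(wave$samples) > 0L)
  if (cfg$cf_max >= wave$rate / 2)
    stop("highest centre frequency (", cfg$cf_max,
         " Hz) is at or above the Nyquist frequency of the waveform")
  cf <- erb_centre_frequencies(cfg$n_channels, cfg$cf_min, cfg$cf_max)
  coefs <- gammatone_coefs(cf, wave$rate)
  act <- periphery_kernel(wave$samples, wave$rate, coefs, cfg$haircell,
                          cfg$out_rate, cfg$compression,
                          cfg$adapt_strength, cfg$adapt_tau)
  structure(
    list(activations = act, rate = cfg$out_rate, cf = cf, config = cfg),
    class = "neural_activation"
  )
}

#' @export
print.neural_activation <- function(x, ...) {
  cat("Neural activation pattern:", nrow(x$activations), "channels x",
      ncol(x$activations), "samples at", x$rate, "samples/s (",
      x$config$haircell, "hair cell )\n")
  invisible(x)
}

#' Channel-averaged magnitude spectra of a neural activation pattern
#'
#' Segments the activation into overlapping analysis windows, computes the
#' per-channel FFT magnitude spectrum of each window and averages the
#' spectra across cochlear channels.
#'
#' @param nap a [periphery_response()] result.
#' @param core_start_offset seconds to skip before the first window.
#' @param window,hop window length and hop in seconds.
#' @param n_segments number of windows.
#' @param noise_subtract apply [subtract_noise()] per channel before the
#'   across-channel average (the periphery path of the full pipeline does).
#' @return list of single-channel [magnitude_spectrum()] objects, one per
#'   segment.
#' @export
channel_average_spectrum <- function(nap, core_start_offset = 0,
                                     window = 14.4, hop = 7.2,
                                     n_segments = 7L,
                                     noise_subtract = FALSE) {
  seg <- segment_signal(nap$activations, nap$rate,
                        core_start_offset = core_start_offset,
                        window = window, hop = hop,
                        n_segments = n_segments, origin = "periphery")
  lapply(seg$segments, function(s) {
    spec <- magnitude_spectrum(s, nap$rate)
    if (noise_subtract) spec <- subtract_noise(spec)
    average_channels(spec)
  })
}
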