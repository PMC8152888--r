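#' Build a regular-to-degraded rhythmic sequence
#'
#' Constructs a 57.6-s sequence of 24 concatenated 12-event patterns whose
#' meter phase-stability decreases, and whose syncopation increases,
#' throughout. Three patterns are drawn uniformly with replacement from each
#' syncopation-range group, walking the groups from the highest working
#' range down to 1 (the single maximal-range pattern is never sampled). For
#' each drawn pattern the rotation (phase) whose syncopation score is
#' closest to the group's target score is selected; ties are broken by a
#' seeded uniform draw. Two sound events are prepended and appended as
#' padding, giving a 292-event (58.4 s) padded grid around the 288-event
#' core.
#'
#' @param seed integer seed; the same seed always yields a bit-identical
#'   sequence.
#' @param template a [metric_template()] used for grouping and phase
#'   selection.
#' @param score_targets integer vector of per-group target syncopation
#'   scores, one per working range group, ordered from the highest range
#'   group to range 1.
#' @param variant scoring variant, see [lhl_score()].
#' @param patterns pattern set; defaults to [enumerate_patterns()].
#' @param groups optional precomputed [categorize_patterns()] result
#'   (avoids rescoring the pattern space when building many sequences).
#' @return an object of class `rhythm_sequence` with fields `placements`
#'   (24-row data.frame: `position`, `group_range`, `pattern_id`, `phase`,
#'   `target_score`, `achieved_score`), `direction`
#'   (`"regular_to_degraded"`), `core_events` (length 288), `padded_events`
#'   (length 292), `event_duration` (0.2 s) and `seed`.
#' @examples
#' s <- build_sequence(seed = 1)
#' s
#' @export
build_sequence <- function(seed,
                           template = metric_template(c(2, 4, 12)),
                           score_targets = c(1, -1, 0, 1, 2, 3, 4, 4),
                           variant = c("lhl", "positive", "signed"),
                           patterns = NULL,
                           groups = NULL) {
  variant <- match.arg(variant)
  if (is.null(patterns)) patterns <- enumerate_patterns(template$cycle)
  if (is.null(groups)) groups <- categorize_patterns(patterns, template, variant)
  ranges <- groups$working_ranges
  if (length(score_targets) != length(ranges))
    stop("score_targets must have one entry per working range group (",
         length(ranges), ")")
  empty <- ranges[!as.character(ranges) %in% names(groups$groups)]
  if (length(empty) > 0L)
    stop("empty syncopation-range group: ", paste(empty, collapse = ", "))

  placements <- with_sequence_rng(seed, {
    rows <- vector("list", 3L * length(ranges))
    k <- 0L
    for (gi in seq_along(ranges)) {
      g <- ranges[gi]
      ids <- groups$groups[[as.character(g)]]
      target <- score_targets[gi]
      for (j in 1:3) {
        id <- ids[sample.int(length(ids), 1L)]
        prof <- groups$profiles[[as.character(id)]]$per_phase_scores
        dist <- abs(prof - target)
        cand <- which(dist == min(dist))
        phase <- cand[sample.int(length(cand), 1L)] - 1L
        k <- k + 1L
        rows[[k]] <- data.frame(position = k, group_range = g,
                                pattern_id = id, phase = phase,
                                target_score = target,
                                achieved_score = prof[phase + 1L])
      }
    }
    do.call(rbind, rows)
  })

  core <- unlist(lapply(seq_len(nrow(placements)), function(i) {
    rotate_pattern(patterns[as.character(placements$pattern_id[i]), ],
                   placements$phase[i])
  }), use.names = FALSE)
  structure(
    list(placements = placements,
         direction = "regular_to_degraded",
         core_events = as.integer(core),
         padded_events = c(1L, 1L, as.integer(core), 1L, 1L),
         event_duration = 0.2,
         template = template,
         variant = variant,
         seed = as.integer(seed)),
    class = "rhythm_sequence"
  )
}

# run expr under a private Mersenne-Twister stream, restoring global RNG state
with_sequence_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

#' Derive a per-item seed from a master seed
#'
#' Deterministic stream splitting used to give each sequence, trial or
#' participant its own reproducible seed. Kept below 2^31.
#'
#' @param master master integer seed.
#' @param index non-negative item index.
#' @return integer seed.
#' @export
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + 7919 * as.double(index)) %%
               2147483647)
}

#' Time-invert a sequence
#'
#' Reverses the 288-event core (the first event becomes the last) and
#' re-applies the 2-event sound padding, turning a regular-to-degraded
#' sequence into its degraded-to-regular twin. Because time reversal leaves
#' discrete Fourier magnitudes untouched, the envelope magnitude spectra of
#' a sequence and its inversion are identical bin by bin.
#'
#' @param seq a `rhythm_sequence`.
#' @return the inverted `rhythm_sequence`; placements are stored in reversed
#'   order with a `time_reversed` attribute set to `TRUE`.
#' @export
invert_sequence <- function(seq) {
  stopifnot(inherits(seq, "rhythm_sequence"))
  core <- rev(seq$core_events)
  placements <- seq$placements[rev(seq_len(nrow(seq$placements))), ]
  rownames(placements) <- NULL
  placements$position <- seq_len(nrow(placements))
  out <- seq
  out$core_events <- core
  out$padded_events <- c(1L, 1L, core, 1L, 1L)
  out$placements <- placements
  out$direction <- if (seq$direction == "regular_to_degraded")
    "degraded_to_regular" else "regular_to_degraded"
  attr(out$placements, "time_reversed") <-
    !isTRUE(attr(seq$placements, "time_reversed"))
  out
}

#' @export
print.rhythm_sequence <- function(x, ...) {
  n_core <- length(x$core_events)
  cat("Rhythm sequence (", x$direction, ", seed ", x$seed, ")\n", sep = "")
  cat("  ", nrow(x$placements), " placements, ", n_core, " core events (",
      n_core * x$event_duration, " s), ", length(x$padded_events),
      " padded events (", length(x$padded_events) * x$event_duration,
      " s)\n", sep = "")
  cat("  group order:", paste(x$placements$group_range, collapse = " "), "\n")
  cat("  achieved scores:",
      paste(x$placements$achieved_score, collapse = " "), "\n")
  invisible(x)
}

#' Render a sequence as audio
#'
#' One 200-ms frame per padded event; sound events carry a 440-Hz pure tone
#' with 10-ms linear onset and offset ramps, silent events are exactly zero.
#' All sound events are identical (the carrier restarts at zero phase), so
#' peak amplitude is constant across events.
#'
#' @param seq a `rhythm_sequence`.
#' @param rate sampling rate in samples/s (>= 8000, and such that a 200-ms
#'   event spans an integer number of samples).
#' @param carrier carrier frequency in Hz (default 440).
#' @param ramp linear ramp duration in s (default 0.010).
#' @return an object of class `stimulus_waveform`: list with `samples`,
#'   `rate`, `event_duration`, `carrier`, `ramp`.
#' @export
render_audio <- function(seq, rate = 44100, carrier = 440, ramp = 0.010) {
  stopifnot(inherits(seq, "rhythm_sequence"))
  if (rate < 8000) stop("rate must be at least 8000 samples/s")
  if (rate < 2 * carrier) stop("rate below Nyquist for the ", carrier,
                               "-Hz carrier")
  n_ev <- rate * seq$event_duration
  if (abs(n_ev - round(n_ev)) > 1e-9)
    stop("a ", seq$event_duration * 1000,
         "-ms event must span an integer number of samples at rate ", rate)
  n_ev <- as.integer(round(n_ev))
  t <- (seq_len(n_ev) - 1L) / rate
  env <- rep(1, n_ev)
  n_ramp <- round(ramp * rate)
  if (n_ramp > 0L) {
    up <- seq(0, 1, length.out = n_ramp)
    env[seq_len(n_ramp)] <- up
    env[n_ev - n_ramp + seq_len(n_ramp)] <- rev(up)
  }
  tone <- sin(2 * pi * carrier * t) * env
  samples <- numeric(n_ev * length(seq$padded_events))
  on <- which(seq$padded_events == 1L)
  for (j in on) samples[(j - 1L) * n_ev + seq_len(n_ev)] <- tone
  structure(
    list(samples = samples, rate = rate,
         event_duration = seq$event_duration,
         carrier = carrier, ramp = ramp),
    class = "stimulus_waveform"
  )
}

#' @export
print.stimulus_waveform <- function(x, ...) {
  cat("Stimulus waveform:", length(x$samples), "samples at", x$rate,
      "samples/s (", length(x$samples) / x$rate, "s ),",
      x$carrier, "Hz carrier\n")
  invisible(x)
}

#' Ideal event-gate envelope of a sequence
#'
#' The rectangular on/off gate (1 during sound events, 0 during silences)
#' sampled at `rate`. This is the envelope used for spectral-identity
#' diagnostics: the sample-wise reversal of the core gate equals the gate of
#' the inverted core, so Fourier magnitudes match exactly.
#'
#' @param seq a `rhythm_sequence`.
#' @param rate sampling rate (200-ms events must span an integer number of
#'   samples).
#' @param region `"core"` (default) for the 288-event core only, or
#'   `"padded"` for the full 292-event grid.
#' @return numeric vector of 0/1 samples.
#' @export
event_envelope <- function(seq, rate = 512, region = c("core", "padded")) {
  region <- match.arg(region)
  events <- if (region == "core") seq$core_events else seq$padded_events
  n_ev <- rate * seq$event_duration
  if (abs(n_ev - round(n_ev)) > 1e-9)
    stop("a 200-ms event must span an integer number of samples at rate ",
         rate)
  rep(as.numeric(events), each = as.integer(round(n_ev)))
}

# linear (non-cyclic) scoring of a 0/1 event window: template weights are
# aligned to the window start; silences before the first sound are unpaired
lhl_score_linear <- function(events, template, variant = "lhl") {
  w <- template$weights
  cyc <- template$cycle
  pair_values <- integer(0)
  last_note <- NA_integer_
  for (j in seq_along(events)) {
    if (events[j] == 1L) {
      last_note <- j
    } else if (!is.na(last_note)) {
      pair_values <- c(pair_values,
                       w[((j - 1L) %% cyc) + 1L] -
                         w[((last_note - 1L) %% cyc) + 1L])
    }
  }
  sum_pairs(pair_values, variant)
}

#' Per-segment syncopation of a sequence
#'
#' Divides the 288-event core into seven 72-event segments with 50% overlap
#' and scores each against a nested template (default pulses every 2 and 4
#' events, the construction meter without its slowest pulse, since patterns
#' are not looped within a sequence). Because the phase of the perceived
#' meter is unknown, each segment is rescored after shifting the analysis
#' window by -2..+2 events (indexing into the padding events at the
#' sequence edges) and the minimum score across shifts is taken.
#'
#' @param seq a `rhythm_sequence`.
#' @param template a [metric_template()] for the segment windows.
#' @param shifts integer window shifts in events.
#' @param variant scoring variant, see [lhl_score()].
#' @param segment_events segment length in events (default 72, i.e. 14.4 s).
#' @return an object of class `segment_syncopation`: list with `per_segment`
#'   (minimum score per segment), `by_shift` (segments x shifts matrix),
#'   `template` and `shifts`.
#' @export
segment_syncopation <- function(seq,
                                template = metric_template(c(2, 4)),
                                shifts = -2:2,
                                variant = c("lhl", "positive", "signed"),
                                segment_events = 72L) {
  variant <- match.arg(variant)
  stopifnot(inherits(seq, "rhythm_sequence"))
  hop <- segment_events %/% 2L
  n_core <- length(seq$core_events)
  n_seg <- (n_core - segment_events) %/% hop + 1L
  pad_before <- (length(seq$padded_events) - n_core) %/% 2L
  by_shift <- matrix(NA_integer_, n_seg, length(shifts),
                     dimnames = list(segment = seq_len(n_seg),
                                     shift = shifts))
  for (s in seq_len(n_seg)) {
    start_core <- (s - 1L) * hop # 0-based
    for (h in seq_along(shifts)) {
      start_pad <- start_core + pad_before + shifts[h] # 0-based in padding
      if (start_pad < 0L || start_pad + segment_events >
            length(seq$padded_events))
        stop("window shift ", shifts[h], " falls outside the padded grid")
      win <- seq$padded_events[start_pad + seq_len(segment_events)]
      by_shift[s, h] <- lhl_score_linear(win, template, variant)
    }
  }
  structure(
    list(per_segment = apply(by_shift, 1L, min),
         by_shift = by_shift,
         template = template,
         shifts = shifts),
    class = "segment_syncopation"
  )
}

#' @export
print.segment_syncopation <- function(x, ...) {
  cat("Segment syncopation under", template_label(x$template),
      "(min over shifts", paste0(min(x$shifts), "..", max(x$shifts), "):\n"))
  print(x$per_segment)
  invisible(x)
}

#' Segment syncopation under alternative metric interpretations
#'
#' Evaluates [segment_syncopation()] under each of several candidate
#' templates, for checking that a sequence degrades with respect to its
#' construction meter rather than converging onto a different meter.
#'
#' @param seq a `rhythm_sequence`.
#' @param templates list of [metric_template()]s; the default compares the
#'   construction meter \{2,4\} with the \{3,6\} and \{2,6\}
#'   interpretations.
#' @inheritParams segment_syncopation
#' @return data.frame with columns `template`, `segment`, `score`.
#' @export
alternative_meter_check <- function(seq,
                                    templates = list(
                                      metric_template(c(2, 4)),
                                      metric_template(c(3, 6)),
                                      metric_template(c(2, 6))),
                                    variant = c("lhl", "positive", "signed")) {
  variant <- match.arg(variant)
  if (length(templates) == 0L)
    return(data.frame(template = character(0), segment = integer(0),
                      score = integer(0)))
  do.call(rbind, lapply(templates, function(tpl) {
    ss <- segment_syncopation(seq, tpl, variant = variant)
    data.frame(template = template_label(tpl),
               segment = seq_along(ss$per_segment),
               score = as.integer(ss$per_segment),
               row.names = NULL)
  }))
}
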