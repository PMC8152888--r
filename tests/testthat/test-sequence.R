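tpl <- metric_template(c(2, 4, 12))
pats <- enumerate_patterns()
grps <- categorize_patterns(pats, tpl)

test_that("built sequences have 24 placements, a 57.6-s core and the
           decreasing group order", {
  s <- build_sequence(seed = 1, patterns = pats, groups = grps)
  expect_equal(nrow(s$placements), 24L)
  expect_length(s$core_events, 288L)
  expect_length(s$padded_events, 292L)
  expect_equal(length(s$core_events) * s$event_duration, 57.6)
  expect_equal(length(s$padded_events) * s$event_duration, 58.4)
  expect_equal(s$placements$group_range, rep(8:1, each = 3L))
  expect_equal(s$padded_events[1:2], c(1L, 1L))
  expect_equal(s$padded_events[291:292], c(1L, 1L))
  expect_identical(s$padded_events[3:290], s$core_events)
  # core is the concatenation of the placed (rotated) patterns
  first <- rotate_pattern(pats[as.character(s$placements$pattern_id[1]), ],
                          s$placements$phase[1])
  expect_identical(s$core_events[1:12], as.integer(first))
})

test_that("sequence construction is deterministic given the seed", {
  s1 <- build_sequence(seed = 123, patterns = pats, groups = grps)
  s2 <- build_sequence(seed = 123, patterns = pats, groups = grps)
  expect_identical(s1, s2)
  s3 <- build_sequence(seed = 124, patterns = pats, groups = grps)
  expect_false(identical(s1$core_events, s3$core_events))
})

test_that("achieved scores equal targets whenever the sampled pattern can
           realize the target, and are nearest otherwise", {
  targets <- c(1, -1, 0, 1, 2, 3, 4, 4)
  for (seed in 1:25) {
    s <- build_sequence(seed, patterns = pats, groups = grps)
    for (i in seq_len(24)) {
      prof <- grps$profiles[[as.character(s$placements$pattern_id[i])]]
      tgt <- s$placements$target_score[i]
      ach <- s$placements$achieved_score[i]
      expect_equal(ach, prof$per_phase_scores[s$placements$phase[i] + 1L])
      if (tgt %in% prof$per_phase_scores) expect_equal(ach, tgt)
      else expect_equal(abs(ach - tgt),
                        min(abs(prof$per_phase_scores - tgt)))
    }
    expect_equal(s$placements$target_score, rep(targets, each = 3L))
  }
})

test_that("inversion reverses the core, flips direction and is an
           involution", {
  s <- build_sequence(seed = 5, patterns = pats, groups = grps)
  si <- invert_sequence(s)
  expect_equal(si$direction, "degraded_to_regular")
  expect_identical(si$core_events, rev(s$core_events))
  expect_equal(si$core_events[1L], s$core_events[288L])
  expect_identical(invert_sequence(si)$core_events, s$core_events)
  expect_equal(si$padded_events[1:2], c(1L, 1L))
})

test_that("core envelope magnitude spectra are identical under inversion
           for many seeds", {
  for (seed in 1:20) {
    s <- build_sequence(seed, patterns = pats, groups = grps)
    si <- invert_sequence(s)
    e <- event_envelope(s, rate = 500)
    ei <- event_envelope(si, rate = 500)
    m <- Mod(stats::fft(e))
    mi <- Mod(stats::fft(ei))
    expect_lt(max(abs(m - mi)) / max(m), 1e-9)
  }
})

test_that("audio rendering produces symmetric ramped tone events", {
  s <- build_sequence(seed = 2, patterns = pats, groups = grps)
  w <- render_audio(s, rate = 20000)
  expect_equal(length(w$samples) / w$rate, 58.4)
  n_ev <- w$rate * 0.2
  # silence events are exactly zero
  sil <- which(s$padded_events == 0L)[1L]
  idx <- (sil - 1L) * n_ev + seq_len(n_ev)
  expect_true(all(w$samples[idx] == 0))
  # all sound events are identical, with equal peak amplitude
  on <- which(s$padded_events == 1L)
  ev1 <- w$samples[(on[1L] - 1L) * n_ev + seq_len(n_ev)]
  ev2 <- w$samples[(on[5L] - 1L) * n_ev + seq_len(n_ev)]
  expect_identical(ev1, ev2)
  # a sound event is the 440-Hz carrier under a time-symmetric linear
  # on/off gate (10 ms up, 10 ms down)
  n_ramp <- round(0.010 * w$rate)
  env_ref <- rep(1, n_ev)
  env_ref[seq_len(n_ramp)] <- seq(0, 1, length.out = n_ramp)
  env_ref[n_ev - n_ramp + seq_len(n_ramp)] <- seq(1, 0,
                                                  length.out = n_ramp)
  expect_equal(env_ref, rev(env_ref))
  carrier <- sin(2 * pi * 440 * (seq_len(n_ev) - 1) / w$rate)
  expect_equal(ev1, carrier * env_ref, tolerance = 1e-12)
  expect_error(render_audio(s, rate = 4000), "8000")
  # idempotence
  expect_identical(render_audio(s, 20000)$samples, w$samples)
})

test_that("segment syncopation yields 7 windows scored as the minimum over
           -2..+2 shifts", {
  s <- build_sequence(seed = 3, patterns = pats, groups = grps)
  ss <- segment_syncopation(s)
  expect_length(ss$per_segment, 7L)
  expect_equal(dim(ss$by_shift), c(7L, 5L))
  expect_equal(unname(ss$per_segment), unname(apply(ss$by_shift, 1, min)))
  # all-sounds core scores zero everywhere
  s_all <- s
  s_all$core_events <- rep(1L, 288L)
  s_all$padded_events <- c(1L, 1L, s_all$core_events, 1L, 1L)
  expect_true(all(segment_syncopation(s_all)$per_segment == 0L))
})

test_that("segment i of the inverted core is the reversal of segment 8-i of
           the original", {
  s <- build_sequence(seed = 9, patterns = pats, groups = grps)
  si <- invert_sequence(s)
  for (i in 1:7) {
    start <- (i - 1L) * 36L
    seg_inv <- si$core_events[start + 1:72]
    start_o <- (7L - i) * 36L
    seg_orig <- s$core_events[start_o + 1:72]
    expect_identical(seg_inv, rev(seg_orig))
  }
})

test_that("construction-meter syncopation trends upward over segments while
           alternative meters do not decrease monotonically", {
  n_seeds <- 20L
  first_last <- matrix(NA_real_, n_seeds, 2L)
  alt_monotone_down <- c("{3,6}" = 0L, "{2,6}" = 0L)
  for (seed in seq_len(n_seeds)) {
    s <- build_sequence(seed, patterns = pats, groups = grps)
    tab <- alternative_meter_check(s)
    main <- tab$score[tab$template == "{2,4}"]
    first_last[seed, ] <- c(mean(main[1:3]), mean(main[5:7]))
    for (lab in names(alt_monotone_down)) {
      alt <- tab$score[tab$template == lab]
      if (all(diff(alt) <= 0) && any(diff(alt) < 0))
        alt_monotone_down[lab] <- alt_monotone_down[lab] + 1L
    }
  }
  # degradation: later segments are more syncopated than earlier ones
  expect_true(all(first_last[, 2] >= first_last[, 1]))
  expect_gt(mean(first_last[, 2] - first_last[, 1]), 1)
  # the sequences do not converge onto the {3,6} or {2,6} meter
  expect_lt(alt_monotone_down[["{3,6}"]], n_seeds / 2)
  expect_lt(alt_monotone_down[["{2,6}"]], n_seeds / 2)
})

test_that("alternative meter check handles an empty template list", {
  s <- build_sequence(seed = 4, patterns = pats, groups = grps)
  empty <- alternative_meter_check(s, templates = list())
  expect_equal(nrow(empty), 0L)
})

test_that("empty range groups are reported as configuration errors", {
  small <- pats[1:2, , drop = FALSE]
  g_small <- categorize_patterns(small, tpl)
  expect_error(build_sequence(1, patterns = small, groups = g_small,
                              score_targets = rep(0, length(g_small$working_ranges) + 2)),
               "score_targets")
})
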