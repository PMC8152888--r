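# Independent oracles, implemented separately from the package internals.

# Brute-force necklace enumeration: generate all arrangements, reduce each
# to its smallest rotation by string comparison, count distinct strings.
oracle_necklaces <- function(n = 12L, k = 4L) {
  sets <- utils::combn(n, k)
  keys <- apply(sets, 2L, function(z) {
    v <- rep(1L, n)
    v[z] <- 0L
    rots <- vapply(0:(n - 1L), function(r)
      paste(v[((seq_len(n) - 1L + r) %% n) + 1L], collapse = ""), "")
    min(rots)
  })
  sort(unique(keys))
}

# Burnside / orbit-counting formula for binary necklaces with k zeros:
# (1/n) * sum over d | gcd(n, k) of phi(d) * C(n/d, k/d)
oracle_necklace_count <- function(n = 12L, k = 4L) {
  phi <- function(m) sum(vapply(seq_len(m), function(j)
    Reduce(function(a, b) if (b == 0) a else Recall(b, a %% b),
           c(j, m)) == 1L, logical(1)))
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  divisors <- which(gcd(n, k) %% seq_len(gcd(n, k)) == 0L)
  sum(vapply(divisors, function(d)
    phi(d) * choose(n / d, k / d), numeric(1))) / n
}

# Independent cyclic syncopation scorer: rotates the PATTERN instead of the
# template (score of pattern p at template phase k equals the score of the
# pattern rotated by k against the fixed template).
oracle_score <- function(onsets, weights, phase,
                         variant = c("lhl", "positive", "signed")) {
  variant <- match.arg(variant)
  n <- length(onsets)
  rotated <- onsets[((seq_len(n) - 1L + phase) %% n) + 1L]
  rests <- which(rotated == 0L)
  if (length(rests) == 0L) return(0L)
  pvs <- vapply(rests, function(r1) {
    q <- r1
    repeat {
      q <- if (q == 1L) n else q - 1L
      if (rotated[q] == 1L) break
    }
    weights[r1] - weights[q]
  }, numeric(1))
  switch(variant,
         lhl = if (any(pvs >= 0)) sum(pvs[pvs >= 0]) else -1,
         positive = sum(pvs[pvs > 0]),
         signed = sum(pvs))
}

oracle_weights_2_4_12 <- c(0, -3, -2, -3, -1, -3, -2, -3, -1, -3, -2, -3)

# pattern with silences at 0-based positions {0, 2, 4, 8}
pattern_02448 <- function() {
  p <- rep(1L, 12L)
  p[c(1L, 3L, 5L, 9L)] <- 0L
  p
}

default_targets <- function() build_target_frequencies()

# small helper: meter_mean_z difference (regular minus degraded) per
# aligned segment from a freqtag summary table
summary_direction_diff <- function(summary) {
  reg <- summary[summary$direction == "regular_to_degraded", ]
  deg <- summary[summary$direction == "degraded_to_regular", ]
  m <- merge(reg[, c("segment_aligned", "meter_mean_z")],
             deg[, c("segment_aligned", "meter_mean_z")],
             by = "segment_aligned", suffixes = c("_reg", "_deg"))
  data.frame(segment_aligned = m$segment_aligned,
             difference = m$meter_mean_z_reg - m$meter_mean_z_deg)
}
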