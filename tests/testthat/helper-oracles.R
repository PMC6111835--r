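# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive quantities by the most literal possible
# route (explicit loops, per-sample state tracking) so they stay
# independent of the package's vectorized implementations.

# Brute-force whole-body COM: enumerate the segments one by one and
# accumulate fraction * midpoint with an explicit loop.
com_oracle <- function(frame, table = default_segment_table()) {
  total <- c(0, 0, 0)
  wsum <- 0
  for (i in seq_len(nrow(table))) {
    p <- unlist(frame[frame$joint == table$proximal[i], c("x_m", "y_m", "z_m")])
    d <- unlist(frame[frame$joint == table$distal[i], c("x_m", "y_m", "z_m")])
    mid <- (p + d) / 2
    total <- total + table$fraction[i] * mid
    wsum <- wsum + table$fraction[i]
  }
  unname(total / wsum)
}

# Brute-force hysteresis counter: walk the trace sample by sample with an
# explicit state variable. Thresholds are on the deviation scale,
# flexed-side inclusive (>= flex), extended-side inclusive (<= ext).
flexion_oracle <- function(x, flex, ext) {
  state <- "extended"
  count <- 0L
  for (v in x) {
    if (state == "extended" && v >= flex) state <- "flexed"
    else if (state == "flexed" && v <= ext) {
      state <- "extended"
      count <- count + 1L
    }
  }
  count
}

# Random piecewise trace generator for property tests: values drawn to
# straddle both thresholds with intermediate dwell samples.
random_trace <- function(n, lo = 0, hi = 120) {
  round(stats::runif(n, lo, hi), 1)
}

# A bent stick-figure pose for COM fixtures: perturb the base skeleton
# joint-by-joint with a deterministic offset so no symmetry hides errors.
bent_pose <- function(height = 1.72) {
  fr <- make_base_skeleton(height)
  k <- seq_len(nrow(fr))
  fr$x_m <- fr$x_m + 0.013 * sin(k)
  fr$y_m <- fr$y_m + 0.011 * cos(2 * k)
  fr$z_m <- fr$z_m + 0.017 * sin(3 * k)
  fr
}

# Single-frame stream wrapper around a frame data frame.
frame_stream <- function(frame, sample_rate = 30) {
  skeleton_stream(frame, sample_rate = sample_rate)
}
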