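# Independent oracles for the shake/episode machinery. Deliberately different
# constructions from the package internals: the hysteresis oracle is a
# vectorised running-extremum segment scan (the package uses a pointwise C++
# state machine); the episode oracle enumerates maximal linked runs via rle()
# (the package splits on gap indices).

oracle_zigzag <- function(x, thr) {
  n <- length(x)
  idx <- integer(0); amp <- numeric(0); pol <- integer(0)
  if (n >= 2) {
    ref <- x[1]; start <- 1L; dir <- 0L
    repeat {
      seg <- x[start:n]
      if (dir == 0L) {
        j <- which(abs(seg - ref) >= thr)[1]
        if (is.na(j)) break
        dir <- as.integer(sign(seg[j] - ref))
        start <- start + j - 1L
      } else if (dir == 1L) {
        M <- cummax(seg)
        k <- which(M - seg >= thr)[1]
        if (is.na(k)) break
        ext <- which.max(seg[1:k])
        idx <- c(idx, start + ext - 1L)
        amp <- c(amp, M[k] - ref)
        pol <- c(pol, 1L)
        ref <- M[k]; start <- start + k - 1L; dir <- -1L
      } else {
        m <- cummin(seg)
        k <- which(seg - m >= thr)[1]
        if (is.na(k)) break
        ext <- which.min(seg[1:k])
        idx <- c(idx, start + ext - 1L)
        amp <- c(amp, ref - m[k])
        pol <- c(pol, -1L)
        ref <- m[k]; start <- start + k - 1L; dir <- 1L
      }
    }
  }
  data.frame(idx = idx, amplitude = amp, polarity = pol)
}

oracle_episodes <- function(t_ms, min_shakes, max_gap_ms) {
  out <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                    n_shakes = integer(0))
  n <- length(t_ms)
  if (n < 2) return(out)
  r <- rle(diff(t_ms) < max_gap_ms)
  pos <- 1L
  for (q in seq_along(r$lengths)) {
    if (r$values[q]) {
      i <- pos; j <- pos + r$lengths[q]
      if (j - i + 1L >= min_shakes)
        out <- rbind(out, data.frame(start_ms = t_ms[i], end_ms = t_ms[j],
                                     n_shakes = j - i + 1L))
    }
    pos <- pos + r$lengths[q]
  }
  out
}

# Body-frame single-signal trajectory: the given trace on one leg's x axis,
# everything else flat. Convenient substrate for detector-level tests.
make_body_traj <- function(x, y = NULL, leg = "L1", fps = 1000,
                           body_length_px = 128,
                           legs = c("L1", "L2", "L3", "R1", "R2", "R3")) {
  n <- length(x)
  if (is.null(y)) y <- rep(0, n)
  frames <- tidyr::expand_grid(leg = union(legs, leg),
                               frame = seq_len(n) - 1L)
  frames$x <- 0
  frames$y <- 0
  frames$x[frames$leg == leg] <- x
  frames$y[frames$leg == leg] <- y
  fly_traj(frames, fly_id = "unit", body_length_px = body_length_px,
           calibration = calibration(fps = fps),
           frame_of_reference = "body")
}

# Random-walk traces used for oracle-equivalence sweeps.
random_trace <- function(n, sigma = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cumsum(stats::rnorm(n, 0, sigma))
}

# Spaced episode start times with a >100 ms guard between bursts, mirroring
# the generator's layout.
episode_starts_for_test <- function(k, dur_ms, episode_ms = 150, margin = 60,
                                    guard = 120) {
  slot <- (dur_ms - 2 * margin) / k
  margin + (seq_len(k) - 1) * slot +
    stats::runif(k, 0, max(0, slot - episode_ms - guard))
}

expect_zigzag_matches_oracle <- function(x, thr, fps = 1000) {
  orc <- oracle_zigzag(x, thr)
  tr <- make_body_traj(x, fps = fps, legs = "L1")
  got <- detect_shakes(tr, detection_params(min_amplitude_norm_px = thr,
                                            highpass_hz = 0))
  got <- got[got$leg == "L1", ]
  expect_equal(got$t_ms, (orc$idx - 1) / fps * 1000)
  expect_equal(got$amplitude_norm_px, orc$amplitude)
  expect_equal(got$polarity, c("min", "max")[(orc$polarity > 0) + 1L])
}
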