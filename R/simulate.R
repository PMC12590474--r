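#' Gait simulation parameters
#'
#' The stated world of the synthetic walking fly: a straight-walking hexapod
#' with tripod coordination ({L1, R2, L3} in antiphase to {R1, L2, R3}),
#' sinusoidal anterior-posterior claw excursion at the control stride rate
#' (~10 Hz), recorded at 1000 frames/s, with additive tracking noise whose
#' per-frame marginal SD is 1.29 px so that ~98% of per-axis errors fall
#' within 3 px (3 / 2.326).
#'
#' Tracking error is modelled as a slow AR(1) drift (localisation offsets
#' persisting across near-identical adjacent video frames; correlation time
#' `noise_drift_tau_ms`) plus fast iid sub-pixel jitter
#' (`noise_jitter_sigma_px`); the two variances sum to
#' `tracking_noise_sigma_px^2`. This reproduces the reference workflow's
#' property that tracking error rarely produces 3 px reversals (the rationale
#' for the 3 px amplitude floor), which an iid model at the same marginal SD
#' would violate.
#'
#' @param stride_rate_hz Stride frequency (default 10).
#' @param stride_amplitude_px Half-amplitude of the AP claw excursion in px
#'   (default 30, ~0.5 body length peak-to-peak).
#' @param body_speed_px_s Forward speed; default `2 * stride_amplitude_px *
#'   stride_rate_hz` (no-slip tripod estimate, ~600 px/s = 11.7 mm/s).
#' @param fps Frame rate (default 1000).
#' @param body_length_px Body length (default 128 px = 2.5 mm at 51.2 px/mm).
#' @param duration_s Recording length in seconds (default 1).
#' @param tracking_noise_sigma_px Total per-axis tracking-error SD (default
#'   1.29; 0 disables noise).
#' @param noise_drift_tau_ms Drift correlation time (default 250 ms).
#' @param noise_jitter_sigma_px Fast jitter SD (default 0.4 px).
#' @param heading_deg Walking direction in the arena (default 0).
#' @param start_px Arena start position of the body centroid.
#' @param calibration A [calibration()] object.
#' @return A list of class `gait_params`.
#' @export
gait_params <- function(stride_rate_hz = 10, stride_amplitude_px = 30,
                        body_speed_px_s = NULL, fps = 1000,
                        body_length_px = 128, duration_s = 1,
                        tracking_noise_sigma_px = 1.29,
                        noise_drift_tau_ms = 250,
                        noise_jitter_sigma_px = 0.4,
                        heading_deg = 0, start_px = c(100, 256),
                        calibration = flytremor::calibration(fps = fps)) {
  stopifnot(stride_rate_hz > 0, stride_amplitude_px > 0, fps > 0,
            body_length_px > 0, duration_s > 0,
            tracking_noise_sigma_px >= 0, noise_drift_tau_ms > 0,
            noise_jitter_sigma_px >= 0)
  if (tracking_noise_sigma_px > 0 &&
      noise_jitter_sigma_px > tracking_noise_sigma_px)
    abort("`noise_jitter_sigma_px` cannot exceed `tracking_noise_sigma_px`.")
  structure(list(
    stride_rate_hz = stride_rate_hz,
    stride_amplitude_px = stride_amplitude_px,
    body_speed_px_s = body_speed_px_s %||%
      (2 * stride_amplitude_px * stride_rate_hz),
    fps = fps, body_length_px = body_length_px, duration_s = duration_s,
    tracking_noise_sigma_px = tracking_noise_sigma_px,
    noise_drift_tau_ms = noise_drift_tau_ms,
    noise_jitter_sigma_px = noise_jitter_sigma_px,
    heading_deg = heading_deg, start_px = start_px,
    calibration = as_calibration(calibration)
  ), class = "gait_params")
}

# body-frame leg base positions (px): front/mid/hind x AP offset, y ML offset
leg_bases <- function(body_length_px) {
  s <- body_length_px / 128
  tibble(
    leg = LEG_IDS,
    base_x = s * c(40, 0, -40, 40, 0, -40),
    base_y = s * c(-30, -35, -30, 30, 35, 30),
    phase = c(0, pi, 0, pi, 0, pi)  # tripod: L1,L3,R2 vs L2,R1,R3
  )
}

# AR(1) drift + iid jitter, marginal SD sigma_total; vectorised recursion
tracking_noise <- function(n, sigma_total, tau_ms, sigma_jitter, dt_ms) {
  if (sigma_total <= 0) return(numeric(n))
  sigma_jitter <- min(sigma_jitter, sigma_total)
  sigma_drift <- sqrt(sigma_total^2 - sigma_jitter^2)
  drift <- 0
  if (sigma_drift > 0) {
    phi <- exp(-dt_ms / tau_ms)
    innov <- c(stats::rnorm(1, 0, sigma_drift),
               stats::rnorm(n - 1, 0, sigma_drift * sqrt(1 - phi^2)))
    drift <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  }
  drift + stats::rnorm(n, 0, sigma_jitter)
}

#' Simulate a straight-walking fly
#'
#' Generates arena-frame 6-leg claw trajectories of a tripod-gait walker with
#' seeded tracking noise, plus exact body-pose columns and a ground-truth
#' record. Deterministic for a fixed seed. The noiseless body-frame AP traces
#' are exact sinusoids (see [gait_params()]).
#'
#' @param params A [gait_params()] object.
#' @param fly_id,genotype Metadata for the emitted [fly_traj()].
#' @param climbing_score_cm Optional climbing score to carry along.
#' @param seed RNG seed for the tracking noise (`NULL` uses the global
#'   stream).
#' @return A [fly_traj()] (arena frame) whose `sim_truth` metadata holds the
#'   generator parameters, per-leg base positions/phases and an (initially
#'   empty) injected-episode table.
#' @export
simulate_walking_fly <- function(params = gait_params(), fly_id = "sim_fly",
                                 genotype = "sim", climbing_score_cm = NA_real_,
                                 seed = NULL) {
  stopifnot(inherits(params, "gait_params"))
  with_seed(seed, {
    n <- as.integer(round(params$duration_s * params$fps))
    fr <- seq_len(n) - 1L
    t_s <- fr / params$fps
    th <- params$heading_deg * pi / 180
    bx <- params$start_px[1] + params$body_speed_px_s * t_s * cos(th)
    by <- params$start_px[2] + params$body_speed_px_s * t_s * sin(th)
    bases <- leg_bases(params$body_length_px)

    dt_ms <- 1000 / params$fps
    frames <- purrr::pmap_dfr(bases, function(leg, base_x, base_y, phase) {
      ap <- base_x + params$stride_amplitude_px *
        sin(2 * pi * params$stride_rate_hz * t_s + phase)
      ml <- rep(base_y, n)
      x <- bx + cos(th) * ap - sin(th) * ml +
        tracking_noise(n, params$tracking_noise_sigma_px,
                       params$noise_drift_tau_ms,
                       params$noise_jitter_sigma_px, dt_ms)
      y <- by + sin(th) * ap + cos(th) * ml +
        tracking_noise(n, params$tracking_noise_sigma_px,
                       params$noise_drift_tau_ms,
                       params$noise_jitter_sigma_px, dt_ms)
      tibble(frame = fr, leg = leg, x = x, y = y,
             body_x = bx, body_y = by,
             heading_deg = rep(params$heading_deg, n))
    })

    tr <- fly_traj(frames, fly_id = fly_id, genotype = genotype,
                   body_length_px = params$body_length_px,
                   climbing_score_cm = climbing_score_cm,
                   calibration = params$calibration,
                   frame_of_reference = "arena")
    update_traj(tr, sim_truth = list(
      gait = unclass(params)[setdiff(names(params), "calibration")],
      bases = bases,
      episodes = empty_tremor_spec()
    ))
  })
}

#' Tremor episode specification
#'
#' Describes band-limited oscillation bursts to superimpose on simulated
#' trajectories: one row per (episode, leg). Episodes on one leg must not
#' overlap, and each must span at least one full oscillation cycle (two
#' reversals); boundary cases with exactly two reversals are thereby
#' constructible for the relaxed two-shake screen mode.
#'
#' @param start_ms,end_ms Episode interval (ms from recording start).
#' @param freq_hz Oscillation frequency (default 40). Real tremor frequency
#'   content is uncharacterised; the 30-60 Hz band used by the generators is a
#'   labelled placeholder chosen to sit above the gait band.
#' @param half_amplitude_norm_px Oscillation half-amplitude in normalised px
#'   (default 6 = twice the 3 px detection floor).
#' @param leg Affected leg id(s).
#' @return A tibble of class `tremor_spec`.
#' @export
tremor_spec <- function(start_ms, end_ms, freq_hz = 40,
                        half_amplitude_norm_px = 6, leg = "L1") {
  spec <- tibble(leg = leg, start_ms = start_ms, end_ms = end_ms,
                 freq_hz = freq_hz,
                 half_amplitude_norm_px = half_amplitude_norm_px)
  validate_tremor_spec(spec)
}

validate_tremor_spec <- function(spec) {
  if (any(spec$end_ms <= spec$start_ms)) abort("Episode end must follow start.")
  if (any(spec$half_amplitude_norm_px <= 0)) abort("Amplitudes must be positive.")
  if (any(spec$freq_hz <= 0)) abort("Frequencies must be positive.")
  dur_s <- (spec$end_ms - spec$start_ms) / 1000
  if (any(dur_s * spec$freq_hz < 1))
    abort("Episodes must span at least one full oscillation cycle.")
  for (lg in unique(spec$leg)) {
    sub <- spec[spec$leg == lg, ]
    sub <- sub[order(sub$start_ms), ]
    if (nrow(sub) > 1 && any(sub$start_ms[-1] < sub$end_ms[-nrow(sub)]))
      abort(sprintf("Overlapping episode specs on leg %s.", lg))
  }
  structure(spec, class = c("tremor_spec", class(tibble())))
}

empty_tremor_spec <- function() {
  structure(tibble(leg = character(), start_ms = numeric(),
                   end_ms = numeric(), freq_hz = numeric(),
                   half_amplitude_norm_px = numeric()),
            class = c("tremor_spec", class(tibble())))
}

#' Inject tremor oscillations into a trajectory
#'
#' Adds sinusoidal bursts along the body's anterior-posterior axis to the
#' specified legs and intervals, and appends them to the trajectory's
#' ground-truth record. Tremor is modelled purely as a trajectory signature
#' (additive band-limited oscillation), matching how it is detected.
#'
#' @param traj A [fly_traj()] (typically simulator output; arena or body
#'   frame).
#' @param spec A [tremor_spec()] table.
#' @return The modified `fly_traj`.
#' @export
inject_tremor <- function(traj, spec) {
  spec <- validate_tremor_spec(as_tibble(spec))
  m <- traj_meta(traj)
  fps <- m$calibration$fps
  df <- as_tibble(traj)
  span_ms <- (max(df$frame) + 1) / fps * 1000
  if (any(spec$start_ms < 0) || any(spec$end_ms > span_ms))
    abort("Episodes must lie within the recording span.")
  arena <- m$frame_of_reference == "arena"
  if (arena && !"heading_deg" %in% names(df))
    abort("Arena-frame injection needs the `heading_deg` column.")

  for (i in seq_len(nrow(spec))) {
    sel <- df$leg == spec$leg[i]
    t_ms <- df$frame[sel] / fps * 1000
    on <- t_ms >= spec$start_ms[i] & t_ms < spec$end_ms[i]
    osc <- spec$half_amplitude_norm_px[i] *
      sin(2 * pi * spec$freq_hz[i] * (t_ms[on] - spec$start_ms[i]) / 1000)
    idx <- which(sel)[on]
    if (arena) {
      th <- df$heading_deg[idx] * pi / 180
      df$x[idx] <- df$x[idx] + osc * cos(th)
      df$y[idx] <- df$y[idx] + osc * sin(th)
    } else {
      df$x[idx] <- df$x[idx] + osc
    }
  }
  truth <- m$sim_truth %||% list(episodes = empty_tremor_spec())
  prev <- truth$episodes
  if (!is.null(prev) && nrow(prev)) {
    comb <- dplyr::bind_rows(as_tibble(prev), as_tibble(spec))
    validate_tremor_spec(comb)  # overlap check across old + new
    truth$episodes <- validate_tremor_spec(comb)
  } else {
    truth$episodes <- spec
  }
  update_traj(traj, frames = df, sim_truth = truth)
}

#' Simulate a screen cohort with known penetrance
#'
#' Generates `n_lines` genotypes with `flies_per_line` flies each; every fly
#' is independently tremor-affected with probability `penetrance`, and
#' affected flies receive `episodes_per_fly` injected supra-threshold episodes
#' at random times, legs and in-band frequencies. Deterministic given `seed`.
#'
#' @param n_lines,flies_per_line Cohort dimensions.
#' @param penetrance Per-fly probability of being tremor-affected, in
#'   \[0, 1\].
#' @param params A [gait_params()] object used for every fly.
#' @param episodes_per_fly Episodes injected into each affected fly
#'   (default 2).
#' @param episode_ms Episode duration (default 150 ms).
#' @param freq_range_hz Tremor frequency band (default 30-60 Hz).
#' @param half_amplitude_norm_px Injected half-amplitude (default 6).
#' @param seed RNG seed.
#' @return A nested tibble: `line`, `fly_id`, `affected` (ground truth) and a
#'   `traj` list-column of [fly_traj()] objects.
#' @export
simulate_cohort <- function(n_lines, flies_per_line, penetrance,
                            params = gait_params(), episodes_per_fly = 2,
                            episode_ms = 150, freq_range_hz = c(30, 60),
                            half_amplitude_norm_px = 6, seed = NULL) {
  if (penetrance < 0 || penetrance > 1) abort("`penetrance` must be in [0, 1].")
  dur_ms <- params$duration_s * 1000
  margin <- 60   # keep clear of filter edge transients
  guard <- 120   # minimum separation between injected episodes
  if (dur_ms < 2 * margin + episodes_per_fly * (episode_ms + guard))
    abort("Recording too short for the requested episode layout.")
  with_seed(seed, {
    grid <- tidyr::expand_grid(line = seq_len(n_lines),
                               fly = seq_len(flies_per_line))
    grid$affected <- stats::runif(nrow(grid)) < penetrance
    grid$fly_id <- sprintf("line%03d_fly%d", grid$line, grid$fly)
    grid$traj <- purrr::pmap(grid, function(line, fly, affected, fly_id) {
      tr <- simulate_walking_fly(params, fly_id = fly_id,
                                 genotype = sprintf("line%03d", line))
      if (affected) {
        starts <- episode_starts(episodes_per_fly, dur_ms, episode_ms, margin,
                                 guard)
        spec <- tremor_spec(
          start_ms = starts, end_ms = starts + episode_ms,
          freq_hz = stats::runif(episodes_per_fly, freq_range_hz[1],
                                 freq_range_hz[2]),
          half_amplitude_norm_px = half_amplitude_norm_px,
          leg = sample(LEG_IDS, episodes_per_fly, replace = TRUE)
        )
        tr <- inject_tremor(tr, spec)
      }
      tr
    })
    grid[, c("line", "fly_id", "affected", "traj")]
  })
}

# Episode start times: one episode per equal slot, with >= `guard` ms between
# consecutive episodes (kept above the 100 ms grouping gap so distinct
# injections are never merged into one detected run), disjoint regardless of
# leg.
episode_starts <- function(k, dur_ms, episode_ms, margin, guard = 120) {
  slot <- (dur_ms - 2 * margin) / k
  margin + (seq_len(k) - 1) * slot +
    stats::runif(k, 0, pmax(0, slot - episode_ms - guard))
}

#' Detect tremor across a simulated cohort
#'
#' Maps [summarize_fly()] over a [simulate_cohort()] table and joins the
#' ground-truth affected flag, giving the end-to-end simulate-then-detect
#' readout used for penetrance-recovery checks.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param params A [detection_params()] object.
#' @return A tibble: one row per fly with the [summarize_fly()] columns plus
#'   `line` and `affected`.
#' @export
detect_cohort <- function(cohort, params = detection_params()) {
  res <- purrr::map_dfr(cohort$traj, summarize_fly, params = params)
  dplyr::bind_cols(cohort[, c("line", "affected")], res)
}

#' Simulate colocalisation spot sets with known positive fraction
#'
#' Places `round(fraction_positive * n_spots)` spots within `jitter_um` of a
#' random target point and the remainder at least `min_negative_um` from every
#' target, so the true positive fraction at the 0.1 um rule is exact by
#' construction.
#'
#' @param n_spots Number of query spots.
#' @param fraction_positive Target positive fraction in \[0, 1\].
#' @param n_targets Number of target points.
#' @param jitter_um Positive-spot displacement bound (default 0.02 um,
#'   well inside the 0.1 um rule).
#' @param box_um Field dimensions (x, y, z) in um.
#' @param min_negative_um Minimum distance of negative spots from any target.
#' @param seed RNG seed.
#' @return A list: `spots`, `targets` (tibbles with `id`, `x_um`, `y_um`,
#'   `z_um`) and `truth` (per-spot `positive` flag).
#' @export
simulate_coloc_spots <- function(n_spots = 100, fraction_positive = 0.8,
                                 n_targets = 150, jitter_um = 0.02,
                                 box_um = c(50, 50, 20),
                                 min_negative_um = 0.5, seed = NULL) {
  if (fraction_positive < 0 || fraction_positive > 1)
    abort("`fraction_positive` must be in [0, 1].")
  if (jitter_um >= 0.1)
    warn("`jitter_um` >= 0.1 um: positives may fall outside the distance rule.")
  with_seed(seed, {
    rand_points <- function(k) matrix(stats::runif(3 * k) *
                                        rep(box_um, each = k), ncol = 3)
    tm <- rand_points(n_targets)
    n_pos <- round(fraction_positive * n_spots)
    pos <- NULL
    if (n_pos > 0) {
      anchor <- tm[sample.int(n_targets, n_pos, replace = TRUE), , drop = FALSE]
      dir <- matrix(stats::rnorm(3 * n_pos), ncol = 3)
      dir <- dir / sqrt(rowSums(dir^2))
      pos <- anchor + dir * stats::runif(n_pos, 0, jitter_um)
    }
    neg <- matrix(numeric(0), ncol = 3)
    while (nrow(neg) < n_spots - n_pos) {
      cand <- rand_points(n_spots)
      d2 <- outer(rowSums(cand^2), rowSums(tm^2), "+") - 2 * cand %*% t(tm)
      ok <- sqrt(pmax(apply(d2, 1, min), 0)) >= min_negative_um
      neg <- rbind(neg, cand[ok, , drop = FALSE])
    }
    neg <- neg[seq_len(n_spots - n_pos), , drop = FALSE]
    sm <- rbind(pos, neg)
    list(
      spots = tibble(id = seq_len(n_spots), x_um = sm[, 1], y_um = sm[, 2],
                     z_um = sm[, 3]),
      targets = tibble(id = seq_len(n_targets), x_um = tm[, 1],
                       y_um = tm[, 2], z_um = tm[, 3]),
      truth = tibble(id = seq_len(n_spots),
                     positive = seq_len(n_spots) <= n_pos)
    )
  })
}
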