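#' Tremor detection parameters
#'
#' Thresholds of the shake/tremor detector. A shake is an accepted
#' turning point of a body-centred, body-size-normalised claw trace whose
#' excursion from the previously accepted extremum is at least
#' `min_amplitude_norm_px` (default 3 px, the tracking-error floor). A tremor
#' episode is a maximal run of at least `min_shakes` shakes (default 3;
#' relaxed primary-screen mode uses 2) in which every inter-shake gap is
#' strictly under `max_gap_ms` (default 100 ms, one stride period).
#'
#' `highpass_hz` (default 25 Hz) is the cutoff of the zero-phase Butterworth
#' high-pass applied to body-frame traces before detection in [summarize_fly()]
#' and the pipeline: it removes stride-scale movement (~10 Hz), which would
#' otherwise itself register as supra-threshold reversals every half-stride,
#' while passing the tremor band (30-60 Hz). Set 0 to disable. Optional
#' moving-average denoising (`smooth_window_ms`) is off by default.
#'
#' @param min_amplitude_norm_px Amplitude floor in normalised pixels.
#' @param min_shakes Minimum shakes per episode (>= 2).
#' @param max_gap_ms Maximum inter-shake gap (strict upper bound), ms.
#' @param dedup_window_ms Events on the two body axes closer than this merge
#'   into one shake (axis `"merged"`).
#' @param highpass_hz Gait-removal high-pass cutoff (0 = off).
#' @param smooth_window_ms Optional centred moving-average smoothing (0 = off).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(min_amplitude_norm_px = 3, min_shakes = 3,
                             max_gap_ms = 100, dedup_window_ms = 3,
                             highpass_hz = 25, smooth_window_ms = 0) {
  stopifnot(min_amplitude_norm_px > 0, max_gap_ms > 0, dedup_window_ms > 0,
            highpass_hz >= 0, smooth_window_ms >= 0)
  if (min_shakes < 2) abort("`min_shakes` must be >= 2.")
  structure(list(min_amplitude_norm_px = min_amplitude_norm_px,
                 min_shakes = as.integer(min_shakes),
                 max_gap_ms = max_gap_ms,
                 dedup_window_ms = dedup_window_ms,
                 highpass_hz = highpass_hz,
                 smooth_window_ms = smooth_window_ms),
            class = "detection_params")
}

as_detection_params <- function(x) {
  if (inherits(x, "detection_params")) return(x)
  if (is.list(x)) return(do.call(detection_params, x))
  abort("Cannot interpret `x` as detection_params.")
}

#' Remove stride-scale movement from a body-frame trajectory
#'
#' Applies two cascaded zero-phase (forward-backward) 2nd-order Butterworth
#' high-pass sections to the x and y traces of every leg. With the default
#' 25 Hz cutoff, ~10 Hz stride oscillation is suppressed to far below the 3 px
#' shake threshold (~60 px peak-to-peak attenuated by a factor of ~1600) while
#' the 30-60 Hz tremor band keeps at least ~45% of its amplitude, leaving
#' twice-threshold injections clearly detectable.
#'
#' @param traj A body-frame [fly_traj()].
#' @param cutoff_hz High-pass cutoff in Hz; 0 returns the input unchanged.
#' @return A filtered `fly_traj`.
#' @export
highpass_trajectory <- function(traj, cutoff_hz = 25) {
  if (cutoff_hz == 0) return(traj)
  m <- traj_meta(traj)
  fs <- m$calibration$fps
  if (cutoff_hz >= fs / 2) abort("`cutoff_hz` must be below the Nyquist rate.")
  df <- as_tibble(traj)
  pad <- as.integer(min(3 * fs / cutoff_hz, 500))
  hp2 <- function(v) .highpass_cpp(.highpass_cpp(v, cutoff_hz, fs, pad),
                                   cutoff_hz, fs, pad)
  df <- df |>
    dplyr::group_by(.data$leg) |>
    dplyr::mutate(x = hp2(.data$x), y = hp2(.data$y)) |>
    dplyr::ungroup()
  prov <- m$provenance
  prov$highpass_hz <- cutoff_hz
  update_traj(traj, frames = df, provenance = prov)
}

# Hysteresis scan of one numeric trace; returns idx/amplitude/polarity.
zigzag <- function(x, thr) {
  r <- .zigzag_cpp(as.numeric(x), thr)
  tibble(idx = as.integer(r$idx), amplitude = as.numeric(r$amplitude),
         polarity = as.integer(r$polarity))
}

#' Detect shake events
#'
#' Scans each leg's body-frame x (anterior-posterior) and y (medio-lateral)
#' trace with an amplitude-hysteresis turning-point detector: an extremum is
#' accepted once the trace has reversed by at least
#' `params$min_amplitude_norm_px` from it, and each accepted extremum lies at
#' least that threshold from the previously accepted one, so accepted extrema
#' alternate in polarity per axis. Events from the two axes are then merged:
#' events on different axes closer than `params$dedup_window_ms` collapse into
#' a single shake with axis `"merged"` (a single physical leg jerk registers
#' on both axes).
#'
#' The input should already be body-centred, body-size normalised and (for
#' pipeline use) gait-filtered; `detect_shakes()` itself applies no filtering.
#'
#' @param traj A body-frame [fly_traj()] (arena-frame input is an error).
#' @param params A [detection_params()] object.
#' @return A tibble of shakes: `leg`, `t_ms`, `axis` (`"ap"`, `"ml"` or
#'   `"merged"`), `amplitude_norm_px`, `polarity` (`"max"`/`"min"`), sorted by
#'   leg and time.
#' @export
detect_shakes <- function(traj, params = detection_params()) {
  params <- as_detection_params(params)
  m <- traj_meta(traj)
  if (m$frame_of_reference != "body")
    abort("Shake detection requires a body-frame trajectory; see to_body_frame().")
  fps <- m$calibration$fps
  thr <- params$min_amplitude_norm_px
  df <- as_tibble(traj)

  one_leg <- function(sub, lg) {
    if (nrow(sub) < 3) {
      warn(sprintf("Leg %s: trace shorter than 3 samples; no shakes.", lg))
      return(empty_shakes())
    }
    x <- sub$x
    y <- sub$y
    if (params$smooth_window_ms > 0) {
      w <- max(1L, as.integer(round(params$smooth_window_ms * fs_ms(fps))))
      x <- moving_average(x, w)
      y <- moving_average(y, w)
    }
    t0 <- sub$frame / fps * 1000
    ev_tbl <- function(z, ax) tibble(
      t_ms = t0[z$idx], axis = rep(ax, nrow(z)),
      amplitude_norm_px = z$amplitude,
      polarity = c("min", "max")[(z$polarity > 0) + 1L])
    ev <- dplyr::bind_rows(ev_tbl(zigzag(x, thr), "ap"),
                           ev_tbl(zigzag(y, thr), "ml"))
    ev <- ev[order(ev$t_ms, ev$axis), , drop = FALSE]
    merge_axes(ev, params$dedup_window_ms)
  }

  out <- purrr::imap(split(df, df$leg), function(sub, lg) {
    ev <- one_leg(sub, lg)
    dplyr::bind_cols(tibble(leg = rep(lg, nrow(ev))), ev)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0)
    out <- dplyr::bind_cols(tibble(leg = character()), empty_shakes())
  dplyr::arrange(out, .data$leg, .data$t_ms)
}

fs_ms <- function(fps) fps / 1000

empty_shakes <- function() {
  tibble(t_ms = numeric(), axis = character(),
         amplitude_norm_px = numeric(), polarity = character())
}

# Greedy left-to-right collapse of cross-axis duplicates: an event within
# `window_ms` of the previous kept event, on the other axis, merges into it.
merge_axes <- function(ev, window_ms) {
  n <- nrow(ev)
  if (n <= 1) return(ev)
  keep <- rep(TRUE, n)
  last <- 1L
  for (i in 2:n) {
    if (keep[i] && ev$axis[i] != ev$axis[last] &&
        ev$t_ms[i] - ev$t_ms[last] < window_ms) {
      keep[i] <- FALSE
      ev$axis[last] <- "merged"
      ev$amplitude_norm_px[last] <-
        max(ev$amplitude_norm_px[last], ev$amplitude_norm_px[i])
    } else if (keep[i]) {
      last <- i
    }
  }
  ev[keep, , drop = FALSE]
}

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  k <- rep(1 / w, w)
  y <- stats::filter(x, k, sides = 2)
  y <- as.numeric(y)
  y[is.na(y)] <- x[is.na(y)]
  y
}

#' Group shakes into tremor episodes
#'
#' A tremor episode is a maximal run of consecutive shakes on one leg in which
#' every inter-shake interval is strictly under `params$max_gap_ms`, with at
#' least `params$min_shakes` shakes. Runs are maximal by construction (greedy
#' splitting at gaps >= the bound), so episodes on a leg are disjoint.
#'
#' @param shakes A shake tibble from [detect_shakes()] (columns `leg`, `t_ms`),
#'   sorted by time within leg.
#' @param params A [detection_params()] object.
#' @return A tibble of episodes: `leg`, `start_ms`, `end_ms`, `n_shakes`,
#'   `max_gap_ms`.
#' @export
group_tremor_episodes <- function(shakes, params = detection_params()) {
  params <- as_detection_params(params)
  need <- c("leg", "t_ms")
  if (!all(need %in% names(shakes)))
    abort("`shakes` must have columns `leg` and `t_ms`.")
  if (nrow(shakes) == 0) return(empty_episodes())

  one_leg <- function(t_ms) {
    if (is.unsorted(t_ms)) abort("Shake times must be sorted within leg.")
    run <- cumsum(c(0, diff(t_ms) >= params$max_gap_ms))
    parts <- split(t_ms, run)
    parts <- parts[vapply(parts, length, 1L) >= params$min_shakes]
    if (!length(parts)) return(empty_episodes()[, -1])
    tibble(
      start_ms = unname(vapply(parts, min, 1)),
      end_ms = unname(vapply(parts, max, 1)),
      n_shakes = unname(vapply(parts, length, 1L)),
      max_gap_ms = unname(vapply(parts, function(p)
        if (length(p) > 1) max(diff(p)) else 0, 1))
    )
  }
  out <- as_tibble(shakes) |>
    dplyr::group_by(.data$leg) |>
    dplyr::reframe(one_leg(.data$t_ms)) |>
    dplyr::ungroup()
  dplyr::arrange(out, .data$leg, .data$start_ms)
}

empty_episodes <- function() {
  tibble(leg = character(), start_ms = numeric(), end_ms = numeric(),
         n_shakes = integer(), max_gap_ms = numeric())
}

#' Per-fly tremor summary
#'
#' Runs the full single-fly pipeline -- body-frame transform (if needed),
#' body-size normalisation, gait high-pass, shake detection, episode grouping
#' -- and pools episodes over all six legs. The tremor rate divides the total
#' episode count by the analysed bout duration; a fly is tremor-positive when
#' at least one episode was detected.
#'
#' @param traj A [fly_traj()] (arena or body frame).
#' @param params A [detection_params()] object.
#' @param reference_body_length_px Body-size normalisation reference passed to
#'   [normalize_body_size()]; default uses the fly's own length.
#' @return A one-row tibble: `fly_id`, `genotype`, `duration_s`, per-leg
#'   episode counts (`episodes_L1` ... `episodes_R3`), `n_shakes_total`,
#'   `n_episodes_total`, `tremor_rate_per_s`, `tremor_positive`,
#'   `climbing_score_cm`.
#' @export
summarize_fly <- function(traj, params = detection_params(),
                          reference_body_length_px = NULL) {
  params <- as_detection_params(params)
  m <- traj_meta(traj)
  if (m$duration_s <= 0) abort("Zero-duration bout.")
  tr <- traj
  if (traj_meta(tr)$frame_of_reference == "arena") tr <- to_body_frame(tr)
  tr <- normalize_body_size(tr, reference_body_length_px)
  tr <- highpass_trajectory(tr, params$highpass_hz)
  shakes <- detect_shakes(tr, params)
  eps <- group_tremor_episodes(shakes, params)

  counts <- stats::setNames(rep(0L, length(LEG_IDS)),
                            paste0("episodes_", LEG_IDS))
  if (nrow(eps)) {
    tab <- table(eps$leg)
    counts[paste0("episodes_", names(tab))] <- as.integer(tab)
  }
  total <- sum(counts)
  dplyr::bind_cols(
    tibble(fly_id = m$fly_id, genotype = m$genotype,
           duration_s = m$duration_s),
    as_tibble(as.list(counts)),
    tibble(n_shakes_total = nrow(shakes),
           n_episodes_total = total,
           tremor_rate_per_s = total / m$duration_s,
           tremor_positive = total >= 1,
           climbing_score_cm = m$climbing_score_cm)
  )
}
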