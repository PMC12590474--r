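#' Detect stride boundaries
#'
#' Minimal stride statistics used to contextualise the tremor window and to
#' validate the gait simulator. Stride boundaries are the gait-scale turning
#' points of each leg's anterior-posterior (body-frame x) trace, found with
#' the same amplitude-hysteresis scan as shake detection but with a large
#' threshold: `hysteresis_frac` (default 0.25) of the leg's AP excursion
#' range. Boundaries of one polarity (posterior extreme, ~stance onset) define
#' strides; successive differences give stride periods.
#'
#' @param traj A body-frame [fly_traj()].
#' @param hysteresis_frac Hysteresis threshold as a fraction of each leg's AP
#'   range.
#' @return A tibble of stride boundaries: `leg`, `t_ms`, `polarity`. Legs with
#'   fewer than 2 boundaries contribute no rows (with a warning).
#' @seealso [summarize_strides()]
#' @export
detect_strides <- function(traj, hysteresis_frac = 0.25) {
  m <- traj_meta(traj)
  if (m$frame_of_reference != "body")
    abort("Stride detection needs a body-frame trajectory.")
  fps <- m$calibration$fps
  df <- as_tibble(traj)
  out <- purrr::imap(split(df, df$leg), function(sub, lg) {
    rng <- diff(range(sub$x))
    if (rng <= 0) {
      warn(sprintf("Leg %s: constant AP position; no strides.", lg))
      return(tibble(leg = character(), t_ms = numeric(),
                    polarity = character()))
    }
    z <- zigzag(sub$x, hysteresis_frac * rng)
    if (nrow(z) < 2) {
      warn(sprintf("Leg %s: fewer than 2 stride boundaries.", lg))
      return(tibble(leg = character(), t_ms = numeric(),
                    polarity = character()))
    }
    tibble(leg = lg, t_ms = sub$frame[z$idx] / fps * 1000,
           polarity = ifelse(z$polarity > 0, "max", "min"))
  })
  dplyr::bind_rows(out)
}

#' Summarise stride periods and rate
#'
#' Collapses [detect_strides()] output to per-leg stride statistics. Periods
#' are successive differences of same-polarity boundaries (full gait cycles);
#' the stride rate is `1000 / mean period`.
#'
#' @param strides Output of [detect_strides()].
#' @param polarity Which boundary polarity anchors a stride (default `"min"`,
#'   the posterior extreme).
#' @return A tibble: `leg`, `n_strides`, `mean_period_ms`, `stride_rate_hz`.
#' @export
summarize_strides <- function(strides, polarity = "min") {
  if (nrow(strides) == 0)
    return(tibble(leg = character(), n_strides = integer(),
                  mean_period_ms = numeric(), stride_rate_hz = numeric()))
  strides |>
    dplyr::filter(.data$polarity == !!polarity) |>
    dplyr::group_by(.data$leg) |>
    dplyr::summarise(
      n_strides = dplyr::n() - 1L,
      mean_period_ms = if (dplyr::n() > 1) mean(diff(.data$t_ms)) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(stride_rate_hz = 1000 / .data$mean_period_ms)
}
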