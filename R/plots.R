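#' Plot leg-claw traces
#'
#' Body-frame (or arena-frame) claw position against time, one panel per leg.
#' Useful for eyeballing stride oscillation and tremor bursts before running
#' detection.
#'
#' @param traj A [fly_traj()].
#' @param axis `"x"` (anterior-posterior in body frame), `"y"`
#'   (medio-lateral) or `"both"`.
#' @param legs Legs to show (default all present).
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj, axis = c("both", "x", "y"), legs = NULL) {
  axis <- match.arg(axis)
  m <- traj_meta(traj)
  df <- as_tibble(traj)
  if (!is.null(legs)) df <- df[df$leg %in% legs, ]
  df$t_ms <- df$frame / m$calibration$fps * 1000
  long <- tidyr::pivot_longer(df[, c("leg", "t_ms", "x", "y")],
                              c("x", "y"), names_to = "axis",
                              values_to = "position_px")
  if (axis != "both") long <- long[long$axis == axis, ]
  lab <- if (m$frame_of_reference == "body") "body-frame position (px)"
         else "arena position (px)"
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_ms, y = .data$position_px,
                                     colour = .data$axis)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~leg, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = lab,
                  title = sprintf("fly %s (%s)", m$fly_id, m$genotype)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_trajectory
#' @param object A `fly_traj`.
#' @param ... Passed to [plot_trajectory()].
#' @export
autoplot.fly_traj <- function(object, ...) plot_trajectory(object, ...)

#' Plot detected shakes and episodes on a trace
#'
#' Overlays shake events (points) and tremor-episode extents (shaded bands) on
#' the high-passed anterior-posterior trace of each leg -- the package's
#' equivalent of the annotated leg-trace figure used to illustrate the
#' detection parameters.
#'
#' @param traj The body-frame, gait-filtered [fly_traj()] that was passed to
#'   [detect_shakes()].
#' @param shakes Output of [detect_shakes()].
#' @param episodes Output of [group_tremor_episodes()] (optional).
#' @return A ggplot object.
#' @export
plot_shakes <- function(traj, shakes, episodes = NULL) {
  m <- traj_meta(traj)
  df <- as_tibble(traj)
  df$t_ms <- df$frame / m$calibration$fps * 1000
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$x)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::facet_wrap(~leg) +
    ggplot2::labs(x = "time (ms)", y = "filtered AP position (norm px)") +
    ggplot2::theme_minimal()
  if (!is.null(episodes) && nrow(episodes))
    p <- p + ggplot2::geom_rect(
      data = episodes,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "red",
      inherit.aes = FALSE)
  if (nrow(shakes))
    p <- p + ggplot2::geom_point(
      data = shakes, ggplot2::aes(x = .data$t_ms, y = 0),
      colour = "black", size = 0.8, inherit.aes = FALSE)
  p
}

#' Plot line-level screen results
#'
#' Penetrance per genotype with exact binomial intervals; hits highlighted,
#' control marked.
#'
#' @param object A `line_result` table from [summarize_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.line_result <- function(object, ...) {
  df <- as_tibble(object)
  df$genotype <- stats::reorder(df$genotype, df$penetrance)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype, y = .data$penetrance,
                                   colour = .data$hit)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "penetrance (tremor-positive fraction)") +
    ggplot2::theme_minimal()
}
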