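#' Recording calibration
#'
#' Bundles the acquisition constants of a high-speed gait recording: the frame
#' rate, the spatial scale, and the sensor size. Defaults match a 1000
#' frames/s camera imaging a 10 x 10 mm arena at 512 x 512 px (51.2 px/mm).
#'
#' @param fps Frames per second. Must be positive.
#' @param px_per_mm Pixels per millimetre. Must be positive.
#' @param frame_size_px Integer pair, sensor width and height in pixels.
#'
#' @return A list of class `fly_calibration`.
#' @examples
#' cal <- calibration()
#' cal$px_per_mm
#' @export
calibration <- function(fps = 1000, px_per_mm = 51.2,
                        frame_size_px = c(512L, 512L)) {
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0)
    abort("`fps` must be a single positive number.")
  if (!is.numeric(px_per_mm) || length(px_per_mm) != 1 || px_per_mm <= 0)
    abort("`px_per_mm` must be a single positive number.")
  if (!is.numeric(frame_size_px) || length(frame_size_px) != 2 ||
      any(frame_size_px <= 0))
    abort("`frame_size_px` must be two positive integers.")
  structure(
    list(fps = as.numeric(fps), px_per_mm = as.numeric(px_per_mm),
         frame_size_px = as.integer(frame_size_px)),
    class = "fly_calibration"
  )
}

#' @export
print.fly_calibration <- function(x, ...) {
  cat(sprintf("<calibration> %g fps, %g px/mm, %d x %d px\n",
              x$fps, x$px_per_mm, x$frame_size_px[1], x$frame_size_px[2]))
  invisible(x)
}

as_calibration <- function(x) {
  if (inherits(x, "fly_calibration")) return(x)
  if (is.list(x))
    return(calibration(fps = x$fps %||% 1000,
                       px_per_mm = x$px_per_mm %||% 51.2,
                       frame_size_px = x$frame_size_px %||% c(512L, 512L)))
  abort("Cannot interpret `x` as a calibration.")
}
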