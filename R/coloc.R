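#' Spot-to-target proximity classification
#'
#' For each spot (e.g. a nucleus marked by Histone-RFP), finds the nearest
#' point of a target set (e.g. a sampled GABA-immunostain surface) in 3-D and
#' classifies the spot as positive when that distance is strictly below
#' `max_dist_um` (default 0.1 um, the "shortest distance below 0.1 um"
#' filter). The positive fraction over spots is the colocalisation readout
#' used for neurotransmitter-identity calls.
#'
#' Targets are treated as a point cloud (surfaces are represented by their
#' sampled points); distances are point-to-point.
#'
#' @param spots A data frame with columns `x_um`, `y_um`, `z_um` and
#'   optionally `id`.
#' @param targets A data frame with columns `x_um`, `y_um`, `z_um`; must be
#'   nonempty.
#' @param max_dist_um Strict distance bound in micrometres.
#' @return A tibble of class `spot_proximity`, one row per spot: `id`,
#'   `nearest_dist_um`, `positive`; the positive fraction is available via
#'   [glance()] or `attr(, "fraction")`.
#' @export
spot_proximity_fraction <- function(spots, targets, max_dist_um = 0.1) {
  for (nm in c("x_um", "y_um", "z_um")) {
    if (!nm %in% names(spots)) abort(sprintf("`spots` lacks column %s.", nm))
    if (!nm %in% names(targets)) abort(sprintf("`targets` lacks column %s.", nm))
  }
  if (nrow(targets) == 0) abort("`targets` is empty.")
  if (nrow(spots) == 0) abort("`spots` is empty.")
  sm <- as.matrix(spots[, c("x_um", "y_um", "z_um")])
  tm <- as.matrix(targets[, c("x_um", "y_um", "z_um")])
  if (!all(is.finite(sm)) || !all(is.finite(tm)))
    abort("Coordinates must be finite.")

  # chunked pairwise distances: the fast |s|^2 + |t|^2 - 2 s.t form locates
  # the nearest target, then the winning distance is recomputed by direct
  # differencing (no cancellation error at the strict 0.1 um boundary)
  t2 <- rowSums(tm^2)
  nd <- numeric(nrow(sm))
  chunk <- max(1L, as.integer(2e6 / max(1, nrow(tm))))
  for (i0 in seq(1, nrow(sm), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(sm))
    s <- sm[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(s^2), t2, "+") - 2 * s %*% t(tm)
    near <- apply(d2, 1, which.min)
    nd[i0:i1] <- sqrt(rowSums((s - tm[near, , drop = FALSE])^2))
  }
  out <- tibble(
    id = if ("id" %in% names(spots)) spots$id else seq_len(nrow(sm)),
    nearest_dist_um = nd,
    positive = nd < max_dist_um
  )
  structure(out, class = c("spot_proximity", class(out)),
            fraction = mean(out$positive), max_dist_um = max_dist_um)
}

#' @rdname spot_proximity_fraction
#' @param x A `spot_proximity` object.
#' @param ... Unused.
#' @export
glance.spot_proximity <- function(x, ...) {
  tibble(n_spots = nrow(x), n_positive = sum(x$positive),
         fraction = attr(x, "fraction"),
         max_dist_um = attr(x, "max_dist_um"))
}

#' Manders colocalisation coefficients
#'
#' Thresholded Manders coefficients for two co-registered intensity channels,
#' using the upper-right-quadrant region of interest of the joint intensity
#' scatter: with thresholds `t1`, `t2`,
#' `M1 = sum(ch1[ch1 > t1 & ch2 > t2]) / sum(ch1[ch1 > t1])` and symmetrically
#' `M2` for channel 2. Both coefficients lie in \[0, 1\]. Thresholds are
#' mandatory: the reference workflow sets them manually per image and no
#' sensible hidden default exists.
#'
#' @param ch1,ch2 Numeric arrays (any shape) of equal dimensions,
#'   non-negative.
#' @param t1,t2 Intensity thresholds for channel 1 and 2.
#' @return A one-row tibble: `m1`, `m2`, `n_voxels`, `n_coloc` (voxels above
#'   both thresholds).
#' @examples
#' manders_coefficients(c(10, 10, 0, 0), c(10, 0, 10, 0), t1 = 5, t2 = 5)
#' @export
manders_coefficients <- function(ch1, ch2, t1, t2) {
  if (!identical(dim(ch1) %||% length(ch1), dim(ch2) %||% length(ch2)))
    abort("`ch1` and `ch2` must have identical dimensions.")
  c1 <- as.numeric(ch1); c2 <- as.numeric(ch2)
  if (any(c1 < 0) || any(c2 < 0)) abort("Intensities must be non-negative.")
  if (missing(t1) || missing(t2)) abort("Thresholds `t1` and `t2` are required.")
  sup1 <- c1 > t1
  sup2 <- c2 > t2
  den1 <- sum(c1[sup1]); den2 <- sum(c2[sup2])
  if (den1 <= 0 || den2 <= 0)
    abort("No supra-threshold signal in one channel; coefficients undefined.")
  both <- sup1 & sup2
  tibble(m1 = sum(c1[both]) / den1, m2 = sum(c2[both]) / den2,
         n_voxels = length(c1), n_coloc = sum(both))
}

#' Read a spot table
#'
#' Reads a CSV of 3-D points (`id, x_um, y_um, z_um[, channel]`) as exported
#' from image-analysis spot/surface objects, optionally split by channel.
#'
#' @param path CSV path.
#' @return A tibble, or a named list of tibbles when a `channel` column is
#'   present.
#' @export
read_spots <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("x_um", "y_um", "z_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(sprintf("%s: missing column(s) %s.", path,
                  paste(miss, collapse = ", ")))
  if ("channel" %in% names(df)) split(as_tibble(df), df$channel)
  else as_tibble(df)
}
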