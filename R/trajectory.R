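#' Leg-claw trajectory table
#'
#' The central container: a long tibble with one row per (frame, leg) holding
#' tracked claw positions, plus fly-level metadata carried as attributes.
#' Positions are pixel centres with y increasing downward (image convention);
#' frame indices are 0-based and time in ms is `frame / fps * 1000`.
#'
#' A `fly_traj` holds a single contiguous walking bout: frames must form an
#' unbroken 0-gap sequence per leg (see [read_trajectories()] for gap
#' handling on import).
#'
#' @param frames A data frame with columns `frame`, `leg`, `x`, `y` and
#'   optionally `body_x`, `body_y`, `heading_deg` (per-frame body centroid and
#'   heading, identical across legs) and `interpolated`.
#' @param fly_id,genotype Identifier strings.
#' @param body_length_px Body length in pixels; must be positive.
#' @param climbing_score_cm Optional climbing assay score (maximum height
#'   climbed, cm).
#' @param calibration A [calibration()] object.
#' @param frame_of_reference `"arena"` (camera frame) or `"body"`
#'   (body-centred: origin at the centroid, x along the anterior-posterior
#'   axis, anterior positive).
#'
#' @return A tibble of class `fly_traj`.
#' @seealso [read_trajectories()], [to_body_frame()], [normalize_body_size()]
#' @export
fly_traj <- function(frames, fly_id, genotype = NA_character_,
                     body_length_px, climbing_score_cm = NA_real_,
                     calibration = flytremor::calibration(),
                     frame_of_reference = c("arena", "body")) {
  frame_of_reference <- match.arg(frame_of_reference)
  calibration <- as_calibration(calibration)
  if (!is.numeric(body_length_px) || length(body_length_px) != 1 ||
      is.na(body_length_px) || body_length_px <= 0)
    abort("`body_length_px` must be a single positive number.")

  need <- c("frame", "leg", "x", "y")
  miss <- setdiff(need, names(frames))
  if (length(miss))
    abort(paste0("`frames` is missing column(s): ",
                 paste(miss, collapse = ", "), "."))
  frames <- as_tibble(frames)
  frames$frame <- as.integer(frames$frame)
  frames$leg <- as.character(frames$leg)

  bad_leg <- setdiff(unique(frames$leg), LEG_IDS)
  if (length(bad_leg))
    abort(paste0("Unknown leg id(s): ", paste(bad_leg, collapse = ", "),
                 " (expected ", paste(LEG_IDS, collapse = ", "), ")."))
  if (anyNA(frames$x) || anyNA(frames$y))
    abort("Positions contain missing values.")

  frames <- dplyr::arrange(frames, .data$leg, .data$frame)
  for (lg in unique(frames$leg)) {
    fr <- frames$frame[frames$leg == lg]
    if (anyDuplicated(fr))
      abort(sprintf("Duplicated frame index for leg %s (frame %d).",
                    lg, fr[which(duplicated(fr))[1]]))
    d <- diff(fr)
    if (any(d <= 0))
      abort(sprintf("Frame indices not strictly increasing for leg %s.", lg))
    if (any(d > 1))
      abort(sprintf(
        "Leg %s has a %d-frame gap at frame %d; a fly_traj holds one contiguous bout (see read_trajectories for gap handling).",
        lg, max(d) - 1L, fr[which(d > 1)[1]]))
  }
  spans <- tapply(frames$frame, frames$leg, range)
  if (length(unique(vapply(spans, paste, "", collapse = ":"))) != 1)
    abort("All legs must cover the same frame span.")

  n_frames <- length(unique(frames$frame))
  new_fly_traj(frames,
               fly_id = as.character(fly_id),
               genotype = as.character(genotype),
               body_length_px = body_length_px,
               climbing_score_cm = climbing_score_cm,
               calibration = calibration,
               frame_of_reference = frame_of_reference,
               duration_s = n_frames / calibration$fps,
               norm_factor = 1,
               sim_truth = NULL,
               provenance = list())
}

new_fly_traj <- function(frames, ...) {
  meta <- list(...)
  structure(
    as_tibble(frames),
    class = c("fly_traj", class(tibble())),
    traj_meta = meta
  )
}

#' Trajectory metadata
#'
#' Returns the fly-level metadata attached to a [fly_traj()]: `fly_id`,
#' `genotype`, `body_length_px`, `climbing_score_cm`, `calibration`,
#' `frame_of_reference`, `duration_s`, `norm_factor`, `sim_truth`,
#' `provenance`.
#'
#' @param traj A `fly_traj`.
#' @return A named list.
#' @export
traj_meta <- function(traj) {
  m <- attr(traj, "traj_meta", exact = TRUE)
  if (is.null(m)) abort("`traj` is not a fly_traj (no metadata attribute).")
  m
}

# Rebuild a fly_traj from modified frames, carrying metadata forward with
# selective overrides.
update_traj <- function(traj, frames = NULL, ...) {
  meta <- traj_meta(traj)
  over <- list(...)
  for (nm in names(over)) meta[nm] <- list(over[[nm]])
  do.call(new_fly_traj, c(list(frames = frames %||% as_tibble(traj)), meta))
}

#' @export
print.fly_traj <- function(x, ...) {
  m <- traj_meta(x)
  cat(sprintf(
    "<fly_traj> fly %s (%s), %s frame, %d legs, %.3f s, body %.1f px\n",
    m$fly_id, m$genotype, m$frame_of_reference,
    length(unique(x$leg)), m$duration_s, m$body_length_px))
  NextMethod()
}

traj_times_ms <- function(traj) {
  fps <- traj_meta(traj)$calibration$fps
  traj$frame / fps * 1000
}

# Per-frame body centroid / heading: the tracked columns when present,
# otherwise estimated from the six claws (centroid = mean position; heading =
# first principal axis, sign fixed so front legs point forward).
body_pose <- function(traj, estimate = TRUE) {
  df <- as_tibble(traj)
  if (all(c("body_x", "body_y", "heading_deg") %in% names(df))) {
    pose <- dplyr::distinct(df[, c("frame", "body_x", "body_y", "heading_deg")])
    if (anyDuplicated(pose$frame))
      abort("Inconsistent body pose columns across legs.")
    return(dplyr::arrange(pose, .data$frame))
  }
  if (!estimate)
    abort("No body pose columns and estimation disabled.")
  if (length(unique(df$leg)) < 3)
    abort("Body-pose estimation needs at least 3 tracked legs.")
  pose <- df |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(
      body_x = mean(.data$x), body_y = mean(.data$y),
      cxx = mean(.data$x^2) - mean(.data$x)^2,
      cyy = mean(.data$y^2) - mean(.data$y)^2,
      cxy = mean(.data$x * .data$y) - mean(.data$x) * mean(.data$y),
      .groups = "drop"
    )
  theta <- 0.5 * atan2(2 * pose$cxy, pose$cxx - pose$cyy)
  # fix sign: mean front-leg (L1/R1) offset should project positively
  front <- df[df$leg %in% c("L1", "R1"), ]
  if (nrow(front)) {
    fo <- front |>
      dplyr::group_by(.data$frame) |>
      dplyr::summarise(fx = mean(.data$x), fy = mean(.data$y),
                       .groups = "drop")
    fo <- dplyr::left_join(fo, pose[, c("frame", "body_x", "body_y")],
                           by = "frame")
    proj <- (fo$fx - fo$body_x) * cos(theta) + (fo$fy - fo$body_y) * sin(theta)
    theta <- ifelse(proj < 0, theta + pi, theta)
  }
  tibble(frame = pose$frame, body_x = pose$body_x, body_y = pose$body_y,
         heading_deg = theta * 180 / pi)
}

#' Transform a trajectory to body-centred coordinates
#'
#' Re-expresses arena-frame claw positions relative to the fly's body: the
#' origin moves to the per-frame body centroid and the axes rotate so that x
#' runs along the anterior-posterior axis (anterior positive) and y along the
#' medio-lateral axis. Whole-body translation and rotation are thereby
#' removed, leaving only leg movement relative to the body -- the substrate of
#' shake detection.
#'
#' Body pose comes from `body_x`/`body_y`/`heading_deg` columns when present;
#' otherwise (with `estimate_pose = TRUE`) the centroid is estimated as the
#' mean of the tracked claws and the heading as their first principal axis,
#' sign-fixed by the front legs.
#'
#' @param traj An arena-frame [fly_traj()].
#' @param estimate_pose Allow pose estimation when pose columns are absent.
#' @return A body-frame `fly_traj` (pose columns dropped).
#' @export
to_body_frame <- function(traj, estimate_pose = TRUE) {
  m <- traj_meta(traj)
  if (m$frame_of_reference != "arena")
    abort("`traj` is already in the body frame.")
  pose <- body_pose(traj, estimate = estimate_pose)
  df <- dplyr::left_join(as_tibble(traj), pose, by = "frame",
                         suffix = c("", ".pose"))
  bx <- df[["body_x.pose"]] %||% df$body_x
  by <- df[["body_y.pose"]] %||% df$body_y
  hd <- df[["heading_deg.pose"]] %||% df$heading_deg
  th <- hd * pi / 180
  dx <- df$x - bx
  dy <- df$y - by
  out <- as_tibble(traj)
  out$x <- cos(th) * dx + sin(th) * dy
  out$y <- -sin(th) * dx + cos(th) * dy
  out$body_x <- NULL; out$body_y <- NULL; out$heading_deg <- NULL
  update_traj(traj, frames = out, frame_of_reference = "body")
}

#' Normalise displacements to a reference body size
#'
#' Scales all positions by `reference_body_length_px / body_length_px`, so
#' that the fixed 3 px shake-amplitude threshold is comparable across flies of
#' different sizes. The scale factor is recorded in the trajectory's
#' provenance and compounds across repeated calls.
#'
#' @param traj A [fly_traj()].
#' @param reference_body_length_px Reference length in px. Defaults to the
#'   fly's own body length (identity scaling); screen pipelines typically pass
#'   the cohort mean.
#' @return A rescaled `fly_traj`.
#' @export
normalize_body_size <- function(traj, reference_body_length_px = NULL) {
  m <- traj_meta(traj)
  ref <- reference_body_length_px %||% m$body_length_px
  if (!is.numeric(ref) || length(ref) != 1 || is.na(ref) || ref <= 0)
    abort("`reference_body_length_px` must be a single positive number.")
  fac <- ref / m$body_length_px
  df <- as_tibble(traj)
  for (col in intersect(c("x", "y", "body_x", "body_y"), names(df)))
    df[[col]] <- df[[col]] * fac
  prov <- m$provenance
  prov$norm_reference_px <- ref
  update_traj(traj, frames = df,
              norm_factor = m$norm_factor * fac,
              provenance = prov)
}

#' Walking-bout quality control
#'
#' Checks the inclusion rule for gait recordings: the fly must have walked at
#' least `min_body_lengths` (default 1.5) body lengths in net displacement
#' over the bout. The bound is inclusive ("at least").
#'
#' @param traj An arena-frame [fly_traj()] (the body path is needed).
#' @param min_body_lengths Minimum net displacement, in body lengths.
#' @return A one-row tibble: `fly_id`, `displacement_px`,
#'   `displacement_body_lengths`, `duration_s`, `pass`.
#' @export
qc_walking_bout <- function(traj, min_body_lengths = 1.5) {
  m <- traj_meta(traj)
  if (m$frame_of_reference != "arena")
    abort("QC needs the arena-frame trajectory (body path).")
  pose <- body_pose(traj, estimate = TRUE)
  n <- nrow(pose)
  disp <- sqrt((pose$body_x[n] - pose$body_x[1])^2 +
               (pose$body_y[n] - pose$body_y[1])^2)
  # displacement is measured on raw positions; undo any normalisation scale
  bl <- m$body_length_px * m$norm_factor
  tibble(
    fly_id = m$fly_id,
    displacement_px = disp,
    displacement_body_lengths = disp / bl,
    duration_s = m$duration_s,
    pass = disp / bl >= min_body_lengths
  )
}
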