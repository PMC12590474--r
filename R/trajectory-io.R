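#' Read tracked leg-claw trajectories
#'
#' Reads FLLIT-style tabular tracking output: a CSV/TSV with columns
#' `frame,leg,x,y` and optionally `body_x,body_y,heading_deg` (one row per
#' frame and leg). Fly-level metadata is taken from a JSON sidecar
#' (`<path>.json` by default) with fields `fly_id`, `genotype`,
#' `body_length_px`, `climbing_score_cm`, `frame_of_reference` and
#' `calibration`; arguments override sidecar values.
#'
#' Tracking dropouts are handled per the package's bout policy: gaps of at
#' most 2 frames are linearly interpolated (rows flagged in the
#' `interpolated` column); larger gaps split the recording into contiguous
#' bouts, of which the longest is returned unless `all_bouts = TRUE`.
#'
#' @param path Trajectory table (CSV, or TSV when the extension is `.tsv`).
#' @param sidecar Path to the JSON sidecar; `NULL` tries `<path>.json`.
#' @param calibration,frame_of_reference,fly_id,genotype,body_length_px,climbing_score_cm
#'   Metadata overrides. `body_length_px` is required if absent from the
#'   sidecar.
#' @param all_bouts Return a list of all contiguous bouts instead of the
#'   longest one.
#' @return A [fly_traj()] (or a list of them when `all_bouts = TRUE`).
#' @export
read_trajectories <- function(path, sidecar = NULL, calibration = NULL,
                              frame_of_reference = NULL, fly_id = NULL,
                              genotype = NULL, body_length_px = NULL,
                              climbing_score_cm = NULL, all_bouts = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  # parse numerics via strtod (bit-exact round trip of %.17g output)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  for (col in setdiff(names(df), c("leg", "interpolated"))) {
    suppressWarnings(df[[col]] <- as.numeric(df[[col]]))
  }
  if ("interpolated" %in% names(df))
    df$interpolated <- as.logical(df$interpolated)
  need <- c("frame", "leg", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(sprintf("%s: missing column(s) %s.", path,
                  paste(miss, collapse = ", ")))
  bad <- which(is.na(df$frame) | is.na(df$x) | is.na(df$y) | is.na(df$leg))
  if (length(bad))
    abort(sprintf("%s: malformed row at line %d (missing value).",
                  path, bad[1] + 1L))
  df$frame <- as.integer(df$frame)

  side_path <- sidecar %||% paste0(path, ".json")
  side <- if (file.exists(side_path))
    jsonlite::read_json(side_path, simplifyVector = TRUE) else list()

  cal <- as_calibration(calibration %||% side$calibration %||% calibration())
  for_ <- frame_of_reference %||% side$frame_of_reference %||% "arena"
  bl <- body_length_px %||% side$body_length_px
  if (is.null(bl))
    abort("`body_length_px` not given and absent from sidecar.")
  bl <- as.numeric(bl)

  # flag frames missing any tracked leg, interpolate short gaps, split bouts
  df <- dplyr::arrange(as_tibble(df), .data$leg, .data$frame)
  for (lg in unique(df$leg)) {
    fr <- df$frame[df$leg == lg]
    if (anyDuplicated(fr))
      abort(sprintf("%s: duplicated frame %d for leg %s.",
                    path, fr[which(duplicated(fr))[1]], lg))
  }
  full <- sort(unique(df$frame))
  counts <- table(df$frame)
  n_legs <- length(unique(df$leg))
  incomplete <- as.integer(names(counts)[counts < n_legs])
  complete <- setdiff(full, incomplete)
  if (!length(complete)) abort(sprintf("%s: no frame has all legs tracked.", path))

  gaps <- diff(complete)
  bout_id <- cumsum(c(0L, gaps > 3L))  # gap = missing span; <=2 missing frames ok
  bouts <- split(complete, bout_id)
  if (!all_bouts) {
    lens <- vapply(bouts, function(b) max(b) - min(b) + 1L, 1L)
    if (length(bouts) > 1)
      message(sprintf("%d bouts found (gaps > 2 frames); keeping the longest.",
                      length(bouts)))
    bouts <- bouts[which.max(lens)]
  }

  make_bout <- function(b) {
    span <- seq(min(b), max(b))
    sub <- df[df$frame %in% b, , drop = FALSE]
    filled <- sub |>
      dplyr::group_by(.data$leg) |>
      dplyr::reframe(interp_leg(dplyr::pick(dplyr::everything()), span)) |>
      dplyr::ungroup()
    tr <- fly_traj(filled, fly_id = fly_id %||% side$fly_id %||% "fly",
                   genotype = genotype %||% side$genotype %||% NA_character_,
                   body_length_px = bl,
                   climbing_score_cm = climbing_score_cm %||%
                     side$climbing_score_cm %||% NA_real_,
                   calibration = cal, frame_of_reference = for_)
    update_traj(tr, provenance = list(source = path))
  }
  out <- lapply(bouts, make_bout)
  if (all_bouts) unname(out) else out[[1]]
}

# Linearly interpolate a single leg's track onto a contiguous frame span.
interp_leg <- function(sub, span) {
  num <- setdiff(names(sub), c("frame", "leg"))
  out <- tibble(frame = span)
  for (col in num) {
    out[[col]] <- stats::approx(sub$frame, sub[[col]], xout = span,
                                rule = 2)$y
  }
  out$interpolated <- !(span %in% sub$frame)
  out
}

#' Write a trajectory table (with JSON sidecar)
#'
#' Inverse of [read_trajectories()]: writes the per-frame table as CSV/TSV and
#' the fly metadata (including calibration, frame of reference and provenance)
#' as `<path>.json`. Positions round-trip losslessly (full double precision).
#'
#' @param traj A [fly_traj()].
#' @param path Output table path (`.tsv` extension selects tab delimiting).
#' @param sidecar Write the JSON sidecar too.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path, sidecar = TRUE) {
  m <- traj_meta(traj)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- as_tibble(traj)
  num <- vapply(df, is.numeric, TRUE) & names(df) != "frame"
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  if (sidecar) {
    meta <- list(
      fly_id = m$fly_id, genotype = m$genotype,
      body_length_px = m$body_length_px,
      climbing_score_cm = m$climbing_score_cm,
      frame_of_reference = m$frame_of_reference,
      calibration = unclass(m$calibration),
      norm_factor = m$norm_factor,
      provenance = m$provenance
    )
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  invisible(path)
}
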