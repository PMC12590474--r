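#' Run configuration
#'
#' Builds and validates the configuration driving [run_detect()] and
#' [run_screen()]. Either supply `inputs` (trajectory tables on disk) or a
#' `simulate` block (arguments to [simulate_cohort()]); detection thresholds
#' come from a [detection_params()] list. `screen_mode` selects the shake
#' criterion: `"strict"` keeps `min_shakes = 3` (the confirmatory-screen
#' criterion), `"primary-relaxed"` lowers it to 2 (the false-negative-averse
#' primary screen).
#'
#' @param out_dir Output directory (created if needed).
#' @param inputs Character vector of trajectory CSV/TSV paths (each with its
#'   JSON sidecar), or `NULL` when simulating.
#' @param simulate Optional named list of [simulate_cohort()] arguments.
#' @param detection Named list of [detection_params()] overrides.
#' @param screen_mode `"strict"` or `"primary-relaxed"`.
#' @param control Control genotype for [run_screen()].
#' @param alpha Hit-calling level.
#' @param seed Integer seed for all pipeline randomness.
#' @param reference_body_length_px Normalisation reference; `NULL` = cohort
#'   mean, computed at run time and recorded in provenance.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir, inputs = NULL, simulate = NULL,
                       detection = list(), screen_mode = c("strict",
                                                           "primary-relaxed"),
                       control = NULL, alpha = 0.05, seed = 1L,
                       reference_body_length_px = NULL) {
  screen_mode <- match.arg(screen_mode)
  det <- do.call(detection_params, detection)
  if (screen_mode == "primary-relaxed" && !("min_shakes" %in% names(detection)))
    det$min_shakes <- 2L
  if (is.null(inputs) && is.null(simulate))
    abort("Provide `inputs` or a `simulate` block.")
  if (!is.null(inputs)) {
    missing_files <- inputs[!file.exists(inputs)]
    if (length(missing_files))
      abort(sprintf("Input file(s) not found: %s",
                    paste(missing_files, collapse = ", ")))
  }
  structure(list(out_dir = out_dir, inputs = inputs, simulate = simulate,
                 detection = det, screen_mode = screen_mode,
                 control = control, alpha = alpha, seed = as.integer(seed),
                 reference_body_length_px = reference_body_length_px),
            class = "run_config")
}

#' Read a pipeline configuration file
#'
#' JSON (always) or YAML (when the yaml package is installed) with the fields
#' of [run_config()].
#'
#' @param path Config file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort("YAML config requires the yaml package; use JSON.")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.data.frame(cfg$simulate)) cfg$simulate <- as.list(cfg$simulate)
  do.call(run_config, cfg)
}

#' Detect tremor over a set of recordings
#'
#' The end-to-end detection stage: loads (or simulates) trajectories, runs the
#' per-fly pipeline (body-frame transform, body-size normalisation to the
#' cohort mean, gait high-pass, shake detection, episode grouping), and writes
#' `shakes.tsv`, `episodes.tsv`, `fly_summaries.tsv` and a `provenance.json`
#' echoing every parameter and the seed. Outputs are byte-identical across
#' runs with the same config and seed.
#'
#' @param config A [run_config()] (or path to a config file).
#' @return Invisibly, a list with the three tables and the output paths.
#' @export
run_detect <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  flies <- if (!is.null(config$inputs)) {
    message("stage: load (", length(config$inputs), " files)")
    lapply(config$inputs, read_trajectories)
  } else {
    message("stage: simulate")
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    if (!is.null(sim_args$params) && !inherits(sim_args$params, "gait_params"))
      sim_args$params <- do.call(gait_params, sim_args$params)
    cohort <- do.call(simulate_cohort, sim_args)
    cohort$traj
  }

  ref <- config$reference_body_length_px %||%
    mean(vapply(flies, function(f) traj_meta(f)$body_length_px, 1))

  message("stage: detect (", length(flies), " flies)")
  per_fly <- lapply(flies, function(tr) {
    m <- traj_meta(tr)
    body <- if (m$frame_of_reference == "arena") to_body_frame(tr) else tr
    body <- normalize_body_size(body, ref)
    filt <- highpass_trajectory(body, config$detection$highpass_hz)
    shakes <- detect_shakes(filt, config$detection)
    eps <- group_tremor_episodes(shakes, config$detection)
    smry <- summarize_fly(tr, config$detection,
                          reference_body_length_px = ref)
    add_id <- function(d) dplyr::bind_cols(
      tibble(fly_id = rep(m$fly_id, nrow(d)),
             genotype = rep(m$genotype, nrow(d))), d)
    list(shakes = add_id(shakes), episodes = add_id(eps), summary = smry)
  })

  shakes <- purrr::map_dfr(per_fly, "shakes")
  episodes <- purrr::map_dfr(per_fly, "episodes")
  summaries <- purrr::map_dfr(per_fly, "summary")

  message("stage: write")
  paths <- file.path(config$out_dir,
                     c("shakes.tsv", "episodes.tsv", "fly_summaries.tsv",
                       "provenance.json"))
  write_tsv_stable(shakes, paths[1])
  write_tsv_stable(episodes, paths[2])
  write_tsv_stable(summaries, paths[3])
  prov <- list(
    tool = "flytremor",
    version = as.character(utils::packageVersion("flytremor")),
    seed = config$seed,
    screen_mode = config$screen_mode,
    detection = unclass(config$detection),
    reference_body_length_px = ref,
    n_flies = length(flies),
    inputs = config$inputs
  )
  jsonlite::write_json(prov, paths[4], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(list(shakes = shakes, episodes = episodes, summaries = summaries,
                 paths = paths))
}

#' Screen-level analysis of per-fly summaries
#'
#' Reads per-fly tremor summaries (from [run_detect()] or assembled by hand),
#' computes line-level penetrance with exact intervals and comparisons vs the
#' control line, flags hits, and writes `screen_results.tsv` plus a JSON
#' report.
#'
#' @param config A [run_config()] with `control` set (or a path to one).
#' @param fly_summaries Optional in-memory summary table; default reads
#'   `fly_summaries.tsv` from `config$out_dir`.
#' @return Invisibly, the [summarize_screen()] table.
#' @export
run_screen <- function(config, fly_summaries = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$control)) abort("`config$control` is required for a screen.")
  if (is.null(fly_summaries)) {
    p <- file.path(config$out_dir, "fly_summaries.tsv")
    if (!file.exists(p)) abort("No fly summaries; run run_detect() first.")
    fly_summaries <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
  }
  message("stage: screen (", length(unique(fly_summaries$genotype)), " lines)")
  res <- summarize_screen(fly_summaries, control = config$control,
                          alpha = config$alpha)
  write_tsv_stable(as_tibble(res), file.path(config$out_dir, "screen_results.tsv"))
  report <- list(
    control = config$control, alpha = config$alpha,
    screen_mode = config$screen_mode,
    hits = res$genotype[res$hit],
    lines = as_tibble(res)
  )
  jsonlite::write_json(report, file.path(config$out_dir, "screen_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
  invisible(res)
}

#' Colocalisation analysis of spot tables
#'
#' Applies the strict 0.1 um nearest-distance rule to a spots/targets CSV pair
#' and writes a JSON report with the positive fraction and per-spot labels.
#'
#' @param spots_path,targets_path CSVs with `x_um`, `y_um`, `z_um` columns.
#' @param out_path Output JSON path.
#' @param max_dist_um Distance rule (default 0.1 um).
#' @return Invisibly, the [spot_proximity_fraction()] table.
#' @export
run_coloc <- function(spots_path, targets_path, out_path,
                      max_dist_um = 0.1) {
  spots <- read_spots(spots_path)
  targets <- read_spots(targets_path)
  res <- spot_proximity_fraction(spots, targets, max_dist_um = max_dist_um)
  jsonlite::write_json(
    list(summary = glance(res), spots = as_tibble(res)),
    out_path, auto_unbox = TRUE, digits = NA, dataframe = "rows",
    pretty = TRUE)
  invisible(res)
}

# Deterministic TSV writer: fixed significant digits, no scientific notation
# drift, so identical inputs produce byte-identical files.
write_tsv_stable <- function(df, path) {
  out <- df
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(v) sprintf("%.10g", v))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
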