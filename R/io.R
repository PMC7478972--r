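#' Read tracks from CSV
#'
#' The interchange format is a plain CSV with header
#' `track_id, frame, t_s, x_um, y_um, z_um`, one row per frame. Rows are
#' grouped by `track_id` and sorted by `frame`; malformed input (missing
#' columns, non-numeric fields, duplicate frames) is rejected with the
#' offending line numbers.
#'
#' @param path CSV file path.
#' @return A `track_set`.
#' @export
read_tracks <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "track_id"))
  required <- c("track_id", "frame", "t_s", "x_um", "y_um", "z_um")
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
  num_cols <- setdiff(required, "track_id")
  for (col in num_cols) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v)))) + 1L
      stop(sprintf("non-numeric values in column '%s' (lines %s)",
                   col, paste(head(bad, 5), collapse = ", ")))
    }
    if (anyNA(v)) {
      bad <- which(is.na(v)) + 1L
      stop(sprintf("missing values in column '%s' (lines %s)",
                   col, paste(head(bad, 5), collapse = ", ")))
    }
  }
  key <- paste(dt$track_id, dt$frame)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key)) + 1L
    stop(sprintf("duplicate (track_id, frame) rows (lines %s)",
                 paste(head(bad, 5), collapse = ", ")))
  }
  ids <- unique(dt$track_id)
  tracks <- lapply(ids, function(id) {
    sub <- dt[dt$track_id == id, ]
    sub <- sub[order(sub$frame), ]
    swim_track(id, sub$t_s,
               cbind(sub$x_um, sub$y_um, sub$z_um), validate = FALSE)
  })
  track_set(tracks)
}

#' Write tracks to CSV
#' @param tracks a `track_set` or single `swim_track`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "swim_track")) tracks <- track_set(list(tracks))
  data.table::fwrite(as.data.frame(tracks), path)
  invisible(path)
}

#' Write a run table to CSV
#' @param runs a `run_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_runs <- function(runs, path) {
  data.table::fwrite(as.data.frame(runs), path)
  invisible(path)
}

# reject unknown keys against a prototype function's formals
check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown))
    stop(sprintf("unknown key(s) in '%s' config: %s", where,
                 paste(unknown, collapse = ", ")))
  block
}

#' Run the full analysis pipeline on a synthetic population
#'
#' Executes generate -> smooth/filter -> run segmentation -> duration and
#' speed fits -> orientation fits -> sector assay from a single nested
#' configuration, with every random draw governed by the global seed, and
#' returns a machine-readable report of all fitted quantities together with
#' the full parameter provenance.
#'
#' The configuration is a nested list (or path to a YAML file) with blocks
#' `generate` (fields of [generator_config()] plus `n_cells` and optionally
#' `chemotaxis = list(mode, beta)`), `process` (arguments of
#' [process_tracks()]), `orientation` (`max_lag`), `assay` (`gradient`,
#' `cone_cosine`, `projection_factor`) and a global `seed`. Unknown keys are
#' rejected before any computation.
#'
#' @param config nested list or YAML path.
#' @param out optional path for the JSON report.
#' @return The report as a list (invisibly also written to `out`).
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_keys(config, c("seed", "generate", "process", "orientation", "assay"),
             "pipeline")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  gen <- config$generate
  if (is.null(gen)) gen <- list()
  check_keys(gen, c(names(formals(generator_config)), "n_cells", "chemotaxis"),
             "generate")
  n_cells <- if (is.null(gen$n_cells)) 20L else as.integer(gen$n_cells)
  chemo <- gen$chemotaxis
  gen$n_cells <- NULL; gen$chemotaxis <- NULL
  gcfg <- do.call(generator_config, gen)
  gradient <- c(1, 0, 0)
  response <- NULL
  if (!is.null(chemo)) {
    check_keys(chemo, c("mode", "beta", "gradient", "memory_rate"),
               "generate$chemotaxis")
    if (!is.null(chemo$gradient)) gradient <- as.numeric(chemo$gradient)
    k <- if (is.null(chemo$memory_rate)) 0.5 else chemo$memory_rate
    beta <- if (is.null(chemo$beta)) 0.9 else chemo$beta
    W <- calibrate_sensitivity(gcfg$v0, sqrt(sum(gradient^2)), k, beta)
    response <- response_params(1 / gcfg$tau_run, k, W, chemo$mode)
  }
  tracks <- generate_population(gcfg, n_cells, seed = seed,
                                response = response, gradient = gradient)

  prc <- config$process
  if (is.null(prc)) prc <- list()
  check_keys(prc, c("max_gap", "min_duration", "noise_lateral", "noise_axial"),
             "process")
  prc$noise_lateral <- if (is.null(prc$noise_lateral)) gcfg$noise_lateral
  else prc$noise_lateral
  prc$noise_axial <- if (is.null(prc$noise_axial)) gcfg$noise_axial
  else prc$noise_axial
  smoothed <- do.call(process_tracks, c(list(tracks), prc))
  discards <- attr(smoothed, "discards")

  labels <- vapply(unclass(smoothed), function(tr)
    as.character(classify_motile(tr)), character(1))
  swimming <- smoothed[labels == "swimming"]

  runs <- segment_all_runs(swimming)
  dur_fit <- fit_run_durations(runs$duration_s[!runs$censored])
  speed_fit <- fit_speed_distribution(pooled_speeds(swimming))

  ori <- config$orientation
  if (is.null(ori)) ori <- list()
  check_keys(ori, c("max_lag"), "orientation")
  max_lag <- if (is.null(ori$max_lag)) 10 else ori$max_lag
  ofits <- fit_orientation_population(swimming, max_lag = max_lag)
  dr_summary <- if (!is.null(ofits) && nrow(ofits) >= 10) {
    ln <- fit_lognormal(ofits$D_r[ofits$D_r > 0])
    list(modal_D_r = ln$mode, meanlog = ln$meanlog, sdlog = ln$sdlog,
         n_tracks = nrow(ofits))
  } else {
    list(modal_D_r = median(ofits$D_r), n_tracks = nrow(ofits))
  }

  asy <- config$assay
  if (is.null(asy)) asy <- list()
  check_keys(asy, c("gradient", "cone_cosine", "projection_factor"), "assay")
  asy_grad <- if (is.null(asy$gradient)) gradient else as.numeric(asy$gradient)
  sector <- sector_summary(
    runs, gradient = asy_grad,
    cone_cosine = if (is.null(asy$cone_cosine)) 0.5 else asy$cone_cosine,
    projection_factor = if (is.null(asy$projection_factor)) 1 / 3
    else asy$projection_factor)

  report <- list(
    provenance = list(
      package = "halotaxis",
      version = as.character(packageVersion("halotaxis")),
      seed = seed, config = config),
    counts = list(
      generated = n_cells, smoothed = length(smoothed),
      swimming = length(swimming), discarded = nrow(discards),
      runs_total = nrow(runs), runs_censored = sum(runs$censored)),
    run_duration_fit = unclass(dur_fit),
    speed_fit = unclass(speed_fit),
    orientation = dr_summary,
    sector_summary = unclass(sector))
  if (!is.null(out))
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(report)
}
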