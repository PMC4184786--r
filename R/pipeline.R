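#' Assemble a pipeline run configuration
#'
#' One object holds every tunable of an end-to-end run. Defaults mirror the
#' acquisition and analysis constants this package models: 0.5 s frame
#' interval, 20-point MSD fit, tracks kept only when longer than 150 frames.
#' Every run writes its resolved configuration verbatim next to its outputs,
#' so a result can always be traced to the exact parameters that produced
#' it.
#'
#' @param pixel_size um per pixel.
#' @param frame_interval s between frames.
#' @param detection list: `expected_diameter` (um), `quality_threshold`.
#' @param linking list: `max_displacement` (um), `min_track_length`.
#' @param fit list: `n_points`, `max_lag_fraction`, `method`.
#' @param morphometry list: `n_angles`, `half_length` (um).
#' @param seed integer seed for any simulation stages.
#' @param conditions character vector of condition labels.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(pixel_size = 0.1, frame_interval = 0.5,
                       detection = list(expected_diameter = 1,
                                        quality_threshold = NULL),
                       linking = list(max_displacement = 0.5,
                                      min_track_length = 150L),
                       fit = list(n_points = 20L, max_lag_fraction = 0.25,
                                  method = "loglog"),
                       morphometry = list(n_angles = 8L, half_length = 2),
                       seed = 1L,
                       conditions = c("untreated", "nocodazole")) {
  stop_if_not_scalar_pos(pixel_size, "pixel_size")
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  defaults <- formals(run_config)
  cfg <- list(pixel_size = pixel_size, frame_interval = frame_interval,
              detection = modifyList(eval(defaults$detection), detection),
              linking = modifyList(eval(defaults$linking), linking),
              fit = modifyList(eval(defaults$fit), fit),
              morphometry = modifyList(eval(defaults$morphometry),
                                       morphometry),
              seed = seed, conditions = conditions)
  stop_if_not_scalar_pos(cfg$detection$expected_diameter,
                         "detection$expected_diameter")
  stop_if_not_scalar_pos(cfg$linking$max_displacement,
                         "linking$max_displacement")
  structure(cfg, class = "run_config")
}

write_run_config <- function(cfg, dir) {
  path <- file.path(dir, "run_config.json")
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  path
}

#' Run the tracking-and-mobility pipeline end to end
#'
#' Composes the stages — ingest or simulate tracks per condition, filter by
#' length, compute MSD curves, fit the anomalous-diffusion model, summarise
#' each population, and (for two conditions) compare them — and returns a
#' structured report. Inputs come either from track CSV files
#' (`inputs = list(<condition> = <path>)`) or from simulation configs
#' (`simulate = list(<condition> = list(cfg = track_sim_config(...),
#' n_tracks = ...))`); exactly one source must be given.
#'
#' @param run a [run_config()].
#' @param inputs named list of track-table CSV paths, one per condition.
#' @param simulate named list of simulation requests, one per condition.
#' @param output_dir if non-`NULL`, the resolved config, per-track fits CSV,
#'   and the JSON + text report are written here.
#' @return list of class `"run_report"`: `config_hash`, `input_manifest`,
#'   `counts` (per condition: tracks in, kept, dropped by the length filter,
#'   dropped by the fit), `summaries` (per-condition
#'   [summarize_population()] results), `comparison` (or `NULL`), `fits`
#'   (per-condition fit tables), `version`.
#' @export
end_to_end <- function(run, inputs = NULL, simulate = NULL,
                       output_dir = NULL) {
  stopifnot(inherits(run, "run_config"))
  if (is.null(inputs) == is.null(simulate)) {
    stop("give exactly one of `inputs` (track CSVs) or `simulate` ",
         "(simulation requests)", call. = FALSE)
  }
  src <- inputs %||% simulate
  conditions <- names(src)
  if (is.null(conditions) || any(!nzchar(conditions))) {
    stop("`inputs`/`simulate` must be a named list (condition labels)",
         call. = FALSE)
  }

  manifest <- list()
  tracks_by_cond <- list()
  if (!is.null(inputs)) {
    for (cond in conditions) {
      if (!file.exists(inputs[[cond]])) {
        stop(sprintf("ingest stage: input '%s' for condition '%s' not found",
                     inputs[[cond]], cond), call. = FALSE)
      }
      manifest[[cond]] <- list(file = inputs[[cond]],
                               md5 = unname(tools::md5sum(inputs[[cond]])))
      tracks_by_cond[[cond]] <- read_track_table(inputs[[cond]],
                                                 run$frame_interval)
    }
  } else {
    seeds <- derive_seeds(run$seed, length(conditions))
    for (i in seq_along(conditions)) {
      req <- simulate[[conditions[i]]]
      tracks_by_cond[[conditions[i]]] <-
        simulate_population(req$cfg, req$n_tracks, seed = seeds[i],
                            condition = conditions[i])
      manifest[[conditions[i]]] <- list(simulated = TRUE,
                                        n_tracks = req$n_tracks,
                                        seed = seeds[i])
    }
  }

  counts <- list()
  summaries <- list()
  fit_tables <- list()
  fits_by_cond <- list()
  for (cond in conditions) {
    trs <- tracks_by_cond[[cond]]
    n_in <- length(trs)
    keep <- vapply(trs, nrow, integer(1L)) > run$linking$min_track_length
    trs <- trs[keep]
    fits <- fit_population(trs, n_points = run$fit$n_points,
                           max_lag_fraction = run$fit$max_lag_fraction,
                           method = run$fit$method)
    counts[[cond]] <- list(tracks_in = n_in,
                           dropped_short = n_in - length(trs),
                           dropped_fit = attr(fits, "n_dropped"),
                           tracks_fit = length(fits))
    if (length(fits) == 0L) {
      warning(sprintf(
        "condition '%s': no usable tracks (%d dropped by the %d-frame length filter, %d at the fit)",
        cond, n_in - length(trs), run$linking$min_track_length,
        attr(fits, "n_dropped")), call. = FALSE)
      next
    }
    fits_by_cond[[cond]] <- fits
    summaries[[cond]] <- summarize_population(fits, condition = cond)
    fit_tables[[cond]] <- data.frame(
      track_id = vapply(fits, function(f) f$track_id, character(1L)),
      condition = cond,
      D_um2_s = vapply(fits, function(f) unname(f$coefficients["D"]),
                       numeric(1L)),
      alpha = vapply(fits, function(f) unname(f$coefficients["alpha"]),
                     numeric(1L)),
      r2 = vapply(fits, function(f) f$r_squared, numeric(1L)),
      n_points_fit = run$fit$n_points)
  }

  comparison <- NULL
  if (length(fits_by_cond) == 2L) {
    comparison <- compare_conditions(fits_by_cond[[1L]], fits_by_cond[[2L]],
                                     labels = names(fits_by_cond))
  }

  report <- structure(
    list(input_manifest = manifest, counts = counts, summaries = summaries,
         comparison = comparison, fits = fit_tables,
         version = as.character(packageVersion("rbtrack")),
         config = unclass(run)),
    class = "run_report")

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_path <- write_run_config(run, output_dir)
    report$config_hash <- unname(tools::md5sum(cfg_path))
    all_fits <- do.call(rbind, fit_tables)
    write.csv(all_fits, file.path(output_dir, "fits.csv"),
              row.names = FALSE)
    jsonlite::write_json(report_as_list(report),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(utils::capture.output(print(report)),
               file.path(output_dir, "report.txt"))
  }
  report
}

report_as_list <- function(report) {
  out <- unclass(report)
  out$summaries <- lapply(out$summaries, unclass)
  if (!is.null(out$comparison)) {
    out$comparison <- as.data.frame(out$comparison)
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run report (rbtrack %s)\n", x$version))
  for (cond in names(x$counts)) {
    ct <- x$counts[[cond]]
    cat(sprintf(
      "  %s: %d tracks in, %d dropped (<= %d frames), %d dropped at fit, %d fitted\n",
      cond, ct$tracks_in, ct$dropped_short,
      x$config$linking$min_track_length, ct$dropped_fit, ct$tracks_fit))
  }
  for (s in x$summaries) print(s)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
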