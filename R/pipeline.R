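#' Configuration for an end-to-end pipeline run
#'
#' Collects every stage's parameters in one validated object.  In
#' `"simulate"` mode the pipeline generates its own input movies from the
#' kinetic and optical parameters; in `"movies"` mode it analyzes
#' pre-rendered stacks supplied to [run_pipeline()].
#'
#' @param mode `"simulate"` or `"movies"`.
#' @param seed master seed; every random stage derives from it.
#' @param n_spots number of template molecules (simulate mode).
#' @param kinetics a [kinetic_params()].
#' @param optics an [optics_params()].
#' @param channels channel roles to analyze: must contain `"template"` and
#'   `"target"`; include `"partner"` for ternary analysis.
#' @param registration_method,upsample see [estimate_drift()].
#' @param threshold_sigmas,min_area,max_area,min_persistence see
#'   [detect_spots()].
#' @param annulus see [extract_traces()].
#' @param z_threshold,min_on_frames,max_gap_frames see [call_pulses()];
#'   one `z_threshold` per image set, applied to all traces of a channel.
#' @param simultaneity_tol,short_cut,long_cut see [classify_ternary()] and
#'   [residence_summaries()].
#' @param template_photons see [render_movie()].
#' @param output_dir optional directory for the per-stage CSV/JSON artifacts.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "movies"), seed = 1,
                            n_spots = 200,
                            kinetics = kinetic_params(),
                            optics = optics_params(),
                            channels = c("template", "target", "partner"),
                            registration_method = "fft_xcorr", upsample = 10,
                            threshold_sigmas = 5, min_area = 2, max_area = 50,
                            min_persistence = 0.8,
                            annulus = c(4, 7),
                            z_threshold = 4, min_on_frames = 2,
                            max_gap_frames = 1,
                            simultaneity_tol = 5, short_cut = 120,
                            long_cut = 300,
                            template_photons = NULL,
                            output_dir = NULL) {
  mode <- match.arg(mode)
  bad <- setdiff(channels, c("template", "target", "partner"))
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  if (!all(c("template", "target") %in% channels))
    stop("channels must include 'template' and 'target'")
  stopifnot(inherits(kinetics, "kinetic_params"),
            inherits(optics, "optics_params"))
  if (z_threshold <= 0) stop("z_threshold must be > 0")
  cfg <- list(mode = mode, seed = as.integer(seed), n_spots = n_spots,
              kinetics = kinetics, optics = optics, channels = channels,
              registration_method = registration_method, upsample = upsample,
              threshold_sigmas = threshold_sigmas, min_area = min_area,
              max_area = max_area, min_persistence = min_persistence,
              annulus = annulus, z_threshold = z_threshold,
              min_on_frames = min_on_frames, max_gap_frames = max_gap_frames,
              simultaneity_tol = simultaneity_tol, short_cut = short_cut,
              long_cut = long_cut, template_photons = template_photons,
              output_dir = output_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialize / restore a pipeline configuration
#'
#' Round-trips a [pipeline_config()] through JSON.  The optics drift
#' specification must be serializable (`NULL` or a linear velocity pair);
#' arbitrary drift functions are a run-time-only convenience.
#'
#' @param config a `pipeline_config`.
#' @param file JSON path.
#' @return `config_to_json` returns `file` invisibly; `config_from_json`
#'   returns the restored `pipeline_config`.
#' @export
config_to_json <- function(config, file) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.function(config$optics$drift))
    stop("function-valued drift cannot be serialized; use a velocity pair")
  x <- unclass(config)
  x$kinetics <- unclass(x$kinetics)
  op <- unclass(x$optics)
  op$drift_fun <- NULL
  x$optics <- op
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' @rdname config_to_json
#' @export
config_from_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  kin <- do.call(kinetic_params, x$kinetics)
  op <- x$optics
  opt <- optics_params(image_size = op$image_size, pixel_size = op$pixel_size,
                       psf_sigma = op$psf_sigma,
                       photons_per_fluor = op$photons_per_fluor,
                       background_level = op$background_level,
                       read_noise_sd = op$read_noise_sd,
                       drift = if (is.null(op$drift)) NULL else unlist(op$drift))
  pipeline_config(mode = x$mode, seed = x$seed, n_spots = x$n_spots,
                  kinetics = kin, optics = opt, channels = x$channels,
                  registration_method = x$registration_method,
                  upsample = x$upsample,
                  threshold_sigmas = x$threshold_sigmas,
                  min_area = x$min_area, max_area = x$max_area,
                  min_persistence = x$min_persistence,
                  annulus = unlist(x$annulus), z_threshold = x$z_threshold,
                  min_on_frames = x$min_on_frames,
                  max_gap_frames = x$max_gap_frames,
                  simultaneity_tol = x$simultaneity_tol,
                  short_cut = x$short_cut, long_cut = x$long_cut,
                  template_photons = x$template_photons,
                  output_dir = x$output_dir)
}

#' Run the full colocalization analysis pipeline
#'
#' Orchestrates simulate (optional) -> render -> drift estimation and
#' correction -> template-spot detection -> trace extraction -> pulse
#' calling -> ternary residence analysis -> survival summaries, logging each
#' stage, and optionally writing every stage's artifact to
#' `config$output_dir`.  Identical configuration and seed give identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param movies in `"movies"` mode, a named list of [movie_stack()]s with
#'   the roles in `config$channels`.
#' @param quiet suppress progress messages.
#' @return A report list: detection counts, per-channel pulse tables, the
#'   residence records, off-rate estimates (`kt`, `kn`), arrival-order
#'   proportions, residence summaries, Kaplan-Meier medians, and in simulate
#'   mode the `ground_truth`.
#' @export
run_pipeline <- function(config, movies = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[3]
  truth <- NULL
  if (config$mode == "simulate") {
    say("simulating %d spots (seed %d)", config$n_spots, config$seed)
    truth <- simulate_pulse_trains(config$kinetics, config$n_spots,
                                   seed = config$seed,
                                   image_size = config$optics$image_size)
    say("rendering channels: %s", paste(config$channels, collapse = ", "))
    movies <- render_movie(truth, config$optics, seed = config$seed + 1L,
                           channels = config$channels,
                           template_photons = config$template_photons)
  }
  if (is.null(movies) || !all(config$channels %in% names(movies)))
    stop("movies must supply every configured channel: ",
         paste(config$channels, collapse = ", "))

  say("estimating drift (%s)", config$registration_method)
  path <- estimate_drift(movies$template, method = config$registration_method,
                         upsample = config$upsample)
  corrected <- lapply(movies[config$channels], apply_drift, path = path)

  say("detecting template spots")
  spots <- detect_spots(corrected$template,
                        threshold_sigmas = config$threshold_sigmas,
                        min_area = config$min_area, max_area = config$max_area,
                        min_persistence = config$min_persistence)
  say("  %d spots", nrow(spots$spots))

  prot_channels <- intersect(config$channels, c("target", "partner"))
  pulses <- list()
  traces <- list()
  for (ch in prot_channels) {
    say("extracting traces and calling pulses: %s", ch)
    traces[[ch]] <- extract_traces(corrected[[ch]], spots,
                                   annulus = config$annulus)
    pulses[[ch]] <- call_pulses_all(traces[[ch]], config$z_threshold,
                                    min_on_frames = config$min_on_frames,
                                    max_gap_frames = config$max_gap_frames)
  }

  target_pulses <- pulses$target
  records <- NULL
  rates <- list(kt = NULL, kn = NULL)
  order_prop <- NULL
  if (!is.null(target_pulses) && nrow(target_pulses)) {
    partner <- if ("partner" %in% names(pulses)) pulses$partner
               else target_pulses[0, ]
    records <- classify_ternary(target_pulses, partner,
                                simultaneity_tol = config$simultaneity_tol)
    rates <- estimate_off_rates(records)
    order_prop <- arrival_order(records, config$simultaneity_tol)
  }

  km <- NULL
  summaries <- NULL
  if (!is.null(target_pulses) && nrow(target_pulses)) {
    km <- kaplan_meier(target_pulses$duration, target_pulses$censored)
    summaries <- residence_summaries(target_pulses, nrow(spots$spots),
                                     short_cut = config$short_cut,
                                     long_cut = config$long_cut,
                                     records = records)
  }

  report <- list(config_seed = config$seed,
                 n_spots_detected = nrow(spots$spots),
                 drift = path,
                 spots = spots,
                 pulses = pulses,
                 records = records,
                 kt = rates$kt, kn = rates$kn,
                 arrival_order = order_prop,
                 summaries = summaries,
                 km_target = km,
                 median_lifetime_s = if (!is.null(km)) km$median else NA_real_,
                 ground_truth = truth,
                 elapsed_s = unname(proc.time()[3] - t0))
  if (!is.null(config$output_dir)) write_report(report, config)
  say("done in %.1f s", report$elapsed_s)
  invisible(report)
}

## Per-stage artifacts: CSVs for tables, JSON for the run-level summary.
write_report <- function(report, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  write_drift(report$drift, out("drift.csv"))
  utils::write.csv(report$spots$spots, out("spots.csv"), row.names = FALSE)
  for (ch in names(report$pulses))
    write_pulses(report$pulses[[ch]], out(sprintf("pulses_%s.csv", ch)))
  if (!is.null(report$records))
    utils::write.csv(report$records, out("residence_records.csv"),
                     row.names = FALSE)
  summary <- list(
    seed = config$seed,
    n_spots_detected = report$n_spots_detected,
    median_lifetime_s = report$median_lifetime_s,
    kt = report$kt[c("k", "n_events", "total_time", "se", "defined")],
    kn = report$kn[c("k", "n_events", "total_time", "se", "defined")],
    arrival_order = report$arrival_order[c("partner_first", "target_first",
                                           "simultaneous")],
    summaries = report$summaries)
  jsonlite::write_json(summary, out("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(NULL)
}
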