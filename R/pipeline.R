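#' Default pipeline configuration
#'
#' A nested list holding the parameter blocks of every stage with the
#' reference study conditions: a 3 cm droplet photographed every 5 min
#' (r0 = 15 mm at 0.05 mm/px), the composite front law (sqrt-t phase,
#' delamination onset at 240 min, contrast-collapse jump after
#' 420 min), and the 1 mm / 30 degree tilted-plate cuvette with
#' D_bulk = 1.676e-6 cm^2/s and a 1450 min lag (placing the top-edge
#' onset near 1500 min).  Files carry minutes and mm; physics runs in
#' seconds and cm.
#'
#' @param seed global integer seed.
#' @param out_dir optional output directory for [run_simulate()].
#' @return A config list.
#' @export
default_config <- function(seed = 1L, out_dir = NULL) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    units = list(length = "mm", time = "min"),
    generator = list(
      law = list(alpha = 1, t1 = 240, v2 = 0.05, t2 = 420, jump = NA),
      duration_min = 500,
      scene = list(droplet_radius_px = 300, image_size_px = c(640, 640),
                   mm_per_px = 0.05, frame_interval_min = 5,
                   n_frames = 100, noise_sd = 0,
                   illumination_gradient = 0),
      cuvette = list(D_bulk = 1.676e-6, offset_mm = 1, tilt_deg = 30,
                     plate_length_mm = 10, n_positions = 20,
                     lag_min = 1450, onset_noise = 0)),
    imaging = list(margin = 90, grayscale = "rec601"),
    phases = list(min_seg = 5),
    bulk = list(lag = "fit"))
}

# Build typed objects from the config, validating every numeric field
# against the owning module's preconditions before any work starts.
config_objects <- function(config) {
  g <- config$generator
  law_args <- g$law
  scene_args <- g$scene
  n_frames <- scene_args$n_frames
  step <- scene_args$frame_interval_min
  duration <- if (!is.null(g$duration_min)) g$duration_min
              else step * (n_frames - 1)
  if (is.null(law_args$jump) || is.na(law_args$jump)) {
    # default jump completes corrosion of the disk at the collapse
    tmp <- composite_front_law(law_args$alpha, law_args$t1, law_args$v2,
                               law_args$t2, jump = 0)
    law_args$jump <- max(0, scene_args$droplet_radius_px -
                              eval_front_law(tmp, law_args$t2))
  }
  law <- do.call(composite_front_law, law_args)
  scene <- scene_config(
    droplet_radius_px = scene_args$droplet_radius_px,
    image_size_px = scene_args$image_size_px,
    mm_per_px = scene_args$mm_per_px,
    frame_interval_min = step,
    n_frames = n_frames,
    noise_sd = scene_args$noise_sd,
    illumination_gradient = scene_args$illumination_gradient,
    seed = config$seed)
  cv <- g$cuvette
  geom <- plate_geometry(cv$offset_mm, cv$tilt_deg, cv$plate_length_mm)
  rule <- binarization_rule(config$imaging$margin,
                            config$imaging$grayscale)
  list(law = law, scene = scene, geom = geom, rule = rule,
       duration = duration, cuvette = cv)
}

#' Validate a pipeline configuration
#'
#' Checks every numeric field against the owning module's preconditions
#' (by constructing the typed objects) without doing any work or
#' writing any file.  Errors carry field-level messages.
#'
#' @param config a config list as from [default_config()].
#' @return Invisibly `TRUE`.
#' @export
validate_config <- function(config) {
  invisible(!is.null(config_objects(config)))
}

config_hash <- function(config) {
  config$out_dir <- NULL  # hash the analysis conditions, not the sink
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' Simulate the two experiments from a configuration
#'
#' Generates the droplet front trace (and, on request, the rendered
#' time-lapse frames) and the cuvette onset table, with the ground
#' truth echoed to a JSON sidecar so every downstream stage can be
#' scored.  Deterministic given the config seed.  When `out_dir` is set
#' the frames are rendered one at a time and streamed to PNG files so
#' long series do not accumulate in memory.
#'
#' @param config a config list as from [default_config()].
#' @param render whether to produce frames at all (in memory when
#'   `out_dir` is `NULL`).
#' @return A list of class `simulation_bundle`: `trace`
#'   ([front_trace()], noise-free truth), `frames` (`frame_series` or
#'   `NULL`), `cuvette` (onset table), `truth` (generator parameters),
#'   `files` (written paths, if any).
#' @export
run_simulate <- function(config = default_config(), render = TRUE) {
  obj <- config_objects(config)   # fail-fast validation, no files yet
  step <- obj$scene$frame_interval_min
  t <- seq(0, by = step, length.out = obj$scene$n_frames)
  trace <- front_trace(t = t, s = eval_front_law(obj$law, t))
  cv <- obj$cuvette
  cuvette <- simulate_cuvette(cv$D_bulk, obj$geom, cv$n_positions,
                              cv$lag_min, cv$onset_noise,
                              seed = config$seed)
  truth <- list(law = unclass(obj$law),
                scene = unclass(obj$scene),
                cuvette = list(D_bulk = cv$D_bulk, lag_min = cv$lag_min,
                               geom = unclass(obj$geom)),
                seed = config$seed,
                config_md5 = config_hash(config),
                version = as.character(utils::packageVersion("corrfront")),
                units = config$units)
  files <- character()
  frames <- NULL
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(files, write_front_trace(trace,
                                        file.path(out_dir, "trace.csv")))
    files <- c(files, write_cuvette_table(cuvette,
                                          file.path(out_dir, "cuvette.csv")))
    tj <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    files <- c(files, tj)
    if (render) {
      dist <- scene_dist(obj$scene)
      frame_dir <- file.path(out_dir, "frames")
      dir.create(frame_dir, showWarnings = FALSE)
      with_seed(obj$scene$seed, for (i in seq_along(t)) {
        img <- render_frame(obj$scene, trace$s[i], dist = dist)
        p <- file.path(frame_dir, sprintf("frame_%04d_t%06dmin.png", i,
                                          as.integer(round(t[i]))))
        png::writePNG(img / 255, p)
        files <- c(files, p)
      })
    }
  } else if (render) {
    frames <- render_frames(trace, obj$scene)
  }
  structure(list(trace = trace, frames = frames, cuvette = cuvette,
                 truth = truth, files = files),
            class = "simulation_bundle")
}

#' Analyze a droplet series and/or cuvette table end-to-end
#'
#' Runs the measurement pipeline: front extraction from images (when
#' frames are given; skipped for trace-only input), three-phase
#' segmentation, sqrt-t fit of the phase-I window, and (when a cuvette
#' table is present) the bulk-diffusivity estimate.  The report embeds
#' the config hash, seed and package version so identical configs give
#' identical reruns.
#'
#' @param config a config list as from [default_config()].
#' @param frames a `frame_series`, list of frames, or file paths;
#'   `NULL` to skip imaging.
#' @param trace a [front_trace()] or CSV path; ignored when `frames`
#'   are given.
#' @param cuvette an onset table (data frame or CSV path) or `NULL`.
#' @param times frame timestamps if `frames` is a bare list.
#' @return A list of class `analysis_report` with `alpha_hat`,
#'   `alpha_r2`, `t1_min`, `t2_min`, `v2_hat`, `D_bulk_cm2_s`,
#'   `lag_min`, plus `stages` (per-stage parameter echo) and
#'   `provenance` (config hash, seed, version).
#' @export
run_analyze <- function(config = default_config(), frames = NULL,
                        trace = NULL, cuvette = NULL, times = NULL) {
  obj <- config_objects(config)
  stages <- list()
  if (!is.null(frames)) {
    # analyse only the droplet region: a circle covering the corroded
    # annulus, excluding the (bright) background beyond the specimen
    roi <- circular_roi((obj$scene$image_size_px + 1) / 2,
                        obj$scene$corroded_outer_px)
    trace <- extract_front_trace(frames, times = times, rule = obj$rule,
                                 roi = roi)
    stages$imaging <- list(margin = obj$rule$margin,
                           grayscale = obj$rule$grayscale,
                           roi = unclass(roi),
                           n_frames = length(trace$t))
  } else {
    if (is.character(trace)) trace <- read_front_trace(trace)
    if (is.null(trace))
      stopf("run_analyze: need frames or a front trace")
    stages$imaging <- list(skipped = TRUE)
  }
  seg <- segment_phases(trace, min_seg = config$phases$min_seg)
  window <- if (!is.na(seg$t1)) c(0, seg$t1) else range(trace$t)
  fit <- fit_alpha(trace, window = window)
  stages$phases <- list(min_seg = config$phases$min_seg,
                        n_per_phase = as.list(seg$n_per_phase))
  stages$stefan_fit <- list(window_min = window, n = fit$n)
  report <- list(alpha_hat = fit$alpha_hat, alpha_r2 = fit$r_squared,
                 t1_min = seg$t1, t2_min = seg$t2, v2_hat = seg$v2_hat,
                 D_bulk_cm2_s = NA_real_, lag_min = NA_real_)
  if (!is.null(cuvette)) {
    if (is.character(cuvette)) cuvette <- read_cuvette_table(cuvette)
    est <- estimate_bulk_D(cuvette, obj$geom, lag = config$bulk$lag)
    report$D_bulk_cm2_s <- est$D_bar
    report$lag_min <- est$lag_min
    stages$bulk <- list(lag_mode = est$lag_mode,
                        interval = est$interval,
                        n = nrow(est$per_position))
  }
  report$stages <- stages
  report$provenance <- list(
    config_md5 = config_hash(config), seed = config$seed,
    version = as.character(utils::packageVersion("corrfront")),
    config = config)
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Corrosion-front analysis report:\n")
  cat(sprintf("  alpha_hat = %.4g (R^2 = %.4f)\n", x$alpha_hat,
              x$alpha_r2))
  if (!is.na(x$t1_min)) cat(sprintf("  t1 = %g min, v2_hat = %.4g\n",
                                    x$t1_min, x$v2_hat))
  if (!is.na(x$t2_min)) cat(sprintf("  t2 (contrast collapse) = %g min\n",
                                    x$t2_min))
  if (!is.na(x$D_bulk_cm2_s))
    cat(sprintf("  D_bulk = %.4g cm^2/s (lag %.4g min)\n",
                x$D_bulk_cm2_s, x$lag_min))
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' @param report an `analysis_report` from [run_analyze()].
#' @param path JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
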