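#' Composite three-phase front law
#'
#' Piecewise law for the corrosion-front length observed in the droplet
#' experiment: phase I follows interface diffusion, `s = alpha sqrt(t)`;
#' phase II (after delamination onset at `t1`) is linear with velocity
#' `v2`, continuous at `t1`; phase III (after `t2`) adds an
#' instantaneous advance `jump`, the artifact produced when bulk
#' corrosion collapses the image contrast and the threshold stops
#' discriminating the front.
#'
#' Length units are whatever the caller uses consistently (pixels by
#' default downstream); times in minutes.
#'
#' @param alpha phase-I front coefficient, length/sqrt(min), >= 0.
#' @param t1 phase I -> II changepoint, min.
#' @param v2 phase-II front velocity, length/min, >= 0.
#' @param t2 phase II -> III changepoint, min, > `t1`.
#' @param jump phase-III instantaneous front advance, length, >= 0.
#' @return An object of class `composite_front_law`.
#' @export
composite_front_law <- function(alpha = 1, t1 = 240, v2 = 0.05,
                                t2 = 420, jump = 250) {
  check_number(alpha, "alpha", 0)
  check_number(t1, "t1", 0)
  check_number(v2, "v2", 0)
  check_number(t2, "t2", 0)
  check_number(jump, "jump", 0)
  if (!(t1 < t2)) stopf("composite_front_law: need t1 < t2 (got %g, %g)",
                        t1, t2)
  structure(list(alpha = alpha, t1 = t1, v2 = v2, t2 = t2, jump = jump),
            class = "composite_front_law")
}

# s(t) for a composite_front_law, vectorized, noise-free.
eval_front_law <- function(law, t) {
  s1 <- law$alpha * sqrt(pmax(t, 0))
  s_t1 <- law$alpha * sqrt(law$t1)
  s2 <- s_t1 + law$v2 * (t - law$t1)
  s_t2 <- s_t1 + law$v2 * (law$t2 - law$t1)
  s3 <- s_t2 + law$jump
  ifelse(t <= law$t1, s1, ifelse(t <= law$t2, s2, s3))
}

#' Simulate a corrosion-front trace from the composite law
#'
#' Evaluates the three-phase law on a regular time grid, optionally with
#' additive Gaussian measurement noise (emulating rasterization and
#' segmentation scatter at trace level).
#'
#' @param law a [composite_front_law()].
#' @param duration total duration, min, > 0.
#' @param step sampling interval, min, > 0 (the frame cadence; the
#'   droplet experiment photographs every 5 min).
#' @param noise_sd additive Gaussian noise SD on `s`, same length unit,
#'   default 0.
#' @param seed optional integer seed for the noise (caller RNG state is
#'   preserved).
#' @return A [front_trace()] with `t` in minutes starting at 0.
#' @export
simulate_front_trace <- function(law, duration, step, noise_sd = 0,
                                 seed = NULL) {
  stopifnot(inherits(law, "composite_front_law"))
  check_number(duration, "duration", 0, strict_lower = TRUE)
  check_number(step, "step", 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  t <- seq(0, duration, by = step)
  s <- eval_front_law(law, t)
  if (noise_sd > 0) {
    e <- with_seed(seed, rnorm(length(t), sd = noise_sd))
    e[1] <- 0  # s is measured relative to the first frame, exactly 0 there
    s <- s + e
  }
  front_trace(t = t, s = s)
}

#' Scene configuration for rendered time-lapse frames
#'
#' Describes the synthetic droplet scene: a bright disk of protected
#' (uncorroded) copper of initial radius `droplet_radius_px`, surrounded
#' by dark corroded copper out to `corroded_outer_px`, on a neutral
#' background.  Colors are chosen so that the margin-90 grayscale
#' threshold (Rec. 601 luminance) separates corroded (below) from
#' protected and background (above); they are rendering conventions, not
#' measured values.
#'
#' @param droplet_radius_px initial protected radius r0, px, >= 10.
#' @param image_size_px integer pair (height, width).
#' @param mm_per_px pixel calibration, mm, > 0.
#' @param frame_interval_min frame cadence, min (default 5).
#' @param n_frames number of frames, >= 2.
#' @param protected_color,corroded_color,background_color RGB triples in
#'   0-255.
#' @param noise_sd additive Gaussian pixel noise SD on the 0-255 scale.
#' @param illumination_gradient peak-to-trough additive illumination ramp
#'   across the image width, 0-255 units, >= 0.
#' @param corroded_outer_px outer radius of the corroded annulus;
#'   default fills the frame to 2 px from the nearest edge.
#' @param seed integer seed controlling the pixel noise.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(droplet_radius_px = 300,
                         image_size_px = c(640, 640),
                         mm_per_px = 0.05,
                         frame_interval_min = 5,
                         n_frames = 100,
                         protected_color = c(200, 110, 50),
                         corroded_color = c(35, 25, 20),
                         background_color = c(120, 120, 120),
                         noise_sd = 0,
                         illumination_gradient = 0,
                         corroded_outer_px = NULL,
                         seed = 1L) {
  check_number(droplet_radius_px, "droplet_radius_px", 10)
  stopifnot(length(image_size_px) == 2, all(image_size_px >= 16))
  check_number(mm_per_px, "mm_per_px", 0, strict_lower = TRUE)
  check_number(frame_interval_min, "frame_interval_min", 0,
               strict_lower = TRUE)
  if (n_frames < 2) stopf("scene_config: n_frames must be >= 2, got %g",
                          n_frames)
  check_number(noise_sd, "noise_sd", 0)
  check_number(illumination_gradient, "illumination_gradient", 0)
  for (nm in c("protected_color", "corroded_color", "background_color")) {
    v <- get(nm)
    if (length(v) != 3 || any(v < 0) || any(v > 255))
      stopf("scene_config: %s must be an RGB triple in 0-255", nm)
  }
  if (is.null(corroded_outer_px))
    corroded_outer_px <- floor(min(image_size_px) / 2) - 2
  if (droplet_radius_px >= corroded_outer_px)
    stopf(paste0("scene_config: droplet (r0 = %g px) must fit inside the ",
                 "corroded region (outer radius %g px)"),
          droplet_radius_px, corroded_outer_px)
  grays <- vapply(list(protected_color, corroded_color, background_color),
                  function(v) round(sum(c(0.299, 0.587, 0.114) * v)), 0)
  if (!(grays[1] > 90 && grays[3] > 90 && grays[2] <= 90))
    warning("scene colors do not separate under the default margin-90 ",
            "Rec. 601 rule; front extraction with defaults will fail",
            call. = FALSE)
  structure(list(droplet_radius_px = droplet_radius_px,
                 image_size_px = as.integer(image_size_px),
                 mm_per_px = mm_per_px,
                 frame_interval_min = frame_interval_min,
                 n_frames = as.integer(n_frames),
                 protected_color = protected_color,
                 corroded_color = corroded_color,
                 background_color = background_color,
                 noise_sd = noise_sd,
                 illumination_gradient = illumination_gradient,
                 corroded_outer_px = corroded_outer_px,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Squared distance (px) of every pixel center from the image center.
scene_dist <- function(scene) {
  h <- scene$image_size_px[1]; w <- scene$image_size_px[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  dy2 <- (seq_len(h) - cy)^2
  dx2 <- (seq_len(w) - cx)^2
  sqrt(outer(dy2, dx2, `+`))
}

#' Render a single frame of the droplet scene
#'
#' @param scene a [scene_config()].
#' @param s front length at this time, px (protected radius is
#'   `r0 - s`).
#' @param dist optional precomputed distance matrix from an internal
#'   cache (used by [render_frames()]).
#' @param add_noise whether to apply the scene's pixel noise (drawn from
#'   the current RNG stream).
#' @return An integer array `height x width x 3` with values 0-255.
#' @export
render_frame <- function(scene, s, dist = NULL, add_noise = TRUE) {
  stopifnot(inherits(scene, "scene_config"))
  r0 <- scene$droplet_radius_px
  if (!is.finite(s) || s < 0)
    stopf("render_frame: front length must be finite and >= 0, got %g", s)
  if (s > r0)
    stopf(paste0("render_frame: front length s = %g px exceeds the initial ",
                 "radius r0 = %g px (corrosion is complete; no frame beyond ",
                 "full corrosion)"), s, r0)
  if (is.null(dist)) dist <- scene_dist(scene)
  h <- scene$image_size_px[1]; w <- scene$image_size_px[2]
  rt <- r0 - s
  corroded <- dist <= scene$corroded_outer_px
  protected <- dist <= rt
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(scene$background_color[ch], h, w)
    plane[corroded] <- scene$corroded_color[ch]
    plane[protected] <- scene$protected_color[ch]
    img[, , ch] <- plane
  }
  if (scene$illumination_gradient > 0) {
    ramp <- scene$illumination_gradient *
      ((seq_len(w) - 1) / (w - 1) - 0.5)
    img <- img + rep(matrix(ramp, h, w, byrow = TRUE), 3)
  }
  if (add_noise && scene$noise_sd > 0)
    img <- img + rnorm(length(img), sd = scene$noise_sd)
  img <- round(img)
  img[img < 0] <- 0
  img[img > 255] <- 255
  storage.mode(img) <- "integer"
  img
}

#' Render a time-lapse image series from a front trace
#'
#' Produces one frame per trace point, deterministic given the scene
#' seed.  Frame `i` shows a protected disk of radius
#' `r0 - s(t_i)`; rejects traces whose front exceeds `r0`.
#'
#' @param trace a [front_trace()] with `s` in pixels.
#' @param scene a [scene_config()].
#' @return A list of class `frame_series`: `frames` (list of integer
#'   arrays), `t` (minutes), `scene`.
#' @export
render_frames <- function(trace, scene) {
  stopifnot(inherits(scene, "scene_config"))
  if (any(trace$s > scene$droplet_radius_px))
    stopf(paste0("render_frames: trace exceeds full corrosion ",
                 "(max s = %g px > r0 = %g px)"),
          max(trace$s), scene$droplet_radius_px)
  dist <- scene_dist(scene)
  frames <- with_seed(scene$seed, lapply(trace$s, function(si)
    render_frame(scene, si, dist = dist)))
  structure(list(frames = frames, t = trace$t, scene = scene),
            class = "frame_series")
}

#' Simulate tilted-plate cuvette onset times
#'
#' Forward model of the bulk-diffusion experiment: a copper plate sits
#' tilted in a cuvette under a polymer layer whose thickness grows along
#' the plate, `h(y) = offset + y tan(tilt)`.  Each layer acts as a
#' membrane; visible corrosion at position `y` sets on when the species
#' has traversed it, `onset(y) = lag + h(y)^2 / (2 D_bulk)`.
#'
#' @param D_bulk bulk diffusivity, cm^2/s, > 0.
#' @param geom a [plate_geometry()] (mm).
#' @param n_positions number of equally spaced positions along the
#'   plate, >= 2.
#' @param lag lag time before diffusion effectively starts, min, >= 0.
#'   The default geometry with `lag = 1450` places the top-edge onset at
#'   about 1500 min for `D_bulk = 1.676e-6` cm^2/s.
#' @param onset_noise multiplicative Gaussian noise SD on onset times
#'   (0 = exact).
#' @param seed optional integer seed for the noise.
#' @return A data frame with columns `y_mm` and `onset_min`
#'   (nondecreasing in `y` when noise-free), with the ground truth
#'   attached as attribute `truth`.
#' @export
simulate_cuvette <- function(D_bulk, geom, n_positions = 20, lag = 1450,
                             onset_noise = 0, seed = NULL) {
  check_number(D_bulk, "D_bulk", 0, strict_lower = TRUE)
  stopifnot(inherits(geom, "plate_geometry"))
  if (n_positions < 2) stopf("simulate_cuvette: n_positions must be >= 2")
  check_number(lag, "lag", 0)
  check_number(onset_noise, "onset_noise", 0)
  y <- seq(0, geom$plate_length_mm, length.out = n_positions)
  h_cm <- mm_to_cm(layer_thickness(geom, y))
  onset <- lag + s_to_min(h_cm^2 / (2 * D_bulk))
  if (onset_noise > 0)
    onset <- onset * (1 + with_seed(seed,
                                    rnorm(length(onset), sd = onset_noise)))
  out <- data.frame(y_mm = y, onset_min = onset)
  attr(out, "truth") <- list(D_bulk = D_bulk, lag_min = lag, geom = geom)
  out
}
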