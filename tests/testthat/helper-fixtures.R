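# Shared fixtures: small scenes and parameter sets sized for fast tests.

test_scene <- function(r0 = 100, size = 256, n_frames = 30, noise_sd = 0,
                       seed = 7, ...) {
  scene_config(droplet_radius_px = r0, image_size_px = c(size, size),
               n_frames = n_frames, noise_sd = noise_sd, seed = seed, ...)
}

# ROI covering the corroded annulus but not the bright background.
test_roi <- function(scene) {
  c0 <- (scene$image_size_px + 1) / 2
  circular_roi(c0, scene$corroded_outer_px)
}

# Pure sqrt-t law (changepoints pushed beyond any test horizon).
sqrt_law <- function(alpha = 1) {
  composite_front_law(alpha = alpha, t1 = 1e7, v2 = 0, t2 = 2e7, jump = 0)
}

ref_params <- function() stefan_params(D = 1e-6, C0 = 1, S = 10)

# Uniform-color 8-bit frame.
uniform_frame <- function(rgb, h = 8, w = 8) {
  img <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- as.integer(rgb[ch])
  img
}
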