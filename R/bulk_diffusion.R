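#' Tilted-plate cuvette geometry
#'
#' A copper plate sits tilted at `tilt_deg` in a cuvette under the
#' polymer; the polymer layer above position `y` along the plate has
#' thickness `h(y) = offset + y * tan(tilt)` — the opposite cathetus of
#' the tilt triangle plus the layer height over the upper edge.  The
#' reference cuvette has a 1 mm offset and a 30 degree tilt.
#'
#' @param offset_mm layer thickness over the plate's upper edge, mm,
#'   >= 0.
#' @param tilt_deg plate tilt, degrees, in `[0, 89]`.
#' @param plate_length_mm plate length along the slant, mm, > 0.
#' @return An object of class `plate_geometry`.
#' @export
plate_geometry <- function(offset_mm = 1, tilt_deg = 30,
                           plate_length_mm = 10) {
  check_number(offset_mm, "offset_mm", 0)
  check_number(tilt_deg, "tilt_deg", 0, upper = 89)
  check_number(plate_length_mm, "plate_length_mm", 0, strict_lower = TRUE)
  structure(list(offset_mm = offset_mm, tilt_deg = tilt_deg,
                 plate_length_mm = plate_length_mm),
            class = "plate_geometry")
}

#' Polymer layer thickness above a plate position
#'
#' @param geom a [plate_geometry()].
#' @param y_mm position(s) along the plate, mm, in
#'   `[0, plate_length_mm]`.
#' @return Thickness `h = offset + y * tan(tilt)`, mm.
#' @export
layer_thickness <- function(geom, y_mm) {
  stopifnot(inherits(geom, "plate_geometry"))
  if (any(!is.finite(y_mm)) || any(y_mm < 0) ||
      any(y_mm > geom$plate_length_mm))
    stopf("layer_thickness: y must lie in [0, %g] mm",
          geom$plate_length_mm)
  geom$offset_mm + y_mm * tan(geom$tilt_deg * pi / 180)
}

#' Einstein-Smoluchowski diffusivity from a traversal time
#'
#' `D = h^2 / (2 t)`: the diffusivity of a species that needs time `t`
#' to traverse a membrane of thickness `h`.  Units are consistent:
#' cm^2/s when `h` is in cm and `t` in s.
#'
#' @param h membrane (layer) thickness, >= 0.
#' @param t traversal time, > 0.
#' @return Diffusivity `h^2 / (2 t)`.
#' @examples
#' einstein_smoluchowski(0.1, 2983)  # ~1.676e-6 cm^2/s
#' @export
einstein_smoluchowski <- function(h, t) {
  if (any(!is.finite(h)) || any(h < 0))
    stopf("einstein_smoluchowski: h must be finite and >= 0")
  if (any(!is.finite(t)) || any(t <= 0))
    stopf("einstein_smoluchowski: t must be > 0")
  h^2 / (2 * t)
}

# Maximal contiguous run of indices over which onset vs y is linear
# (expanding-window least squares, R^2 >= r2_min).  Runs of length 2
# are trivially linear and not accepted; need >= 3 points.
linear_interval <- function(y, t, r2_min = 0.98) {
  n <- length(y)
  best <- c(1L, 0L)
  for (i in seq_len(n - 2)) {
    jmax <- i + 1L
    for (j in (i + 2L):n) {
      yy <- y[i:j]; tt <- t[i:j]
      f <- .lm.fit(cbind(1, yy), tt)
      sse <- sum(f$residuals^2)
      sst <- sum((tt - mean(tt))^2)
      r2 <- if (sst > 0) 1 - sse / sst else 1
      if (r2 >= r2_min) jmax <- j else break
    }
    if (jmax - i > best[2] - best[1]) best <- c(i, jmax)
  }
  if (best[2] - best[1] + 1L < 3L) return(NULL)
  best
}

#' Estimate the bulk diffusivity from tilted-plate onset times
#'
#' Inverts the membrane picture of the cuvette experiment: at each
#' position the layer thickness `h(y)` follows from the geometry and the
#' per-position diffusivity is `D_i = h_i^2 / (2 (t_i - lag))`
#' (Einstein-Smoluchowski).  The average is taken over the maximal
#' contiguous run of positions where onset vs `y` is linear (expanding
#' window, R^2 >= 0.98) — the regime where corrosion migrates steadily
#' along the plate, away from the early plateau and late saturation.
#'
#' Lag handling: `lag = "fit"` (default) estimates the lag as the
#' intercept of the regression `t = lag + h^2 / (2 D)`; a numeric `lag`
#' (minutes) is subtracted as given.  The mode is recorded in the
#' result.
#'
#' @param onsets data frame with columns `y_mm`, `onset_min` (>= 3
#'   rows, `y` increasing).
#' @param geom a [plate_geometry()].
#' @param lag `"fit"` or a fixed lag in minutes.
#' @return A list of class `bulk_D_estimate`: `D_bar` (cm^2/s), `D_fit`
#'   (regression-slope estimate, cm^2/s; `NA` for fixed lag), `lag_min`,
#'   `lag_mode`, `per_position` (data frame `y_mm`, `h_mm`, `onset_min`,
#'   `D_cm2_s`, `in_interval`), `interval` (index range of the linear
#'   run).
#' @export
estimate_bulk_D <- function(onsets, geom, lag = "fit") {
  stopifnot(inherits(geom, "plate_geometry"))
  for (col in c("y_mm", "onset_min"))
    if (!col %in% names(onsets))
      stopf("estimate_bulk_D: onset table is missing column '%s'", col)
  if (nrow(onsets) < 3)
    stopf("estimate_bulk_D: need >= 3 positions, got %d", nrow(onsets))
  y <- onsets$y_mm
  if (any(diff(y) <= 0))
    stopf("estimate_bulk_D: y_mm must be strictly increasing")
  h_cm <- mm_to_cm(layer_thickness(geom, y))
  t_s <- min_to_s(onsets$onset_min)
  h2 <- h_cm^2

  fitted <- identical(lag, "fit")
  D_fit <- NA_real_
  if (fitted) {
    if (var(h2) == 0)
      stopf(paste0("estimate_bulk_D: degenerate regression - all layer ",
                   "thicknesses are equal (tilt = %g deg); cannot fit a lag"),
            geom$tilt_deg)
    f <- lm(t_s ~ h2)
    lag_s <- unname(coef(f)[1])
    slope <- unname(coef(f)[2])
    if (!is.finite(slope) || slope <= 0)
      stopf("estimate_bulk_D: fitted slope of t vs h^2 is not positive")
    D_fit <- 1 / (2 * slope)
  } else {
    check_number(lag, "lag", 0)
    lag_s <- min_to_s(lag)
  }
  bad <- which(t_s - lag_s <= 0)
  if (length(bad) > 0)
    stopf(paste0("estimate_bulk_D: onset <= lag (%g min) at row(s) %s; ",
                 "per-position diffusivities undefined there"),
          s_to_min(lag_s), paste(bad, collapse = ", "))
  D_i <- h2 / (2 * (t_s - lag_s))

  iv <- linear_interval(y, t_s)
  if (is.null(iv))
    stopf(paste0("estimate_bulk_D: fewer than 3 points in the linear ",
                 "interval (R^2 >= 0.98); onset vs y is not locally linear"))
  in_iv <- seq_along(y) >= iv[1] & seq_along(y) <= iv[2]
  structure(list(
    D_bar = mean(D_i[in_iv]),
    D_fit = D_fit,
    lag_min = s_to_min(lag_s),
    lag_mode = if (fitted) "fit" else "fixed",
    per_position = data.frame(y_mm = y, h_mm = cm_to_mm(h_cm),
                              onset_min = onsets$onset_min,
                              D_cm2_s = D_i, in_interval = in_iv),
    interval = iv),
    class = "bulk_D_estimate")
}

#' @export
print.bulk_D_estimate <- function(x, ...) {
  cat(sprintf(
    "Bulk diffusivity: D_bar = %.4g cm^2/s over linear interval [%d, %d]\n",
    x$D_bar, x$interval[1], x$interval[2]))
  cat(sprintf("  lag = %.4g min (%s)", x$lag_min, x$lag_mode))
  if (is.finite(x$D_fit))
    cat(sprintf("; regression D = %.4g cm^2/s", x$D_fit))
  cat("\n")
  invisible(x)
}

#' Write / read a cuvette onset table as CSV
#'
#' Columns `y_mm`, `onset_min`.
#'
#' @param onsets data frame from [simulate_cuvette()] or measured.
#' @param path CSV path.
#' @export
write_cuvette_table <- function(onsets, path) {
  write.csv(onsets[c("y_mm", "onset_min")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cuvette_table
#' @export
read_cuvette_table <- function(path) {
  df <- read.csv(path)
  for (col in c("y_mm", "onset_min"))
    if (!col %in% names(df))
      stopf("read_cuvette_table: %s is missing required column '%s'",
            path, col)
  df
}
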