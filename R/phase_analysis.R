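#' Segment a front trace into the three corrosion phases
#'
#' Front traces from the droplet experiment divide into three
#' characteristic segments: phase I, undisturbed interface diffusion
#' (`s = alpha sqrt(t)`); phase II, corrosion-triggered delamination
#' with a steady-state-like linear advance, continuous at the
#' changepoint `t1`; and phase III, a sharp artifactual jump when bulk
#' corrosion collapses the image contrast and the threshold stops
#' discriminating the front.
#'
#' Phase III is detected first, as the largest forward jump in `s`
#' exceeding 5 local (robust) SDs of the inter-frame increments; points
#' after the jump are labelled and excluded from fitting, because the
#' jump is an artifact, not front physics.  The changepoint `t1` is then
#' found by exhaustive search over observed timestamps: for each
#' candidate the continuous sqrt-linear model is fit by least squares
#' and the SSE-minimizing candidate wins.  When the two-phase model
#' improves on the best single-phase sqrt(t) fit by less than 5% of its
#' SSE, a single-phase result is returned (`t1` absent).
#'
#' @param trace a [front_trace()] (minutes / px, or any consistent
#'   units).
#' @param min_seg minimum points per retained phase (default 5).
#' @return An object of class `phase_segmentation`: `t1`, `t2` (`NA`
#'   when absent), `alpha_hat`, `v2_hat`, `sse`, `n_per_phase`
#'   (named counts), `phase` (per-point labels 1/2/3).
#' @export
segment_phases <- function(trace, min_seg = 5) {
  t <- trace$t; s <- trace$s
  n <- length(t)
  if (n < 3 * min_seg)
    stopf("segment_phases: need >= %d points (3*min_seg), got %d",
          3 * min_seg, n)
  if (any(diff(t) <= 0))
    stopf("segment_phases: timestamps must be strictly increasing")

  # --- phase III: largest increment jump > 5 robust SDs ---
  # Each increment is compared against the median of its trailing
  # window, so the steep (but decelerating) sqrt-t start is not
  # mistaken for the late contrast-collapse jump.
  d <- diff(s)
  # scale: robust SD of the increments, floored by the median absolute
  # increment (mad() alone collapses to 0 on piecewise-constant
  # increments, where the t1 kink would masquerade as a jump)
  sd_loc <- max(mad(d), stats::median(abs(d)), 1e-9 * max(abs(s), 1))
  excess <- vapply(seq_along(d), function(i) {
    if (i == 1) return(-Inf)
    d[i] - stats::median(d[max(1, i - 5):(i - 1)])
  }, 0)
  jumps <- which(excess > 5 * sd_loc)
  t2 <- NA_real_
  keep <- seq_len(n)
  if (length(jumps) > 0) {
    j <- jumps[which.max(excess[jumps])]
    t2 <- t[j]            # last time before the contrast collapse
    keep <- seq_len(j)
  }
  tk <- t[keep]; sk <- s[keep]
  m <- length(tk)
  phase <- rep(3L, n)

  # --- single-phase fit (alpha sqrt(t), no intercept) ---
  stk <- sqrt(tk)
  alpha0 <- if (sum(tk) > 0) sum(sk * stk) / sum(tk) else 0
  sse0 <- sum((sk - alpha0 * stk)^2)

  # --- exhaustive t1 search with continuity at t1 ---
  best <- list(sse = Inf, k = NA_integer_, alpha = NA_real_,
               v2 = NA_real_)
  if (m >= 2 * min_seg) {
    for (k in min_seg:(m - min_seg)) {   # t1 = tk[k]
      t1c <- tk[k]
      x1 <- ifelse(tk <= t1c, stk, sqrt(t1c))
      x2 <- pmax(tk - t1c, 0)
      f <- .lm.fit(cbind(x1, x2), sk)
      sse <- sum(f$residuals^2)
      if (sse < best$sse)
        best <- list(sse = sse, k = k, alpha = f$coefficients[1],
                     v2 = f$coefficients[2])
    }
  }

  scale_sse <- max(sum(sk^2), .Machine$double.eps)
  two_phase <- is.finite(best$sse) &&
    sse0 > 1e-12 * scale_sse &&
    (sse0 - best$sse) / sse0 >= 0.05
  if (two_phase) {
    t1 <- tk[best$k]
    phase[keep] <- ifelse(tk <= t1, 1L, 2L)
    out <- list(t1 = t1, t2 = t2, alpha_hat = unname(best$alpha),
                v2_hat = unname(best$v2), sse = best$sse)
  } else {
    phase[keep] <- 1L
    out <- list(t1 = NA_real_, t2 = t2, alpha_hat = alpha0,
                v2_hat = NA_real_, sse = sse0)
  }
  out$sse_single <- sse0
  out$n_per_phase <- c(I = sum(phase == 1L), II = sum(phase == 2L),
                       III = sum(phase == 3L))
  out$phase <- phase
  structure(out, class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat("Three-phase segmentation:\n")
  if (is.na(x$t1)) cat(sprintf(
    "  single sqrt-t phase: alpha_hat = %g\n", x$alpha_hat))
  else cat(sprintf(
    "  t1 = %g min, alpha_hat = %g, v2_hat = %g\n",
    x$t1, x$alpha_hat, x$v2_hat))
  if (!is.na(x$t2)) cat(sprintf(
    "  phase-III contrast-collapse jump after t2 = %g min\n", x$t2))
  cat(sprintf("  points per phase: I = %d, II = %d, III = %d (SSE = %.4g)\n",
              x$n_per_phase[1], x$n_per_phase[2], x$n_per_phase[3], x$sse))
  invisible(x)
}

#' Delamination front trailing the diffusion front at constant lag
#'
#' The point of delamination correlates with the diffusion front,
#' following it at a constant distance `delta`: the polymer detaches
#' where the interface concentration has reached `Climit`, a fixed
#' distance behind the visible (`Ci`) front.  Elementwise,
#' `d(t) = max(0, X(t) - delta)`.
#'
#' @param X diffusion-front positions (any consistent length unit).
#' @param delta constant lag distance, same unit, >= 0.
#' @param t optional times carried through to the result.
#' @return An object of class `delamination_state`: `delta`, `d`
#'   (positions), `t`.
#' @export
delamination_front <- function(X, delta, t = NULL) {
  check_number(delta, "delta", 0)
  if (any(!is.finite(X))) stopf("delamination_front: X must be finite")
  structure(list(delta = delta, d = pmax(0, X - delta), X = X, t = t),
            class = "delamination_state")
}

#' Steady-state membrane rate of the delamination-driven front
#'
#' In phase II the not-yet-delaminated polymer between the delamination
#' edge and the diffusion front acts as a membrane of fixed width
#' `delta`: the cavity behind the delamination edge floods to the bath
#' concentration `C0`, the front consumes `S` per unit advance, and the
#' steady-state flux across the membrane sets the front velocity
#' \deqn{v_2 = \frac{D\,C_0}{S\,\delta}.}{v2 = D*C0/(S*delta).}
#'
#' @param p a [stefan_params()].
#' @param delta membrane width (constant delamination lag), cm, > 0.
#' @return Front velocity, cm/s.
#' @export
steady_state_membrane_rate <- function(p, delta) {
  stopifnot(inherits(p, "stefan_params"))
  if (!is.numeric(delta) || length(delta) != 1 || !is.finite(delta) ||
      delta <= 0)
    stopf(paste0("steady_state_membrane_rate: delta must be > 0 ",
                 "(delta = 0 gives an unbounded rate)"))
  p$D * p$C0 / (p$S * delta)
}

#' Predict when interface and bulk failure paths merge
#'
#' Two routes lead to global delamination: the composite interface front
#' (phase-I sqrt(t) until the delamination lag `delta` is established,
#' then the phase-II membrane-limited linear advance) traversing the
#' droplet radius, and bulk diffusion through the polymer cover
#' reaching the buried interface.  Whichever arrives first sets the
#' failure mode; when both arrive on comparable time scales they merge
#' into near-simultaneous global delamination.
#'
#' All arguments in CGS units (cm, cm^2/s); times returned in s.
#'
#' @param p a [stefan_params()].
#' @param D_bulk bulk diffusivity, cm^2/s, >= 0 (0 = no bulk route).
#' @param cover_thickness polymer cover thickness above the interface,
#'   cm, > 0.
#' @param r0 droplet radius the interface front must traverse, cm, > 0
#'   (may be `Inf`).
#' @param delta constant delamination lag, cm, > 0.
#' @return A list of class `merge_prediction`: `t_interface`, `t_bulk`,
#'   `t_merge` (s), and `mode` (`"interface"`, `"bulk"`, or
#'   `"no failure within horizon"` when both are infinite).
#' @export
predict_merge <- function(p, D_bulk, cover_thickness, r0, delta) {
  stopifnot(inherits(p, "stefan_params"))
  check_number(D_bulk, "D_bulk", 0)
  check_number(cover_thickness, "cover_thickness", 0, strict_lower = TRUE)
  check_number(r0, "r0", 0, strict_lower = TRUE, allow_inf = TRUE)
  check_number(delta, "delta", 0, strict_lower = TRUE)
  alpha <- suppressWarnings(goodman_alpha(p)$alpha)
  t_interface <- if (alpha == 0 || !is.finite(r0)) {
    Inf
  } else if (r0 <= delta) {
    (r0 / alpha)^2
  } else {
    v2 <- steady_state_membrane_rate(p, delta)
    (delta / alpha)^2 + (r0 - delta) / v2
  }
  t_bulk <- if (D_bulk > 0) cover_thickness^2 / (2 * D_bulk) else Inf
  t_merge <- min(t_interface, t_bulk)
  mode <- if (!is.finite(t_merge)) "no failure within horizon"
          else if (t_interface <= t_bulk) "interface" else "bulk"
  structure(list(t_interface = t_interface, t_bulk = t_bulk,
                 t_merge = t_merge, mode = mode),
            class = "merge_prediction")
}

#' @export
print.merge_prediction <- function(x, ...) {
  cat(sprintf(
    "Merge prediction: mode = %s, t_merge = %g s\n", x$mode, x$t_merge))
  cat(sprintf("  t_interface = %g s, t_bulk = %g s\n",
              x$t_interface, x$t_bulk))
  invisible(x)
}
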