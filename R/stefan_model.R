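#' Parameters of the interface-diffusion Stefan problem
#'
#' Bundles the physical constants of the one-phase moving-boundary model
#' of interface diffusion: corroding species diffuse along the
#' metal-polymer interface from a bath held at concentration `C0`,
#' and are immobilized at the corrosion front, which consumes an amount
#' `S` per unit front advance (per unit cross-section).  Concentrations
#' `Ci` (visible-corrosion indicator) and `Climit` (adhesion-failure
#' trigger) locate the observable front and the delamination front on the
#' concentration axis; they order as `0 < Ci <= Climit <= C0`.
#'
#' Units are CGS: lengths in cm, times in s, `D` in cm^2/s; `C0`, `S`,
#' `Ci`, `Climit` share one (arbitrary) amount/volume unit.
#'
#' @param D interface diffusivity, cm^2/s, > 0.
#' @param C0 bath boundary concentration, >= 0.
#' @param S immobilized amount per unit boundary advance (same
#'   concentration unit as `C0`), > 0.
#' @param l surface-layer capacity length, cm, >= 0.  `l = 0` (default)
#'   means the bath holds `C(0, t) = C0` fixed; `l > 0` models a finite
#'   well-stirred reservoir of depth `l` initially at `C0` that depletes
#'   as material enters the interface (experimental).
#' @param Ci indicator concentration at which corrosion becomes visible;
#'   default `0.1 * C0`.
#' @param Climit concentration at which adhesion fails and the polymer
#'   delaminates; default `0.5 * C0`.
#' @return An object of class `stefan_params`.
#' @examples
#' p <- stefan_params(D = 1e-6, C0 = 1, S = 10)
#' goodman_alpha(p)$alpha
#' @export
stefan_params <- function(D, C0, S, l = 0,
                          Ci = 0.1 * C0, Climit = 0.5 * C0) {
  check_number(D, "D", 0, strict_lower = TRUE)
  check_number(C0, "C0", 0)
  check_number(S, "S", 0, strict_lower = TRUE)
  check_number(l, "l", 0)
  if (C0 > 0) {
    check_number(Ci, "Ci", 0, strict_lower = TRUE)
    check_number(Climit, "Climit", 0)
    if (!(Ci <= Climit && Climit <= C0))
      stopf("need 0 < Ci <= Climit <= C0, got Ci = %g, Climit = %g, C0 = %g",
            Ci, Climit, C0)
  }
  structure(list(D = D, C0 = C0, S = S, l = l, Ci = Ci, Climit = Climit),
            class = "stefan_params")
}

#' @export
print.stefan_params <- function(x, ...) {
  cat("Stefan interface-diffusion parameters (cm, s):\n")
  cat(sprintf("  D = %g cm^2/s, C0 = %g, S = %g, l = %g cm\n",
              x$D, x$C0, x$S, x$l))
  cat(sprintf("  Ci = %g, Climit = %g\n", x$Ci, x$Climit))
  invisible(x)
}

# Shape equation of the heat-balance-integral solution.  With the
# quadratic profile C = C0 * (a*xi + b*xi^2), xi = 1 - x/X, a + b = 1
# (surface value C0), the Stefan condition gives alpha^2 = 2*D*beta*a
# (beta = C0/S) and the integrated diffusion equation gives
# alpha^2 = 4*D*b / (a/2 + b/3).  Eliminating alpha:
#   g(b) = 4*b - 2*beta*(1 - b)*((1 - b)/2 + b/3) = 0,  b in (0, 1).
# goodman_alpha() root-finds the equivalent residual in alpha.
hbi_residual <- function(alpha, D, beta) {
  a <- alpha^2 / (2 * D * beta)
  b <- 1 - a
  alpha^2 - 4 * D * b / (a / 2 + b / 3)
}

#' Goodman heat-balance-integral solution of the moving boundary
#'
#' Solves the one-phase Stefan sorption problem approximately with
#' Goodman's integral method.  A quadratic concentration profile
#' \deqn{C(x,t) = C_0\,[\,a\,(1 - x/X) + b\,(1 - x/X)^2\,]}{
#'   C(x,t) = C0 * (a*(1 - x/X) + b*(1 - x/X)^2)}
#' is required to satisfy (i) `C(X) = 0` at the front, (ii) the surface
#' condition at `x = 0` (constant bath concentration `C0` in the default
#' `l = 0` configuration), (iii) the Stefan condition
#' `S dX/dt = -D dC/dx` at `x = X`, and (iv) the spatially integrated
#' diffusion equation over `[0, X]`.  These force `X = alpha sqrt(t)`;
#' `alpha` is found by root-finding on the resulting scalar equation,
#' bracketed in `(0, sqrt(2 D C0 / S) * 10]` with up to 10 bracket
#' doublings, relative tolerance 1e-10.
#'
#' For `l > 0` the closed form neglects reservoir depletion and is valid
#' while the drawn mass is small against the reservoir capacity
#' `l * C0`; a warning marks this regime assumption.  Use [fd_solve()]
#' for the full depleting-reservoir dynamics.
#'
#' @param p a [stefan_params()] object.
#' @return An object of class `moving_boundary_solution` with fields
#'   `alpha` (front coefficient, cm/sqrt(s)), `a`, `b` (dimensionless
#'   profile coefficients in the similarity variable `xi = 1 - x/X`, with
#'   `a + b = 1` for `C0 > 0`), and diagnostics (`beta = C0/S`,
#'   `residual` of the solved equation).
#' @seealso [front_position()], [goodman_profile()], [fd_solve()],
#'   [stefan_alpha_exact()]
#' @export
goodman_alpha <- function(p) {
  stopifnot(inherits(p, "stefan_params"))
  if (p$C0 == 0)
    return(structure(list(alpha = 0, a = 0, b = 0, beta = 0, residual = 0),
                     class = "moving_boundary_solution"))
  if (p$l > 0)
    warning("l > 0: closed form assumes an undepleted surface reservoir ",
            "(valid while S*X << l*C0); use fd_solve() for depletion",
            call. = FALSE)
  beta <- p$C0 / p$S
  upper0 <- sqrt(2 * p$D * beta) * 10
  lower <- upper0 * 1e-12
  upper <- upper0
  g <- function(alpha) hbi_residual(alpha, p$D, beta)
  n_try <- 0
  while (sign(g(lower)) == sign(g(upper))) {
    n_try <- n_try + 1
    upper <- upper * 2
    if (n_try > 10)
      stopf(paste0("goodman_alpha: no sign change in bracket ",
                   "[%g, %g] after 10 doublings"), lower, upper)
  }
  root <- uniroot(g, c(lower, upper), tol = upper0 * 1e-10)
  a <- root$root^2 / (2 * p$D * beta)
  structure(list(alpha = root$root, a = a, b = 1 - a, beta = beta,
                 residual = root$f.root),
            class = "moving_boundary_solution")
}

#' @export
print.moving_boundary_solution <- function(x, ...) {
  cat(sprintf(
    "Moving-boundary solution: X(t) = alpha*sqrt(t), alpha = %g\n", x$alpha))
  cat(sprintf("  profile C/C0 = a*xi + b*xi^2 (xi = 1 - x/X): a = %g, b = %g\n",
              x$a, x$b))
  invisible(x)
}

#' Front position under the square-root law
#'
#' @param sol a `moving_boundary_solution` from [goodman_alpha()].
#' @param t time(s), s, >= 0 (vectorized).
#' @return Front position `X = alpha * sqrt(t)`, cm.
#' @export
front_position <- function(sol, t) {
  stopifnot(inherits(sol, "moving_boundary_solution"))
  if (any(!is.finite(t)) || any(t < 0))
    stopf("front_position: t must be finite and >= 0")
  sol$alpha * sqrt(t)
}

#' Concentration profile of the Goodman solution at a given time
#'
#' Evaluates the quadratic similarity profile on `[0, X(t)]`.  The
#' boundary anchor `C(X) = 0` holds exactly by construction; for the
#' default bath boundary the surface value `C(0) = C0` is reproduced.
#' Outside the front (`x > X`) the concentration is zero.
#'
#' @param sol a `moving_boundary_solution`.
#' @param p the [stefan_params()] used to compute `sol`.
#' @param t time, s, > 0.
#' @param n number of grid points on `[0, X]`.
#' @return A data frame of class `concentration_profile` with columns
#'   `x` (cm) and `C`, and attributes `t`, `X`, and the dimensional
#'   coefficients `a_dim = -C0*a/X` (concentration/cm) and
#'   `b_dim = C0*b/X^2` (concentration/cm^2) of the equivalent form
#'   `C = a_dim*(x - X) + b_dim*(x - X)^2`.
#' @export
goodman_profile <- function(sol, p, t, n = 201) {
  stopifnot(inherits(sol, "moving_boundary_solution"),
            inherits(p, "stefan_params"))
  check_number(t, "t", 0, strict_lower = TRUE)
  X <- sol$alpha * sqrt(t)
  if (X == 0) {
    out <- data.frame(x = 0, C = 0)
    attr(out, "t") <- t; attr(out, "X") <- 0
    attr(out, "a_dim") <- 0; attr(out, "b_dim") <- 0
    class(out) <- c("concentration_profile", "data.frame")
    return(out)
  }
  x <- seq(0, X, length.out = n)
  xi <- 1 - x / X
  C <- p$C0 * (sol$a * xi + sol$b * xi^2)
  C[length(C)] <- 0  # exact anchor at the front
  out <- data.frame(x = x, C = C)
  attr(out, "t") <- t; attr(out, "X") <- X
  attr(out, "a_dim") <- -p$C0 * sol$a / X
  attr(out, "b_dim") <- p$C0 * sol$b / X^2
  class(out) <- c("concentration_profile", "data.frame")
  out
}

#' Exact similarity solution of the Stefan sorption problem
#'
#' For the constant-bath configuration (`l = 0`) the problem has the
#' classical exact solution `X = 2 k sqrt(D t)` with `k` the root of
#' \deqn{\sqrt{\pi}\,k\,e^{k^2}\,\mathrm{erf}(k) = C_0/S.}{
#'   sqrt(pi) k exp(k^2) erf(k) = C0/S.}
#' Used as an independent benchmark for [goodman_alpha()] and
#' [fd_solve()].
#'
#' @inheritParams goodman_alpha
#' @return The exact front coefficient `alpha = 2 k sqrt(D)`, cm/sqrt(s).
#' @export
stefan_alpha_exact <- function(p) {
  stopifnot(inherits(p, "stefan_params"))
  if (p$C0 == 0) return(0)
  beta <- p$C0 / p$S
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  g <- function(k) sqrt(pi) * k * exp(k^2) * erf(k) - beta
  upper <- 1
  while (g(upper) < 0) upper <- upper * 2
  k <- uniroot(g, c(1e-12, upper), tol = 1e-12)$root
  2 * k * sqrt(p$D)
}

#' Finite-difference solution of the moving-boundary problem
#'
#' Explicit time stepping on a fixed grid with a front-cell accumulator:
#' the front advances one cell whenever the time-integrated flux into it
#' has delivered `S * dx` of immobilized amount.  The scheme's mass
#' bookkeeping is flux-consistent, so the global balance
#' (influx at `x = 0` = stored in profile + immobilized `S X`) is
#' auditable and its relative residual is returned.
#'
#' Serves as the numerical oracle for the closed-form
#' [goodman_alpha()] solution, and additionally supports the
#' delamination-flood configuration used to check the steady-state
#' membrane picture of phase II: with `delam_delta` set, every grid node
#' behind the delamination front `d(t) = X(t) - delta` is held at `C0`,
#' emulating corroding agent flooding the newly opened cavity.
#'
#' @inheritParams goodman_alpha
#' @param t_end simulation horizon, s, > 0.
#' @param nx number of grid cells, >= 50.
#' @param cfl diffusive stability number `D dt / dx^2`, in (0, 0.5].
#' @param L domain length, cm.  Default sizes the domain to
#'   `1.35 * alpha * sqrt(t_end)` from the closed form (must be given
#'   explicitly when `C0 = 0`).
#' @param n_save approximate number of saved front positions.
#' @param delam_delta constant delamination lag `delta`, cm, or `NULL`
#'   (default) for the plain Stefan problem.
#' @return An object of class `fd_solution`: `front` (data frame `t`,
#'   `X`), `profile` (data frame `x`, `C` at `t_end`), and `diagnostics`
#'   (mass accounts, `balance_rel_err`, `dx`, `dt`, `nsteps`).
#' @export
fd_solve <- function(p, t_end, nx = 200, cfl = 0.4, L = NULL,
                     n_save = 200, delam_delta = NULL) {
  stopifnot(inherits(p, "stefan_params"))
  check_number(t_end, "t_end", 0, strict_lower = TRUE)
  if (!is.numeric(nx) || nx < 50) stopf("fd_solve: nx must be >= 50")
  if (!is.numeric(cfl) || cfl <= 0 || cfl > 0.5)
    stopf("fd_solve: cfl must be in (0, 0.5], got %g (CFL violation)", cfl)
  if (is.null(L)) {
    if (p$C0 == 0)
      stopf("fd_solve: L must be given when C0 = 0")
    alpha <- suppressWarnings(goodman_alpha(p)$alpha)
    L <- 1.35 * alpha * sqrt(t_end)
  }
  check_number(L, "L", 0, strict_lower = TRUE)
  dx <- L / nx
  dt <- cfl * dx^2 / p$D
  delam_on <- !is.null(delam_delta)
  if (delam_on) check_number(delam_delta, "delam_delta", 0,
                             strict_lower = TRUE)
  res <- fd_stefan_core(p$D, p$C0, p$S, p$l, dx, dt, t_end, as.integer(nx),
                        as.integer(n_save),
                        if (delam_on) delam_delta else 0, delam_on)
  if (res$overflow)
    warning(sprintf(
      "fd_solve: front reached the domain end at t = %g (< t_end = %g); ",
      res$t_reached, t_end), "increase L", call. = FALSE)
  structure(list(
    front = data.frame(t = res$t, X = res$X),
    profile = data.frame(x = res$x, C = res$C),
    diagnostics = list(influx = res$influx, stored = res$stored,
                       consumed = res$consumed,
                       balance_rel_err = res$balance_rel_err,
                       dx = dx, dt = dt,
                       nsteps = ceiling(t_end / dt),
                       overflow = res$overflow, X_end = res$X_end),
    params = p, delam_delta = delam_delta),
    class = "fd_solution")
}

#' @export
print.fd_solution <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "FD Stefan solution: X(t_end) = %g cm after %d steps (dx = %g, dt = %g)\n",
    d$X_end, d$nsteps, d$dx, d$dt))
  cat(sprintf("  mass balance residual: %.3g (relative)\n", d$balance_rel_err))
  invisible(x)
}

#' Fit the square-root front law to a measured trace
#'
#' Least-squares fit of `s = alpha * sqrt(t)` (no intercept) to a front
#' trace over a time window; this is the estimator used to compare the
#' theoretical front coefficient with time-lapse measurements.
#'
#' @param trace a [front_trace()] (or any data frame with columns `t`,
#'   `s`).
#' @param window optional `c(tmin, tmax)` restricting the fit; default
#'   uses all points.
#' @return A list of class `alpha_fit`: `alpha_hat`, `resid_sd`,
#'   `r_squared` (no-intercept convention), `n`.
#' @examples
#' tr <- data.frame(t = 1:50, s = 3 * sqrt(1:50))
#' fit_alpha(tr)$alpha_hat  # 3 to machine precision
#' @export
fit_alpha <- function(trace, window = NULL) {
  t <- trace$t; s <- trace$s
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; s <- s[keep]
  }
  if (length(t) < 3)
    stopf("fit_alpha: need >= 3 points in the window, got %d", length(t))
  st <- sqrt(t)
  denom <- sum(t)
  if (denom == 0) stopf("fit_alpha: window contains only t = 0")
  alpha_hat <- sum(s * st) / denom
  resid <- s - alpha_hat * st
  sse <- sum(resid^2)
  sst <- sum(s^2)
  structure(list(alpha_hat = alpha_hat,
                 resid_sd = sqrt(sse / max(length(t) - 1, 1)),
                 r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
                 n = length(t)),
            class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf("sqrt-t front fit: alpha_hat = %g (n = %d, resid SD = %.3g, R^2 = %.4f)\n",
              x$alpha_hat, x$n, x$resid_sd, x$r_squared))
  invisible(x)
}
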