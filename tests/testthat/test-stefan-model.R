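test_that("parameter validation enforces the concentration ordering", {
  expect_error(stefan_params(D = 0, C0 = 1, S = 1), "> 0")
  expect_error(stefan_params(D = 1e-6, C0 = 1, S = 0), "> 0")
  expect_error(stefan_params(D = 1e-6, C0 = 1, S = 1, Ci = 0.9,
                             Climit = 0.5), "Ci <= Climit")
  expect_silent(stefan_params(D = 1e-6, C0 = 0, S = 1))
})

test_that("no driving concentration gives a motionless front", {
  p0 <- stefan_params(D = 1e-6, C0 = 0, S = 1)
  sol <- goodman_alpha(p0)
  expect_equal(sol$alpha, 0)
  expect_equal(sol$a, 0)
  expect_equal(sol$b, 0)
  fd <- fd_solve(p0, t_end = 100, L = 0.1)
  expect_true(all(fd$front$X == 0))
  expect_true(all(fd$profile$C == 0))
})

test_that("Goodman alpha matches the exact similarity solution closely", {
  for (beta in c(0.05, 0.1, 0.316, 1)) {
    p <- stefan_params(D = 1e-6, C0 = beta, S = 1)
    a_hbi <- goodman_alpha(p)$alpha
    a_ex <- stefan_alpha_exact(p)
    expect_lt(abs(a_hbi - a_ex) / a_ex, 0.03)
  }
})

test_that("front position obeys the sqrt-t law and its scaling", {
  sol <- goodman_alpha(ref_params())
  expect_equal(front_position(sol, 0), 0)
  t <- c(10, 1234, 5e4)
  expect_equal(front_position(sol, 4 * t), 2 * front_position(sol, t))
  sol2 <- structure(list(alpha = 2e-3, a = 1, b = 0),
                    class = "moving_boundary_solution")
  expect_equal(front_position(sol2, 1e4), 0.2)
  expect_error(front_position(sol, -1), ">= 0")
})

test_that("the quadratic profile anchors at the front and the surface", {
  p <- ref_params()
  sol <- goodman_alpha(p)
  prof <- goodman_profile(sol, p, t = 1e4)
  expect_equal(prof$C[nrow(prof)], 0)                    # C(X) = 0 exact
  expect_equal(prof$C[1], p$C0)                          # bath value at x=0
  expect_true(all(prof$C >= 0))
  # internal consistency: quadrature equals the HBI mass-balance value
  X <- attr(prof, "X")
  f <- function(x) p$C0 * (sol$a * (1 - x / X) + sol$b * (1 - x / X)^2)
  num <- integrate(f, 0, X, rel.tol = 1e-12)$value
  closed <- p$C0 * X * (sol$a / 2 + sol$b / 3)
  expect_lt(abs(num - closed) / closed, 1e-10)
})

test_that("alpha sweeps are monotone in D and in S", {
  Ds <- 10^seq(-7, -6, length.out = 4)
  alphas <- vapply(Ds, function(D)
    goodman_alpha(stefan_params(D = D, C0 = 1, S = 10))$alpha, 0)
  expect_true(all(diff(alphas) > 0))
  Ss <- 10^seq(0, 1, length.out = 4)
  alphas <- vapply(Ss, function(S)
    goodman_alpha(stefan_params(D = 1e-6, C0 = 1, S = S))$alpha, 0)
  expect_true(all(diff(alphas) < 0))
})

test_that("alpha depends on C0 and S only through their ratio, and on sqrt(D)", {
  a1 <- goodman_alpha(stefan_params(D = 1e-6, C0 = 0.5, S = 5))$alpha
  a2 <- goodman_alpha(stefan_params(D = 1e-6, C0 = 1, S = 10))$alpha
  expect_equal(a1, a2, tolerance = 1e-12)
  a4 <- goodman_alpha(stefan_params(D = 4e-6, C0 = 1, S = 10))$alpha
  expect_equal(a4, 2 * a2, tolerance = 1e-10)
})

test_that("the FD solver conserves mass and converges on itself", {
  p <- ref_params()
  sol <- goodman_alpha(p)
  t_end <- (0.1 / sol$alpha)^2
  fd1 <- fd_solve(p, t_end, nx = 100)
  fd2 <- fd_solve(p, t_end, nx = 200)
  expect_lt(fd1$diagnostics$balance_rel_err, 1e-3)
  expect_lt(fd2$diagnostics$balance_rel_err, 1e-3)
  # halving the grid spacing changes X(t_end) by < 0.5%
  expect_lt(abs(fd1$diagnostics$X_end - fd2$diagnostics$X_end) /
              fd2$diagnostics$X_end, 0.005)
  # concentrations stay nonnegative
  expect_true(all(fd2$profile$C >= -1e-12))
})

test_that("the sqrt-t law emerges from the FD numerics", {
  p <- ref_params()
  sol <- goodman_alpha(p)
  t_end <- (0.12 / sol$alpha)^2
  fd <- fd_solve(p, t_end, nx = 200)
  late <- fd$front[fd$front$t >= t_end / 2, ]
  f <- lm(log(X) ~ log(t), late)
  expect_gt(summary(f)$r.squared, 0.999)
  expect_lt(abs(coef(f)[2] - 0.5), 0.01)
})

test_that("Goodman and FD fronts agree over the second half of the horizon", {
  for (beta in c(0.1, 1)) {
    p <- stefan_params(D = 1e-6, C0 = beta, S = 1)
    sol <- goodman_alpha(p)
    t_end <- (0.1 / sol$alpha)^2
    fd <- fd_solve(p, t_end, nx = 200)
    half <- fd$front[fd$front$t >= t_end / 2, ]
    dev <- abs(sol$alpha * sqrt(half$t) - half$X) / half$X
    expect_lt(max(dev), 0.05)
  }
})

test_that("a depleting surface reservoir slows the front below sqrt-t", {
  # small reservoir: capacity l*C0 well below the mass a sqrt-t front
  # would draw; the FD front must fall behind the closed form
  p <- stefan_params(D = 1e-6, C0 = 1, S = 1, l = 0.01)
  sol <- suppressWarnings(goodman_alpha(p))
  expect_warning(goodman_alpha(p), "undepleted")
  t_end <- (0.1 / sol$alpha)^2
  fd <- fd_solve(p, t_end, nx = 100, L = 0.15)
  expect_lt(fd$diagnostics$X_end, 0.9 * sol$alpha * sqrt(t_end))
  expect_lt(fd$diagnostics$balance_rel_err, 1e-3)
})

test_that("solver preconditions are enforced", {
  p <- ref_params()
  expect_error(fd_solve(p, 100, nx = 20, L = 0.1), "nx")
  expect_error(fd_solve(p, 100, cfl = 0.7, L = 0.1), "CFL")
  expect_error(fd_solve(p, -5, L = 0.1), "> 0")
})

test_that("fit_alpha recovers exact sqrt-t data to machine precision", {
  t <- seq(0, 500, by = 5)
  tr <- data.frame(t = t, s = 3 * sqrt(t))
  fit <- fit_alpha(tr)
  expect_equal(fit$alpha_hat, 3, tolerance = 1e-14)
  expect_equal(fit$resid_sd, 0, tolerance = 1e-12)
  expect_equal(fit_alpha(data.frame(t = t, s = 0 * t))$alpha_hat, 0)
  expect_error(fit_alpha(data.frame(t = t[1:2], s = t[1:2])), ">= 3")
  expect_error(fit_alpha(tr, window = c(600, 700)), ">= 3")
})

test_that("fit_alpha is accurate under measurement noise", {
  errs <- vapply(1:20, function(i) {
    tr <- simulate_front_trace(sqrt_law(alpha = 1), duration = 500,
                               step = 5, noise_sd = 0.5, seed = 100 + i)
    abs(fit_alpha(tr)$alpha_hat - 1)
  }, 0)
  expect_true(all(errs < 0.02))
})
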