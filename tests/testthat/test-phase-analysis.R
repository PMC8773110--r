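test_that("a pure sqrt-t trace yields a single phase", {
  tr <- simulate_front_trace(sqrt_law(alpha = 1.3), duration = 600, step = 5)
  seg <- segment_phases(tr)
  expect_true(is.na(seg$t1))
  expect_true(is.na(seg$t2))
  expect_equal(seg$alpha_hat, 1.3, tolerance = 1e-12)
})

test_that("the changepoint of a noise-free composite is recovered exactly", {
  law <- composite_front_law(alpha = 1, t1 = 420, v2 = 0.05, t2 = 1e4,
                             jump = 0)
  tr <- simulate_front_trace(law, duration = 600, step = 5)
  seg <- segment_phases(tr)
  expect_equal(seg$t1, 420)            # within one frame interval: exact here
  expect_equal(seg$alpha_hat, 1, tolerance = 1e-6)
  expect_equal(seg$v2_hat, 0.05, tolerance = 1e-6)
  # piecewise SSE never exceeds the single-phase SSE
  expect_lte(seg$sse, seg$sse_single)
})

test_that("the phase-III artifact jump is isolated, not fitted", {
  law <- composite_front_law(alpha = 1, t1 = 240, v2 = 0.05, t2 = 420,
                             jump = 250)
  tr <- simulate_front_trace(law, duration = 495, step = 5)
  seg <- segment_phases(tr)
  expect_equal(seg$t2, 420)
  expect_equal(seg$t1, 240)
  expect_equal(unname(seg$n_per_phase["III"]), sum(tr$t > 420))
  expect_equal(seg$v2_hat, 0.05, tolerance = 1e-6)
})

test_that("changepoint recovery is robust to pixel noise", {
  law <- composite_front_law(alpha = 1, t1 = 420, v2 = 0.05, t2 = 1e4,
                             jump = 0)
  ok <- 0
  for (i in 1:30) {
    tr <- simulate_front_trace(law, duration = 600, step = 5,
                               noise_sd = 0.5, seed = 300 + i)
    seg <- segment_phases(tr)
    if (!is.na(seg$t1) && abs(seg$t1 - 420) <= 15) ok <- ok + 1
  }
  expect_gte(ok, 27)   # >= 90%
})

test_that("t1 error stays small across the front-law parameter space", {
  # sweep alpha, v2 and noise; median |t1_hat - t1| <= 2 frame intervals
  set.seed(99)
  cases <- expand.grid(alpha = c(0.5, 1, 2), v2 = c(0.02, 0.05, 0.2),
                       noise = c(0, 0.5, 1))
  errs <- c()
  for (r in seq_len(nrow(cases))) {
    for (k in 1:8) {
      t1_true <- sample(seq(150, 350, by = 5), 1)
      law <- composite_front_law(alpha = cases$alpha[r], t1 = t1_true,
                                 v2 = cases$v2[r], t2 = 1e4, jump = 0)
      tr <- simulate_front_trace(law, duration = 600, step = 5,
                                 noise_sd = cases$noise[r],
                                 seed = 5000 + 10 * r + k)
      seg <- segment_phases(tr)
      errs <- c(errs, if (is.na(seg$t1)) Inf else abs(seg$t1 - t1_true))
    }
  }
  expect_lte(median(errs), 10)   # 2 frame intervals at 5 min cadence
})

test_that("segmentation preconditions are enforced", {
  tr <- simulate_front_trace(sqrt_law(), duration = 40, step = 5)
  expect_error(segment_phases(tr), "points")
  bad <- data.frame(t = c(0, 5, 5, 10), s = c(0, 1, 1, 2))
  expect_error(segment_phases(bad, min_seg = 1), "increasing")
})

test_that("the delamination front trails at the constant lag", {
  X <- seq(0, 0.3, by = 0.01)
  st <- delamination_front(X, delta = 0)
  expect_equal(st$d, X)                              # delta = 0
  st2 <- delamination_front(X, delta = 1)
  expect_true(all(st2$d == 0))                       # X always < delta
  st3 <- delamination_front(X, delta = 0.1)
  expect_true(all(diff(st3$d) >= 0))
  pos <- st3$d > 0
  expect_equal(X[pos] - st3$d[pos], rep(0.1, sum(pos)))  # defining identity
  expect_error(delamination_front(X, delta = -1), ">=")
})

test_that("the membrane rate follows the closed form and its scaling", {
  p <- stefan_params(D = 1e-6, C0 = 1, S = 10)
  expect_equal(steady_state_membrane_rate(p, 0.02),
               2 * steady_state_membrane_rate(p, 0.04))
  # D*C0/S = 0.05 mm^2/min, delta = 1 mm -> 0.05 mm/min (unit-agnostic)
  p2 <- stefan_params(D = 0.5, C0 = 1, S = 10)
  expect_equal(steady_state_membrane_rate(p2, 1), 0.05)
  expect_error(steady_state_membrane_rate(p, 0), "unbounded")
})

test_that("the FD solver with cavity flooding approaches the membrane rate", {
  p <- stefan_params(D = 1e-6, C0 = 1, S = 20)   # C0/S = 0.05
  delta <- 0.03
  v2 <- steady_state_membrane_rate(p, delta)
  sol <- goodman_alpha(p)
  t_end <- (delta / sol$alpha)^2 + 0.15 / v2
  fd <- fd_solve(p, t_end, nx = 300, L = 0.25, delam_delta = delta)
  expect_lt(fd$diagnostics$balance_rel_err, 1e-3)
  late <- fd$front[fd$front$t >= 0.6 * t_end, ]
  slope <- coef(lm(X ~ t, late))[2]
  expect_lt(abs(slope - v2) / v2, 0.1)
})

test_that("membrane rate and segmentation are mutually consistent", {
  # feed the closed-form v2 into the generator's phase II and re-segment
  p <- stefan_params(D = 0.5, C0 = 1, S = 10)    # mm/min scale
  delta <- 1
  v2 <- steady_state_membrane_rate(p, delta)     # 0.05 mm/min
  law <- composite_front_law(alpha = 0.1, t1 = 200, v2 = v2, t2 = 1e4,
                             jump = 0)
  tr <- simulate_front_trace(law, duration = 600, step = 5)
  seg <- segment_phases(tr)
  expect_lt(abs(seg$v2_hat - v2) / v2, 0.05)
})

test_that("merge prediction selects the faster failure route", {
  p <- stefan_params(D = 1e-6, C0 = 1, S = 10)
  # D_bulk -> 0: interface route wins
  m1 <- predict_merge(p, D_bulk = 0, cover_thickness = 0.1, r0 = 1,
                      delta = 0.02)
  expect_equal(m1$mode, "interface")
  expect_equal(m1$t_merge, m1$t_interface)
  # r0 -> Inf with finite D_bulk: bulk route wins
  m2 <- predict_merge(p, D_bulk = 1.676e-6, cover_thickness = 0.1,
                      r0 = Inf, delta = 0.02)
  expect_equal(m2$mode, "bulk")
  expect_equal(m2$t_merge, m2$t_bulk)
  # closed-form cross-check of both times
  sol <- goodman_alpha(p)
  v2 <- p$D * p$C0 / (p$S * 0.02)
  m3 <- predict_merge(p, D_bulk = 1.676e-6, cover_thickness = 0.1,
                      r0 = 1.5, delta = 0.02)
  expect_equal(m3$t_interface, (0.02 / sol$alpha)^2 + (1.5 - 0.02) / v2,
               tolerance = 1e-12)
  expect_equal(m3$t_bulk, 0.01 / (2 * 1.676e-6), tolerance = 1e-12)
  # no route available at all
  m4 <- predict_merge(stefan_params(D = 1e-6, C0 = 0, S = 1), 0, 0.1, 1,
                      delta = 0.02)
  expect_match(m4$mode, "no failure")
})
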