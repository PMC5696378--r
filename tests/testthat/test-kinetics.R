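ref_params <- kinetics_params(N = 1, beta = 1, p0 = 0.05, p1 = 1, p2 = 0.025)

random_params <- function() {
  kinetics_params(N = runif(1, 0.5, 5), beta = runif(1, 0.5, 5),
                  p0 = runif(1, 0.01, 2), p1 = runif(1, 0.01, 2),
                  p2 = runif(1, 0.01, 2))
}

test_that("closed forms satisfy initial conditions and frozen asymptotes", {
  for (f in list(one_step_closed_form, two_step_closed_form)) {
    s0 <- f(ref_params, 0)
    expect_equal(s0$omega, 2 * ref_params$N)
    expect_equal(s0$x, 0)
    expect_equal(s0$y, 0)
    expect_equal(s0$z, 0)
  }
  # one-step asymptotes: y_inf = p1 (2N)^2 / (2 (p1+p2)) = 4 / 2.05,
  # z_inf = p2 beta (2N) / (p1+p2) = 0.05 / 1.025
  late <- one_step_closed_form(ref_params, 5000)
  expect_equal(late$y, 4 / 2.05, tolerance = 1e-9)
  expect_equal(late$y, 1.951220, tolerance = 1e-6)
  expect_equal(late$z, 0.05 / 1.025, tolerance = 1e-9)
  expect_equal(late$z, 0.048780, tolerance = 1e-4)
  # alpha for the reference parameters
  expect_equal(two_step_alpha(ref_params), 0.1 / (0.1 - 1.025),
               tolerance = 1e-12)
  expect_equal(two_step_alpha(ref_params), -0.1081081, tolerance = 1e-6)
  # zero signal rate gives exactly zero signal product
  p0sig <- kinetics_params(p1 = 0, p2 = 0.5)
  expect_identical(one_step_closed_form(p0sig, 3)$y, 0)
  # domain errors
  expect_error(one_step_closed_form(ref_params, -1), "negative")
  expect_error(two_step_closed_form(ref_params, -0.5), "negative")
})

test_that("two-step x stays non-negative although alpha is negative", {
  expect_lt(two_step_alpha(ref_params), 0)
  st <- two_step_closed_form(ref_params, seq(0, 50, length.out = 400))
  expect_true(all(st$x >= 0))
})

test_that("noise products of both models share the asymptote", {
  set.seed(101)
  for (i in 1:25) {
    p <- random_params()
    z_inf <- p$p2 * p$beta * 2 * p$N / (p$p1 + p$p2)
    t_late <- 40 / min(p$p1 + p$p2, 2 * p$p0)
    expect_equal(one_step_closed_form(p, t_late)$z, z_inf,
                 tolerance = 1e-9)
    expect_equal(two_step_closed_form(p, t_late)$z, z_inf,
                 tolerance = 1e-9)
  }
})

test_that("closed forms satisfy their stated differential equations", {
  set.seed(42)
  h <- 1e-4
  # relative 1e-6 plus an absolute term on the state scale: where the true
  # derivative has decayed below the float-cancellation noise of the
  # central difference (~ eps * state / h), only the absolute term binds
  rel_ok <- function(num, rhs, states) {
    scale <- max(1, abs(unlist(states)))
    all(abs(num - rhs) <= 1e-6 * abs(rhs) + 1e-9 * scale)
  }
  for (i in 1:20) {
    p <- random_params()
    s <- p$p1 + p$p2
    for (t in c(0.5, 2, 10)) {
      # one-step: domega = -(p1+p2) omega, dy = p1 omega^2, dz = p2 beta omega
      st <- one_step_closed_form(p, t)
      num <- unlist((one_step_closed_form(p, t + h)[, c("omega", "y", "z")] -
                one_step_closed_form(p, t - h)[, c("omega", "y", "z")]) /
        (2 * h), use.names = FALSE)
      rhs <- c(-s * st$omega, p$p1 * st$omega^2, p$p2 * p$beta * st$omega)
      expect_true(rel_ok(num, rhs, st[, -1]))
      # two-step: domega = -2 p0 omega, dx = 2 p0 omega - (p1+p2) x,
      # dy = p1 x omega, dz = p2 x beta
      st2 <- two_step_closed_form(p, t)
      num2 <- unlist((two_step_closed_form(p, t + h)[, 2:5] -
                 two_step_closed_form(p, t - h)[, 2:5]) / (2 * h),
                 use.names = FALSE)
      rhs2 <- c(-2 * p$p0 * st2$omega,
                2 * p$p0 * st2$omega - s * st2$x,
                p$p1 * st2$x * st2$omega,
                p$p2 * st2$x * p$beta)
      expect_true(rel_ok(num2, rhs2, st2[, -1]))
    }
  }
})

test_that("RK4 trajectories agree with the closed forms", {
  set.seed(7)
  for (i in 1:10) {
    p <- random_params()
    if (abs(2 * p$p0 - (p$p1 + p$p2)) <
        0.01 * (2 * p$p0 + p$p1 + p$p2)) next  # singular manifold
    tr1 <- integrate_kinetics(p, "one-step", t_end = 10, n_steps = 10000)
    cf1 <- one_step_closed_form(p, tr1$states$t)
    rel1 <- abs(as.matrix(tr1$states[, c("omega", "y", "z")]) -
                  as.matrix(cf1[, c("omega", "y", "z")])) /
      pmax(abs(as.matrix(cf1[, c("omega", "y", "z")])), 1e-300)
    rel1[as.matrix(cf1[, c("omega", "y", "z")]) == 0] <- 0
    expect_lt(max(rel1), 1e-6)
    tr2 <- integrate_kinetics(p, "two-step", t_end = 10, n_steps = 10000)
    cf2 <- two_step_closed_form(p, tr2$states$t)
    rel2 <- abs(as.matrix(tr2$states[, -1]) - as.matrix(cf2[, -1])) /
      pmax(abs(as.matrix(cf2[, -1])), 1e-300)
    rel2[as.matrix(cf2[, -1]) == 0] <- 0
    expect_lt(max(rel2), 1e-6)
  }
  expect_error(integrate_kinetics(ref_params, "one-step", t_end = -1),
               "t_end")
  expect_error(
    integrate_kinetics(kinetics_params(p1 = 1), "one-step", t_end = 1,
                       n_steps = 1), "n_steps")
})

test_that("trajectories are monotone and non-negative", {
  set.seed(13)
  for (i in 1:10) {
    p <- random_params()
    for (model in c("one-step", "two-step")) {
      st <- integrate_kinetics(p, model, t_end = 20, n_steps = 4000)$states
      expect_true(all(diff(st$omega) < 0))
      expect_true(all(diff(st$y) >= 0))
      expect_true(all(diff(st$z) >= 0))
      expect_true(all(st$omega >= 0 & st$x >= -1e-12 & st$y >= 0 &
                        st$z >= 0))
    }
  }
})

test_that("singular two-step limit is continuous and matches the integrator", {
  # exactly on the manifold 2 p0 = p1 + p2
  p <- kinetics_params(N = 1.2, beta = 0.8, p0 = 0.5125, p1 = 1, p2 = 0.025)
  expect_equal(2 * p$p0, p$p1 + p$p2)
  cf <- two_step_closed_form(p, c(0.5, 1, 5, 20))
  expect_true(attr(cf, "singular"))
  tr <- integrate_kinetics(p, "two-step", t_end = 20, n_steps = 40000)
  at <- vapply(c(0.5, 1, 5, 20), function(t) {
    which.min(abs(tr$states$t - t))
  }, integer(1))
  expect_equal(as.matrix(tr$states[at, -1]), as.matrix(cf[, -1]),
               tolerance = 1e-6, ignore_attr = TRUE)
  # approach: nearby non-singular parameters converge to the limit branch
  p_eps <- kinetics_params(N = 1.2, beta = 0.8, p0 = 0.5125 * (1 + 1e-6),
                           p1 = 1, p2 = 0.025)
  cf_eps <- two_step_closed_form(p_eps, c(0.5, 1, 5, 20))
  expect_false(attr(cf_eps, "singular"))
  expect_equal(as.matrix(cf_eps[, -1]), as.matrix(cf[, -1]),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("signal/noise ratio has the (p1/p2)(2N/beta) small-time limit", {
  st <- two_step_closed_form(ref_params, 1e-3)
  expect_equal(st$y / st$z, 80, tolerance = 0.01)
  st1 <- one_step_closed_form(ref_params, 1e-3)
  expect_equal(st1$y / st1$z, 80, tolerance = 0.01)
  expect_equal(signal_noise_limit0(ref_params), 80)
  # symmetric parameters: ratio 1
  psym <- kinetics_params(N = 0.5, beta = 1, p0 = 0.05, p1 = 0.3, p2 = 0.3)
  stsym <- one_step_closed_form(psym, 1e-4)
  expect_equal(stsym$y / stsym$z, 1, tolerance = 0.01)
  # curve extraction drops the t = 0 point where z = 0
  tr <- integrate_kinetics(ref_params, "two-step", t_end = 5, n_steps = 100)
  curve <- signal_noise_curve(tr)
  expect_equal(nrow(curve), 100)
  expect_true(all(curve$ratio > 0))
  # all-zero z warns and returns an empty series
  pz <- kinetics_params(p0 = 0.05, p1 = 1, p2 = 0)
  expect_warning(out <- signal_noise_curve(one_step_closed_form(pz, 0:5)),
                 "zero")
  expect_equal(nrow(out), 0)
})
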