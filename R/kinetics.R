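#' Parameters of the proximity-ligation kinetic models
#'
#' The ligation of chromatin fragments during a proximity-ligation
#' experiment is modelled by two kinetic systems. In the one-step model,
#' free proximal fragments (omega, initially `2N`) ligate directly to each
#' other, producing signal pairs `y` at rate `p1` and noise pairs `z` (via
#' collisions with isolated fragments of abundance `beta`) at rate `p2`.
#' In the two-step model, fragments first ligate to a bridge linker at rate
#' `p0`, forming intermediates `x`, and only the intermediates then ligate
#' to partners (signal `p1`, noise `p2`). Time and rates are dimensionless
#' model units.
#'
#' Defaults are `p0 = 0.05`, `p1 = 1`, `p2 = 0.025` (the noise channel per
#' collision partner is slow, but isolated fragments are plentiful) and
#' `N = beta = 1`, so that signal-to-noise ratios reduce to pure functions
#' of the rates.
#'
#' @param N initial chromatin-fragment pair count; initial free fragments
#'   are `2N`.
#' @param beta abundance of isolated (noise-partner) fragments.
#' @param p0 linker-ligation rate (two-step model only).
#' @param p1 signal ligation rate.
#' @param p2 noise ligation rate.
#' @return an object of class `kinetics_params`.
#' @examples
#' kinetics_params()
#' @export
kinetics_params <- function(N = 1, beta = 1, p0 = 0.05, p1 = 1, p2 = 0.025) {
  for (nm in c("N", "beta", "p0", "p1", "p2")) {
    stop_if_not_scalar_num(get(nm), nm)
  }
  if (N <= 0) stop("N must be > 0")
  if (beta < 0 || p0 < 0 || p1 < 0 || p2 < 0) {
    stop("beta, p0, p1, p2 must be >= 0")
  }
  structure(list(N = N, beta = beta, p0 = p0, p1 = p1, p2 = p2),
            class = "kinetics_params")
}

#' @exportS3Method base::print
print.kinetics_params <- function(x, ...) {
  cat(sprintf(
    "kinetics_params: N=%g beta=%g p0=%g p1=%g p2=%g (alpha=%g)\n",
    x$N, x$beta, x$p0, x$p1, x$p2, two_step_alpha(x)
  ))
  invisible(x)
}

#' Coefficient alpha of the two-step closed-form solution
#'
#' `alpha = 2 p0 / (2 p0 - (p1 + p2))`; undefined on the singular manifold
#' `2 p0 = p1 + p2`, where the closed form is evaluated as an analytic
#' limit instead.
#'
#' @param params a [kinetics_params()] object.
#' @return numeric scalar (may be `Inf` on the singular manifold).
#' @export
two_step_alpha <- function(params) {
  2 * params$p0 / (2 * params$p0 - (params$p1 + params$p2))
}

check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t))) stop("t must be finite numeric")
  if (any(t < 0)) stop("negative time is outside the model domain")
  invisible(t)
}

#' Closed-form solution of the one-step ligation model
#'
#' Solves
#' \deqn{d\omega/dt = -(p_1+p_2)\omega,\quad dy/dt = p_1\omega^2,\quad
#'       dz/dt = p_2\beta\omega}
#' with \eqn{\omega_0 = 2N}, \eqn{y_0 = z_0 = 0}, giving
#' \deqn{\omega = 2N e^{-(p_1+p_2)t}}
#' \deqn{y = p_1 (2N)^2 \frac{1 - e^{-2(p_1+p_2)t}}{2(p_1+p_2)}}
#' \deqn{z = p_2 \beta (2N) \frac{1 - e^{-(p_1+p_2)t}}{p_1+p_2}}
#' The intermediate pool `x` does not exist in this model and is reported
#' as zero. When `p1 + p2 = 0` nothing ligates and the initial state is
#' returned.
#'
#' @param params a [kinetics_params()] object.
#' @param t vector of times, all `>= 0`.
#' @return data.frame with columns `t, omega, x, y, z`.
#' @examples
#' one_step_closed_form(kinetics_params(), t = c(0, 1, 10))
#' @export
one_step_closed_form <- function(params, t) {
  stopifnot(inherits(params, "kinetics_params"))
  check_time(t)
  s <- params$p1 + params$p2
  twoN <- 2 * params$N
  if (s == 0) {
    return(data.frame(t = t, omega = rep(twoN, length(t)), x = 0, y = 0,
                      z = 0))
  }
  omega <- twoN * exp(-s * t)
  y <- params$p1 * twoN^2 * (-expm1(-2 * s * t)) / (2 * s)
  z <- params$p2 * params$beta * twoN * (-expm1(-s * t)) / s
  data.frame(t = t, omega = omega, x = 0, y = y, z = z)
}

#' Closed-form solution of the two-step ligation model
#'
#' Solves
#' \deqn{d\omega/dt = -2p_0\omega,\quad dx/dt = 2p_0\omega - (p_1+p_2)x,}
#' \deqn{dy/dt = p_1 x \omega,\quad dz/dt = p_2 x \beta}
#' with \eqn{\omega_0 = 2N}, \eqn{x_0 = y_0 = z_0 = 0}:
#' \deqn{\omega = 2N e^{-2p_0 t}}
#' \deqn{x = \alpha (2N) (e^{-(p_1+p_2)t} - e^{-2p_0 t})}
#' \deqn{y = \alpha p_1 (2N)^2 \left[\frac{1-e^{-(p_1+p_2+2p_0)t}}{p_1+p_2+2p_0}
#'          - \frac{1-e^{-4p_0 t}}{4p_0}\right]}
#' \deqn{z = \alpha \beta p_2 (2N) \left[\frac{1-e^{-(p_1+p_2)t}}{p_1+p_2}
#'          - \frac{1-e^{-2p_0 t}}{2p_0}\right]}
#' with \eqn{\alpha = 2p_0/(2p_0 - (p_1+p_2))}. Note that `x >= 0` for all
#' `t >= 0` even when `alpha < 0`, because the bracketed exponential
#' difference then has the opposite sign.
#'
#' On the singular manifold `|2 p0 - (p1+p2)| < singular_tol * (2 p0 + p1
#' + p2)` the printed form is 0/0 and the analytic limit is used instead
#' (with `s = p1 + p2 = 2 p0`):
#' \deqn{x = 2N s t e^{-st},\quad
#'       y = p_1 (2N)^2 \frac{1 - (1 + 2st)e^{-2st}}{4s},\quad
#'       z = p_2 \beta (2N) \frac{1 - (1 + st)e^{-st}}{s}}
#' The returned frame then carries `attr(., "singular") = TRUE`.
#'
#' @inheritParams one_step_closed_form
#' @param singular_tol relative tolerance for detecting the singular
#'   manifold.
#' @return data.frame with columns `t, omega, x, y, z`.
#' @examples
#' two_step_closed_form(kinetics_params(), t = c(0, 1, 10))
#' @export
two_step_closed_form <- function(params, t, singular_tol = 1e-9) {
  stopifnot(inherits(params, "kinetics_params"))
  check_time(t)
  s <- params$p1 + params$p2
  q <- 2 * params$p0
  twoN <- 2 * params$N
  if (q == 0) {
    # no linker ligation: nothing ever leaves the free pool
    out <- data.frame(t = t, omega = rep(twoN, length(t)), x = 0, y = 0,
                      z = 0)
    attr(out, "singular") <- FALSE
    return(out)
  }
  singular <- abs(q - s) < singular_tol * (q + s)
  omega <- twoN * exp(-q * t)
  if (singular) {
    x <- twoN * s * t * exp(-s * t)
    y <- params$p1 * twoN^2 * (1 - (1 + 2 * s * t) * exp(-2 * s * t)) /
      (4 * s)
    z <- params$p2 * params$beta * twoN * (1 - (1 + s * t) * exp(-s * t)) / s
  } else {
    alpha <- q / (q - s)
    x <- alpha * twoN * (exp(-s * t) - exp(-q * t))
    y <- alpha * params$p1 * twoN^2 *
      ((-expm1(-(s + q) * t)) / (s + q) - (-expm1(-2 * q * t)) / (2 * q))
    z <- alpha * params$beta * params$p2 * twoN *
      ((-expm1(-s * t)) / s - (-expm1(-q * t)) / q)
  }
  out <- data.frame(t = t, omega = omega, x = x, y = y, z = z)
  attr(out, "singular") <- singular
  out
}

#' Numerically integrate a ligation model with fixed-step RK4
#'
#' Classical 4th-order Runge-Kutta on a uniform grid. For non-singular
#' parameters the trajectory agrees with the closed forms to within about
#' `1e-6` relative error when the step is small relative to the fastest
#' rate; it also serves as the reference solution on the singular manifold
#' where the printed two-step closed form degenerates.
#'
#' @inheritParams one_step_closed_form
#' @param model `"one-step"` or `"two-step"`.
#' @param t_end end time (> 0).
#' @param n_steps number of RK4 steps (>= 2); the grid has `n_steps + 1`
#'   points including `t = 0`.
#' @return an object of class `kinetics_trajectory`: a list with `params`,
#'   `model`, and `states` (data.frame `t, omega, x, y, z`).
#' @examples
#' tr <- integrate_kinetics(kinetics_params(), "two-step", t_end = 10,
#'                          n_steps = 1000)
#' head(tr$states)
#' @export
integrate_kinetics <- function(params, model = c("one-step", "two-step"),
                               t_end, n_steps = 10000L) {
  stopifnot(inherits(params, "kinetics_params"))
  model <- match.arg(model)
  m <- .rk4_kinetics_cpp(params$N, params$beta, params$p0, params$p1,
                         params$p2, if (model == "one-step") 1L else 2L,
                         t_end, as.integer(n_steps))
  states <- as.data.frame(m)
  names(states) <- c("t", "omega", "x", "y", "z")
  structure(list(params = params, model = model, states = states),
            class = "kinetics_trajectory")
}

#' @exportS3Method base::print
print.kinetics_trajectory <- function(x, ...) {
  cat(sprintf("kinetics_trajectory: %s model, %d grid points, t in [0, %g]\n",
              x$model, nrow(x$states), max(x$states$t)))
  invisible(x)
}

#' Signal-to-noise ratio curve of a trajectory
#'
#' Returns `y/z` per time point wherever `z > 0`. As `t -> 0+` the ratio
#' tends to `(p1/p2) * (2N/beta)` for both models: with the default
#' parameters (`p1 = 1`, `p2 = 0.025`, `N = beta = 1`) that limit is 80.
#'
#' @param trajectory a `kinetics_trajectory`, or a closed-form state
#'   data.frame as returned by [one_step_closed_form()].
#' @return data.frame with columns `t, ratio`.
#' @export
signal_noise_curve <- function(trajectory) {
  states <- if (inherits(trajectory, "kinetics_trajectory")) {
    trajectory$states
  } else {
    trajectory
  }
  keep <- states$z > 0
  if (!any(keep)) {
    warning("z is zero everywhere; signal/noise ratio undefined")
    return(data.frame(t = numeric(0), ratio = numeric(0)))
  }
  data.frame(t = states$t[keep], ratio = states$y[keep] / states$z[keep])
}

#' Small-time limit of the signal-to-noise ratio
#'
#' Leading-order expansion of `y/z` at `t -> 0+`, equal for both models:
#' `(p1/p2) * (2N/beta)`.
#'
#' @inheritParams one_step_closed_form
#' @return numeric scalar.
#' @export
signal_noise_limit0 <- function(params) {
  (params$p1 / params$p2) * (2 * params$N / params$beta)
}
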