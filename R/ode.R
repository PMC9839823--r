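#' Adaptive Dormand-Prince RK45 integrator
#'
#' Light-weight explicit integrator for the small, non-stiff ODE systems in
#' this package (homogeneous base states, linear mode amplitudes, and
#' independent test oracles). Steps land exactly on the requested output
#' times; error control is per-step WRMS with an embedded 4th-order
#' estimate.
#'
#' @param f function `f(t, y)` returning `dy/dt`.
#' @param y0 numeric initial state.
#' @param times numeric vector of output times (first entry is `t0`).
#' @param rtol,atol relative/absolute tolerances.
#' @param hmax maximum step size.
#' @param max_steps step budget before aborting.
#' @return matrix with `length(times)` rows and `length(y0)` columns.
#' @export
ode_dp45 <- function(f, y0, times, rtol = 1e-8, atol = 1e-10, hmax = Inf,
                     max_steps = 1e6) {
  stopifnot(length(times) >= 2, all(diff(times) > 0))
  n <- length(y0)
  A <- list(
    c(1 / 5),
    c(3 / 40, 9 / 40),
    c(44 / 45, -56 / 15, 32 / 9),
    c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
    c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
    c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
  cc <- c(1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)

  out <- matrix(NA_real_, length(times), n)
  out[1, ] <- y0
  t <- times[1]
  y <- as.numeric(y0)
  k1 <- f(t, y)
  h <- min(hmax, (times[2] - times[1]) / 10, 0.1)
  nstep <- 0L

  for (iout in 2:length(times)) {
    tend <- times[iout]
    while (t < tend - 1e-14 * max(1, abs(tend))) {
      nstep <- nstep + 1L
      if (nstep > max_steps) stop("ode_dp45: step budget exceeded at t = ", t)
      h <- min(h, tend - t, hmax)
      K <- matrix(0, 7, n)
      K[1, ] <- k1
      for (s in 1:6) {
        ys <- y + h * as.numeric(A[[s]] %*% K[seq_along(A[[s]]), , drop = FALSE])
        K[s + 1, ] <- f(t + cc[s] * h, ys)
      }
      y5 <- y + h * as.numeric(b5 %*% K)
      err <- h * as.numeric((b5 - b4) %*% K)
      w <- atol + rtol * pmax(abs(y), abs(y5))
      enorm <- sqrt(mean((err / w)^2))
      if (!is.finite(enorm)) {
        h <- h / 2
        if (h < 1e-14 * max(1, abs(t))) stop("ode_dp45: non-finite state at t = ", t)
        k1 <- f(t, y)
        next
      }
      if (enorm <= 1) {
        t <- t + h
        y <- y5
        k1 <- K[7, ]  # FSAL
        h <- h * min(5, max(0.2, 0.9 * max(enorm, 1e-10)^(-1 / 5)))
      } else {
        h <- h * min(0.9, max(0.1, 0.9 * enorm^(-1 / 5)))
        if (h < 1e-14 * max(1, abs(t))) stop("ode_dp45: step underflow at t = ", t)
      }
    }
    out[iout, ] <- y
  }
  out
}
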