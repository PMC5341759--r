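#' Fixed-step explicit Euler integration
#'
#' Integrates \eqn{\dot x = f(t, x)} with the explicit Euler update
#' \eqn{x(t+\Delta t) = x(t) + \Delta t f(t, x(t))}. The number of steps is
#' `round(T / dt)`; the trajectory includes the initial state and every step.
#' If any state component becomes non-finite or exceeds `overflow_guard` in
#' magnitude, integration aborts with an instability error naming the step.
#'
#' @param deriv_fn function `(t, state) -> numeric` of the same length as
#'   `state0`.
#' @param state0 named numeric vector of initial values.
#' @param dt time step (> 0, `dt <= T`).
#' @param T integration horizon (time units).
#' @param overflow_guard magnitude beyond which the run is declared unstable.
#' @return a data.frame with column `t` followed by one column per state
#'   component.
#' @examples
#' tr <- euler_integrate(function(t, x) -x, c(x = 1), dt = 0.01, T = 5)
#' tail(tr, 1)  # close to exp(-5)
#' @export
euler_integrate <- function(deriv_fn, state0, dt, T, overflow_guard = 1e8) {
  stopifnot(is.numeric(state0), length(state0) >= 1, dt > 0, dt <= T)
  n_steps <- round(T / dt)
  out <- matrix(NA_real_, nrow = n_steps + 1, ncol = length(state0))
  out[1, ] <- state0
  x <- state0
  for (k in seq_len(n_steps)) {
    x <- x + dt * deriv_fn((k - 1) * dt, x)
    if (any(!is.finite(x)) || max(abs(x)) > overflow_guard)
      stop(sprintf(
        "integration unstable at step %d (t = %.4g, dt = %g): state exceeded %g",
        k, k * dt, dt, overflow_guard), call. = FALSE)
    out[k + 1, ] <- x
  }
  df <- data.frame(t = seq(0, by = dt, length.out = n_steps + 1))
  states <- as.data.frame(out)
  names(states) <- if (is.null(names(state0)))
    paste0("x", seq_along(state0)) else names(state0)
  cbind(df, states)
}

#' Central finite-difference gradient
#'
#' The standing numerical oracle for the analytic gradients in this package.
#' For vector arguments, each coordinate is perturbed in turn. For matrix
#' arguments with `symmetric = TRUE`, entries (i, j) and (j, i) are perturbed
#' together (the correct directional derivative when the function is only
#' defined on symmetric matrices, e.g. covariance arguments).
#'
#' @param f scalar-valued function of `x`.
#' @param x numeric vector or matrix.
#' @param step perturbation half-width.
#' @param symmetric for matrix `x`: perturb symmetric pairs jointly.
#' @return gradient with the same shape as `x`.
#' @export
finite_diff_gradient <- function(f, x, step = 1e-5, symmetric = FALSE) {
  stopifnot(step > 0)
  if (is.matrix(x)) {
    g <- matrix(0, nrow(x), ncol(x))
    for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
      hi <- x; lo <- x
      if (symmetric && i != j) {
        hi[i, j] <- hi[i, j] + step; hi[j, i] <- hi[j, i] + step
        lo[i, j] <- lo[i, j] - step; lo[j, i] <- lo[j, i] - step
      } else {
        hi[i, j] <- hi[i, j] + step
        lo[i, j] <- lo[i, j] - step
      }
      g[i, j] <- (f(hi) - f(lo)) / (2 * step)
    }
    return(g)
  }
  vapply(seq_along(x), function(i) {
    hi <- x; lo <- x
    hi[i] <- hi[i] + step
    lo[i] <- lo[i] - step
    (f(hi) - f(lo)) / (2 * step)
  }, numeric(1))
}
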