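#' Observation nonlinearity g(v)
#'
#' The generative models in this package relate a hidden feature `v` to the
#' mean of the observation through a map `g`. Three families are supported:
#'
#' * `"square"`: \eqn{g(v) = v^2} (light intensity proportional to the area of
#'   an object of diameter `v`),
#' * `"linear_theta"`: \eqn{g(v) = \theta v}, a linear gain,
#' * `"theta_h"`: \eqn{g(v) = \theta h(v)}, a gain applied to an inner
#'   nonlinearity `h` (itself `"square"` or `"identity"`).
#'
#' @param kind character; one of `"square"`, `"linear_theta"`, `"theta_h"`.
#' @param theta gain parameter (dimensionless); used by `"linear_theta"` and
#'   `"theta_h"`.
#' @param h_kind inner nonlinearity for `"theta_h"`: `"square"` or
#'   `"identity"`.
#' @return An object of class `nonlinear_map`.
#' @examples
#' g <- nonlinear_map("square")
#' observation_map(g, 3)        # 9
#' observation_deriv(g, 3)      # 6
#' @export
nonlinear_map <- function(kind = c("square", "linear_theta", "theta_h"),
                          theta = 1,
                          h_kind = c("square", "identity")) {
  kind <- match.arg(kind)
  h_kind <- match.arg(h_kind)
  stopifnot(is.numeric(theta), length(theta) == 1, is.finite(theta))
  structure(list(kind = kind, theta = theta, h_kind = h_kind),
            class = "nonlinear_map")
}

#' @export
print.nonlinear_map <- function(x, ...) {
  form <- switch(x$kind,
    square = "g(v) = v^2",
    linear_theta = sprintf("g(v) = theta * v, theta = %g", x$theta),
    theta_h = sprintf("g(v) = theta * h(v), theta = %g, h = %s",
                      x$theta, x$h_kind))
  cat("<nonlinear_map> ", form, "\n", sep = "")
  invisible(x)
}

# inner nonlinearity h and its derivative, applied element-wise
h_eval <- function(h_kind, v) {
  switch(h_kind, square = v^2, identity = v,
         stop("unknown h kind: ", h_kind))
}

h_deriv <- function(h_kind, v) {
  switch(h_kind, square = 2 * v, identity = rep(1, length(v)),
         stop("unknown h kind: ", h_kind))
}

#' Evaluate the observation map and its derivative
#'
#' `observation_map(g, v)` returns \eqn{g(v)}; `observation_deriv(g, v)`
#' returns \eqn{g'(v)}. Both are vectorized over `v`.
#'
#' @param g a [nonlinear_map].
#' @param v numeric vector of feature values.
#' @return numeric vector of the same length as `v`.
#' @export
observation_map <- function(g, v) {
  stopifnot(inherits(g, "nonlinear_map"))
  switch(g$kind,
    square = v^2,
    linear_theta = g$theta * v,
    theta_h = g$theta * h_eval(g$h_kind, v))
}

#' @rdname observation_map
#' @export
observation_deriv <- function(g, v) {
  stopifnot(inherits(g, "nonlinear_map"))
  switch(g$kind,
    square = 2 * v,
    linear_theta = rep(g$theta, length(v)),
    theta_h = g$theta * h_deriv(g$h_kind, v))
}
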