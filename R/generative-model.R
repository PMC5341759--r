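#' Scalar Gaussian generative model
#'
#' A one-feature, one-observation generative model: the hidden feature has a
#' Gaussian prior \eqn{v \sim N(v_p, \Sigma_p)} and the observation is
#' Gaussian around the mapped feature, \eqn{u | v \sim N(g(v), \Sigma_u)}.
#' Note the observation model admits negative intensities; this simplification
#' is kept deliberately and no truncation is applied.
#'
#' @param v_p prior mean of the feature (stimulus units).
#' @param Sigma_p prior variance (> 0).
#' @param Sigma_u observation-noise variance (> 0).
#' @param g a [nonlinear_map]; defaults to the square map.
#' @return An object of class `scalar_model`.
#' @examples
#' m <- scalar_model(v_p = 3, Sigma_p = 1, Sigma_u = 1)
#' post <- exact_posterior(m, u = 2)
#' posterior_argmax(post)
#' @export
scalar_model <- function(v_p, Sigma_p, Sigma_u, g = nonlinear_map("square")) {
  stopifnot(is.numeric(v_p), length(v_p) == 1, is.finite(v_p),
            inherits(g, "nonlinear_map"))
  if (!is.numeric(Sigma_p) || length(Sigma_p) != 1 || !is.finite(Sigma_p) ||
      Sigma_p <= 0)
    stop("Sigma_p must be a positive variance", call. = FALSE)
  if (!is.numeric(Sigma_u) || length(Sigma_u) != 1 || !is.finite(Sigma_u) ||
      Sigma_u <= 0)
    stop("Sigma_u must be a positive variance", call. = FALSE)
  structure(list(v_p = v_p, Sigma_p = Sigma_p, Sigma_u = Sigma_u, g = g),
            class = "scalar_model")
}

#' @export
print.scalar_model <- function(x, ...) {
  cat("<scalar_model> prior N(", x$v_p, ", ", x$Sigma_p,
      "), observation noise Sigma_u = ", x$Sigma_u, "\n", sep = "")
  print(x$g)
  invisible(x)
}

#' Univariate normal density
#'
#' Density of \eqn{N(\mu, \sigma^2)} parameterized by the variance (not the
#' standard deviation, as elsewhere in the circuit equations).
#'
#' @param x evaluation point(s).
#' @param mu mean.
#' @param sigma2 variance (> 0).
#' @param log if `TRUE`, return the log density.
#' @return numeric vector of densities.
#' @examples
#' normal_density(0, 0, 1)   # 1/sqrt(2*pi)
#' @export
normal_density <- function(x, mu, sigma2, log = FALSE) {
  if (!is.numeric(sigma2) || any(!is.finite(sigma2)) || any(sigma2 <= 0))
    stop("sigma2 must be a positive variance", call. = FALSE)
  stats::dnorm(x, mean = mu, sd = sqrt(sigma2), log = log)
}

#' Exact grid posterior over the feature
#'
#' Evaluates the unnormalized posterior \eqn{p(v) p(u|v)} on a uniform grid
#' and normalizes it numerically with the trapezoidal rule; the trapezoidal
#' integral over the grid also estimates the model evidence \eqn{p(u)}.
#' Densities are computed in log space and exponentiated after subtracting
#' the maximum, so regions where the likelihood underflows (the typical case
#' under the square map) do not destabilize the normalization.
#'
#' @param model a [scalar_model].
#' @param u observed value.
#' @param grid_lo,grid_hi,grid_step uniform grid specification (both endpoints
#'   included); defaults reproduce the standard worked example, sizes 0.01 to
#'   5 in steps of 0.01.
#' @return An object of class `posterior_grid` with fields `grid`, `density`
#'   (normalized to integrate to 1) and `normalizer` (the estimate of p(u)).
#' @export
exact_posterior <- function(model, u, grid_lo = 0.01, grid_hi = 5,
                            grid_step = 0.01) {
  stopifnot(inherits(model, "scalar_model"), grid_lo < grid_hi, grid_step > 0)
  grid <- seq(grid_lo, grid_hi, by = grid_step)
  logpost <- normal_density(grid, model$v_p, model$Sigma_p, log = TRUE) +
    normal_density(u, observation_map(model$g, grid), model$Sigma_u,
                   log = TRUE)
  m <- max(logpost)
  if (!is.finite(m))
    stop("degenerate posterior: all grid densities underflow", call. = FALSE)
  w <- exp(logpost - m)
  z <- pracma::trapz(grid, w)
  if (!is.finite(z) || z <= 0)
    stop("degenerate posterior: normalizer is numerically zero",
         call. = FALSE)
  structure(list(grid = grid, density = w / z, normalizer = z * exp(m),
                 u = u),
            class = "posterior_grid")
}

#' @export
print.posterior_grid <- function(x, ...) {
  cat("<posterior_grid> ", length(x$grid), " points on [",
      min(x$grid), ", ", max(x$grid), "], argmax at v = ",
      posterior_argmax(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.posterior_grid <- function(x, ...) {
  data.frame(v = x$grid, posterior_density = x$density)
}

#' Location of the posterior mode on the grid
#'
#' Ties are broken toward the smallest grid value.
#'
#' @param post a `posterior_grid`.
#' @return the grid value with maximal density.
#' @export
posterior_argmax <- function(post) {
  stopifnot(inherits(post, "posterior_grid"), length(post$density) > 0)
  post$grid[which.max(post$density)]
}

#' Write a grid posterior as a two-column CSV
#'
#' @param post a `posterior_grid`.
#' @param path output file; columns `v` and `posterior_density`, with header.
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(post, path) {
  utils::write.csv(as.data.frame(post), path, row.names = FALSE)
  invisible(path)
}

#' Read a scalar model from a flat key-value config file
#'
#' Recognized keys: `v_p`, `sigma_p`, `sigma_u`, `g.kind`, `g.theta`,
#' `g.h_kind` (the `g.*` keys are optional; default is the square map).
#'
#' @param path a YAML-formatted flat key-value file.
#' @return a [scalar_model].
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("v_p", "sigma_p", "sigma_u")
  if (!all(need %in% names(cfg)))
    stop("model config must define keys: ", paste(need, collapse = ", "),
         call. = FALSE)
  g <- nonlinear_map(
    kind = if (is.null(cfg[["g.kind"]])) "square" else cfg[["g.kind"]],
    theta = if (is.null(cfg[["g.theta"]])) 1 else cfg[["g.theta"]],
    h_kind = if (is.null(cfg[["g.h_kind"]])) "square" else cfg[["g.h_kind"]])
  scalar_model(cfg$v_p, cfg$sigma_p, cfg$sigma_u, g)
}
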