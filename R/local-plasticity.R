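#' Prediction-error unit with an inhibitory interneuron
#'
#' In the plain circuit, dividing by the variance (or multiplying by a
#' covariance inverse) appears both in the error fixed point and in the
#' learning rule, which a single synapse cannot compute locally. Pairing each
#' error node \eqn{\varepsilon} with an inhibitory interneuron \eqn{e}
#' removes the inverse: the dynamics
#' \deqn{\dot{\bar\varepsilon} = \mathrm{drive} - \bar e, \qquad
#'       \dot{\bar e} = \Sigma\bar\varepsilon - \bar e,}
#' (drive \eqn{= \bar\phi_i - g_i(\bar\phi_{i+1})}, held constant on the fast
#' timescale of these nodes) have their fixed point at
#' \eqn{\bar\varepsilon = \Sigma^{-1}\mathrm{drive}},
#' \eqn{\bar e = \mathrm{drive}}: the division is performed dynamically by
#' the loop through the interneuron.
#'
#' @param eps,e activity vectors of the error nodes and interneurons (same
#'   length).
#' @param Sigma connection-weight matrix (scalar allowed for one unit);
#'   symmetric under the covariance interpretation.
#' @param drive input vector \eqn{\bar\phi_i - g_i(\bar\phi_{i+1})}.
#' @return `error_unit_derivatives`: list with `deps` and `de`.
#' @export
error_unit_derivatives <- function(eps, e, Sigma, drive) {
  Sigma <- as.matrix(Sigma)
  n <- length(eps)
  stopifnot(length(e) == n, length(drive) == n,
            nrow(Sigma) == n, ncol(Sigma) == n)
  list(deps = drive - e,
       de = as.numeric(Sigma %*% eps) - e)
}

#' @rdname error_unit_derivatives
#' @return `error_unit_fixed_point`: list with `eps` (\eqn{\Sigma^{-1}}
#'   drive) and `e` (drive).
#' @export
error_unit_fixed_point <- function(Sigma, drive) {
  Sigma <- as.matrix(Sigma)
  eps <- tryCatch(solve(Sigma, drive), error = function(err)
    stop("Sigma is singular: ", conditionMessage(err), call. = FALSE))
  list(eps = as.numeric(eps), e = as.numeric(drive))
}

#' Linear stability of the error/interneuron loop
#'
#' Written in vector form the loop is linear,
#' \eqn{d/dt\,(\bar\varepsilon, \bar e)^T = M (\bar\varepsilon, \bar e)^T +
#' (\mathrm{drive}, 0)^T} with block system matrix
#' \deqn{M = \begin{pmatrix} 0 & -I \\ \Sigma & -I \end{pmatrix}.}
#' For a single unit, \eqn{M = [[0, -1], [\Sigma, -1]]} has trace \eqn{-1}
#' and determinant \eqn{\Sigma}; for any \eqn{\Sigma > 0} the eigenvalue sum
#' is negative and the product positive, so both eigenvalues have negative
#' real part and the fixed point is stable.
#'
#' @param Sigma weight matrix (scalar allowed).
#' @return a list of class `stability_analysis`: `matrix` (the 2n x 2n system
#'   matrix), `eigenvalues`, `trace`, `determinant`, `stable` (all real parts
#'   negative).
#' @examples
#' stability_analysis(1)$eigenvalues  # -0.5 +- 0.866i
#' @export
stability_analysis <- function(Sigma) {
  Sigma <- as.matrix(Sigma)
  n <- nrow(Sigma)
  M <- rbind(cbind(matrix(0, n, n), -diag(n)),
             cbind(Sigma, -diag(n)))
  ev <- eigen(M, only.values = TRUE)$values
  structure(list(matrix = M, eigenvalues = ev,
                 trace = sum(diag(M)), determinant = det(M),
                 stable = all(Re(ev) < 0)),
            class = "stability_analysis")
}

#' @export
print.stability_analysis <- function(x, ...) {
  cat("<stability_analysis> trace ", x$trace, ", determinant ",
      format(x$determinant), ", ",
      if (x$stable) "stable" else "UNSTABLE", "\n", sep = "")
  cat("eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

#' Local Hebbian update of the error-unit weights
#'
#' \deqn{\Sigma \leftarrow \Sigma + \alpha(\bar\varepsilon\bar e^T - I)}
#' (scalar case \eqn{\Sigma \leftarrow \Sigma + \alpha(\varepsilon e - 1)}).
#' Each weight update reads only the activities of the two neurons the
#' connection joins, so learning is strictly local: no matrix inverse appears
#' anywhere on this path. The instantaneous outer product is not symmetric,
#' so the matrix is re-symmetrized after the step (the expected update is
#' symmetric, and symmetry preserves the covariance interpretation); finally
#' eigenvalues are clipped from below at `floor` (scalar: a hard floor),
#' preventing the loop dynamics from losing stability as weights shrink.
#'
#' @param Sigma current weight matrix (scalar allowed).
#' @param eps,e converged activity vectors.
#' @param alpha learning rate (>= 0).
#' @param floor minimum variance / eigenvalue after the update.
#' @return updated weight matrix (scalar in, scalar out).
#' @export
local_sigma_update <- function(Sigma, eps, e, alpha, floor = 1) {
  stopifnot(alpha >= 0)
  scalar_in <- is.null(dim(Sigma)) && length(Sigma) == 1
  S <- as.matrix(Sigma)
  n <- nrow(S)
  stopifnot(length(eps) == n, length(e) == n)
  if (alpha == 0) return(if (scalar_in) as.numeric(S) else S)
  S <- S + alpha * (tcrossprod(eps, e) - diag(n))
  S <- if (n == 1) pmax(floor, S) else floor_covariance(S, floor)
  if (scalar_in) as.numeric(S) else S
}

#' Learn variances and covariances over trials with local plasticity
#'
#' Per trial: a constant drive is taken from the stream, the error/interneuron
#' loop is integrated from rest for `T_inner` time units (long enough, at the
#' default settings, for the activities to settle at their fixed point), and
#' the weights are updated with [local_sigma_update()]. The stochastic fixed
#' point of the rule is the covariance of the drives,
#' \eqn{\Sigma = \langle \mathrm{drive}\,\mathrm{drive}^T\rangle}, so over
#' many trials the weights fluctuate around the generating (co)variance.
#'
#' @param trials a [trial_stream], or a matrix of drives (one trial per row;
#'   a numeric vector is treated as single-unit drives).
#' @param Sigma0 initial weights; defaults to the identity (scalar 1).
#' @param alpha learning rate.
#' @param T_inner inner integration horizon per trial (time units).
#' @param dt inner Euler step.
#' @param floor variance / eigenvalue floor.
#' @return for a single unit, a data.frame `trial`, `Sigma`; otherwise a list
#'   with `Sigma` (final matrix) and `path` (array n_trials x n x n).
#' @examples
#' st <- trial_stream(200, mean = 5, cov = 2, g_pred = 5, seed = 42)
#' tail(run_variance_learning(st), 1)
#' @export
run_variance_learning <- function(trials, Sigma0 = NULL, alpha = 0.01,
                                  T_inner = 20, dt = 0.01, floor = 1) {
  stopifnot(alpha > 0, T_inner > 0, dt > 0, dt <= T_inner)
  drives <- if (inherits(trials, "trial_stream")) generate_trials(trials)
            else if (is.null(dim(trials))) matrix(trials, ncol = 1)
            else as.matrix(trials)
  n <- ncol(drives)
  n_trials <- nrow(drives)
  if (is.null(Sigma0)) Sigma0 <- diag(n)
  S <- as.matrix(Sigma0)
  stopifnot(nrow(S) == n, ncol(S) == n)
  n_steps <- round(T_inner / dt)
  if (n == 1) {
    path <- numeric(n_trials)
    sig <- S[1, 1]
    for (k in seq_len(n_trials)) {
      d <- drives[k, 1]
      eps <- 0; e <- 0
      for (s in seq_len(n_steps)) {
        deps <- d - e
        de <- sig * eps - e
        eps <- eps + dt * deps
        e <- e + dt * de
      }
      if (!is.finite(eps) || abs(eps) > 1e8)
        stop("error-unit dynamics unstable at trial ", k, call. = FALSE)
      sig <- max(floor, sig + alpha * (eps * e - 1))
      path[k] <- sig
    }
    return(data.frame(trial = seq_len(n_trials), Sigma = path))
  }
  path <- array(NA_real_, c(n_trials, n, n))
  I_n <- diag(n)
  for (k in seq_len(n_trials)) {
    d <- drives[k, ]
    eps <- numeric(n); e <- numeric(n)
    for (s in seq_len(n_steps)) {
      deps <- d - e
      de <- as.numeric(S %*% eps) - e
      eps <- eps + dt * deps
      e <- e + dt * de
    }
    if (any(!is.finite(eps)) || max(abs(eps)) > 1e8)
      stop("error-unit dynamics unstable at trial ", k, call. = FALSE)
    S <- S + alpha * (tcrossprod(eps, e) - I_n)
    S <- floor_covariance(S, floor)
    path[k, , ] <- S
  }
  list(Sigma = S, path = path)
}

#' Attention as precision modulation
#'
#' Attending to a feature can be modelled as decreasing the variance
#' associated with it, which boosts the gain of its prediction-error node on
#' the rest of the network. This helper scales the selected rows/columns of a
#' weight (covariance) matrix by `factor` (< 1 = attend) and re-applies the
#' eigenvalue floor; it is a configuration of existing operations, not a new
#' mechanism.
#'
#' @param Sigma weight matrix (scalar allowed).
#' @param features indices of the attended features.
#' @param factor multiplicative change of the associated variances.
#' @param floor eigenvalue floor re-applied after scaling.
#' @return modulated matrix.
#' @export
modulate_precision <- function(Sigma, features, factor, floor = 1) {
  scalar_in <- is.null(dim(Sigma)) && length(Sigma) == 1
  S <- as.matrix(Sigma)
  scale <- rep(1, nrow(S))
  scale[features] <- sqrt(factor)
  S <- diag(scale, nrow(S)) %*% S %*% diag(scale, nrow(S))
  S <- if (nrow(S) == 1) pmax(floor, S) else floor_covariance(S, floor)
  if (scalar_in) as.numeric(S) else S
}
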