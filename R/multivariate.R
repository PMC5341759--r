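# Internal helpers for the multivariate model ---------------------------------

# log |A| for a symmetric positive-definite matrix, via Cholesky
logdet_spd <- function(A) {
  ch <- tryCatch(chol(A), error = function(e)
    stop("covariance matrix is singular or not positive definite",
         call. = FALSE))
  2 * sum(log(diag(ch)))
}

solve_spd <- function(A, b) {
  tryCatch(solve(A, b), error = function(e)
    stop("covariance matrix is singular: ", conditionMessage(e),
         call. = FALSE))
}

# Symmetrize and clip eigenvalues from below: the matrix generalization of the
# scalar variance floor.
floor_covariance <- function(S, min_eig = 1) {
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  vals <- pmax(es$values, min_eig)
  S2 <- es$vectors %*% (vals * t(es$vectors))
  (S2 + t(S2)) / 2
}

#' Multivariate generative model
#'
#' Several features generating several observations: the feature vector has a
#' Gaussian prior \eqn{\bar v \sim N(\bar v_p, \Sigma_p)} and the observation
#' is Gaussian around \eqn{g(\bar v) = \Theta h(\bar v)}, where `h` acts
#' element-wise and \eqn{\Theta} is a matrix of synaptic weights (features
#' combine linearly after the element-wise nonlinearity).
#'
#' @param v_p prior mean vector (length = number of features).
#' @param Sigma_p prior covariance (features x features), symmetric positive
#'   definite.
#' @param Sigma_u observation-noise covariance (observations x observations).
#' @param Theta weight matrix, observations x features.
#' @param h element-wise nonlinearity: `"square"` or `"identity"`.
#' @return an object of class `mv_model`.
#' @export
mv_model <- function(v_p, Sigma_p, Sigma_u, Theta,
                     h = c("square", "identity")) {
  h <- match.arg(h)
  v_p <- as.numeric(v_p)
  Sigma_p <- as.matrix(Sigma_p); Sigma_u <- as.matrix(Sigma_u)
  Theta <- as.matrix(Theta)
  n_phi <- length(v_p); n_u <- nrow(Theta)
  if (ncol(Theta) != n_phi || nrow(Sigma_p) != n_phi ||
      ncol(Sigma_p) != n_phi || nrow(Sigma_u) != n_u || ncol(Sigma_u) != n_u)
    stop("inconsistent dimensions among v_p, Sigma_p, Sigma_u, Theta",
         call. = FALSE)
  if (max(abs(Sigma_p - t(Sigma_p))) > 1e-8 ||
      max(abs(Sigma_u - t(Sigma_u))) > 1e-8)
    stop("covariance matrices must be symmetric", call. = FALSE)
  structure(list(v_p = v_p, Sigma_p = Sigma_p, Sigma_u = Sigma_u,
                 Theta = Theta, h = h, n_phi = n_phi, n_u = n_u),
            class = "mv_model")
}

#' @export
print.mv_model <- function(x, ...) {
  cat("<mv_model> ", x$n_phi, " features -> ", x$n_u,
      " observations, h = ", x$h, "\n", sep = "")
  invisible(x)
}

mv_predict <- function(model, phi) as.numeric(model$Theta %*% h_eval(model$h, phi))

#' Negative free energy of the multivariate model
#'
#' \deqn{F = \tfrac12\big(-\ln|\Sigma_p|
#'   - (\bar\phi-\bar v_p)^T\Sigma_p^{-1}(\bar\phi-\bar v_p)
#'   - \ln|\Sigma_u|
#'   - (\bar u-\Theta h(\bar\phi))^T\Sigma_u^{-1}(\bar u-\Theta h(\bar\phi))
#'   \big) - N\ln 2\pi,}
#' with \eqn{N = (n_\phi + n_u)/2}-fold constants retained so the value
#' equals the joint log density \eqn{\ln p(\bar u, \bar\phi)} exactly.
#'
#' @param model an [mv_model].
#' @param u observation vector.
#' @param phi candidate feature vector.
#' @return F (nats).
#' @export
mv_negative_free_energy <- function(model, u, phi) {
  stopifnot(inherits(model, "mv_model"),
            length(u) == model$n_u, length(phi) == model$n_phi)
  rp <- phi - model$v_p
  ru <- u - mv_predict(model, phi)
  0.5 * (-logdet_spd(model$Sigma_p) -
           sum(rp * solve_spd(model$Sigma_p, rp)) -
           logdet_spd(model$Sigma_u) -
           sum(ru * solve_spd(model$Sigma_u, ru))) -
    (model$n_phi + model$n_u) / 2 * log(2 * pi)
}

#' Gradient of F with respect to the feature vector
#'
#' \deqn{\partial F/\partial\bar\phi = -\bar\varepsilon_p
#'   + h'(\bar\phi)\circ(\Theta^T\bar\varepsilon_u)} with
#' \eqn{\bar\varepsilon_p = \Sigma_p^{-1}(\bar\phi-\bar v_p)} and
#' \eqn{\bar\varepsilon_u = \Sigma_u^{-1}(\bar u-\Theta h(\bar\phi))};
#' \eqn{\circ} is the element-wise product arising from the diagonal
#' structure of the Jacobian of the element-wise `h`.
#'
#' @inheritParams mv_negative_free_energy
#' @return gradient vector, length `n_phi`.
#' @export
mv_grad_phi <- function(model, u, phi) {
  stopifnot(inherits(model, "mv_model"))
  eps_p <- as.numeric(solve_spd(model$Sigma_p, phi - model$v_p))
  eps_u <- as.numeric(solve_spd(model$Sigma_u, u - mv_predict(model, phi)))
  -eps_p + h_deriv(model$h, phi) * as.numeric(crossprod(model$Theta, eps_u))
}

#' Infer the feature vector by gradient ascent on F
#'
#' @inheritParams mv_negative_free_energy
#' @param phi0 initial feature vector; defaults to the prior mean.
#' @param dt,T Euler step and horizon.
#' @return data.frame with `t` and one column per feature (`phi1`, ...).
#' @export
mv_infer_phi <- function(model, u, phi0 = model$v_p, dt = 0.01, T = 5) {
  state0 <- stats::setNames(phi0, paste0("phi", seq_along(phi0)))
  euler_integrate(function(t, s) mv_grad_phi(model, u, s),
                  state0, dt = dt, T = T)
}

#' Hebbian gradients for the multivariate model parameters
#'
#' At the error fixed points
#' \eqn{\bar\varepsilon_p = \Sigma_p^{-1}(\bar\phi-\bar v_p)},
#' \eqn{\bar\varepsilon_u = \Sigma_u^{-1}(\bar u - \Theta h(\bar\phi))}:
#' \deqn{\partial F/\partial\bar v_p = \bar\varepsilon_p,\quad
#'   \partial F/\partial\Sigma =
#'     \tfrac12(\bar\varepsilon\bar\varepsilon^T - \Sigma^{-1}),\quad
#'   \partial F/\partial\Theta = \bar\varepsilon_u h(\bar\phi)^T.}
#' The covariance gradients are symmetric by construction. Note the
#' \eqn{\Sigma^{-1}} terms: each covariance synapse would need to know the
#' whole matrix, which motivates the interneuron circuit in
#' [error_unit_derivatives()] where that inverse is computed dynamically.
#'
#' @inheritParams mv_negative_free_energy
#' @return list with components `v_p`, `Sigma_p`, `Sigma_u`, `Theta`.
#' @export
mv_parameter_gradients <- function(model, u, phi) {
  stopifnot(inherits(model, "mv_model"))
  eps_p <- as.numeric(solve_spd(model$Sigma_p, phi - model$v_p))
  eps_u <- as.numeric(solve_spd(model$Sigma_u, u - mv_predict(model, phi)))
  list(v_p = eps_p,
       Sigma_p = 0.5 * (tcrossprod(eps_p) - solve(model$Sigma_p)),
       Sigma_u = 0.5 * (tcrossprod(eps_u) - solve(model$Sigma_u)),
       Theta = tcrossprod(eps_u, h_eval(model$h, phi)))
}

#' Learn the observation weights over trials
#'
#' Per trial: infer the features by gradient ascent under the current model,
#' then apply the Hebbian update
#' \eqn{\Theta \leftarrow \Theta + \alpha\,\bar\varepsilon_u h(\bar\phi)^T}.
#' Covariances and the prior are held fixed. With enough trials, low
#' observation noise and features drawn independently, the learned weights
#' come to reconstruct the observations (recovery is up to permutation and
#' sign of the feature axes, so quality is judged on reconstructions, not raw
#' weights).
#'
#' @param model an [mv_model]; `model$Theta` is the starting weight matrix.
#' @param U matrix of observations, one trial per row.
#' @param alpha learning rate for `Theta`.
#' @param dt,T Euler step and per-trial inference horizon.
#' @return a list: `model` (with learned `Theta`) and `Theta_path` (array
#'   n_trials x n_u x n_phi of post-update weights).
#' @export
mv_learn_theta <- function(model, U, alpha = 0.01, dt = 0.05, T = 5) {
  stopifnot(inherits(model, "mv_model"), is.matrix(U),
            ncol(U) == model$n_u, alpha > 0)
  Theta <- model$Theta
  inv_Sp <- solve(model$Sigma_p)
  inv_Su <- solve(model$Sigma_u)
  n_steps <- round(T / dt)
  path <- array(NA_real_, c(nrow(U), model$n_u, model$n_phi))
  for (k in seq_len(nrow(U))) {
    u <- U[k, ]
    phi <- model$v_p
    for (s in seq_len(n_steps)) {
      eps_p <- as.numeric(inv_Sp %*% (phi - model$v_p))
      eps_u <- as.numeric(inv_Su %*% (u - Theta %*% h_eval(model$h, phi)))
      phi <- phi + dt * (-eps_p +
        h_deriv(model$h, phi) * as.numeric(crossprod(Theta, eps_u)))
      if (max(abs(phi)) > 1e8)
        stop("inference diverged during weight learning at trial ", k,
             call. = FALSE)
    }
    eps_u <- as.numeric(inv_Su %*% (u - Theta %*% h_eval(model$h, phi)))
    Theta <- Theta + alpha * tcrossprod(eps_u, h_eval(model$h, phi))
    path[k, , ] <- Theta
  }
  out <- model
  out$Theta <- Theta
  list(model = out, Theta_path = path)
}
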