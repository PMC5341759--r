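#' Negative free energy of a scalar model
#'
#' With a point-mass (delta) approximate posterior centred at `phi`, the
#' negative free energy reduces to the joint log density
#' \eqn{F = \ln p(\phi) + \ln p(u|\phi)}. All constant terms are retained, so
#' the returned value equals \eqn{\ln p(u, \phi)} exactly:
#' \deqn{F = \tfrac12\big(-\ln\Sigma_p - (\phi-v_p)^2/\Sigma_p
#'       - \ln\Sigma_u - (u-g(\phi))^2/\Sigma_u\big) - \ln 2\pi.}
#'
#' @param model a [scalar_model].
#' @param u observed value.
#' @param phi candidate feature value (vectorized).
#' @return F (nats).
#' @export
negative_free_energy <- function(model, u, phi) {
  stopifnot(inherits(model, "scalar_model"))
  0.5 * (-log(model$Sigma_p) - (phi - model$v_p)^2 / model$Sigma_p -
         log(model$Sigma_u) -
         (u - observation_map(model$g, phi))^2 / model$Sigma_u) - log(2 * pi)
}

#' Gradient of F with respect to the inferred feature
#'
#' \deqn{\partial F/\partial\phi = (v_p-\phi)/\Sigma_p
#'       + g'(\phi)(u-g(\phi))/\Sigma_u.}
#'
#' @inheritParams negative_free_energy
#' @return dF/dphi (vectorized over `phi`).
#' @export
grad_F_phi <- function(model, u, phi) {
  stopifnot(inherits(model, "scalar_model"))
  (model$v_p - phi) / model$Sigma_p +
    (u - observation_map(model$g, phi)) *
      observation_deriv(model$g, phi) / model$Sigma_u
}

#' Infer the feature by gradient ascent on F
#'
#' Euler iteration of \eqn{\dot\phi = \partial F/\partial\phi} from `phi0`.
#'
#' @inheritParams negative_free_energy
#' @param phi0 initial value; defaults to the prior mean.
#' @param dt Euler step (time units).
#' @param T integration horizon.
#' @return data.frame with columns `t`, `phi`; the last row holds the final
#'   estimate.
#' @examples
#' m <- scalar_model(3, 1, 1)
#' tr <- infer_phi_gradient(m, u = 2)
#' round(tr$phi[nrow(tr)], 1)  # 1.6
#' @export
infer_phi_gradient <- function(model, u, phi0 = model$v_p, dt = 0.01, T = 5) {
  euler_integrate(function(t, s) grad_F_phi(model, u, s),
                  c(phi = phi0), dt = dt, T = T)
}

#' Prediction-error circuit derivatives
#'
#' Right-hand sides of the three-node circuit in which prediction errors are
#' computed dynamically rather than read off in closed form:
#' \deqn{\dot\phi = \varepsilon_u g'(\phi) - \varepsilon_p, \quad
#'       \dot\varepsilon_p = \phi - v_p - \Sigma_p\varepsilon_p, \quad
#'       \dot\varepsilon_u = u - g(\phi) - \Sigma_u\varepsilon_u.}
#' At the error nodes' fixed points \eqn{\varepsilon_p = (\phi-v_p)/\Sigma_p}
#' and \eqn{\varepsilon_u = (u-g(\phi))/\Sigma_u}, and \eqn{\dot\phi} equals
#' [grad_F_phi()].
#'
#' @inheritParams negative_free_energy
#' @param state named numeric vector `c(phi=, eps_p=, eps_u=)`.
#' @return named numeric vector of derivatives.
#' @export
circuit_derivatives <- function(model, u, state) {
  stopifnot(inherits(model, "scalar_model"),
            all(c("phi", "eps_p", "eps_u") %in% names(state)))
  phi <- state[["phi"]]; ep <- state[["eps_p"]]; eu <- state[["eps_u"]]
  c(phi = eu * observation_deriv(model$g, phi) - ep,
    eps_p = phi - model$v_p - model$Sigma_p * ep,
    eps_u = u - observation_map(model$g, phi) - model$Sigma_u * eu)
}

#' Simulate the scalar prediction-error circuit
#'
#' Euler integration of [circuit_derivatives()]. The default initial state is
#' the one used throughout the worked exercises: \eqn{\phi = v_p},
#' \eqn{\varepsilon_p = \varepsilon_u = 0}. Convergence is slower and
#' oscillatory compared with direct gradient ascent, because the coupled
#' excitatory/inhibitory nodes ring before settling.
#'
#' @inheritParams negative_free_energy
#' @param state0 initial state, named as in [circuit_derivatives()].
#' @param dt,T Euler step and horizon.
#' @return data.frame with columns `t`, `phi`, `eps_p`, `eps_u`.
#' @export
simulate_circuit <- function(model, u,
                             state0 = c(phi = model$v_p, eps_p = 0,
                                        eps_u = 0),
                             dt = 0.01, T = 5) {
  euler_integrate(function(t, s) circuit_derivatives(model, u, s),
                  state0, dt = dt, T = T)
}

#' Hebbian gradients for the scalar model parameters
#'
#' In terms of the converged prediction errors the parameter gradients are
#' purely local:
#' \deqn{\partial F/\partial v_p = \varepsilon_p,\quad
#'   \partial F/\partial\Sigma_p = \tfrac12(\varepsilon_p^2 - 1/\Sigma_p),
#'   \quad
#'   \partial F/\partial\Sigma_u = \tfrac12(\varepsilon_u^2 - 1/\Sigma_u).}
#' `parameter_gradients_direct()` computes the same three gradients from
#' `(phi, u)` without reference to error-node activities; the two agree
#' whenever the errors are at their fixed-point values.
#'
#' @param model a [scalar_model].
#' @param eps_p,eps_u prediction-error activities.
#' @return named numeric vector `c(v_p=, Sigma_p=, Sigma_u=)`.
#' @export
parameter_gradients <- function(model, eps_p, eps_u) {
  stopifnot(inherits(model, "scalar_model"))
  c(v_p = eps_p,
    Sigma_p = 0.5 * (eps_p^2 - 1 / model$Sigma_p),
    Sigma_u = 0.5 * (eps_u^2 - 1 / model$Sigma_u))
}

#' @rdname parameter_gradients
#' @param u observed value.
#' @param phi inferred feature value.
#' @export
parameter_gradients_direct <- function(model, u, phi) {
  stopifnot(inherits(model, "scalar_model"))
  r_p <- phi - model$v_p
  r_u <- u - observation_map(model$g, phi)
  c(v_p = r_p / model$Sigma_p,
    Sigma_p = 0.5 * (r_p^2 / model$Sigma_p^2 - 1 / model$Sigma_p),
    Sigma_u = 0.5 * (r_u^2 / model$Sigma_u^2 - 1 / model$Sigma_u))
}

#' Per-trial learning rates
#'
#' @param alpha_vp,alpha_sigma,alpha_theta positive per-trial step sizes for
#'   the prior mean, the variances and the observation gain respectively.
#' @return an object of class `learning_rates`.
#' @export
learning_rates <- function(alpha_vp = 0.01, alpha_sigma = 0.01,
                           alpha_theta = 0.01) {
  stopifnot(alpha_vp >= 0, alpha_sigma >= 0, alpha_theta >= 0)
  structure(list(alpha_vp = alpha_vp, alpha_sigma = alpha_sigma,
                 alpha_theta = alpha_theta), class = "learning_rates")
}

#' Learn the scalar model parameters over trials
#'
#' Runs one inference episode per trial, then nudges `v_p`, `Sigma_p` and
#' `Sigma_u` along their Hebbian gradients. Learned variances are floored at
#' 1 after every update (a variance near zero would make the error-node
#' dynamics diverge or converge arbitrarily slowly); the floor is applied
#' only to parameters actually being learned, so a fixed sub-unit variance in
#' the model is left alone when its rate is zero.
#'
#' Two interpretations of the trial stream are supported:
#' * `clamp_phi = FALSE` (default): each trial value is an observation `u`;
#'   the full circuit is simulated for `T` time units and the final error
#'   activities drive the updates.
#' * `clamp_phi = TRUE`: each trial value is a direct sample of the feature
#'   \eqn{\phi}; errors are evaluated at their fixed points and only the
#'   prior parameters `(v_p, Sigma_p)` are updated. This mode matches the
#'   stationarity analysis \eqn{v_p = \langle\phi\rangle},
#'   \eqn{\Sigma_p = \langle(\phi - v_p)^2\rangle} exactly.
#'
#' @param model a [scalar_model]; starting parameter values.
#' @param trials numeric vector of per-trial inputs, or a [trial_stream]
#'   (drives are generated and the stream mean re-added, i.e. raw draws are
#'   used).
#' @param rates a [learning_rates].
#' @param dt,T Euler step and per-trial horizon for the circuit simulation.
#' @param clamp_phi see Details.
#' @return data.frame with one row per trial: `trial`, `v_p`, `Sigma_p`,
#'   `Sigma_u` (values after that trial's update).
#' @export
learn_parameters <- function(model, trials, rates = learning_rates(),
                             dt = 0.01, T = 5, clamp_phi = FALSE) {
  stopifnot(inherits(model, "scalar_model"),
            inherits(rates, "learning_rates"))
  if (inherits(trials, "trial_stream")) {
    stopifnot(trials$dim == 1)
    trials <- as.numeric(generate_trials(trials)) + trials$g_pred
  }
  stopifnot(is.numeric(trials), length(trials) >= 1)
  vp <- model$v_p; sp <- model$Sigma_p; su <- model$Sigma_u
  out <- matrix(NA_real_, nrow = length(trials), ncol = 3)
  for (k in seq_along(trials)) {
    m_k <- scalar_model(vp, sp, su, model$g)
    if (clamp_phi) {
      phi <- trials[k]
      ep <- (phi - vp) / sp
      vp <- vp + rates$alpha_vp * ep
      sp <- sp + rates$alpha_sigma * 0.5 * (ep^2 - 1 / sp)
      if (rates$alpha_sigma > 0) sp <- max(1, sp)
    } else {
      tr <- simulate_circuit(m_k, trials[k], dt = dt, T = T)
      fin <- tr[nrow(tr), ]
      g <- parameter_gradients(m_k, fin$eps_p, fin$eps_u)
      vp <- vp + rates$alpha_vp * g[["v_p"]]
      sp <- sp + rates$alpha_sigma * g[["Sigma_p"]]
      su <- su + rates$alpha_sigma * g[["Sigma_u"]]
      if (rates$alpha_sigma > 0) {
        sp <- max(1, sp)
        su <- max(1, su)
      }
    }
    out[k, ] <- c(vp, sp, su)
  }
  data.frame(trial = seq_along(trials), v_p = out[, 1], Sigma_p = out[, 2],
             Sigma_u = out[, 3])
}

#' Circuit derivatives for parameterized observation maps
#'
#' The scalar circuit when the observation map carries a learnable gain:
#' for \eqn{g(v) = \theta v},
#' \deqn{\dot\phi = \theta\varepsilon_u - \varepsilon_p,\quad
#'       \dot\varepsilon_u = u - \theta\phi - \Sigma_u\varepsilon_u,}
#' and for \eqn{g(v) = \theta h(v)},
#' \deqn{\dot\phi = \theta\varepsilon_u h'(\phi) - \varepsilon_p,\quad
#'       \dot\varepsilon_u = u - \theta h(\phi) - \Sigma_u\varepsilon_u,}
#' with \eqn{\dot\varepsilon_p} unchanged. Requires `model$g$kind` to be
#' `"linear_theta"` or `"theta_h"`.
#'
#' @inheritParams circuit_derivatives
#' @return named numeric vector of derivatives.
#' @export
theta_circuit_derivatives <- function(model, u, state) {
  stopifnot(inherits(model, "scalar_model"))
  if (!model$g$kind %in% c("linear_theta", "theta_h"))
    stop("theta_circuit_derivatives requires g of kind 'linear_theta' or ",
         "'theta_h', got '", model$g$kind, "'", call. = FALSE)
  phi <- state[["phi"]]; ep <- state[["eps_p"]]; eu <- state[["eps_u"]]
  th <- model$g$theta
  if (model$g$kind == "linear_theta") {
    c(phi = th * eu - ep,
      eps_p = phi - model$v_p - model$Sigma_p * ep,
      eps_u = u - th * phi - model$Sigma_u * eu)
  } else {
    c(phi = th * eu * h_deriv(model$g$h_kind, phi) - ep,
      eps_p = phi - model$v_p - model$Sigma_p * ep,
      eps_u = u - th * h_eval(model$g$h_kind, phi) - model$Sigma_u * eu)
  }
}

#' Hebbian gradient for the observation gain
#'
#' \eqn{\partial F/\partial\theta = \varepsilon_u\phi} for the linear map and
#' \eqn{\varepsilon_u h(\phi)} for the gain-times-nonlinearity map: the
#' product of the activities at the two ends of the connection encoding
#' theta.
#'
#' @param eps_u sensory prediction-error activity.
#' @param phi inferred feature value.
#' @param h_kind `"identity"` for the linear map, or the inner nonlinearity
#'   (`"square"`) of the theta-h map.
#' @return dF/dtheta.
#' @export
grad_theta <- function(eps_u, phi, h_kind = "identity") {
  eps_u * h_eval(h_kind, phi)
}
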