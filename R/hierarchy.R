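#' Per-layer parameters of the hierarchical network
#'
#' A hierarchy with L levels of activity \eqn{\bar\phi_1, \dots, \bar\phi_L}
#' (level 1 is the sensory input, clamped to the observation) is specified by
#' one `layer_params` per level of prediction error. For levels
#' \eqn{i < L}, `Theta` (n_i x n_{i+1}) and `h` define the top-down
#' prediction \eqn{g_i(\bar\phi_{i+1}) = \Theta_i h(\bar\phi_{i+1})} and
#' `Sigma` (n_i x n_i) the covariance of level i's errors. The top level
#' closes the chain with a fixed Gaussian prior: `v_p` instead of `Theta`.
#'
#' @param Sigma error covariance at this level (symmetric, positive
#'   definite).
#' @param Theta top-down weight matrix (omit for the top level).
#' @param h element-wise nonlinearity of the top-down prediction.
#' @param v_p prior mean vector (top level only).
#' @return an object of class `layer_params`.
#' @export
layer_params <- function(Sigma, Theta = NULL, h = c("identity", "square"),
                         v_p = NULL) {
  h <- match.arg(h)
  Sigma <- as.matrix(Sigma)
  if (max(abs(Sigma - t(Sigma))) > 1e-8)
    stop("Sigma must be symmetric", call. = FALSE)
  if (is.null(Theta) == is.null(v_p))
    stop("supply exactly one of Theta (inner level) or v_p (top level)",
         call. = FALSE)
  if (!is.null(Theta)) {
    Theta <- as.matrix(Theta)
    if (nrow(Theta) != nrow(Sigma))
      stop("Theta rows must match Sigma dimension", call. = FALSE)
  }
  if (!is.null(v_p) && length(v_p) != nrow(Sigma))
    stop("v_p length must match Sigma dimension", call. = FALSE)
  structure(list(Sigma = Sigma, Theta = Theta, h = h, v_p = v_p,
                 n = nrow(Sigma)), class = "layer_params")
}

#' Assemble a layer stack
#'
#' @param ... `layer_params` from the bottom (level 1, sensory) upward; the
#'   last one must be a top-level prior (has `v_p`).
#' @return an object of class `hier_stack`.
#' @export
hier_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "layer_params"))
    layers <- layers[[1]]
  stopifnot(length(layers) >= 2,
            all(vapply(layers, inherits, logical(1), "layer_params")))
  L <- length(layers)
  if (is.null(layers[[L]]$v_p))
    stop("the last layer must carry the top prior (v_p)", call. = FALSE)
  for (i in seq_len(L - 1)) {
    if (is.null(layers[[i]]$Theta))
      stop("layer ", i, " must carry Theta", call. = FALSE)
    if (ncol(layers[[i]]$Theta) != layers[[i + 1]]$n)
      stop("Theta of layer ", i, " must have as many columns as layer ",
           i + 1, " has units", call. = FALSE)
  }
  structure(list(layers = layers, L = L,
                 sizes = vapply(layers, function(l) as.integer(l$n),
                                integer(1))),
            class = "hier_stack")
}

#' @export
print.hier_stack <- function(x, ...) {
  cat("<hier_stack> ", x$L, " levels, sizes: ",
      paste(x$sizes, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

# state is a list(phi = list of vectors, eps = list of vectors)
hier_pack <- function(state) unlist(state, use.names = FALSE)

hier_unpack <- function(vec, sizes) {
  L <- length(sizes)
  idx <- c(0, cumsum(c(sizes, sizes)))
  phi <- lapply(seq_len(L), function(i) vec[(idx[i] + 1):idx[i + 1]])
  eps <- lapply(seq_len(L), function(i) vec[(idx[L + i] + 1):idx[L + i + 1]])
  list(phi = phi, eps = eps)
}

#' Top-down initialization of the hierarchy
#'
#' Initializes the top level at its prior mean, each level below at the
#' prediction from the level above, clamps level 1 to the observation, and
#' zeroes all errors.
#'
#' @param stack a [hier_stack].
#' @param u observation vector (length = size of level 1).
#' @return a state list with components `phi` and `eps` (lists of vectors).
#' @export
hier_init <- function(stack, u) {
  stopifnot(inherits(stack, "hier_stack"), length(u) == stack$sizes[1])
  L <- stack$L
  phi <- vector("list", L)
  phi[[L]] <- stack$layers[[L]]$v_p
  if (L > 1) for (i in seq(L - 1, 1)) {
    lay <- stack$layers[[i]]
    phi[[i]] <- as.numeric(lay$Theta %*% h_eval(lay$h, phi[[i + 1]]))
  }
  phi[[1]] <- as.numeric(u)
  list(phi = phi, eps = lapply(stack$sizes, numeric))
}

#' Hierarchical network derivatives
#'
#' Right-hand sides of the coupled dynamics
#' \deqn{\dot{\bar\phi}_i = -\bar\varepsilon_i
#'   + h'(\bar\phi_i) \circ \Theta_{i-1}^T \bar\varepsilon_{i-1}, \quad
#'   \dot{\bar\varepsilon}_i = \bar\phi_i - \Theta_i h(\bar\phi_{i+1})
#'   - \Sigma_i \bar\varepsilon_i,}
#' for levels \eqn{i = 2, \dots, L}; the top level's error is driven by the
#' prior mean instead of a prediction, and level 1's activity is clamped to
#' the observation (its derivative is zero). The element-wise factor
#' \eqn{h'(\bar\phi_i)} belongs to the prediction map of the level below.
#'
#' @param stack a [hier_stack].
#' @param state a state list as returned by [hier_init()].
#' @return a list of the same shape with derivative vectors.
#' @export
hier_derivatives <- function(stack, state) {
  stopifnot(inherits(stack, "hier_stack"))
  L <- stack$L
  phi <- state$phi; eps <- state$eps
  if (length(phi) != L || length(eps) != L)
    stop("state does not match the layer stack", call. = FALSE)
  dphi <- vector("list", L)
  deps <- vector("list", L)
  dphi[[1]] <- numeric(stack$sizes[1])  # clamped to the observation
  for (i in seq_len(L)) {
    lay <- stack$layers[[i]]
    pred <- if (i < L)
      as.numeric(lay$Theta %*% h_eval(lay$h, phi[[i + 1]]))
    else lay$v_p
    deps[[i]] <- phi[[i]] - pred - as.numeric(lay$Sigma %*% eps[[i]])
    if (i > 1) {
      below <- stack$layers[[i - 1]]
      dphi[[i]] <- -eps[[i]] + h_deriv(below$h, phi[[i]]) *
        as.numeric(crossprod(below$Theta, eps[[i - 1]]))
    }
  }
  list(phi = dphi, eps = deps)
}

#' Simulate the hierarchical network
#'
#' Euler integration of [hier_derivatives()] from the top-down initialization
#' of [hier_init()].
#'
#' @param stack a [hier_stack].
#' @param u observation vector, clamped at level 1 throughout.
#' @param dt,T Euler step and horizon.
#' @param keep_trajectory if `FALSE` (default) only the final state is
#'   returned; if `TRUE`, also a matrix of the packed state over time.
#' @return the final state list (components `phi`, `eps`), with the
#'   trajectory attached as attribute `trajectory` when requested.
#' @export
simulate_hierarchy <- function(stack, u, dt = 0.01, T = 5,
                               keep_trajectory = FALSE) {
  state0 <- hier_init(stack, u)
  sizes <- stack$sizes
  deriv <- function(t, v) {
    d <- hier_derivatives(stack, hier_unpack(v, sizes))
    hier_pack(d)
  }
  tr <- euler_integrate(deriv, hier_pack(state0), dt = dt, T = T)
  fin <- hier_unpack(as.numeric(tr[nrow(tr), -1]), sizes)
  if (keep_trajectory) attr(fin, "trajectory") <- tr
  fin
}

#' Hebbian parameter gradients for every level
#'
#' At a converged state: \eqn{\partial F/\partial\Theta_i =
#' \bar\varepsilon_i h(\bar\phi_{i+1})^T} for inner levels,
#' \eqn{\partial F/\partial\bar v_p = \bar\varepsilon_L} at the top, and
#' \eqn{\partial F/\partial\Sigma_i = \tfrac12(\bar\varepsilon_i
#' \bar\varepsilon_i^T - \Sigma_i^{-1})} everywhere.
#'
#' @param stack a [hier_stack].
#' @param state a (converged) state list.
#' @return a list with one element per level; each has `Sigma` and either
#'   `Theta` or `v_p`.
#' @export
hier_parameter_gradients <- function(stack, state) {
  stopifnot(inherits(stack, "hier_stack"))
  L <- stack$L
  lapply(seq_len(L), function(i) {
    lay <- stack$layers[[i]]
    eps <- state$eps[[i]]
    dS <- 0.5 * (tcrossprod(eps) - solve(lay$Sigma))
    if (i < L)
      list(Sigma = dS, Theta = tcrossprod(eps, h_eval(lay$h,
                                                      state$phi[[i + 1]])))
    else
      list(Sigma = dS, v_p = eps)
  })
}
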