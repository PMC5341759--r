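test_that("the 1-D multivariate model reduces exactly to the scalar model", {
  mv <- mv_model(3, matrix(1), matrix(1), matrix(1), h = "square")
  sc <- ex1_model()
  for (phi in c(0.8, 1.6, 2.4)) {
    expect_equal(mv_negative_free_energy(mv, 2, phi),
                 negative_free_energy(sc, 2, phi))
    expect_equal(mv_grad_phi(mv, 2, phi), grad_F_phi(sc, 2, phi))
    gr <- mv_parameter_gradients(mv, 2, phi)
    dir <- parameter_gradients_direct(sc, 2, phi)
    expect_equal(gr$v_p, dir[["v_p"]])
    expect_equal(gr$Sigma_p[1, 1], dir[["Sigma_p"]])
    expect_equal(gr$Sigma_u[1, 1], dir[["Sigma_u"]])
    eps_u <- (2 - phi^2) / 1
    expect_equal(gr$Theta[1, 1], grad_theta(eps_u, phi, "square"))
  }
})

test_that("mv free energy matches an independent density-product oracle", {
  set.seed(42)
  mvn_logdens <- function(x, mu, S) {
    -0.5 * (length(x) * log(2 * pi) +
              as.numeric(determinant(S)$modulus) +
              mahalanobis(x, mu, S))
  }
  for (k in 1:5) {
    mv <- mv_model(v_p = rnorm(2), Sigma_p = random_spd(2),
                   Sigma_u = random_spd(2),
                   Theta = matrix(rnorm(4), 2), h = "square")
    u <- rnorm(2); phi <- rnorm(2)
    oracle <- mvn_logdens(phi, mv$v_p, mv$Sigma_p) +
      mvn_logdens(u, as.numeric(mv$Theta %*% phi^2), mv$Sigma_u)
    expect_equal(mv_negative_free_energy(mv, u, phi), oracle,
                 tolerance = 1e-10)
  }
  # quadratic terms vanish at the prior mean with a perfect prediction
  mv <- mv_model(c(1, 2), diag(c(2, 3)), diag(2), diag(2), h = "identity")
  expect_equal(mv_negative_free_energy(mv, c(1, 2), c(1, 2)),
               0.5 * (-log(6) - 0) - 2 * log(2 * pi))
})

test_that("mv feature gradient matches finite differences and the explicit Jacobian", {
  set.seed(7)
  for (n in 2:3) {
    mv <- mv_model(v_p = rnorm(n), Sigma_p = random_spd(n),
                   Sigma_u = random_spd(n),
                   Theta = matrix(rnorm(n * n), n), h = "square")
    u <- rnorm(n); phi <- rnorm(n)
    fd <- finite_diff_gradient(function(z)
      mv_negative_free_energy(mv, u, z), phi)
    an <- mv_grad_phi(mv, u, phi)
    expect_lt(max(abs(fd - an)), 1e-6 * max(1, max(abs(an))))
    # assemble the Jacobian of g explicitly: J[i, j] = theta_ij * h'(phi_j)
    J <- mv$Theta * matrix(2 * phi, n, n, byrow = TRUE)
    eps_p <- solve(mv$Sigma_p, phi - mv$v_p)
    eps_u <- solve(mv$Sigma_u, u - as.numeric(mv$Theta %*% phi^2))
    expect_equal(an, as.numeric(-eps_p + t(J) %*% eps_u))
  }
  mv0 <- mv_model(c(0.5, -1), random_spd(2), random_spd(2),
                  matrix(c(1, 0, 1, 2), 2), h = "square")
  expect_equal(mv_grad_phi(mv0, as.numeric(mv0$Theta %*% mv0$v_p^2),
                           mv0$v_p), c(0, 0))
})

test_that("mv covariance and weight gradients match finite differences", {
  set.seed(19)
  mv <- mv_model(v_p = rnorm(2), Sigma_p = random_spd(2),
                 Sigma_u = random_spd(2), Theta = matrix(rnorm(4), 2),
                 h = "square")
  u <- rnorm(2); phi <- rnorm(2)
  gr <- mv_parameter_gradients(mv, u, phi)
  # Sigma gradients are symmetric by construction
  expect_equal(gr$Sigma_p, t(gr$Sigma_p))
  expect_equal(gr$Sigma_u, t(gr$Sigma_u))
  # joint symmetric perturbation of (i,j),(j,i) doubles the off-diagonal
  # sensitivity, so FD_sym = 2 G - diag(G)
  for (which in c("Sigma_p", "Sigma_u")) {
    fd <- finite_diff_gradient(function(M) {
      m2 <- mv; m2[[which]] <- M
      mv_negative_free_energy(m2, u, phi)
    }, mv[[which]], symmetric = TRUE)
    G <- gr[[which]]
    expect_lt(max(abs(fd - (2 * G - diag(diag(G))))), 1e-5)
  }
  fd_th <- finite_diff_gradient(function(M) {
    m2 <- mv; m2$Theta <- M
    mv_negative_free_energy(m2, u, phi)
  }, mv$Theta)
  expect_lt(max(abs(fd_th - gr$Theta)), 1e-6)
})

test_that("hierarchical derivatives reduce to the scalar circuit", {
  sc <- ex1_model()
  stack <- hier_stack(
    layer_params(Sigma = matrix(1), Theta = matrix(1), h = "square"),
    layer_params(Sigma = matrix(1), v_p = 3))
  u <- 2
  for (phi2 in c(0.9, 1.6, 2.8)) for (ep in c(-0.3, 0.4)) {
    state <- list(phi = list(u, phi2), eps = list(-0.25, ep))
    d <- hier_derivatives(stack, state)
    # scalar naming: eps_1 is the sensory error, eps_2 the prior error
    ref <- circuit_derivatives(sc, u, c(phi = phi2, eps_p = ep,
                                        eps_u = -0.25))
    expect_equal(d$phi[[1]], 0)  # clamped to the observation
    expect_equal(d$phi[[2]], ref[["phi"]])
    expect_equal(d$eps[[2]], ref[["eps_p"]])
    expect_equal(d$eps[[1]], ref[["eps_u"]])
  }
})

test_that("error derivatives vanish at their per-layer fixed points", {
  set.seed(23)
  stack <- hier_stack(
    layer_params(Sigma = random_spd(3), Theta = matrix(rnorm(6), 3),
                 h = "identity"),
    layer_params(Sigma = random_spd(2), Theta = matrix(rnorm(4), 2),
                 h = "identity"),
    layer_params(Sigma = random_spd(2), v_p = rnorm(2)))
  u <- rnorm(3)
  phi <- list(u, rnorm(2), rnorm(2))
  preds <- list(as.numeric(stack$layers[[1]]$Theta %*% phi[[2]]),
                as.numeric(stack$layers[[2]]$Theta %*% phi[[3]]),
                stack$layers[[3]]$v_p)
  eps <- lapply(1:3, function(i)
    as.numeric(solve(stack$layers[[i]]$Sigma, phi[[i]] - preds[[i]])))
  d <- hier_derivatives(stack, list(phi = phi, eps = eps))
  for (i in 1:3) expect_lt(max(abs(d$eps[[i]])), 1e-12)
})

test_that("a converged hierarchy reproduces the closed-form prediction errors", {
  set.seed(29)
  stack <- hier_stack(
    layer_params(Sigma = diag(2), Theta = matrix(rnorm(4), 2),
                 h = "identity"),
    layer_params(Sigma = diag(2), Theta = matrix(rnorm(4), 2),
                 h = "identity"),
    layer_params(Sigma = diag(2), v_p = c(0.5, -0.5)))
  u <- c(1, 0.5)
  fin <- simulate_hierarchy(stack, u, dt = 0.01, T = 150)
  preds <- list(as.numeric(stack$layers[[1]]$Theta %*% fin$phi[[2]]),
                as.numeric(stack$layers[[2]]$Theta %*% fin$phi[[3]]),
                stack$layers[[3]]$v_p)
  for (i in 1:3)
    expect_lt(max(abs(fin$eps[[i]] -
                        solve(stack$layers[[i]]$Sigma,
                              fin$phi[[i]] - preds[[i]]))), 1e-6)
})

test_that("the linear hierarchy converges to the normal-equations solution", {
  set.seed(31)
  for (n in 2:4) {
    Sp <- random_spd(n); Su <- random_spd(n)
    Th <- matrix(rnorm(n * n, sd = 0.7), n)
    vp <- rnorm(n)
    u <- rnorm(n)
    stack <- hier_stack(layer_params(Sigma = Su, Theta = Th, h = "identity"),
                        layer_params(Sigma = Sp, v_p = vp))
    fin <- simulate_hierarchy(stack, u, dt = 0.005, T = 300)
    gls <- solve(solve(Sp) + t(Th) %*% solve(Su) %*% Th,
                 solve(Sp, vp) + t(Th) %*% solve(Su, u))
    expect_lt(max(abs(fin$phi[[2]] - as.numeric(gls))), 1e-6)
  }
})

test_that("hierarchy inference agrees with direct gradient ascent on F", {
  set.seed(37)
  Sp <- random_spd(2); Su <- random_spd(2)
  Th <- matrix(rnorm(4, sd = 0.5), 2)
  vp <- c(0.4, -0.2); u <- c(0.8, 0.3)
  stack <- hier_stack(layer_params(Sigma = Su, Theta = Th, h = "identity"),
                      layer_params(Sigma = Sp, v_p = vp))
  fin <- simulate_hierarchy(stack, u, dt = 0.01, T = 200)
  mv <- mv_model(vp, Sp, Su, Th, h = "identity")
  phi_g <- as.numeric(tail(mv_infer_phi(mv, u, dt = 0.01, T = 200), 1))[-1]
  expect_lt(max(abs(fin$phi[[2]] - phi_g)), 1e-5)
})

test_that("hier parameter gradients generalize the two-level rules", {
  set.seed(41)
  stack <- hier_stack(
    layer_params(Sigma = random_spd(2), Theta = matrix(rnorm(4), 2),
                 h = "square"),
    layer_params(Sigma = random_spd(2), v_p = rnorm(2)))
  state <- list(phi = list(rnorm(2), rnorm(2)),
                eps = list(rnorm(2), rnorm(2)))
  gr <- hier_parameter_gradients(stack, state)
  expect_equal(gr[[1]]$Theta,
               tcrossprod(state$eps[[1]], state$phi[[2]]^2))
  expect_equal(gr[[2]]$v_p, state$eps[[2]])
  for (i in 1:2) {
    expect_equal(gr[[i]]$Sigma, t(gr[[i]]$Sigma))
    expect_equal(gr[[i]]$Sigma,
                 0.5 * (tcrossprod(state$eps[[i]]) -
                          solve(stack$layers[[i]]$Sigma)))
  }
})

test_that("Hebbian weight learning recovers a reconstructing basis", {
  set.seed(53)
  n_u <- 4; n_phi <- 2
  Th_true <- qr.Q(qr(matrix(rnorm(n_u * n_phi), n_u)))  # orthogonal columns
  n_train <- 5000
  phi_true <- matrix(rnorm(n_train * n_phi), n_train)
  U <- phi_true %*% t(Th_true) +
    matrix(rnorm(n_train * n_u, sd = 0.05), n_train)
  m0 <- mv_model(v_p = numeric(n_phi), Sigma_p = diag(n_phi),
                 Sigma_u = 0.1 * diag(n_u),
                 Theta = matrix(rnorm(n_u * n_phi, sd = 0.1), n_u),
                 h = "identity")
  fit <- mv_learn_theta(m0, U, alpha = 0.001, dt = 0.02, T = 5)
  Th <- fit$model$Theta
  # judge recovery on reconstructions (a rotated/flipped basis is fine);
  # least-squares projection onto the learned columns isolates the subspace
  n_test <- 200
  phi_test <- matrix(rnorm(n_test * n_phi), n_test)
  U_test <- phi_test %*% t(Th_true)
  A <- solve(crossprod(Th), t(Th))
  rel_err <- vapply(seq_len(n_test), function(k) {
    phi_hat <- A %*% U_test[k, ]
    sqrt(sum((U_test[k, ] - Th %*% phi_hat)^2) / sum(U_test[k, ]^2))
  }, numeric(1))
  expect_lt(mean(rel_err), 0.10)
})
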