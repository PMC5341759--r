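# The worked-example model: prior N(3, 1), observation noise 1, g(v) = v^2,
# with the standard observation u = 2.
ex1_model <- function() scalar_model(v_p = 3, Sigma_p = 1, Sigma_u = 1,
                                     g = nonlinear_map("square"))

# Most likely feature under the worked example: real root of 2v^3 - 3v - 3 = 0
# (stationarity of F), found with an independent polynomial root finder.
ex1_root <- function() {
  r <- polyroot(c(3, 3, 0, -2))
  Re(r[abs(Im(r)) < 1e-9])
}

# Random symmetric positive-definite matrix with eigenvalues bounded away
# from zero.
random_spd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + diag(n)
}

# Standard error of the mean of a correlated sequence via batch means.
batch_se <- function(x, n_batches = 5) {
  b <- split(x, cut(seq_along(x), n_batches, labels = FALSE))
  means <- vapply(b, mean, numeric(1))
  stats::sd(means) / sqrt(n_batches)
}
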