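# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Fixed per-component offsets fanned out from one global seed, so adding a
# consumer never shifts another's draws. Kept below 2^31 - offset.
component_seed <- function(seed, component) {
  offsets <- c(trials = 1000L, exercise = 2000L, replicate = 3000L)
  stopifnot(component %in% names(offsets))
  (as.integer(seed) %% 2000000000L) + offsets[[component]]
}

#' Seeded stream of synthetic trial inputs
#'
#' Describes a reproducible sequence of per-trial drives for the learning
#' experiments: draws from \eqn{N(\mu, \Sigma)} minus a fixed top-down
#' prediction `g_pred`, so the drive on each trial is
#' \eqn{\phi - g(\phi_{above})}. The standard variance-learning experiment
#' uses mean 5, variance 2 and `g_pred = 5`, giving zero-mean drives with
#' variance 2.
#'
#' @param n_trials number of trials (> 0).
#' @param mean mean vector of the generating normal.
#' @param cov covariance matrix (or scalar variance for `dim = 1`); must be
#'   symmetric positive semi-definite.
#' @param g_pred top-down prediction subtracted from each draw; defaults to
#'   zero.
#' @param seed integer seed; the stream is bit-reproducible given the seed.
#' @return an object of class `trial_stream`.
#' @export
trial_stream <- function(n_trials, mean, cov, g_pred = NULL, seed = 1L) {
  stopifnot(n_trials >= 1, is.numeric(mean))
  d <- length(mean)
  if (is.null(dim(cov))) {
    stopifnot(d == 1, length(cov) == 1)
    cov <- matrix(cov, 1, 1)
  }
  cov <- as.matrix(cov)
  if (nrow(cov) != d || ncol(cov) != d)
    stop("cov dimensions do not match mean", call. = FALSE)
  if (max(abs(cov - t(cov))) > 1e-8)
    stop("cov must be symmetric", call. = FALSE)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("cov must be positive semi-definite", call. = FALSE)
  if (is.null(g_pred)) g_pred <- numeric(d)
  stopifnot(length(g_pred) == d)
  structure(list(n_trials = as.integer(n_trials), dim = d, mean = mean,
                 cov = cov, g_pred = g_pred, seed = as.integer(seed)),
            class = "trial_stream")
}

#' @export
print.trial_stream <- function(x, ...) {
  cat("<trial_stream> ", x$n_trials, " trials, dim ", x$dim,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate the drives of a trial stream
#'
#' Draws `n_trials` samples from the stream's normal distribution and
#' subtracts the top-down prediction. Reproducible: the same stream yields a
#' bit-identical matrix on every call, and the caller's RNG state is left
#' untouched.
#'
#' @param stream a [trial_stream].
#' @return numeric matrix, `n_trials` rows by `dim` columns, of drive values.
#' @export
generate_trials <- function(stream) {
  stopifnot(inherits(stream, "trial_stream"))
  with_preserved_seed(component_seed(stream$seed, "trials"), {
    if (stream$dim == 1) {
      draws <- matrix(stats::rnorm(stream$n_trials, stream$mean,
                                   sqrt(stream$cov[1, 1])), ncol = 1)
    } else if (max(abs(stream$cov)) == 0) {
      draws <- matrix(stream$mean, nrow = stream$n_trials,
                      ncol = stream$dim, byrow = TRUE)
    } else {
      draws <- MASS::mvrnorm(stream$n_trials, mu = stream$mean,
                             Sigma = stream$cov)
      draws <- matrix(draws, ncol = stream$dim)
    }
    sweep(draws, 2, stream$g_pred)
  })
}
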