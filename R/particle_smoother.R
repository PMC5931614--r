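## Particle smoother: bootstrap particle filter (transition-prior proposal,
## systematic resampling) followed by backward-simulation smoothing (FFBSi).
## The smoothing distribution p(X^(a) | Y^(a), theta) is represented as an
## ensemble of sampled trajectories; after backward simulation the ensemble
## weights are uniform (the likelihood-ratio weights of the generic particle
## representation are realized by the sampling itself).  All likelihood
## arithmetic is done in log space with log-sum-exp stabilization.

systematic_resample <- function(w) {
  P <- length(w)
  u <- (runif(1) + seq_len(P) - 1) / P
  pmin(findInterval(u, cumsum(w) / sum(w)) + 1L, P)
}

## Forward bootstrap filter for one cell.  Returns filtered particles, log
## weights, one-step prediction means (f of every filtered particle, needed
## both for propagation and for the backward-smoothing weights) and the
## log-likelihood estimate  sum_t log( sum_i w_{t-1,i} p(y_t | x_t^i) ).
particle_filter_cell <- function(model, y, times, P, mu_cell) {
  k <- model$k; l <- model$l
  Tn <- nrow(y)
  lt <- latent_times(times)
  xf <- array(NA_real_, c(Tn + 1L, P, k))
  logw <- matrix(-log(P), Tn + 1L, P)
  means <- array(NA_real_, c(Tn, P, k))
  x <- matrix(rnorm(P * k, mean = rep(mu_cell, each = P),
                    sd = rep(model$gamma, each = P)), P, k)
  xf[1, , ] <- x
  loglik <- 0
  thr <- model$solver$resample_threshold
  lw_norm <- rep(-log(P), P)
  for (t in seq_len(Tn)) {
    M <- propagate(model, x, lt[t + 1] - lt[t])
    means[t, , ] <- M
    w <- exp(lw_norm)
    ess <- 1 / sum(w^2)
    if (ess < thr * P) {
      anc <- systematic_resample(w)
      lw_prev <- rep(-log(P), P)
    } else {
      anc <- seq_len(P)
      lw_prev <- lw_norm
    }
    x <- M[anc, , drop = FALSE] +
      matrix(rnorm(P * k, sd = rep(model$sigma, each = P)), P, k)
    resid <- model$alpha * x[, model$obs_idx, drop = FALSE] -
      matrix(y[t, ], P, l, byrow = TRUE)
    lobs <- -0.5 * rowSums(sweep(resid^2, 2, model$eta^2, "/")) -
      sum(0.5 * log(2 * pi * model$eta^2))
    ## collapse: every particle's observation likelihood underflows to zero
    ## in linear space (the weights beta = l / sum l would be 0/0)
    if (max(lobs) < model$l * log(.Machine$double.xmin))
      emps_error("emps_degeneracy",
                 sprintf("particle weights collapsed at time index %d", t),
                 time_index = t)
    lw <- lw_prev + lobs
    norm <- logsumexp(lw)
    if (!is.finite(norm))
      emps_error("emps_degeneracy",
                 sprintf("particle weights collapsed at time index %d", t),
                 time_index = t)
    loglik <- loglik + norm
    lw_norm <- lw - norm
    xf[t + 1, , ] <- x
    logw[t + 1, ] <- lw_norm
  }
  list(xf = xf, logw = logw, means = means, loglik = loglik, times = lt)
}

#' Particle-smoother approximation of the smoothing distribution
#'
#' Runs a bootstrap particle filter with `P` particles over one cell's series,
#' then draws `n_back` smoothed trajectories by backward simulation.  The
#' returned ensemble approximates `p(X | Y, theta)` as an equally weighted set
#' of complete latent trajectories (including the unobserved initial state one
#' spacing before the first observation) and carries the filter estimate of
#' the cell log-likelihood.
#'
#' @param model A [state_space_model()] with valid noise parameters.
#' @param y One cell's observation matrix (`T x l`).
#' @param times Observation times.
#' @param P Number of filter particles, `>= 2`.
#' @param n_back Number of backward-simulated trajectories (default `P`).
#' @param mu_cell Initial-state mean for this cell (length `k`); defaults to
#'   the first row of `model$mu` or, failing that, the first observation.
#' @param seed Optional seed fixing the RNG for this call; identical
#'   `(seed, inputs, P)` give identical ensembles.
#' @return Object of class `particle_ensemble`: `trajectories` array
#'   `(T+1, n_back, k)`, uniform `weights`, `loglik`, latent `times`.
#' @export
smooth_cell <- function(model, y, times, P = 500, n_back = P, mu_cell = NULL,
                        seed = NULL) {
  if (P < 2) emps_error("emps_contract", "need at least 2 particles")
  if (!is.null(seed)) set.seed(seed)
  y <- as.matrix(y)
  if (is.null(mu_cell)) {
    mu_cell <- if (!is.null(model$mu)) model$mu[1, ] else {
      m <- rep(mean(y[1, ]) / model$alpha, model$k)
      m[model$obs_idx] <- y[1, ] / model$alpha
      m
    }
  }
  ff <- particle_filter_cell(model, y, times, P, mu_cell)
  traj <- ffbsi_cpp(ff$xf, ff$logw, ff$means, model$sigma, as.integer(n_back))
  structure(list(trajectories = traj, weights = rep(1 / n_back, n_back),
                 loglik = ff$loglik, times = ff$times, P = P, n_back = n_back),
            class = "particle_ensemble")
}

#' @export
print.particle_ensemble <- function(x, ...) {
  d <- dim(x$trajectories)
  cat(sprintf("<particle_ensemble> %d trajectories x %d time points x %d states; loglik = %.3f\n",
              d[2], d[1], d[3], x$loglik))
  invisible(x)
}

#' Smooth every cell of a dataset
#'
#' Per-cell RNG streams are derived deterministically from `seed`, so the
#' result is reproducible cell by cell.
#'
#' @param model A [state_space_model()]; `model$mu` (one row per cell) supplies
#'   the cell-specific initial means.
#' @param dataset A [timecourse_dataset()].
#' @param P,n_back Particle counts, as in [smooth_cell()].
#' @param seed Master seed.
#' @return List of [smooth_cell()] ensembles, one per cell.
#' @export
particle_smooth <- function(model, dataset, P = 500, n_back = P, seed = 1) {
  lapply(seq_len(dataset$A), function(a) {
    mu_a <- if (!is.null(model$mu)) model$mu[a, ] else NULL
    smooth_cell(model, dataset$cells[[a]], dataset$times, P = P,
                n_back = n_back, mu_cell = mu_a,
                seed = (seed + 7919L * a) %% .Machine$integer.max)
  })
}

#' Dataset log-likelihood from particle ensembles
#'
#' Per-cell filter estimates `ln L^(a) = sum_t ln((1/P) sum_p l)` summed over
#' cells (independent time courses).  Accepts a single ensemble, a list of
#' ensembles, or a vector of per-particle likelihood values (in which case it
#' returns `ln((1/P) sum l)` directly).
#'
#' @param x A `particle_ensemble`, a list of them, or numeric per-particle
#'   likelihoods.
#' @param log Set to `TRUE` when `x` is a numeric vector of per-particle
#'   *log*-likelihoods.
#' @return Scalar log-likelihood estimate; `-Inf` (with a warning) if every
#'   particle likelihood underflows.
#' @export
log_likelihood <- function(x, log = FALSE) {
  if (inherits(x, "particle_ensemble")) return(x$loglik)
  if (is.list(x)) return(sum(vapply(x, log_likelihood, numeric(1))))
  lx <- if (log) x else base::log(x)
  out <- logsumexp(lx) - base::log(length(lx))
  if (!is.finite(out)) warning("all particle likelihoods underflowed")
  out
}

#' Filter-based log-likelihood of a dataset under a fitted model
#'
#' Runs the particle filter only (no smoothing) and sums the per-cell
#' log-likelihood estimates.  Cells without a stored initial mean (held-out
#' test cells) get a *diffuse* initial-state distribution: mean at the first
#' observation mapped through the measurement gain, sd equal to the
#' per-observable data sd (the fitted `gamma` describes the posterior spread
#' of a training cell's initial state and would be far too confident about
#' an unseen cell's oscillation phase).
#'
#' @inheritParams particle_smooth
#' @param mu Optional `A x k` matrix of initial means overriding `model$mu`.
#' @return Scalar log-likelihood.
#' @export
evaluate_loglik <- function(model, dataset, P = 500, seed = 1, mu = NULL) {
  total <- 0
  s_obs <- dataset_scale(dataset)
  s_state <- rep(mean(s_obs), model$k)
  s_state[model$obs_idx] <- s_obs / model$alpha
  for (a in seq_len(dataset$A)) {
    set.seed((seed + 104729L * a) %% .Machine$integer.max)
    y <- dataset$cells[[a]]
    m <- model
    mu_a <- if (!is.null(mu)) mu[a, ]
      else if (!is.null(model$mu) && nrow(model$mu) >= a) model$mu[a, ]
      else {
        m$gamma <- pmax(model$gamma, s_state)
        v <- rep(mean(y[1, ]) / model$alpha, model$k)
        v[model$obs_idx] <- y[1, ] / model$alpha
        v
      }
    ff <- particle_filter_cell(m, y, dataset$times, P, mu_a)
    total <- total + ff$loglik
  }
  total
}
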