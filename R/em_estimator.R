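## EM-PS: maximum-likelihood estimation by expectation-maximization with a
## particle-smoother E-step.
##
## E-step: approximate p(X|Y, theta_old) by per-cell smoothed trajectory
## ensembles and assemble the expected complete-data log-likelihood
##
##   Q(theta, theta_old) = sum_a sum_p beta^(a,p) ln p(X^(a,p), Y^(a) | theta)
##
## whose three Gaussian blocks (initial state, one-step transition,
## measurement) are cached as sufficient statistics where possible.
##
## M-step: theta_sys by bound-constrained quasi-Newton (L-BFGS-B) with the
## analytic gradient of the transition block; sigma, eta, mu, gamma by the
## closed-form stationary points of Q, clipped to their configured bounds.

#' EM run settings
#'
#' @param m_maxit Maximum L-BFGS-B iterations per M-step.  Full inner
#'   convergence is unnecessary (generalized EM); a small budget per
#'   iteration is faster overall.
#' @param K_zero_tol Association constants below this value after an M-step
#'   are snapped to exactly 0 (round-off cleanup at the nonnegativity bound).
#' @param n_range Bounds on Hill coefficients during optimization.
#' @param init_noise_from_data If `TRUE`, initialize sigma, eta, gamma from
#'   the per-observable data sd (0.5, 0.5 and 1 times it) and the per-cell
#'   initial means from the first observations.
#' @param plateau_tol If non-`NULL`, stop early once the relative change of
#'   the 10-iteration median log-likelihood falls below this value.
#' @return A list of settings.
#' @export
em_control <- function(m_maxit = 15L, K_zero_tol = 1e-6, n_range = c(1, 8),
                       init_noise_from_data = TRUE, plateau_tol = NULL) {
  list(m_maxit = as.integer(m_maxit), K_zero_tol = K_zero_tol,
       n_range = n_range, init_noise_from_data = init_noise_from_data,
       plateau_tol = plateau_tol)
}

## resolve NULL noise bounds from the data scale.  The sigma/eta ceilings
## guard against two degenerate EM attractors: noise absorbing the dynamics
## (sigma or eta growing to the oscillation amplitude) and the smoother
## decoupling from the data (sigma collapsing to 0 while eta explains
## everything).  The per-step noise scale is estimated from first
## differences of the series, which tracks sigma and eta but not the
## oscillation amplitude; a floor on sigma prevents the collapse.
resolve_bounds <- function(model, dataset) {
  s_obs <- dataset_scale(dataset)
  s_state <- rep(mean(s_obs), model$k)
  s_state[model$obs_idx] <- s_obs / model$alpha
  r_obs <- dataset_diff_scale(dataset)
  r_state <- rep(mean(r_obs), model$k)
  r_state[model$obs_idx] <- r_obs / model$alpha
  b <- model$bounds
  list(gamma_min = rep_len(b$gamma_min %||% (0.01 * s_state), model$k),
       sigma_max = rep_len(b$sigma_max %||% r_state, model$k),
       eta_max = rep_len(b$eta_max %||% r_obs, model$l),
       sigma_min = rep_len(b$sigma_min %||% (0.1 * r_state), model$k),
       eta_min = rep_len(b$eta_min %||% (1e-3 * s_obs), model$l))
}

## assemble cached sufficient statistics of an ensemble list
estep_cache <- function(model, dataset, ensembles) {
  k <- model$k
  Tn <- length(dataset$times)
  A <- dataset$A
  nb <- ensembles[[1]]$n_back
  Xprev <- vector("list", A); Xnext <- vector("list", A)
  m0 <- matrix(0, A, k); s0 <- matrix(0, A, k)
  meas_ss <- rep(0, model$l)
  for (a in seq_len(A)) {
    tr <- ensembles[[a]]$trajectories            # (Tn+1, nb, k)
    Xp <- tr[-(Tn + 1), , , drop = FALSE]; dim(Xp) <- c(Tn * nb, k)
    Xn <- tr[-1, , , drop = FALSE];        dim(Xn) <- c(Tn * nb, k)
    Xprev[[a]] <- Xp; Xnext[[a]] <- Xn
    x0 <- matrix(tr[1, , ], nb, k)
    m0[a, ] <- colMeans(x0)
    s0[a, ] <- colMeans(x0^2)
    yrep <- dataset$cells[[a]][rep(seq_len(Tn), times = nb), , drop = FALSE]
    xobs <- Xn[, model$obs_idx, drop = FALSE]
    meas_ss <- meas_ss + colSums((yrep - model$alpha * xobs)^2) / nb
  }
  Xprev <- do.call(rbind, Xprev); Xnext <- do.call(rbind, Xnext)
  dts <- diff(latent_times(dataset$times))
  if (diff(range(dts)) > 1e-8 * mean(dts))
    emps_error("emps_contract", "EM fitting requires a uniform observation grid")
  list(Xprev = Xprev, Xnext = Xnext, beta = rep(1 / nb, nrow(Xprev)),
       m0 = m0, s0 = s0, meas_ss = meas_ss, A = A, Tn = Tn, nb = nb,
       dt = dts[1])
}

## transition block of Q (and optionally its gradient) at a flat theta_sys
qtrans_eval <- function(cache, model, theta_sys, grad = FALSE) {
  net <- theta_sys_unpack(model$dynamics, theta_sys)
  A <- net_args(net)
  pos <- theta_positions(net)
  qtrans_cpp(cache$Xprev, cache$Xnext, cache$beta,
             A$src, A$tgt, A$act, A$K, A$n, A$a, A$deg, A$basal,
             cache$dt, model$solver$n_sub, model$sigma,
             grad, pos$posK, pos$posN, pos$posA, pos$posD, pos$posB, pos$M)
}

#' E-step: smooth all cells and expose the Q function
#'
#' Runs the particle smoother for every cell at the current parameters and
#' returns the ensembles together with a callable `Q(theta)` implementing the
#' particle-weighted expected complete-data log-likelihood (initial-state,
#' transition and measurement Gaussian blocks).
#'
#' @param model A [state_space_model()] with a `hill_network` dynamics and a
#'   per-cell `mu` matrix.
#' @param dataset A [timecourse_dataset()].
#' @param P,n_back Particle counts (see [smooth_cell()]).
#' @param seed RNG seed for the smoother.
#' @return Object of class `em_estep`: `ensembles`, `loglik` (filter estimate
#'   at the current theta), `cache` of sufficient statistics, and `q_fun`.
#'   `q_fun(theta_sys, sigma, eta, mu, gamma)` evaluates Q; omitted arguments
#'   default to the model's current values.
#' @export
e_step <- function(model, dataset, P = 500, n_back = P, seed = 1) {
  ensembles <- particle_smooth(model, dataset, P = P, n_back = n_back, seed = seed)
  cache <- estep_cache(model, dataset, ensembles)
  q_fun <- function(theta_sys = NULL, sigma = NULL, eta = NULL,
                    mu = NULL, gamma = NULL) {
    theta_sys <- theta_sys %||% theta_sys_pack(model$dynamics)
    sigma <- sigma %||% model$sigma
    eta <- eta %||% model$eta
    mu <- mu %||% model$mu
    gamma <- gamma %||% model$gamma
    m <- model; m$sigma <- sigma
    q_tr <- qtrans_eval(cache, m, theta_sys)$q
    q_init <- sum(vapply(seq_len(cache$A), function(a) {
      dev2 <- cache$s0[a, ] - 2 * mu[a, ] * cache$m0[a, ] + mu[a, ]^2
      sum(-0.5 * log(2 * pi * gamma^2) - dev2 / (2 * gamma^2))
    }, numeric(1)))
    q_meas <- sum(-0.5 * cache$A * cache$Tn * log(2 * pi * eta^2) -
                    cache$meas_ss / (2 * eta^2))
    q_init + q_tr + q_meas
  }
  structure(list(ensembles = ensembles,
                 loglik = log_likelihood(ensembles),
                 cache = cache, q_fun = q_fun, model = model),
            class = "em_estep")
}

#' M-step update of the kinetic parameters
#'
#' Bound-constrained quasi-Newton (L-BFGS-B, analytic gradient) maximization
#' of the transition block of Q over `theta_sys`, optionally minus the Lasso
#' penalty `lam * sum(K)` (all association constants are constrained `>= 0`,
#' so `|K| = K` and the penalized objective stays smooth on the feasible
#' region; exact zeros arise at the bound).  Falls back to the previous value
#' if the optimizer fails to improve the objective.
#'
#' @param estep An [e_step()] result.
#' @param theta_old Flat named parameter vector (see [theta_sys_pack()]).
#' @param lam Lasso penalty strength on association constants (default 0).
#' @param control An [em_control()] list.
#' @param bounds Optional [theta_sys_bounds()] list; defaults to the bounds
#'   of the model's current network.  [run_em()] computes the bounds once
#'   from the *initial* network so that structural zeros (frozen basal
#'   rates) are decided by the model specification, not by optimizer
#'   excursions.
#' @return List with the updated `theta`, the achieved penalized objective
#'   `value`, and `improved`.
#' @export
m_step_sys <- function(estep, theta_old = NULL, lam = 0, control = em_control(),
                       bounds = NULL) {
  model <- estep$model; cache <- estep$cache
  theta_old <- theta_old %||% theta_sys_pack(model$dynamics)
  bounds <- bounds %||% theta_sys_bounds(model$dynamics, n_range = control$n_range)
  isK <- grepl("^K", names(theta_old))
  cache_env <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    key <- paste(format(par, digits = 17), collapse = ",")
    if (!identical(cache_env$key, key)) {
      r <- qtrans_eval(cache, model, setNames(par, names(theta_old)), grad = TRUE)
      cache_env$key <- key
      cache_env$fn <- -(r$q - lam * sum(par[isK]))
      g <- -r$grad; g[isK] <- g[isK] + lam
      cache_env$gr <- g
      if (!r$finite) { cache_env$fn <- 1e12; cache_env$gr <- rep(0, length(par)) }
    }
    invisible(NULL)
  }
  fn <- function(par) { eval_at(par); cache_env$fn }
  gr <- function(par) { eval_at(par); cache_env$gr }
  f_old <- fn(theta_old)
  opt <- tryCatch(
    optim(theta_old, fn, gr, method = "L-BFGS-B",
          lower = bounds$lower, upper = bounds$upper,
          control = list(maxit = control$m_maxit,
                         parscale = pmax(abs(theta_old), 0.05))),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value > f_old) {
    list(theta = theta_old, value = -f_old, improved = FALSE)
  } else {
    theta <- setNames(pmin(pmax(opt$par, bounds$lower), bounds$upper),
                      names(theta_old))
    theta[isK & theta < control$K_zero_tol] <- 0
    list(theta = theta, value = -opt$value, improved = opt$value < f_old)
  }
}

#' M-step closed-form updates of noise and initial-state parameters
#'
#' The stationary points of Q in `mu`, `gamma`, `sigma`, `eta` are weighted
#' means/variances of the smoothed ensembles:
#' `mu_i^(a)` = ensemble mean of the initial state, `gamma_i^2` = ensemble
#' variance of the initial state averaged over cells, `sigma_i^2` = weighted
#' mean squared one-step prediction residual (at the *updated* kinetic
#' parameters), `eta_j^2` = weighted mean squared measurement residual.
#' Updates are then clipped to the configured bounds.
#'
#' @param estep An [e_step()] result.
#' @param theta_sys Flat kinetic parameters at which the one-step residuals
#'   are evaluated.
#' @param bounds Resolved noise bounds (see [noise_bounds()]); data-dependent
#'   defaults are resolved by [run_em()].
#' @return List with `mu` (A x k), `gamma`, `sigma`, `eta`, and the unclipped
#'   values (`*_raw`).
#' @export
m_step_noise <- function(estep, theta_sys = NULL, bounds = NULL) {
  model <- estep$model; cache <- estep$cache
  theta_sys <- theta_sys %||% theta_sys_pack(model$dynamics)
  mu <- cache$m0
  gamma2 <- colMeans(cache$s0 - cache$m0^2)
  r <- qtrans_eval(cache, model, theta_sys)
  sigma2 <- r$resid2 / (cache$A * cache$Tn)
  eta2 <- cache$meas_ss / (cache$A * cache$Tn)
  out <- list(mu = mu, gamma_raw = sqrt(pmax(gamma2, 0)),
              sigma_raw = sqrt(pmax(sigma2, 0)), eta_raw = sqrt(pmax(eta2, 0)))
  if (is.null(bounds)) bounds <- list(gamma_min = rep(0, model$k),
                                      sigma_max = rep(Inf, model$k),
                                      eta_max = rep(Inf, model$l),
                                      sigma_min = rep(1e-8, model$k),
                                      eta_min = rep(1e-8, model$l))
  out$gamma <- pmax(out$gamma_raw, bounds$gamma_min)
  out$sigma <- pmin(pmax(out$sigma_raw, bounds$sigma_min), bounds$sigma_max)
  out$eta <- pmin(pmax(out$eta_raw, bounds$eta_min), bounds$eta_max)
  out
}

## shared EM loop (lam = 0: plain EM-PS; lam > 0: EM-PS-Lasso)
em_core <- function(model, dataset, lam = 0, P = 500, n_back = P, iters = 100,
                    seed = 1, control = em_control()) {
  if (iters < 1) emps_error("emps_contract", "need at least one EM iteration")
  if (!inherits(model$dynamics, "hill_network"))
    emps_error("emps_contract", "EM fitting requires hill_network dynamics")
  set.seed(seed)
  bounds <- resolve_bounds(model, dataset)
  if (control$init_noise_from_data) {
    s_obs <- dataset_scale(dataset)
    s_state <- rep(mean(s_obs), model$k); s_state[model$obs_idx] <- s_obs / model$alpha
    model$sigma <- pmin(0.5 * s_state, bounds$sigma_max)
    model$eta <- pmin(0.5 * s_obs, bounds$eta_max)
    model$gamma <- s_state
  }
  if (is.null(model$mu)) {
    model$mu <- t(vapply(dataset$cells, function(y) {
      m <- rep(mean(y[1, ]) / model$alpha, model$k)
      m[model$obs_idx] <- y[1, ] / model$alpha
      m
    }, numeric(model$k)))
  }
  theta <- theta_sys_pack(model$dynamics)
  sys_bounds <- theta_sys_bounds(model$dynamics, n_range = control$n_range)
  S <- nrow(model$dynamics$paths)
  pid <- model$dynamics$paths$path_id
  loglik_history <- numeric(0)
  theta_history <- matrix(NA_real_, 0, length(theta) + 2 * model$k + model$l,
                          dimnames = list(NULL, c(names(theta),
                                                  paste0("sigma_", seq_len(model$k)),
                                                  paste0("eta_", seq_len(model$l)),
                                                  paste0("gamma_", seq_len(model$k)))))
  K_history <- matrix(NA_real_, 0, S, dimnames = list(NULL, sprintf("K%02d", pid)))
  es <- NULL
  for (it in seq_len(iters)) {
    it_seed <- (seed + 1009L * it) %% .Machine$integer.max
    es <- e_step(model, dataset, P = P, n_back = n_back, seed = it_seed)
    loglik_history <- c(loglik_history, es$loglik)
    ms <- m_step_sys(es, theta, lam = lam, control = control,
                     bounds = sys_bounds)
    theta <- ms$theta
    nz <- m_step_noise(es, theta_sys = theta, bounds = bounds)
    model$dynamics <- theta_sys_unpack(model$dynamics, theta)
    model$sigma <- nz$sigma; model$eta <- nz$eta
    model$gamma <- nz$gamma; model$mu <- nz$mu
    theta_history <- rbind(theta_history,
                           c(theta, model$sigma, model$eta, model$gamma))
    K_history <- rbind(K_history, theta[grepl("^K", names(theta))])
    if (!is.null(control$plateau_tol) && it >= 20) {
      recent <- stats::median(tail(loglik_history, 10))
      earlier <- stats::median(head(tail(loglik_history, 20), 10))
      if (abs(recent - earlier) < control$plateau_tol * abs(recent)) break
    }
  }
  structure(list(model = model, network = model$dynamics, theta = theta,
                 loglik_history = loglik_history, theta_history = theta_history,
                 K_history = K_history, ensembles = es$ensembles,
                 iterations = length(loglik_history), lam = lam, seed = seed,
                 P = P, n_back = n_back),
            class = "em_fit")
}

#' Fit a state-space network model by EM-PS
#'
#' Alternates the particle-smoother E-step and the M-step for a fixed number
#' of iterations, recording the log-likelihood and parameter trajectory at
#' every iteration.  The log-likelihood trend is nondecreasing up to the
#' Monte-Carlo fluctuation inherent in the particle approximation.
#'
#' @param model A [state_space_model()] whose dynamics is a [hill_network()]
#'   carrying the initial kinetic-parameter values.
#' @param dataset Training data ([timecourse_dataset()]).
#' @param P Filter particle count.
#' @param n_back Smoothed trajectories per cell (default `P`).
#' @param iters Number of EM iterations (fixed-count convergence rule; see
#'   `plateau_tol` in [em_control()] for an optional early stop).
#' @param seed Master RNG seed; identical seeds give identical fits.
#' @param control An [em_control()] list.
#' @return Object of class `em_fit`: final `model` and `network`, flat
#'   `theta`, `loglik_history`, `theta_history`, `K_history`, last-iteration
#'   `ensembles`.
#' @export
run_em <- function(model, dataset, P = 500, n_back = P, iters = 100, seed = 1,
                   control = em_control()) {
  em_core(model, dataset, lam = 0, P = P, n_back = n_back, iters = iters,
          seed = seed, control = control)
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf("<em_fit> %d iterations, lambda = %g, P = %d\n",
              x$iterations, x$lam, x$P))
  cat(sprintf(" log-likelihood: start %.3f -> end %.3f\n",
              x$loglik_history[1], tail(x$loglik_history, 1)))
  invisible(x)
}
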