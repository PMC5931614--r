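## Nonlinear Gaussian state-space model
##
##   x_t = f(x_{t-1}) + v_t,   v_{t,i} ~ N(0, sigma_i^2)
##   y_t = alpha * x_t[obs]  + w_t,   w_{t,j} ~ N(0, eta_j^2)
##   x_0,i ~ N(mu_i^(a), gamma_i^2)        (mu is the only cell-specific part)
##
## f is the flow of an ODE system dx/dt = g(x, theta_sys) over one
## inter-observation interval.  Two integrators coexist: an adaptive
## stiff-capable solver (deSolve::lsoda) behind evolve(), and the fixed-step
## RK4 map used uniformly by the particle smoother and the EM machinery
## (propagate()); the transition density the EM maximizes is defined on the
## RK4 map, so likelihood and gradient always refer to the same f.

#' Solver and smoother settings
#'
#' @param n_sub RK4 substeps per inter-observation interval for the discrete
#'   transition map (default 2).
#' @param rtol,atol Tolerances of the adaptive solver behind [evolve()].
#' @param resample_threshold Effective-sample-size fraction below which the
#'   particle filter resamples; `1` (default) resamples every step, which is
#'   robust for strongly oscillatory dynamics.
#' @return A list of settings.
#' @export
solver_control <- function(n_sub = 2L, rtol = 1e-6, atol = 1e-9,
                           resample_threshold = 1.0) {
  list(n_sub = as.integer(n_sub), rtol = rtol, atol = atol,
       resample_threshold = resample_threshold)
}

#' Bounds on noise and initial-state parameters
#'
#' The M-step clips the closed-form noise updates: a floor on the
#' initial-state spread gamma prevents sample impoverishment of the particle
#' smoother, and ceilings on sigma and eta prevent the noise from absorbing
#' unexplained dynamics early in the fit.  `NULL` entries are resolved from
#' the per-observable standard deviation of the data when the EM starts
#' (gamma_min = 1% of the data sd, sigma_max = eta_max = the data sd).
#'
#' @param gamma_min Floor on initial-state sd.
#' @param sigma_max,eta_max Ceilings on system / measurement noise sd.
#' @param sigma_min,eta_min Strictly positive floors (numerical safety).
#' @return A list of bounds (possibly with `NULL` placeholders).
#' @export
noise_bounds <- function(gamma_min = NULL, sigma_max = NULL, eta_max = NULL,
                         sigma_min = NULL, eta_min = NULL) {
  list(gamma_min = gamma_min, sigma_max = sigma_max, eta_max = eta_max,
       sigma_min = sigma_min, eta_min = eta_min)
}

#' Construct a nonlinear state-space model
#'
#' @param dynamics A [hill_network()] (fast compiled path, required for EM
#'   fitting) or an R function `g(x)` accepting a state vector or a matrix of
#'   state rows and returning `dx/dt` of the same shape.
#' @param k State dimension; defaults to the number of network genes.
#' @param obs_idx Indices of the observed coordinates (`l = length(obs_idx)`,
#'   `l <= k`); default: fully observed.
#' @param alpha Measurement gain (`h(x) = alpha * x`), default 1.
#' @param sigma Per-state system-noise sd (recycled to length `k`), `> 0`.
#' @param eta Per-observable measurement-noise sd (recycled to `l`), `> 0`.
#' @param mu Cell-specific initial means: an `A x k` matrix (row per cell), or
#'   `NULL` to be initialized from the data by the EM.
#' @param gamma Per-state initial-state sd (recycled to `k`), `> 0`.
#' @param bounds A [noise_bounds()] list.
#' @param solver A [solver_control()] list.
#' @return Object of class `state_space_model`.
#' @export
state_space_model <- function(dynamics, k = NULL, obs_idx = NULL, alpha = 1,
                              sigma = 0.5, eta = 0.5, mu = NULL, gamma = 1,
                              bounds = noise_bounds(), solver = solver_control()) {
  is_net <- inherits(dynamics, "hill_network")
  if (!is_net && !is.function(dynamics))
    emps_error("emps_contract", "dynamics must be a hill_network or a function g(x)")
  if (is.null(k)) {
    if (!is_net) emps_error("emps_contract", "k is required for function dynamics")
    k <- length(dynamics$genes)
  }
  if (is_net && k != length(dynamics$genes))
    emps_error("emps_contract", "k must equal the number of network genes")
  if (is.null(obs_idx)) obs_idx <- seq_len(k)
  obs_idx <- as.integer(obs_idx)
  l <- length(obs_idx)
  if (l < 1 || l > k || any(obs_idx < 1 | obs_idx > k))
    emps_error("emps_contract", "need k >= l >= 1 with valid observed coordinates")
  sigma <- rep_len(sigma, k); eta <- rep_len(eta, l); gamma <- rep_len(gamma, k)
  if (any(sigma <= 0) || any(eta <= 0) || any(gamma <= 0))
    emps_error("emps_contract", "sigma, eta, gamma must all be > 0")
  if (!is.null(mu)) {
    mu <- as.matrix(mu)
    if (ncol(mu) != k) emps_error("emps_contract", "mu must have one column per state")
  }
  structure(list(dynamics = dynamics, k = k, l = l, obs_idx = obs_idx,
                 alpha = alpha, sigma = sigma, eta = eta, mu = mu,
                 gamma = gamma, bounds = bounds, solver = solver),
            class = "state_space_model")
}

#' @export
print.state_space_model <- function(x, ...) {
  cat(sprintf("<state_space_model> k=%d, l=%d, alpha=%g\n", x$k, x$l, x$alpha))
  cat(" sigma:", signif(x$sigma, 4), "\n eta:  ", signif(x$eta, 4),
      "\n gamma:", signif(x$gamma, 4), "\n")
  if (inherits(x$dynamics, "hill_network"))
    cat(sprintf(" dynamics: hill_network with %d paths\n", nrow(x$dynamics$paths)))
  invisible(x)
}

#' Deterministic state evolution
#'
#' Integrates `dx/dt = g(x, theta_sys)` from `t0` to `t1` with an adaptive
#' stiff-capable solver; no noise is added.  This is the reference ODE
#' solution; the EM machinery itself uses the fixed-step map [propagate()].
#'
#' @param model A [state_space_model()].
#' @param x_prev State vector at `t0`.
#' @param t0,t1 Interval, `t1 > t0`.
#' @return State vector at `t1`.
#' @export
evolve <- function(model, x_prev, t0 = 0, t1 = 1) {
  if (t1 <= t0) emps_error("emps_contract", "need t1 > t0")
  if (length(x_prev) != model$k)
    emps_error("emps_contract", "x_prev must have dimension k")
  g <- if (inherits(model$dynamics, "hill_network"))
    network_rhs(model$dynamics) else model$dynamics
  fn <- function(t, y, parms) list(as.numeric(g(y)))
  sol <- tryCatch(
    suppressWarnings(
      deSolve::lsoda(y = as.numeric(x_prev), times = c(t0, t1), func = fn,
                     rtol = model$solver$rtol, atol = model$solver$atol)),
    error = function(e)
      emps_error("emps_integration",
                 paste("ODE integration failed:", conditionMessage(e)),
                 state = x_prev))
  out <- as.numeric(sol[nrow(sol), -1])
  reached <- sol[nrow(sol), 1]
  if (nrow(sol) < 2 || any(!is.finite(out)) ||
      abs(reached - t1) > 1e-8 * (t1 - t0))
    emps_error("emps_integration",
               "ODE integration failed (non-finite or truncated solution)",
               state = x_prev)
  out
}

#' One-step transition map used by the filter and the EM
#'
#' Fixed-step RK4 flow of the model ODE over `dt`, vectorized over particle
#' rows.  Deterministic and differentiable; the EM transition density is
#' defined on this map.
#'
#' @param model A [state_space_model()].
#' @param X Matrix of states (rows) or a single state vector.
#' @param dt Interval length.
#' @return Propagated states, same shape as `X`.
#' @export
propagate <- function(model, X, dt = 1) {
  vec <- is.null(dim(X))
  Xm <- if (vec) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(Xm) != model$k) emps_error("emps_contract", "state dimension mismatch")
  n_sub <- model$solver$n_sub
  if (inherits(model$dynamics, "hill_network")) {
    A <- net_args(model$dynamics)
    out <- propagate_cpp(Xm, A$src, A$tgt, A$act, A$K, A$n, A$a, A$deg, A$basal,
                         dt, n_sub)
  } else {
    g <- model$dynamics
    h <- dt / n_sub
    out <- Xm
    for (i in seq_len(n_sub)) {
      k1 <- g(out); k2 <- g(out + h / 2 * k1)
      k3 <- g(out + h / 2 * k2); k4 <- g(out + h * k3)
      out <- out + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  if (vec) drop(out) else out
}

#' Linear measurement function
#'
#' `h(x) = alpha * x` restricted to the observed coordinates.
#'
#' @param model A [state_space_model()].
#' @param x State vector (length `k`) or matrix of state rows.
#' @return Observation mean(s) of dimension `l`.
#' @export
measure <- function(model, x) {
  if (is.null(dim(x))) {
    if (length(x) != model$k) emps_error("emps_contract", "state dimension mismatch")
    model$alpha * x[model$obs_idx]
  } else {
    if (ncol(x) != model$k) emps_error("emps_contract", "state dimension mismatch")
    model$alpha * x[, model$obs_idx, drop = FALSE]
  }
}

#' Gaussian transition log-density
#'
#' Log-density of `x_t` given `x_prev` under the model: independent Gaussian
#' residuals around the deterministic evolution, sd `sigma_i` per state.
#'
#' @inheritParams evolve
#' @param x_t Realized state at `t1`.
#' @param map Either `"evolve"` (adaptive solver) or `"propagate"` (the RK4
#'   map the EM uses).
#' @return Scalar log-density.
#' @export
transition_logpdf <- function(model, x_t, x_prev, t0 = 0, t1 = 1,
                              map = c("evolve", "propagate")) {
  map <- match.arg(map)
  mean_ <- if (map == "evolve") evolve(model, x_prev, t0, t1)
           else propagate(model, x_prev, t1 - t0)
  sum(dnorm(x_t, mean = mean_, sd = model$sigma, log = TRUE))
}

## Time-course datasets -----------------------------------------------------

#' Multi-cell time-course dataset
#'
#' All cells share one strictly increasing time grid and observation
#' dimension; missing values are not allowed.
#'
#' @param times Observation times, strictly increasing, common to all cells.
#' @param cells List of per-cell observation matrices (`T x l`).
#' @param genes Optional observable names (defaults to the column names of the
#'   first cell).
#' @return Object of class `timecourse_dataset`.
#' @export
timecourse_dataset <- function(times, cells, genes = NULL) {
  times <- as.numeric(times)
  if (length(times) < 1 || any(diff(times) <= 0))
    emps_error("emps_contract", "times must be strictly increasing")
  if (!length(cells)) emps_error("emps_empty_dataset", "dataset contains no cells")
  cells <- lapply(cells, as.matrix)
  l <- ncol(cells[[1]])
  for (i in seq_along(cells)) {
    if (nrow(cells[[i]]) != length(times) || ncol(cells[[i]]) != l)
      emps_error("emps_validation",
                 sprintf("cell %d does not match the common time grid / dimension", i))
    if (anyNA(cells[[i]]) || any(!is.finite(cells[[i]])))
      emps_error("emps_validation", sprintf("cell %d contains missing values", i))
  }
  genes <- genes %||% colnames(cells[[1]]) %||% paste0("y", seq_len(l))
  cells <- lapply(cells, function(m) { colnames(m) <- genes; m })
  structure(list(times = times, cells = cells, genes = genes,
                 A = length(cells), l = l),
            class = "timecourse_dataset")
}

#' @export
print.timecourse_dataset <- function(x, ...) {
  cat(sprintf("<timecourse_dataset> %d cells x %d time points x %d observables (%s)\n",
              x$A, length(x$times), x$l, paste(x$genes, collapse = ", ")))
  invisible(x)
}

## latent time grid: one unobserved initial state a single spacing before the
## first observation (x_0), then the observation times (x_1 .. x_T)
latent_times <- function(times) {
  dt0 <- if (length(times) > 1) times[2] - times[1] else 1
  c(times[1] - dt0, times)
}

## pooled per-observable sd, used to resolve data-dependent noise bounds
dataset_scale <- function(dataset) {
  ys <- do.call(rbind, dataset$cells)
  apply(ys, 2, sd)
}

## per-observable noise scale estimated from first differences:
## var(diff y) = sigma^2 + 2 eta^2 + (signal slope)^2, so sd(diff)/sqrt(2) is
## an upper-bound-ish scale for both noise sds that, unlike the raw data sd,
## does not grow with the oscillation amplitude
dataset_diff_scale <- function(dataset) {
  dd <- do.call(rbind, lapply(dataset$cells, function(m) apply(m, 2, diff)))
  apply(dd, 2, sd) / sqrt(2)
}
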