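## Synthetic single-cell data: chemical Langevin dynamics integrated with a
## stochastic Runge-Kutta scheme (Honeycutt SRKII, additive noise), a long
## transient discarded so that cell-to-cell variability arises naturally from
## phase decoherence, and Gaussian measurement noise added to every value.

#' Langevin simulation settings
#'
#' Defaults give the reference collection protocol: simulate over `[0, 400]`, keep the
#' window `[351, 400]` at unit spacing (50 points per cell), 10 training and
#' 10 test cells.
#'
#' @param D System-noise amplitude: `<xi_i(t) xi_j(t')> = 2 D delta_ij
#'   delta(t - t')` (state-units^2 / time).
#' @param eta_obs Measurement-noise sd added to every recorded value.
#' @param horizon Total simulated period.
#' @param window Collection interval `c(start, end)` inside the horizon.
#' @param dt_sample Observation spacing inside the window.
#' @param dt_sim Internal SDE step (must divide `dt_sample` evenly for the
#'   recorded grid to be exact).
#' @param n_train,n_test Independent replicate ("cell") counts.
#' @param clip Reflect states at 0 during simulation (concentrations feed
#'   Hill terms with non-integer exponents); generator-only convention.
#' @return Object of class `langevin_config`.
#' @export
langevin_config <- function(D = 0.02, eta_obs = 0.15, horizon = 400,
                            window = c(351, 400), dt_sample = 1,
                            dt_sim = 0.01, n_train = 10, n_test = 10,
                            clip = TRUE) {
  if (window[1] < 0 || window[2] > horizon || window[2] <= window[1])
    emps_error("emps_contract", "window must lie inside [0, horizon]")
  if (dt_sim > dt_sample) emps_error("emps_contract", "dt_sim must be <= dt_sample")
  if (D < 0 || eta_obs < 0) emps_error("emps_contract", "D and eta_obs must be >= 0")
  structure(list(D = D, eta_obs = eta_obs, horizon = horizon, window = window,
                 dt_sample = dt_sample, dt_sim = dt_sim,
                 n_train = n_train, n_test = n_test, clip = clip),
            class = "langevin_config")
}

#' Simulate one chemical-Langevin trajectory
#'
#' Integrates `dx/dt = g(x) + xi(t)` with additive Gaussian white noise of
#' amplitude `sqrt(2 D)` using the Honeycutt SRKII stochastic Runge-Kutta
#' scheme, and returns the states at the observation grid inside the
#' collection window.  With `D = 0` the scheme reduces to deterministic Heun
#' integration of the ODE.
#'
#' @param net A [hill_network()].
#' @param config A [langevin_config()].
#' @param x0 Initial state at time 0 (length = number of genes).
#' @param seed Optional seed; fixed seed gives an identical trajectory.
#' @return Matrix (times x genes) with attribute `"times"`; errors with a
#'   step report if the state diverges.
#' @export
simulate_langevin <- function(net, config, x0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- length(net$genes)
  if (length(x0) != G) emps_error("emps_contract", "x0 must have one entry per gene")
  obs_times <- seq(config$window[1], config$window[2], by = config$dt_sample)
  dt <- config$dt_sim
  save_steps <- as.integer(round(obs_times / dt))
  nsteps <- max(save_steps)
  if (max(abs(save_steps * dt - obs_times)) > 1e-8)
    emps_error("emps_contract", "dt_sim must divide the observation times evenly")
  A <- net_args(net)
  out <- srk_sim_cpp(as.numeric(x0), A$src, A$tgt, A$act, A$K, A$n, A$a,
                     A$deg, A$basal, config$D, dt, nsteps, save_steps,
                     config$clip)
  colnames(out) <- net$genes
  attr(out, "times") <- obs_times
  out
}

#' Add Gaussian measurement noise
#'
#' `y = x + eta * phi` with `phi` standard normal, independently per value.
#'
#' @param x Matrix (or vector) of true values.
#' @param eta_obs Noise sd, `>= 0`.
#' @param seed Optional seed.
#' @return Noisy copy of `x` (attributes preserved).
#' @export
add_measurement_noise <- function(x, eta_obs, seed = NULL) {
  if (eta_obs < 0) emps_error("emps_contract", "eta_obs must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  x + eta_obs * array(rnorm(length(x)), dim = dim(x) %||% length(x))
}

#' Generate a train/test dataset from a circuit
#'
#' Simulates `n_train + n_test` independent cells, each from an independently
#' drawn initial condition, over the full horizon; only the collection window
#' is retained, so the discarded transient decorrelates the oscillation
#' phases across cells.  Measurement noise is then added to every value.
#'
#' @param net A [hill_network()] (or a [reference_circuits()] entry, whose
#'   attached defaults for `init_box`, `D` and `eta_obs` are then used).
#' @param config A [langevin_config()].
#' @param init_box 2 x G matrix (rows: lower, upper) from which initial
#'   states are drawn uniformly per cell.
#' @param seed Master seed; train and test use disjoint derived streams.
#' @return List with `train` and `test` [timecourse_dataset()]s and the
#'   latent noise-free `states` (list of matrices, train then test).
#' @export
generate_dataset <- function(net, config = NULL, init_box = NULL, seed = 1) {
  if (inherits(net, "reference_circuit")) {
    init_box <- init_box %||% net$init_box
    config <- config %||% langevin_config(D = net$D, eta_obs = net$eta_obs)
    net <- net$network
  }
  config <- config %||% langevin_config()
  G <- length(net$genes)
  if (is.null(init_box))
    init_box <- rbind(rep(0.1, G), rep(2, G))
  obs_times <- seq(config$window[1], config$window[2], by = config$dt_sample)
  one_split <- function(n_cells, split_seed) {
    if (n_cells < 1) return(list(ds = NULL, states = list()))
    cells <- vector("list", n_cells); states <- vector("list", n_cells)
    for (c_i in seq_len(n_cells)) {
      set.seed((split_seed + 523L * c_i) %% .Machine$integer.max)
      x0 <- runif(G, init_box[1, ], init_box[2, ])
      tr <- simulate_langevin(net, config, x0)
      states[[c_i]] <- tr
      y <- add_measurement_noise(unclass(tr), config$eta_obs)
      attr(y, "times") <- NULL
      cells[[c_i]] <- y
    }
    list(ds = timecourse_dataset(obs_times, cells, net$genes),
         states = states)
  }
  tr <- one_split(config$n_train, seed)
  te <- one_split(config$n_test, seed + 500000L)
  list(train = tr$ds, test = te$ds, states = c(tr$states, te$states),
       config = config, network = net)
}

#' Reference ground-truth gene circuits
#'
#' Two oscillatory circuits used as recovery ground truth throughout the
#' package, each returned with documented kinetic parameters, an
#' initial-condition box, and default noise amplitudes:
#'
#' * `three_gene`: negative-feedback loop X -> Y -> Z -| X.  X is produced
#'   constitutively (basal rate) and repressed by Z; Y and Z are activated by
#'   X and Y respectively.
#' * `two_gene`: relaxation-type oscillator with X autoactivation, activation
#'   of Z by X, and repression of X by Z (gene Y does not exist).
#'
#' Both parameter sets are verified by the test suite to give sustained
#' oscillation over the collection window.
#'
#' @return Named list of `reference_circuit` objects, each with fields
#'   `network`, `init_box`, `D`, `eta_obs`, `name`.
#' @export
reference_circuits <- function() {
  three <- hill_network(
    genes = c("X", "Y", "Z"),
    paths = rbind(
      regulatory_path("X", "Y", "activator", K = 1 / 3, n = 4, a = 6),
      regulatory_path("Y", "Z", "activator", K = 1 / 3, n = 4, a = 6),
      regulatory_path("Z", "X", "repressor", K = 0.4, n = 4)),
    degradation = c(X = 0.4, Y = 0.4, Z = 0.4),
    basal = c(X = 3, Y = 0, Z = 0))
  two <- hill_network(
    genes = c("X", "Z"),
    paths = rbind(
      regulatory_path("X", "X", "activator", K = 1 / 3, n = 4, a = 6),
      regulatory_path("X", "Z", "activator", K = 0.27, n = 4, a = 3),
      regulatory_path("Z", "X", "repressor", K = 0.5, n = 4)),
    degradation = c(X = 0.5, Z = 0.2),
    basal = c(X = 0.6, Z = 0))
  list(three_gene = structure(list(network = three,
                                   init_box = rbind(rep(0.5, 3), rep(8, 3)),
                                   D = 0.02, eta_obs = 0.15,
                                   name = "three_gene"),
                              class = "reference_circuit"),
       two_gene = structure(list(network = two,
                                 init_box = rbind(rep(0.5, 2), rep(8, 2)),
                                 D = 0.02, eta_obs = 0.15,
                                 name = "two_gene"),
                            class = "reference_circuit"))
}

#' @export
print.reference_circuit <- function(x, ...) {
  cat(sprintf("<reference_circuit> %s (D = %g, eta_obs = %g)\n",
              x$name, x$D, x$eta_obs))
  print(x$network)
  invisible(x)
}

#' Detect sustained oscillation in a trajectory
#'
#' Counts interior local maxima per species and compares early and late
#' amplitude; used to verify that the reference circuits oscillate over the
#' collection window rather than decaying to a fixed point.
#'
#' @param x Matrix (times x species).
#' @param min_peaks Minimum interior maxima per species.
#' @param amp_ratio Late/early peak-to-trough amplitude ratio required.
#' @return Logical; attributes `peaks` and `amp_ratio` carry the diagnostics.
#' @export
detect_oscillation <- function(x, min_peaks = 3, amp_ratio = 0.5) {
  x <- as.matrix(x)
  n <- nrow(x)
  peaks <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    sum(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n])
  }, numeric(1))
  half <- floor(n / 2)
  amp <- function(v) diff(range(v))
  ratios <- vapply(seq_len(ncol(x)), function(j) {
    a1 <- amp(x[seq_len(half), j]); a2 <- amp(x[(half + 1):n, j])
    if (a1 == 0) 0 else a2 / a1
  }, numeric(1))
  structure(all(peaks >= min_peaks) && all(ratios >= amp_ratio),
            peaks = peaks, amp_ratio = ratios)
}
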