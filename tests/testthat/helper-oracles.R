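# Independent oracles and small fixture builders.  These deliberately avoid
# the package's compiled kernels: plain-R reference implementations against
# which the fast paths are checked.

## fixed-step RK4 integration of an R right-hand side (reference integrator)
rk4_reference <- function(g, x0, t_total, h = 1e-3) {
  n <- ceiling(t_total / h)
  h <- t_total / n
  x <- x0
  for (i in seq_len(n)) {
    k1 <- g(x); k2 <- g(x + h / 2 * k1)
    k3 <- g(x + h / 2 * k2); k4 <- g(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

## exact Kalman filter + RTS smoother for the scalar affine-Gaussian model
##   x_t = F x_{t-1} + c + N(0, Q);  y_t = alpha x_t + N(0, R);  x_0 ~ N(mu0, P0)
kalman_rts <- function(y, F, cc, Q, R, mu0, P0, alpha = 1) {
  Tn <- length(y)
  mp <- Pp <- mf <- Pf <- numeric(Tn + 1)
  mf[1] <- mu0; Pf[1] <- P0
  ll <- 0
  for (t in seq_len(Tn)) {
    mp[t + 1] <- F * mf[t] + cc
    Pp[t + 1] <- F^2 * Pf[t] + Q
    S <- alpha^2 * Pp[t + 1] + R
    ll <- ll + dnorm(y[t], alpha * mp[t + 1], sqrt(S), log = TRUE)
    K <- Pp[t + 1] * alpha / S
    mf[t + 1] <- mp[t + 1] + K * (y[t] - alpha * mp[t + 1])
    Pf[t + 1] <- (1 - K * alpha) * Pp[t + 1]
  }
  ms <- mf; Ps <- Pf
  for (t in Tn:1) {
    J <- Pf[t] * F / Pp[t + 1]
    ms[t] <- mf[t] + J * (ms[t + 1] - mp[t + 1])
    Ps[t] <- Pf[t] + J^2 * (Ps[t + 1] - Pp[t + 1])
  }
  list(smoothed_mean = ms, smoothed_var = Ps, loglik = ll)
}

## naive triple-sum evaluation of the expected complete-data log-likelihood
## (initial + transition + measurement blocks), looping over every cell,
## particle, time point and coordinate; f evaluated with the model's own
## one-step map (that map defines the transition density)
q_naive <- function(model, dataset, ensembles, theta_sys = NULL, sigma = NULL,
                    eta = NULL, mu = NULL, gamma = NULL) {
  theta_sys <- theta_sys %||% theta_sys_pack(model$dynamics)
  sigma <- sigma %||% model$sigma
  eta <- eta %||% model$eta
  mu <- mu %||% model$mu
  gamma <- gamma %||% model$gamma
  m <- model
  m$dynamics <- theta_sys_unpack(model$dynamics, theta_sys)
  total <- 0
  for (a in seq_along(ensembles)) {
    tr <- ensembles[[a]]$trajectories
    w <- ensembles[[a]]$weights
    Tn <- dim(tr)[1] - 1
    y <- dataset$cells[[a]]
    for (p in seq_along(w)) {
      for (i in seq_len(model$k))
        total <- total + w[p] * dnorm(tr[1, p, i], mu[a, i], gamma[i], log = TRUE)
      for (t in seq_len(Tn)) {
        fx <- propagate(m, tr[t, p, ], 1)
        for (i in seq_len(model$k))
          total <- total + w[p] * dnorm(tr[t + 1, p, i], fx[i], sigma[i], log = TRUE)
        for (j in seq_len(model$l))
          total <- total + w[p] *
            dnorm(y[t, j], model$alpha * tr[t + 1, p, model$obs_idx[j]],
                  eta[j], log = TRUE)
      }
    }
  }
  unname(total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## small decaying-oscillation test fixtures -------------------------------

## one-gene linear network (pure birth-death): f is affine, so the model is
## exactly linear-Gaussian and the Kalman oracle applies
linear_gene_model <- function(b = 0.5, d = 0.3, sigma = 0.3, eta = 0.4,
                              gamma = 0.7, mu = 1.5, A = 1) {
  net <- hill_network("X", degradation = d, basal = b)
  state_space_model(net, sigma = sigma, eta = eta, gamma = gamma,
                    mu = matrix(mu, A, 1))
}

## simulate directly from the discrete state-space model (no Langevin):
## self-consistent data for which the transition density is exact
simulate_discrete <- function(model, Tn, x0) {
  k <- model$k
  X <- matrix(NA_real_, Tn + 1, k)
  X[1, ] <- x0
  for (t in seq_len(Tn))
    X[t + 1, ] <- propagate(model, X[t, ], 1) + rnorm(k, 0, model$sigma)
  Y <- model$alpha * X[-1, model$obs_idx, drop = FALSE] +
    matrix(rnorm(Tn * model$l, 0, rep(model$eta, each = Tn)), Tn, model$l)
  list(X = X, Y = Y)
}

## tiny three-gene dataset + ensembles for Q-function tests
tiny_estep_fixture <- function(A = 2, Tn = 5, P = 10, seed = 7) {
  set.seed(seed)
  net <- reference_circuits()$three_gene$network
  model <- state_space_model(net, sigma = 0.3, eta = 0.2, gamma = 0.5,
                             mu = matrix(runif(A * 3, 0.5, 3), A, 3))
  cells <- lapply(seq_len(A), function(a)
    simulate_discrete(model, Tn, model$mu[a, ])$Y)
  dataset <- timecourse_dataset(seq_len(Tn), cells, net$genes)
  es <- e_step(model, dataset, P = P, n_back = P, seed = seed)
  list(model = model, dataset = dataset, estep = es)
}
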