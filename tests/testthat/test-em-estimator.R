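# EM-PS estimator: Q-function correctness against a naive oracle, closed-form
# noise updates, quasi-Newton kinetics updates, and the EM loop contracts.

test_that("vectorized Q equals the naive triple-loop oracle", {
  fx <- tiny_estep_fixture(A = 2, Tn = 5, P = 10)
  q_fast <- fx$estep$q_fun()
  q_slow <- q_naive(fx$model, fx$dataset, fx$estep$ensembles)
  expect_equal(q_fast, q_slow, tolerance = 1e-10)

  # also at a parameter point different from theta_old
  th <- theta_sys_pack(fx$model$dynamics) * 1.3
  sg <- fx$model$sigma * 0.8
  expect_equal(fx$estep$q_fun(theta_sys = th, sigma = sg),
               q_naive(fx$model, fx$dataset, fx$estep$ensembles,
                       theta_sys = th, sigma = sg),
               tolerance = 1e-10)
})

test_that("single-trajectory ensemble gives the complete-data log joint", {
  fx <- tiny_estep_fixture(A = 1, Tn = 4, P = 6)
  es1 <- e_step(fx$model, fx$dataset, P = 6, n_back = 1, seed = 3)
  tr <- es1$ensembles[[1]]$trajectories
  m <- fx$model
  direct <- sum(dnorm(tr[1, 1, ], m$mu[1, ], m$gamma, log = TRUE))
  for (t in 1:4) {
    fxv <- propagate(m, tr[t, 1, ], 1)
    direct <- direct + sum(dnorm(tr[t + 1, 1, ], fxv, m$sigma, log = TRUE)) +
      sum(dnorm(fx$dataset$cells[[1]][t, ], tr[t + 1, 1, ], m$eta, log = TRUE))
  }
  expect_equal(es1$q_fun(), direct, tolerance = 1e-10)
})

test_that("noise updates are the stationary points of Q (numerical gradient check)", {
  fx <- tiny_estep_fixture(A = 2, Tn = 6, P = 15)
  up <- m_step_noise(fx$estep)
  eps <- 1e-5
  # sigma: derivative of Q w.r.t. each sigma_i vanishes at the raw update
  for (i in 1:3) {
    s <- up$sigma_raw
    sp <- s; sp[i] <- s[i] + eps; sm <- s; sm[i] <- s[i] - eps
    dq <- (fx$estep$q_fun(sigma = sp) - fx$estep$q_fun(sigma = sm)) / (2 * eps)
    expect_lt(abs(dq), 1e-4)
  }
  # gamma and mu jointly
  for (i in 1:3) {
    g <- up$gamma_raw
    gp <- g; gp[i] <- g[i] + eps; gm <- g; gm[i] <- g[i] - eps
    dq <- (fx$estep$q_fun(mu = up$mu, gamma = gp) -
           fx$estep$q_fun(mu = up$mu, gamma = gm)) / (2 * eps)
    expect_lt(abs(dq), 1e-4)
  }
  mu_p <- up$mu; mu_p[2, 1] <- mu_p[2, 1] + eps
  mu_m <- up$mu; mu_m[2, 1] <- mu_m[2, 1] - eps
  dq <- (fx$estep$q_fun(mu = mu_p, gamma = up$gamma_raw) -
         fx$estep$q_fun(mu = mu_m, gamma = up$gamma_raw)) / (2 * eps)
  expect_lt(abs(dq), 1e-4)
})

test_that("unweighted special case: updates equal ordinary residual formulas", {
  fx <- tiny_estep_fixture(A = 1, Tn = 5, P = 4)
  es1 <- e_step(fx$model, fx$dataset, P = 4, n_back = 1, seed = 9)
  up <- m_step_noise(es1)
  tr <- es1$ensembles[[1]]$trajectories
  expect_equal(up$mu[1, ], tr[1, 1, ], tolerance = 1e-12)
  resid <- vapply(1:5, function(t)
    tr[t + 1, 1, ] - propagate(fx$model, tr[t, 1, ], 1), numeric(3))
  expect_equal(up$sigma_raw, sqrt(rowMeans(resid^2)), tolerance = 1e-10)
  meas <- vapply(1:5, function(t)
    fx$dataset$cells[[1]][t, ] - tr[t + 1, 1, ], numeric(3))
  expect_equal(up$eta_raw, sqrt(rowMeans(meas^2)), tolerance = 1e-10)
})

test_that("noise bounds clip the updates exactly", {
  fx <- tiny_estep_fixture(A = 1, Tn = 5, P = 8)
  up <- m_step_noise(fx$estep,
                     bounds = list(gamma_min = rep(10, 3),
                                   sigma_max = rep(1e-4, 3),
                                   eta_max = rep(1e-4, 3),
                                   sigma_min = rep(1e-8, 3),
                                   eta_min = rep(1e-8, 3)))
  expect_equal(up$gamma, rep(10, 3), ignore_attr = TRUE)
  expect_equal(up$sigma, rep(1e-4, 3), ignore_attr = TRUE)
  expect_equal(up$eta, rep(1e-4, 3), ignore_attr = TRUE)
})

test_that("m_step_sys ascends the (penalized) Q objective and respects bounds", {
  fx <- tiny_estep_fixture(A = 2, Tn = 6, P = 12)
  th_old <- theta_sys_pack(fx$model$dynamics) * 0.5   # displaced start
  obj <- function(th, lam = 0)
    emps:::qtrans_eval(fx$estep$cache, fx$model, th)$q -
      lam * sum(th[grepl("^K", names(th))])
  for (lam in c(0, 5)) {
    ms <- m_step_sys(fx$estep, th_old, lam = lam)
    expect_gte(obj(ms$theta, lam), obj(th_old, lam) - 1e-8)
    expect_true(all(ms$theta >= 0))
  }
  # huge penalty drives association constants exactly to the zero bound
  ms <- m_step_sys(fx$estep, th_old, lam = 1e7,
                   control = em_control(m_maxit = 40))
  expect_true(all(ms$theta[grepl("^K", names(ms$theta))] == 0))
  # Hill coefficients stay inside their box
  nvals <- ms$theta[grepl("^n", names(ms$theta))]
  expect_true(all(nvals >= 1 & nvals <= 8))
})

test_that("ascent holds across random restarts", {
  fx <- tiny_estep_fixture(A = 2, Tn = 5, P = 10, seed = 21)
  th0 <- theta_sys_pack(fx$model$dynamics)
  obj <- function(th) emps:::qtrans_eval(fx$estep$cache, fx$model, th)$q
  set.seed(31)
  for (r in 1:8) {
    th_r <- th0 * exp(runif(length(th0), -1, 1))
    th_r[grepl("^n", names(th_r))] <- runif(3, 1, 8)
    ms <- m_step_sys(fx$estep, th_r)
    expect_gte(obj(ms$theta), obj(th_r) - 1e-8)
  }
})

test_that("run_em improves the likelihood and keeps coherent history", {
  rc <- reference_circuits()$three_gene
  cfg <- langevin_config(n_train = 3, n_test = 0)
  set.seed(14)
  dat <- generate_dataset(rc$network, cfg, init_box = rc$init_box, seed = 14)
  truth <- theta_sys_pack(rc$network)
  th0 <- truth / 3
  th0[grepl("^n", names(th0))] <- 2
  model <- state_space_model(theta_sys_unpack(rc$network, th0))
  fit <- run_em(model, dat$train, P = 60, n_back = 40, iters = 6, seed = 2)
  expect_length(fit$loglik_history, 6)
  expect_equal(nrow(fit$theta_history), 6)
  expect_equal(nrow(fit$K_history), 6)
  expect_gt(tail(fit$loglik_history, 1), fit$loglik_history[1])
  # parameters inside bounds after every M-step
  nh <- fit$theta_history[, grepl("^n", colnames(fit$theta_history)), drop = FALSE]
  expect_true(all(nh >= 1 & nh <= 8))
  expect_true(all(fit$theta_history[, grepl("^K", colnames(fit$theta_history))] >= 0))
  # structural zeros stay frozen
  expect_equal(unname(fit$theta[c("b_Y", "b_Z")]), c(0, 0))
})

test_that("uniform-grid requirement is enforced", {
  rc <- reference_circuits()$three_gene
  y <- matrix(runif(12, 1, 2), 4, 3)
  ds <- timecourse_dataset(c(1, 2, 4, 8), list(y), rc$network$genes)
  model <- state_space_model(rc$network, mu = matrix(1, 1, 3))
  expect_error(e_step(model, ds, P = 10, seed = 1), class = "emps_contract")
})
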