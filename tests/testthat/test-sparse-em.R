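# Lasso-regularized EM: penalty arithmetic, effective-path accounting,
# consistency filter, and the lambda = 0 equivalence with plain EM-PS.

test_that("penalized_q subtracts exactly lambda * sum(K)", {
  qf <- function(theta_sys, ...) 10
  th <- c(K01 = 1.5, K02 = 1.0, n01 = 2, a01 = 3)
  expect_equal(penalized_q(qf, 0)(th), 10)
  expect_equal(penalized_q(qf, 3)(th), 10 - 3 * 2.5)
  expect_equal(penalized_q(qf, 7)(c(K01 = 0, K02 = 0, n01 = 2)), 10)
  # explicit K name subset
  expect_equal(penalized_q(qf, 2, K_names = "K01")(th), 10 - 3)
})

test_that("count_effective_paths applies thresholding semantics", {
  red <- build_redundant_model(c("X", "Y"), K = 0)
  expect_equal(as.integer(count_effective_paths(red)), 0)
  th <- theta_sys_pack(red)
  th[c("K01", "K03", "K06")] <- c(1e-9, 0.8, 2)
  red2 <- theta_sys_unpack(red, th)
  cnt <- count_effective_paths(red2, threshold = 1e-4)
  expect_equal(as.integer(cnt), 2)
  expect_setequal(attr(cnt, "path_ids"), c(3L, 6L))
  expect_equal(as.integer(count_effective_paths(red2, threshold = 1)), 1)
})

test_that("consistency check flags simultaneous activation+repression of one pair", {
  expect_true(check_consistency(reference_circuits()$three_gene$network)$consistent)
  red <- build_redundant_model(c("X", "Y", "Z"), K = 0)
  th <- theta_sys_pack(red)
  th[c("K17", "K18")] <- 0.5   # Z both activates and represses Z
  bad <- theta_sys_unpack(red, th)
  chk <- check_consistency(bad)
  expect_false(chk$consistent)
  expect_equal(chk$violations, data.frame(source = "Z", target = "Z",
                                          stringsAsFactors = FALSE))
  # different sources regulating one target with opposite signs are fine
  th <- theta_sys_pack(red); th[c("K07", "K12")] <- 0.5  # X->Y act, Z-|Y rep
  expect_true(check_consistency(theta_sys_unpack(red, th))$consistent)
})

test_that("lambda = 0 run is bit-identical to plain EM-PS under a shared seed", {
  rc <- reference_circuits()$three_gene
  cfg <- langevin_config(n_train = 2, n_test = 0)
  dat <- generate_dataset(rc$network, cfg, init_box = rc$init_box, seed = 4)
  red <- build_redundant_model(c("X", "Y", "Z"), K = 0.2, n = 2, a = 2,
                               degradation = 0.3, basal = 0.5)
  f_em <- run_em(state_space_model(red), dat$train, P = 40, n_back = 25,
                 iters = 3, seed = 77)
  f_l0 <- run_em_lasso(state_space_model(red), dat$train, lam = 0, P = 40,
                       n_back = 25, iters = 3, seed = 77)
  expect_identical(f_em$theta, f_l0$fit$theta)
  expect_identical(f_em$loglik_history, f_l0$fit$loglik_history)
  expect_identical(f_em$theta_history, f_l0$fit$theta_history)
})

test_that("lasso run records K history and reports structure", {
  rc <- reference_circuits()$three_gene
  cfg <- langevin_config(n_train = 2, n_test = 2)
  dat <- generate_dataset(rc$network, cfg, init_box = rc$init_box, seed = 6)
  red <- build_redundant_model(c("X", "Y", "Z"), K = 0.2, n = 2, a = 2,
                               degradation = 0.3, basal = 0.5)
  r <- run_em_lasso(state_space_model(red), dat$train, lam = 50, P = 40,
                    n_back = 25, iters = 4, seed = 3, test = dat$test)
  expect_s3_class(r, "lasso_run")
  expect_equal(dim(r$K_history), c(4L, 18L))
  expect_true(all(r$K_history >= 0))
  expect_true(is.finite(r$test_loglik))
  expect_true(all(r$effective_paths %in% 1:18))
  expect_error(run_em_lasso(state_space_model(red), dat$train, lam = -1,
                            P = 40, iters = 1, seed = 1),
               class = "emps_contract")
})

test_that("sweep handles a degenerate {0} grid and orders runs by lambda", {
  rc <- reference_circuits()$three_gene
  cfg <- langevin_config(n_train = 2, n_test = 2)
  dat <- generate_dataset(rc$network, cfg, init_box = rc$init_box, seed = 8)
  red <- build_redundant_model(c("X", "Y", "Z"), K = 0.2, n = 2, a = 2,
                               degradation = 0.3, basal = 0.5)
  sw <- lambda_sweep(state_space_model(red), dat$train, dat$test,
                     lam_grid = 0, P = 40, n_back = 25, iters = 3, seed = 5)
  expect_equal(nrow(sw$summary), 1)
  f_em <- run_em(state_space_model(red), dat$train, P = 40, n_back = 25,
                 iters = 3, seed = 5)
  expect_identical(sw$runs[[1]]$fit$theta, f_em$theta)
  expect_error(lambda_sweep(state_space_model(red), dat$train, dat$test,
                            lam_grid = numeric(0), P = 40, iters = 1),
               class = "emps_contract")
})

test_that("once an association constant hits zero it tends to stay there", {
  rc <- reference_circuits()$three_gene
  cfg <- langevin_config(n_train = 3, n_test = 0)
  dat <- generate_dataset(rc$network, cfg, init_box = rc$init_box, seed = 10)
  red <- build_redundant_model(c("X", "Y", "Z"), K = 0.2, n = 2, a = 2,
                               degradation = 0.3, basal = 0.5)
  r <- run_em_lasso(state_space_model(red), dat$train, lam = 500, P = 50,
                    n_back = 30, iters = 10, seed = 2)
  KH <- r$K_history
  hit0 <- apply(KH == 0, 2, function(z) if (any(z)) which(z)[1] else NA)
  after <- unlist(lapply(which(!is.na(hit0)), function(j)
    KH[seq(hit0[j], nrow(KH)), j] == 0))
  expect_gt(length(after), 0)          # pruning did occur
  expect_gte(mean(after), 0.9)         # re-activation is rare
})
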