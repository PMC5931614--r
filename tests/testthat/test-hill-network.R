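# Hill kinetics, the redundant model, and the paths-to-parameters mapping.

test_that("activator and repressor activities match closed forms", {
  expect_identical(activator_activity(0, 4, 100), 0)
  expect_equal(activator_activity(1, 1, 1), 0.5)
  expect_equal(activator_activity(2, 4, 3), 6^4 / (1 + 6^4), tolerance = 1e-12)
  expect_identical(repressor_activity(0, 2, 10), 1)
  expect_equal(repressor_activity(1, 1, 1), 0.5)
  expect_equal(repressor_activity(1, 2, 10), 1 / 101, tolerance = 1e-12)
})

test_that("activities are monotone in x and K, with the right direction", {
  xs <- seq(0, 5, length.out = 40)
  Ks <- seq(0, 3, length.out = 30)
  for (n in c(1, 2, 4.5)) {
    expect_true(all(diff(activator_activity(1.3, n, xs)) >= 0))
    expect_true(all(diff(repressor_activity(1.3, n, xs)) <= 0))
    expect_true(all(diff(vapply(Ks, activator_activity, 1, n = n, x = 2)) >= 0))
    expect_true(all(diff(vapply(Ks, repressor_activity, 1, n = n, x = 2)) <= 0))
  }
})

test_that("production_rate follows the activator-sum times repressor-product form", {
  paths <- rbind(
    regulatory_path("A", "T", "activator", K = 1.0, n = 2, a = 2),
    regulatory_path("B", "T", "activator", K = 0.5, n = 3, a = 1.5),
    regulatory_path("C", "T", "repressor", K = 2.0, n = 2),
    regulatory_path("D", "T", "repressor", K = 0.8, n = 4))
  x <- c(A = 1.2, B = 2.5, C = 0.4, D = 1.1)
  # independent term-by-term evaluation
  act <- 2 * (1.2^2 / (1 + 1.2^2)) + 1.5 * ((0.5 * 2.5)^3 / (1 + (0.5 * 2.5)^3))
  rep_ <- 1 / (1 + (2 * 0.4)^2) * 1 / (1 + (0.8 * 1.1)^4)
  expect_equal(production_rate(paths, x), act * rep_, tolerance = 1e-12)
  # all-zero activators silence the gene regardless of repressors
  p0 <- paths; p0$K[p0$sign == "activator"] <- 0
  expect_equal(production_rate(p0, x), 0)
  # single activator at half-saturation with amplitude 2
  p1 <- regulatory_path("A", "T", "activator", K = 1, n = 1, a = 2)
  expect_equal(production_rate(p1, c(A = 1)), 1)
  # bounded by the sum of amplitudes (+ basal)
  expect_lt(production_rate(paths, c(A = 100, B = 100, C = 0, D = 0)), 3.5)
})

test_that("redundant model enumerates 2 G^2 canonical paths", {
  expect_equal(nrow(build_redundant_model(3)$paths), 18)
  expect_equal(nrow(build_redundant_model(2)$paths), 8)
  p1 <- build_redundant_model(1)$paths
  expect_equal(nrow(p1), 2)
  expect_setequal(p1$sign, c("activator", "repressor"))
  # numbering: targets-major, then sources, then activator before repressor
  red <- build_redundant_model(c("X", "Y", "Z"))
  expect_identical(red$paths$path_id, 1:18)
  expect_identical(red$paths$target[1:6], rep("X", 6))
  expect_identical(red$paths$source[1:2], c("X", "X"))
  expect_identical(red$paths$sign[1:2], c("activator", "repressor"))
})

test_that("sparse circuits keep their redundant-model path ids", {
  net <- reference_circuits()$three_gene$network
  red_ids <- build_redundant_model(c("X", "Y", "Z"))$paths
  for (i in seq_len(nrow(net$paths))) {
    p <- net$paths[i, ]
    match_row <- red_ids[red_ids$source == p$source & red_ids$target == p$target &
                         red_ids$sign == p$sign, ]
    expect_equal(p$path_id, match_row$path_id)
  }
})

test_that("rhs reduces to pure decay when every path has K = 0", {
  red <- build_redundant_model(c("X", "Y"), K = 0, basal = 0,
                               degradation = c(0.5, 0.7))
  g <- network_rhs(red)
  x <- c(X = 2, Y = 3)
  expect_equal(unname(g(x)), c(-0.5 * 2, -0.7 * 3), tolerance = 1e-12)
})

test_that("setting K = 0 on a path is trajectory-equivalent to deleting it", {
  rc <- reference_circuits()$three_gene
  sparse <- rc$network
  # embed in the 18-path redundant model with all other K = 0
  red <- build_redundant_model(c("X", "Y", "Z"), K = 0, n = 2, a = 1,
                               degradation = sparse$degradation,
                               basal = sparse$basal)
  th <- theta_sys_pack(red)
  for (i in seq_len(nrow(sparse$paths))) {
    p <- sparse$paths[i, ]
    th[sprintf("K%02d", p$path_id)] <- p$K
    th[sprintf("n%02d", p$path_id)] <- p$n
    if (p$sign == "activator") th[sprintf("a%02d", p$path_id)] <- p$a
  }
  red <- theta_sys_unpack(red, th)
  m_red <- state_space_model(red)
  m_sparse <- state_space_model(sparse)
  x <- c(1.1, 0.6, 2.4)
  for (step in 1:30) {
    x_red <- propagate(m_red, x, 1)
    x_sparse <- propagate(m_sparse, x, 1)
    expect_equal(x_red, x_sparse, tolerance = 1e-10)
    x <- x_sparse
  }
})

test_that("theta_sys flattening round-trips and preserves rhs output", {
  red <- build_redundant_model(c("X", "Y", "Z"), K = 0.3, n = 2.5, a = 1.7)
  th <- theta_sys_pack(red)
  expect_equal(length(th), 18 + 18 + 9 + 3 + 3)
  rebuilt <- theta_sys_unpack(red, sample(th))   # order-insensitive by name
  g1 <- network_rhs(red); g2 <- network_rhs(rebuilt)
  set.seed(3)
  X <- matrix(runif(15, 0, 4), 5, 3)
  expect_equal(g1(X), g2(X), tolerance = 1e-14)
  expect_error(theta_sys_unpack(red, th[-1]), class = "emps_contract")
})

test_that("theta_sys_bounds freeze structural zeros and bound Hill coefficients", {
  net <- reference_circuits()$three_gene$network   # basal Y = Z = 0
  b <- theta_sys_bounds(net)
  expect_equal(unname(b$upper[c("b_Y", "b_Z")]), c(0, 0))
  expect_gt(b$upper["b_X"], 0)
  expect_equal(unname(b$lower[grepl("^n", names(b$lower))]), rep(1, 3))
  expect_equal(unname(b$upper[grepl("^n", names(b$upper))]), rep(8, 3))
})

test_that("embed_network preserves dynamics on the original genes", {
  rc2 <- reference_circuits()$two_gene
  emb <- embed_network(rc2$network, c("X", "Y", "Z"))
  expect_identical(emb$paths$path_id, c(1L, 6L, 13L))
  m2 <- state_space_model(rc2$network)
  m3 <- state_space_model(emb)
  x2 <- c(1.4, 2.2); x3 <- c(1.4, 0.3, 2.2)
  p2 <- propagate(m2, x2, 1); p3 <- propagate(m3, x3, 1)
  expect_equal(p3[c(1, 3)], p2, tolerance = 1e-12)
  expect_error(embed_network(rc2$network, c("X", "Q")), class = "emps_contract")
})

test_that("network constructor rejects malformed inputs", {
  expect_error(hill_network("X", degradation = 0), class = "emps_contract")
  expect_error(hill_network("X", regulatory_path("X", "X", "activator", K = -1, a = 1)),
               class = "emps_contract")
  expect_error(regulatory_path("X", "X", "repressor", K = 1, a = 2),
               class = "emps_contract")
  expect_error(
    hill_network(c("X", "Y"),
                 regulatory_path("X", "Y", "activator", K = 1, a = NA)),
    class = "emps_contract")
})
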