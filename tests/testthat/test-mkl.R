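test_that("solve_scuba handles degenerate and symmetric instances", {
  # m = 1: the simplex is a point
  g <- solve_scuba(matrix(1), c_vec = 0.2, lambda_pos = 0.3)
  expect_equal(g$gamma_pos, 1)

  # indistinguishable positives get equal weight
  K <- matrix(c(1, 0.4, 0.4, 1), 2)
  g <- solve_scuba(K, c_vec = c(0.1, 0.1), lambda_pos = 0.5)
  expect_equal(g$gamma_pos, c(0.5, 0.5), tolerance = 1e-6)

  expect_error(solve_scuba(matrix(NaN, 1, 1), 0, 1), "non-finite")
  expect_error(solve_scuba(matrix(1), 0, -1), "nonnegative")
})

test_that("solve_scuba matches the generic QP oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    m <- sample(2:6, 1)
    n <- sample(5:30, 1)
    inst <- random_instance(m, n, R = 1L, seed = seed)
    blocks <- scuba_blocks(inst$bank, inst$sets)
    for (lam in c(0, 0.3, 1)) {
      Q <- blocks$K_pos[[1L]] + lam * diag(m)
      got <- solve_scuba(blocks$K_pos[[1L]], blocks$c_vec[[1L]], lam)
      want <- qp_simplex_oracle(Q, blocks$c_vec[[1L]])
      expect_equal(got$objective, want$objective, tolerance = 1e-6)
      # simplex feasibility
      expect_true(all(got$gamma_pos >= 0))
      expect_equal(sum(got$gamma_pos), 1, tolerance = 1e-8)
    }
  }
})

test_that("solver optimum beats every simplex vertex", {
  inst <- random_instance(5, 20, R = 1L, seed = 11)
  blocks <- scuba_blocks(inst$bank, inst$sets)
  Kp <- blocks$K_pos[[1L]]
  cv <- blocks$c_vec[[1L]]
  got <- solve_scuba(Kp, cv, 0.3)
  for (i in 1:5) {
    v <- replace(rep(0, 5), i, 1)
    vertex_obj <- drop(v %*% Kp %*% v) - 2 * sum(v * cv) + 0.3 * sum(v^2)
    expect_lte(got$objective, vertex_obj + 1e-6)
  }
})

test_that("solve_easymkl matches closed forms and the QP oracle", {
  # lam = 1: centroid solution, uniform on each class
  inst <- random_instance(4, 6, R = 1L, seed = 3)
  Ks <- inst$bank$kernels[[1L]]
  g <- solve_easymkl(Ks, inst$sets, 1)
  expect_equal(g$gamma_pos, rep(1 / 4, 4), tolerance = 1e-8)
  expect_equal(g$gamma_neg, rep(1 / 6, 6), tolerance = 1e-8)

  # both simplices are points
  tiny <- random_instance(1, 1, R = 1L, seed = 5)
  g <- solve_easymkl(tiny$bank$kernels[[1L]], tiny$sets, 0.4)
  expect_equal(c(g$gamma_pos, g$gamma_neg), c(1, 1))

  expect_error(solve_easymkl(Ks, inst$sets, 1.2), "\\[0, 1\\]")

  for (seed in 7:9) {
    inst <- random_instance(4, 6, R = 1L, seed = seed)
    K <- inst$bank$kernels[[1L]]
    for (lam in c(0.2, 0.5, 0.9)) {
      got <- solve_easymkl(K, inst$sets, lam)
      want <- qp_easymkl_oracle(K, inst$sets$labels, lam)
      expect_equal(got$objective, want$objective, tolerance = 1e-6)
    }
  }
})

test_that("kernel weights are a probability vector with sensible structure", {
  inst <- random_instance(4, 10, R = 1L, seed = 2)
  fit <- scuba_fit(inst$bank, inst$sets, 0.5)
  expect_identical(fit$eta, 1)

  # duplicated kernel: equal weights
  bank2 <- as_kernel_bank(list(inst$bank$kernels[[1L]],
                               inst$bank$kernels[[1L]]))
  fit2 <- scuba_fit(bank2, inst$sets, 0.5)
  expect_equal(fit2$eta, c(0.5, 0.5), tolerance = 1e-10)

  # zero kernel gets zero weight
  zero <- inst$bank$kernels[[1L]] * 0
  bank3 <- as_kernel_bank(list(inst$bank$kernels[[1L]], zero))
  fit3 <- scuba_fit(bank3, inst$sets, 0.5)
  expect_equal(fit3$eta, c(1, 0))

  # general instance: nonnegative, sums to one
  inst4 <- random_instance(5, 15, R = 4L, seed = 13)
  fit4 <- scuba_fit(inst4$bank, inst4$sets, 0.3)
  expect_true(all(fit4$eta >= 0))
  expect_equal(sum(fit4$eta), 1, tolerance = 1e-8)

  # all-zero bank falls back to uniform with a warning
  bank0 <- as_kernel_bank(list(zero, zero))
  expect_warning(fit0 <- scuba_fit(bank0, inst$sets, 0.5), "uniform")
  expect_equal(fit0$eta, c(0.5, 0.5))
})

test_that("full-kernel weight formula agrees with the block shortcut", {
  inst <- random_instance(5, 12, R = 3L, seed = 17)
  fit <- scuba_fit(inst$bank, inst$sets, 0.4)
  eta_full <- compute_kernel_weights(
    list(gamma_pos = fit$gamma_pos, gamma_neg = fit$gamma_neg),
    inst$sets, inst$bank)
  blocks <- scuba_blocks(inst$bank, inst$sets)
  eta_blocks <- scuba:::weights_from_blocks(blocks, fit$gamma_pos)
  expect_equal(eta_full, eta_blocks, tolerance = 1e-10)
})

test_that("combine_kernels is exact linear algebra on sub-blocks", {
  genes <- sprintf("g%02d", 1:8)
  K1 <- random_psd_kernel(genes, seed = 1)
  K2 <- random_psd_kernel(genes, seed = 2)
  bank <- as_kernel_bank(list(K1, K2))

  expect_equal(combine_kernels(bank, c(1, 0)), K1, ignore_attr = TRUE)
  expect_equal(combine_kernels(bank, c(0.3, 0.7), genes[1:3], genes[4:8]),
               0.3 * K1[1:3, 4:8] + 0.7 * K2[1:3, 4:8],
               tolerance = 1e-12, ignore_attr = TRUE)
  bank_same <- as_kernel_bank(list(K1, K1))
  expect_equal(combine_kernels(bank_same, c(0.4, 0.6)), K1,
               ignore_attr = TRUE)
  expect_error(combine_kernels(bank, c(1, 0), rows = "nope"), "nope")
})

test_that("scoring implements the weighted similarity contrast", {
  sets <- labeled_gene_sets("p1", "u1")
  fit <- structure(list(gamma_pos = 1, gamma_neg = 1, sets = sets,
                        eta = 1), class = "scuba_fit")
  expect_equal(scuba_score(fit, matrix(c(0.8, 0.2), 1)), 0.6)
  expect_equal(scuba_score(fit, matrix(0, 2, 2)), c(0, 0))
  expect_error(scuba_score(fit, matrix(0, 1, 3)), "m \\+ n")

  # uniform gamma: score = mean similarity to P minus mean similarity to U
  inst <- random_instance(4, 9, R = 1L, seed = 23)
  fitu <- scuba_fit(inst$bank, inst$sets, Inf)
  K <- inst$bank$kernels[[1L]]
  test_rows <- K[6:8, c(inst$sets$positives, inst$sets$unlabelled)]
  expect_equal(scuba_score(fitu, test_rows),
               rowMeans(K[6:8, inst$sets$positives]) -
                 rowMeans(K[6:8, inst$sets$unlabelled]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("two-stage fit collapses correctly for redundant banks", {
  inst <- random_instance(5, 14, R = 1L, seed = 31)
  fit1 <- scuba_fit(inst$bank, inst$sets, 0.3)
  # stage 3 on a single kernel re-solves the stage-1 problem
  expect_equal(fit1$gamma_pos, fit1$stage1$gamma_pos)

  bankR <- as_kernel_bank(rep(inst$bank$kernels, 3L))
  fitR <- scuba_fit(bankR, inst$sets, 0.3)
  expect_equal(fitR$gamma_pos, fit1$gamma_pos, tolerance = 1e-8)
  expect_equal(fitR$eta, rep(1 / 3, 3), tolerance = 1e-8)
})

test_that("large lambda drives gamma to uniform monotonically", {
  inst <- random_instance(6, 20, R = 2L, seed = 41)
  u <- rep(1 / 6, 6)
  dist <- vapply(c(1e2, 1e4, 1e6), function(lam)
    sum(abs(scuba_fit(inst$bank, inst$sets, lam)$gamma_pos - u)),
    numeric(1))
  expect_true(all(diff(dist) <= 1e-12))
  expect_lt(dist[3], 1e-4)
})

test_that("rescaling all kernels by a common constant leaves eta and ranking alone", {
  inst <- random_instance(5, 25, R = 3L, seed = 51)
  fit <- scuba_fit(inst$bank, inst$sets, 0.2)
  bank_s <- as_kernel_bank(lapply(inst$bank$kernels, function(K) {
    Ks <- 7.5 * K; dimnames(Ks) <- dimnames(K); Ks
  }))
  # lambda must scale with the kernels for the optimizer to be equivalent
  fit_s <- scuba_fit(bank_s, inst$sets, 0.2 * 7.5)
  expect_equal(fit_s$eta, fit$eta, tolerance = 1e-6)
  s <- score_with_bank(fit, inst$bank, inst$sets$unlabelled)
  s_s <- score_with_bank(fit_s, bank_s, inst$sets$unlabelled)
  expect_equal(order(-s_s), order(-s))

  # at lambda = 0 the optimizer itself is scale-invariant
  f0 <- scuba_fit(inst$bank, inst$sets, 0)
  f0s <- scuba_fit(bank_s, inst$sets, 0)
  expect_equal(f0s$eta, f0$eta, tolerance = 1e-5)
  expect_equal(order(-score_with_bank(f0s, bank_s, inst$sets$unlabelled)),
               order(-score_with_bank(f0, inst$bank, inst$sets$unlabelled)))
})
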