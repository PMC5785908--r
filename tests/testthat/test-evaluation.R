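test_that("decision_score counts strictly outranked candidates", {
  expect_equal(decision_score(100, 1:99), 1)
  expect_equal(decision_score(0, 1:10), 0)
  expect_equal(decision_score(0.5, c(0.5, 0.4, 0.6)), 1 / 3)
  expect_error(decision_score(1, numeric(0)), "empty")
})

test_that("disease classes are filtered by minimum size", {
  cls <- list(a = letters[1:5], b = letters[1:2], c = letters[1:3])
  expect_named(filter_disease_classes(cls, 3), c("a", "c"))
})

# toy universe: the disease-class clique is disconnected from all else;
# out-of-class disease genes are linked to the non-disease pool so that
# every held-out gene strictly outranks every non-disease candidate
make_loocv_toy <- function() {
  class_genes <- c("c1", "c2", "c3", "c4")
  out_disease <- c("d1", "d2")
  non_disease <- c("x1", "x2", "x3")
  edges <- rbind(
    t(combn(class_genes, 2)),
    as.matrix(expand.grid(out_disease, non_disease, stringsAsFactors = FALSE)))
  net <- gene_network(data.frame(from = edges[, 1L], to = edges[, 2L]),
                      genes = c(class_genes, out_disease, non_disease))
  list(net = net, class_genes = class_genes, out_disease = out_disease,
       non_disease = non_disease)
}

test_that("LOOCV protocol separates a disconnected clique perfectly", {
  toy <- make_loocv_toy()
  bank <- kernel_bank(list(toy$net), kernels = list(medk = 0.04))
  rep <- loocv_protocol(bank, classes = list(cls = toy$class_genes),
                        disease_genes = c(toy$class_genes, toy$out_disease),
                        non_disease_genes = toy$non_disease,
                        lambda_pos = 1, seed = 2)
  expect_equal(rep$scores$decision_score,
               rep(1, nrow(rep$scores)))
  expect_equal(rep$auc, 1)

  rep2 <- loocv_protocol(bank, classes = list(cls = toy$class_genes),
                         disease_genes = c(toy$class_genes, toy$out_disease),
                         non_disease_genes = toy$non_disease,
                         lambda_pos = 1, seed = 2)
  expect_identical(rep, rep2)  # pure function of (data, seed)

  expect_error(
    loocv_protocol(bank, classes = list(cls = toy$class_genes),
                   disease_genes = toy$class_genes,
                   non_disease_genes = toy$non_disease),
    "out-of-class")
})

test_that("pooled AUC equals the mean decision score (pairwise oracle)", {
  # one fitted model, common candidate pool: the ROC area over the pooled
  # held-out/candidate score lists must equal the mean decision score
  sim <- simulate_planted_network(60, 10, 0.8, 0.05, seed = 19)
  sp <- split_positives(sim$module, 6, seed = 4)
  m <- scuba(sim$network, positives = sp$positives, lambda = 0.5)
  held <- predict(m, sp$hidden)
  pool <- predict(m, setdiff(sim$network$genes,
                             c(sim$module, sp$positives)))
  ds <- vapply(held, decision_score, numeric(1),
               candidate_scores = pool)
  expect_equal(mean(ds), pairwise_auc(held, pool), tolerance = 1e-9)
  # and the package's ROC route agrees when scores are tie-free
  expect_equal(scuba:::auc_scores(held, pool), mean(ds), tolerance = 1e-9)
})

test_that("rank_metrics computes TPRs, moments and the pairwise-oracle AUC", {
  r <- rank_metrics(c(0.02, 0.20, 0.50))
  expect_equal(unname(r$tpr), c(1 / 3, 1 / 3, 2 / 3))

  r2 <- rank_metrics(rep(0.4, 5))
  expect_equal(r2$median, 0.4)
  expect_equal(r2$mean, 0.4)
  expect_equal(r2$sd, 0)

  # one test gene at rank 1 of n: AUC against the other n-1 candidates
  for (n in c(10, 100)) {
    r3 <- rank_metrics(1 / n, n_ranked = n)
    expect_equal(r3$auc, (n - 1) / (n - 1))
  }
  # rank 3 of 10: oracle = fraction of other 9 candidates outranked
  expect_equal(rank_metrics(3 / 10, n_ranked = 10)$auc, 7 / 9)
  expect_error(rank_metrics(c(0.5, 1.2)), "\\(0, 1\\]")

  # TPR is non-decreasing in the threshold
  set.seed(33)
  q <- runif(50)
  tpr <- rank_metrics(q)$tpr
  expect_true(all(diff(tpr) >= 0))
})

test_that("Hanley-McNeil statistic matches hand-worked arithmetic", {
  expect_equal(hanley_mcneil(0.7, 0.7, 10, 20), list(
    z = 0, p = 1, se1 = hanley_mcneil(0.7, 0.7, 10, 20)$se1,
    se2 = hanley_mcneil(0.7, 0.7, 10, 20)$se2))

  # A = 0.5, n_pos = n_neg = 10: Q1 = Q2 = 1/3, SE^2 = 0.0175
  h <- hanley_mcneil(0.5, 0.8, 10, 10)
  expect_equal(h$se1^2, 0.0175, tolerance = 1e-12)
  expect_equal(h$se1, sqrt(0.0175), tolerance = 1e-12)

  h12 <- hanley_mcneil(0.9, 0.6, 15, 40)
  h21 <- hanley_mcneil(0.6, 0.9, 15, 40)
  expect_equal(h12$p, h21$p)
  expect_equal(h12$z, -h21$z)
  expect_error(hanley_mcneil(1.1, 0.5, 10, 10), "\\[0, 1\\]")
  expect_error(hanley_mcneil(0.5, 0.6, 1, 10), ">= 2")
})

test_that("paired signed-rank comparison uses the exact null when possible", {
  a <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
  expect_warning(p_same <- paired_rank_test(a, a), "zero")
  expect_equal(p_same, 1)

  # constant one-sided shift, n = 10: smallest attainable two-sided exact p
  p_shift <- paired_rank_test(a, a + 1)
  expect_equal(p_shift, 2 / 2^10, tolerance = 1e-12)

  b <- a + c(0.5, -0.21, 0.13, 0.4, -0.11, 0.7, 0.21, -0.33, 0.6, 0.12)
  expect_equal(paired_rank_test(a, b), paired_rank_test(b, a))
  # untied differences: exact permutation p agrees with the reference
  # exact signed-rank distribution
  expect_equal(paired_rank_test(a, b),
               unname(stats::wilcox.test(a - b, exact = TRUE)$p.value),
               tolerance = 1e-12)
  expect_error(paired_rank_test(a, a[-1]), "equal length")
  expect_error(paired_rank_test(a[1:3], a[1:3]), "at least 5")
})
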