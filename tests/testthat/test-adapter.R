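named_adj <- function(q, ids = paste0("E", seq_len(q)), p = 0.5) {
  A <- random_sym_adj(q, p)
  dimnames(A) <- list(ids, ids)
  A
}

test_that("subnetwork filtering extracts exact submatrices", {
  set.seed(51)
  A <- named_adj(6)
  expect_equal(filter_subnetwork(A, rownames(A)), A)
  expect_equal(dim(filter_subnetwork(A, "E3")), c(1L, 1L))
  sub <- c("E1", "E4", "E5")
  F_ <- filter_subnetwork(A, sub)
  # edges of the filtered matrix = global edges with both endpoints inside
  for (a in sub) for (b in sub) expect_equal(F_[a, b], A[a, b])
  expect_equal(sum(F_), sum(A[sub, sub]))
  expect_error(filter_subnetwork(A, "E9"), "E9")
})

test_that("cdf reweighting reduces to w^2 when the distributions match", {
  w <- c(0.2, 0.4, 0.5, 0.7, 0.9)
  expect_equal(cdf_reweight(w, w), w^2)
  # single edge: the quantile of anything is that weight
  expect_equal(cdf_reweight(0.3, c(0.1, 0.3, 0.8)), 0.3 * 0.3)
})

test_that("cdf reweighting preserves rank order and duplication invariance", {
  set.seed(52)
  for (rep in 1:5) {
    wd <- runif(12); wg <- runif(40)
    out <- cdf_reweight(wd, wg)
    expect_equal(order(out), order(wd))
    expect_equal(cdf_reweight(c(wd, wd), wg), rep(out, 2))
  }
  expect_warning(out <- cdf_reweight(c(0.2, 0.4), rep(0.5, 4)), "constant")
  expect_equal(out, c(0.2, 0.4))
})

test_that("adapted adjacency is the weighted elementwise combination", {
  A <- random_sym_adj(4); W <- matrix(runif(16), 4, 4)
  expect_equal(adapt_adjacency(list(list(A = A, W = NULL)), 1), A)
  expect_equal(adapt_adjacency(list(list(A = A, W = W)), 0), matrix(0, 4, 4))
  B <- random_sym_adj(4); W2 <- matrix(runif(16), 4, 4)
  out <- adapt_adjacency(list(list(A = A, W = W), list(A = B, W = W2)),
                         c(0.3, 1.7))
  expect_equal(out, 0.3 * (W * A) + 1.7 * (W2 * B))
  expect_error(adapt_adjacency(list(list(A = A), list(A = matrix(0, 3, 3))),
                               c(1, 1)), "differ")
})

test_that("alpha coefficients are edge-count proportions", {
  A1 <- matrix(0, 4, 4); A1[1, 2] <- A1[2, 1] <- 1
  A2 <- matrix(1, 4, 4) - diag(4)
  counts <- c(sum(A1 != 0), sum(A2 != 0))
  expect_equal(alpha_coefficients(list(A1, A2)), counts / sum(counts))
  expect_equal(alpha_coefficients(list(A2)), 1)
  expect_equal(sum(alpha_coefficients(list(A1, A2, A2))), 1)
  expect_equal(alpha_coefficients(list(matrix(0, 2, 2), diag(2))), c(0, 1))
  expect_error(alpha_coefficients(list(matrix(0, 2, 2))), "no edges")
})

test_that("the adaptation regularizer is a weighted Frobenius distance", {
  G <- named_adj(4)
  expect_equal(adaptation_regularizer(list(G), list(G), 1), 0)
  A <- matrix(1, 2, 2); Z <- matrix(0, 2, 2)
  expect_equal(adaptation_regularizer(list(A), list(Z), 1), 4)
  expect_equal(adaptation_regularizer(list(A), list(Z), 0.5), 2)
  # dataset matrices are zero-padded onto the global index
  sub <- filter_subnetwork(G, c("E1", "E2"))
  r <- adaptation_regularizer(list(sub), list(G), 1)
  pad <- matrix(0, 4, 4, dimnames = dimnames(G))
  pad[1:2, 1:2] <- sub
  expect_equal(r, sum((pad - G)^2))
})

test_that("meta-learning down-weights a pure-noise network", {
  # planted objective: validation loss rises with weight on network 2
  objective <- function(lam) (lam[1] - 1)^2 + 2 * lam[2]^2 + 0.1 * lam[2]
  res <- learn_combination_weights(2, objective)
  expect_true(all(res$lambda >= 0))
  expect_lt(res$lambda[2], res$lambda[1])
  expect_lt(res$lambda[2], 0.1)
  # deterministic: same inputs, same trajectory
  res2 <- learn_combination_weights(2, objective)
  expect_identical(res$lambda, res2$lambda)
  # single network type short-circuits to weight 1
  expect_equal(learn_combination_weights(1, function(l) sum(l))$lambda, 1)
})

test_that("zero adaptation weight recovers the unadapted objective", {
  # gamma_reg = 0 and uniform lambda: the adapted graph equals the plain
  # aggregate, so the training objective is unchanged end-to-end
  A1 <- random_sym_adj(5); A2 <- random_sym_adj(5)
  lam <- c(0.5, 0.5)
  adapted <- adapt_adjacency(list(list(A = A1), list(A = A2)), lam)
  plain <- aggregate_edge_types(list(A1, A2), lam)
  expect_equal(adapted, plain)
  cfg <- dti_config(gamma_reg = 0, seed = 1)
  expect_equal(cfg$gamma_reg, 0)
})
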