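test_that("dissimilarities follow the max-similarity convention", {
  fa <- fingerprint(1:8, 64)
  expect_equal(chem_dissim(fa, list(fa)), 0)
  expect_equal(chem_dissim(fa, list()), 1)
  # dissimilarity is one minus the best binder similarity
  b1 <- fingerprint(c(1:3, 20:26), 64)   # |int|=3, |uni|=15 -> 0.2
  expect_equal(tanimoto(fa, b1), 0.2)
  binders <- list(b1, fingerprint(c(1:7, 9:11), 64))
  sims <- vapply(binders, function(b) tanimoto(fa, b), numeric(1))
  expect_equal(chem_dissim(fa, binders), 1 - max(sims))

  expect_equal(seq_dissim("MKVLA", c("MKVLA", "ACDEF")), 0)
  expect_equal(seq_dissim("MKVLA", character(0)), 1)
})

test_that("reliability is the alpha/beta mixture of the dissimilarities", {
  cfg <- sampler_config(alpha = 0.5, beta = 0.5)
  expect_equal(reliability_score(1, 1, cfg), 1)
  expect_equal(reliability_score(0, 0, cfg), 0)
  expect_equal(reliability_score(0.5, 1.0, sampler_config(alpha = 0.7, beta = 0.3)),
               0.65)
})

test_that("importance weights are a softmax with the stated limits", {
  expect_equal(importance_weights(c(0.4, 0.4)), c(0.5, 0.5))
  expect_equal(importance_weights(c(0.1, 0.9, 0.5), gamma_temp = 0), rep(1 / 3, 3))
  w <- importance_weights(c(0, 1), gamma_temp = 1)
  expect_equal(w, c(1 / (1 + exp(1)), exp(1) / (1 + exp(1))))
  expect_error(importance_weights(numeric(0)), "empty")
})

test_that("importance weights are monotone and sharpen with temperature", {
  set.seed(6)
  for (rep in 1:5) {
    r <- runif(8)
    w <- importance_weights(r, gamma_temp = 2)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(order(w), order(r))
    w_hot <- importance_weights(r, gamma_temp = 5)
    i <- which.max(r); j <- which.min(r)
    expect_gt(w_hot[i] / w_hot[j], w[i] / w[j])
  }
})

test_that("the weighted interaction loss has its closed forms and limits", {
  expect_equal(weighted_interaction_loss(0), log(2))
  expect_equal(weighted_interaction_loss(numeric(0), 0, 1), log(2))
  expect_lt(weighted_interaction_loss(rep(50, 3), rep(-50, 2), c(0.5, 0.5)), 1e-10)
  expect_gte(weighted_interaction_loss(rnorm(5), rnorm(3), rep(1 / 3, 3)), 0)
})

test_that("refinement keeps exactly the threshold-qualifying unlabeled pairs", {
  probs <- matrix(c(0.1, 0.9, 0.2, 0.8), 2, 2)
  rel <- matrix(c(0.9, 0.9, NA, 0.3), 2, 2)  # (1,2) is a known positive
  prev <- initial_negatives(rel, n_positives = 1, sampler_config(ratio = 1))
  out <- refine_negatives(probs, rel, prev, sampler_config())
  expect_equal(out$pairs, cbind(drug = 1L, target = 1L), ignore_attr = TRUE)
  expect_equal(out$generation, prev$generation + 1L)
  expect_equal(sum(out$weight), 1)
  # positives (NA reliability) can never be selected
  expect_true(all(!is.na(rel[out$pairs])))
  # all above the prediction threshold -> fallback with warning
  expect_warning(out2 <- refine_negatives(probs * 0 + 0.99, rel, prev,
                                          sampler_config()),
                 "keeping previous")
  expect_equal(out2$pairs, prev$pairs)
})

test_that("initial negatives rank by reliability and respect the ratio", {
  set.seed(8)
  rel <- matrix(runif(30), 5, 6)
  rel[cbind(1:3, 1:3)] <- NA  # positives
  ns <- initial_negatives(rel, n_positives = 4, sampler_config(ratio = 2))
  expect_equal(nrow(ns$pairs), 8)
  kept <- rel[ns$pairs]
  dropped <- setdiff(rel[!is.na(rel)], kept)
  expect_gte(min(kept), max(dropped))
  expect_equal(sum(ns$weight), 1, tolerance = 1e-12)
  # random arm: uniform weights, deterministic under a seed
  r1 <- initial_negatives(rel, 4, sampler_config(ratio = 2), random = TRUE, seed = 3)
  r2 <- initial_negatives(rel, 4, sampler_config(ratio = 2), random = TRUE, seed = 3)
  expect_identical(r1$pairs, r2$pairs)
  expect_true(all(r1$weight == r1$weight[1]))
})

test_that("planted negatives are more reliable than masked positives", {
  ds <- std_dataset()
  pos <- which(ds$Y == 1L, arr.ind = TRUE)
  set.seed(9)
  masked <- pos[sample(nrow(pos), 40), , drop = FALSE]
  Y_train <- ds$Y
  Y_train[masked] <- 0L
  rel <- reliability_matrix(ds$sim_D, ds$sim_T, Y_train, sampler_config())
  true_neg <- which(ds$Y_clean == 0L & ds$Y == 0L)
  expect_gt(mean(rel[true_neg], na.rm = TRUE), mean(rel[masked]))
})
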