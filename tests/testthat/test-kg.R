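kg_params <- function(h = 4, relations = c("is_a", "member_of"), seed = 1) {
  init_encoder_params(2, 2, h = h, L = 1, relations = relations,
                      n_free = 3, seed = seed)
}

test_that("the bilinear-diagonal score has its closed forms", {
  p <- kg_params(h = 3)
  p$kg$rel["is_a", ] <- c(1, 1, 1)
  e1 <- c(1, 0, 0)
  expect_equal(score_triple(e1, "is_a", e1, p), 1)
  expect_equal(score_triple(e1, "is_a", c(0, 1, 0), p), 0)
  p$kg$rel["is_a", ] <- c(3, 1, 0)
  expect_equal(score_triple(c(1, 2, 0), "is_a", c(1, 1, 0), p), 5)
  expect_error(score_triple(e1, "bogus", e1, p), "unknown relation")
})

test_that("the score is bilinear in the head embedding", {
  set.seed(21)
  p <- kg_params(h = 5)
  zh <- rnorm(5); zt <- rnorm(5)
  s <- score_triple(zh, "is_a", zt, p)
  for (c_ in c(-2, 0.5, 3)) {
    expect_equal(score_triple(c_ * zh, "is_a", zt, p), c_ * s)
  }
})

test_that("the translational score is available behind the flag", {
  p <- kg_params(h = 3)
  p$kg$rel_vec["is_a", ] <- c(1, 0, 0)
  expect_equal(score_triple(c(0, 0, 0), "is_a", c(1, 0, 0), p,
                            kg_score = "transe"), 0)
  expect_equal(score_triple(c(0, 0, 0), "is_a", c(0, 0, 0), p,
                            kg_score = "transe"), -1)
})

test_that("corruption sampling is filtered, non-identical and seeded", {
  triples <- data.frame(head = "A", relation = "r", tail = "B")
  pool <- c("A", "B")
  # the only non-true triples replace one side with the other entity
  out <- corrupt_triples(triples, pool, k = 1, seed = 4)
  expect_true(out$head == "B" || out$tail == "A")
  expect_false(paste(out$head, out$relation, out$tail) == "A r B")
  set.seed(99)  # corruption draws must not depend on ambient RNG state
  out2 <- corrupt_triples(triples, pool, k = 1, seed = 4)
  expect_identical(out, out2)
  # pool exhausted: every candidate collides with a known triple
  known <- data.frame(head = c("A", "B"), relation = "r", tail = c("B", "B"))
  expect_error(corrupt_triples(data.frame(head = "A", relation = "r", tail = "B"),
                               c("A", "B"), k = 1, known_triples = rbind(
                                 known, data.frame(head = "A", relation = "r", tail = "A")),
                               seed = 1),
               "exhausted")
})

test_that("the margin ranking loss is a hinge over triple pairs", {
  expect_equal(kg_ranking_loss(c(5, 4), c(0, 1), c(1, 2), margin = 1), 0)
  expect_equal(kg_ranking_loss(0, 0, 1, margin = 1), 1)
  # non-increasing as the true score rises
  l1 <- kg_ranking_loss(0.2, 0.5, 1, margin = 1)
  l2 <- kg_ranking_loss(0.8, 0.5, 1, margin = 1)
  expect_lte(l2, l1)
})

test_that("hinge gradients vanish for satisfied margins", {
  set.seed(22)
  h <- 3
  Z <- matrix(rnorm(9), 3, h)
  rel <- matrix(rnorm(3), 1, h)
  triples <- cbind(h = 1L, r = 1L, t = 2L)
  corr <- cbind(h = 3L, r = 1L, t = 2L)
  f <- function(tr) sum(Z[tr[1], ] * rel[1, ] * Z[tr[2], ])
  # scale Z so the margin is comfortably satisfied
  Z[1, ] <- Z[2, ] * 10
  if (f(c(1, 2)) - f(c(3, 2)) < 2) Z[1, ] <- -Z[1, ]
  res <- heterodti:::kg_loss_and_grad(Z, rel, triples, corr, 1L, margin = 1)
  expect_equal(res$loss, 0)
  expect_true(all(res$G_Z == 0))
  expect_true(all(res$G_rel == 0))
})

test_that("the combined objective trades off its two terms", {
  expect_equal(combined_loss(2, 5, 0), 2)
  expect_equal(combined_loss(2, 5, 0.1), 2.5)
  expect_gte(combined_loss(1, 3, 0.7), 1)
})

test_that("KG training pulls co-related entities together", {
  # free entities only: members of two ontology groups plus the group terms
  set.seed(23)
  h <- 6
  n_members <- 6
  ents <- c(paste0("M", 1:n_members), "G1", "G2")
  group <- rep(c(1, 2), each = 3)
  triples <- cbind(h = seq_len(n_members), r = 1L,
                   t = n_members + group)
  E <- matrix(rnorm(length(ents) * h, sd = 0.5), length(ents), h)
  rel <- matrix(1, 1, h)
  known <- paste(triples[, 1], triples[, 2], triples[, 3])
  for (step in 1:300) {
    cs <- heterodti:::sample_corruptions_idx(triples, length(ents), known, 1L)
    g <- heterodti:::kg_loss_and_grad(E, rel, triples, cs$corr, cs$source,
                                      margin = 1)
    E <- E - 0.05 * g$G_Z
  }
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  within <- c(); between <- c()
  for (i in 1:(n_members - 1)) for (j in (i + 1):n_members) {
    cc <- cosine(E[i, ], E[j, ])
    if (group[i] == group[j]) within <- c(within, cc) else between <- c(between, cc)
  }
  expect_gt(mean(within), mean(between))
})
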