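make_params <- function(d, t, h = 4, L = 2, seed = 1, relations = character(0),
                        n_free = 0) {
  init_encoder_params(d, t, h = h, L = L, relations = relations,
                      n_free = n_free, seed = seed)
}

test_that("zeroed attention MLPs give alpha 0.5 on supported edges only", {
  g <- random_graph(4, 3)
  params <- make_params(5, 6)
  for (bl in c("DD", "TT", "DT", "TD")) {
    params$attn[[bl]] <- lapply(params$attn[[bl]], function(x) x * 0)
  }
  state <- list(Z_D = matrix(rnorm(16), 4, 4), Z_T = matrix(rnorm(12), 3, 4))
  for (bl in c("DD", "TT", "DT", "TD")) {
    a <- attention_scores(state, g, params, bl)
    expect_length(a, nrow(g$edges[[bl]]))
    if (length(a)) expect_true(all(a == 0.5))
  }
})

test_that("attention values are per-edge and follow node relabeling", {
  set.seed(11)
  g <- random_graph(5, 4)
  params <- make_params(3, 3)
  Z_D <- matrix(rnorm(20), 5, 4); Z_T <- matrix(rnorm(16), 4, 4)
  a <- attention_scores(list(Z_D = Z_D, Z_T = Z_T), g, params, "DD")
  # permute drugs; the per-edge values must be unchanged under the relabeling
  perm <- sample(5)
  A_DD_p <- g$A$DD[perm, perm]
  g_p <- assemble_unified(A_DD_p, g$A$TT, g$A$DT[perm, , drop = FALSE])
  a_p <- attention_scores(list(Z_D = Z_D[perm, , drop = FALSE], Z_T = Z_T),
                          g_p, params, "DD")
  inv <- order(perm)
  key <- function(e) paste(e[, 1], e[, 2])
  m1 <- setNames(a, key(g$edges$DD))
  e_p <- g_p$edges$DD
  back <- cbind(perm[e_p[, 1]], perm[e_p[, 2]])
  expect_equal(unname(m1[key(back)]), unname(a_p))
})

test_that("conv_layer matches the per-node aggregation oracle", {
  set.seed(12)
  for (rep in 1:5) {
    m <- sample(2:5, 1); n <- sample(2:5, 1); h <- 3
    g <- random_graph(m, n)
    params <- make_params(2, 2, h = h, L = 1, seed = rep)
    state <- list(Z_D = matrix(rnorm(m * h), m, h),
                  Z_T = matrix(rnorm(n * h), n, h))
    out <- conv_layer(state, g, params, layer = 1, use_attention = FALSE)
    orc <- conv_oracle(state$Z_D, state$Z_T, g, params$layers[[1]])
    expect_lt(max(abs(out$Z_D - orc$Z_D)), 1e-6)
    expect_lt(max(abs(out$Z_T - orc$Z_T)), 1e-6)
  }
})

test_that("an isolated node reduces to the rectified bias", {
  A_DD <- matrix(0, 2, 2)   # drugs isolated
  g <- assemble_unified(A_DD, random_sym_adj(3), matrix(0, 2, 3))
  params <- make_params(2, 2, h = 3, L = 1)
  params$layers[[1]]$b_D <- c(-1, 0.5, 2)
  state <- list(Z_D = matrix(rnorm(6), 2, 3), Z_T = matrix(rnorm(9), 3, 3))
  out <- conv_layer(state, g, params, 1)
  expect_equal(out$Z_D, matrix(rep(c(0, 0.5, 2), each = 2), 2, 3))
})

test_that("constant attention cancels under renormalization", {
  set.seed(13)
  g <- random_graph(4, 4)
  params <- make_params(2, 2, h = 3, L = 1)
  # force the attention MLP to output a constant c = sigmoid(b2) on all edges
  for (bl in c("DD", "TT", "DT", "TD")) {
    params$attn[[bl]]$W1 <- params$attn[[bl]]$W1 * 0
    params$attn[[bl]]$w2 <- params$attn[[bl]]$w2 * 0
    params$attn[[bl]]$b2 <- 0.7
  }
  state <- list(Z_D = matrix(rnorm(12), 4, 3), Z_T = matrix(rnorm(12), 4, 3))
  with_attn <- conv_layer(state, g, params, 1, use_attention = TRUE,
                          renormalize = TRUE)
  without <- conv_layer(state, g, params, 1, use_attention = FALSE)
  expect_equal(with_attn$Z_D, without$Z_D, tolerance = 1e-12)
  expect_equal(with_attn$Z_T, without$Z_T, tolerance = 1e-12)
})

test_that("encode composes projections and layers deterministically", {
  set.seed(14)
  m <- 5; n <- 4; d <- 6; t <- 7; h <- 4
  g <- random_graph(m, n)
  X_D <- matrix(rnorm(m * d), m, d); X_T <- matrix(rnorm(n * t), n, t)
  params <- make_params(d, t, h = h, L = 1)
  st <- encode(X_D, X_T, g, params, use_attention = FALSE)
  expect_equal(dim(st$Z_D), c(m, h))
  expect_equal(dim(st$Z_T), c(n, h))
  # L = 1: equals one linear-activation conv_layer on the projected features
  # (the final layer of the encoder is linear)
  manual <- conv_layer(list(Z_D = X_D %*% params$P_D, Z_T = X_T %*% params$P_T),
                       g, params, 1, use_attention = FALSE,
                       activation = "identity")
  expect_equal(st$Z_D, manual$Z_D)
  expect_equal(st$Z_T, manual$Z_T)
  expect_identical(st, encode(X_D, X_T, g, params, use_attention = FALSE))
})

test_that("structurally identical twin drugs receive identical embeddings", {
  # drugs 1 and 2: same features, same neighbors, no edge between them
  A_DD <- matrix(0, 3, 3); A_DD[1, 3] <- A_DD[3, 1] <- 1
  A_DD[2, 3] <- A_DD[3, 2] <- 1
  A_TT <- random_sym_adj(3)
  Y <- matrix(0, 3, 3); Y[1, 1] <- Y[2, 1] <- 1
  g <- assemble_unified(A_DD, A_TT, Y)
  X_D <- rbind(c(1, 2), c(1, 2), c(3, 4))
  X_T <- matrix(rnorm(6), 3, 2)
  params <- make_params(2, 2, h = 4, L = 2, seed = 5)
  st <- encode(X_D, X_T, g, params, use_attention = TRUE)
  expect_equal(st$Z_D[1, ], st$Z_D[2, ], tolerance = 1e-12)
})

test_that("reconstruction loss has its closed forms", {
  set.seed(15)
  m <- 3; n <- 2; d <- 4; t <- 5; h <- 3
  X_D <- matrix(rnorm(m * d), m, d); X_T <- matrix(rnorm(n * t), n, t)
  params <- make_params(d, t, h = h, L = 1)
  state <- list(Z_D = matrix(rnorm(m * h), m, h), Z_T = matrix(rnorm(n * h), n, h))
  # zero decoders -> sum of squared feature norms
  p0 <- params
  p0$dec_D <- lapply(p0$dec_D, function(x) x * 0)
  p0$dec_T <- lapply(p0$dec_T, function(x) x * 0)
  expect_equal(reconstruction_loss(state, X_D, X_T, p0),
               sum(X_D^2) + sum(X_T^2))
  # decoders that reproduce the features exactly -> zero
  pid <- p0
  pid$dec_D$b2 <- X_D[1, ]; pid$dec_T$b2 <- X_T[1, ]
  one_D <- matrix(rep(X_D[1, ], each = m), m, d)
  one_T <- matrix(rep(X_T[1, ], each = n), n, t)
  expect_equal(reconstruction_loss(state, one_D, one_T, pid), 0)
})

test_that("analytic gradients match central finite differences", {
  set.seed(16)
  m <- 4; n <- 3; d <- 4; t <- 5; h <- 3; L <- 2
  X_D <- matrix(rnorm(m * d), m, d); X_T <- matrix(rnorm(n * t), n, t)
  g <- random_graph(m, n)
  params <- make_params(d, t, h = h, L = L, seed = 2)
  # keep pre-activations off the rectifier kinks
  for (l in 1:L) {
    params$layers[[l]]$b_D <- runif(h, 0.05, 0.2)
    params$layers[[l]]$b_T <- runif(h, 0.05, 0.2)
  }
  params$dec_D$b1 <- runif(h, 0.05, 0.2)
  params$dec_T$b1 <- runif(h, 0.05, 0.2)
  pos <- which(g$A$DT == 1, arr.ind = TRUE)[1:3, , drop = FALSE]
  neg <- which(g$A$DT == 0, arr.ind = TRUE)[1:2, , drop = FALSE]
  w <- c(0.4, 0.6)
  lam <- 0.3
  loss_fn <- function(p) {
    fw <- heterodti:::encode_forward(X_D, X_T, g, p, TRUE, TRUE)
    sc <- function(q) rowSums(fw$Z_D[q[, 1], , drop = FALSE] *
                                fw$Z_T[q[, 2], , drop = FALSE])
    weighted_interaction_loss(sc(pos), sc(neg), w) +
      lam * reconstruction_loss(fw, X_D, X_T, p)
  }
  fw <- heterodti:::encode_forward(X_D, X_T, g, params, TRUE, TRUE)
  ig <- heterodti:::interaction_grad(fw$Z_D, fw$Z_T, pos, neg, w)
  cd <- heterodti:::decoder_forward(fw$Z_D, params$dec_D)
  ct <- heterodti:::decoder_forward(fw$Z_T, params$dec_T)
  bd <- heterodti:::decoder_backward(fw$Z_D, X_D, params$dec_D, cd)
  bt <- heterodti:::decoder_backward(fw$Z_T, X_T, params$dec_T, ct)
  enc <- heterodti:::encoder_backward(fw, g, params,
                                      ig$G_ZD + lam * bd$G_Z,
                                      ig$G_ZT + lam * bt$G_Z)
  grads <- enc
  grads$dec_D <- lapply(bd$grads, function(x) lam * x)
  grads$dec_T <- lapply(bt$grads, function(x) lam * x)
  eps <- 1e-5
  get_path <- function(P, path) { for (nm in path) P <- P[[nm]]; P }
  set_path <- function(P, path, v) {
    if (length(path) == 1) { P[[path[[1]]]] <- v; return(P) }
    P[[path[[1]]]] <- set_path(P[[path[[1]]]], path[-1], v)
    P
  }
  paths <- list(list("P_D"), list("P_T"),
                list("layers", 1, "W_DD"), list("layers", 2, "W_TD"),
                list("layers", 1, "b_T"), list("attn", "DD", "W1"),
                list("attn", "DT", "w2"), list("attn", "TD", "b1"),
                list("dec_D", "W2"), list("dec_T", "b1"))
  for (path in paths) {
    pv <- get_path(params, path)
    gv <- get_path(grads, path)
    for (ii in sample(length(pv), min(3, length(pv)))) {
      vv <- pv; vv[ii] <- vv[ii] + eps
      fu <- loss_fn(set_path(params, path, vv))
      vv <- pv; vv[ii] <- vv[ii] - eps
      fd <- loss_fn(set_path(params, path, vv))
      num <- (fu - fd) / (2 * eps)
      expect_lt(abs(num - gv[ii]) / max(1e-6, abs(num) + abs(gv[ii])), 1e-4,
                label = sprintf("gradient mismatch at %s[%d]",
                                paste(unlist(path), collapse = "$"), ii))
    }
  }
})
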