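# Analytic gradients for the encoder, decoders and attention MLPs, plus a
# minimal Adam optimizer over the nested parameter structure. Verified
# against central finite differences in the test suite.

TRAINABLE <- c("P_D", "P_T", "layers", "attn", "dec_D", "dec_T", "kg")

zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0

zero_grads <- function(params) lapply(params[TRAINABLE], zero_like)

grad_add <- function(a, b) {
  if (is.list(a)) return(Map(grad_add, a, b))
  a + b
}

# backward through the L conv layers and input projections.
# fw: cache from encode_forward; G_ZD/G_ZT: dLoss/dZ at the output.
# returns grads for P_D, P_T, layers, attn.
encoder_backward <- function(fw, graph, params, G_ZD, G_ZT) {
  L <- params$L
  h <- params$h
  g <- zero_grads(params)
  G_HD <- G_ZD
  G_HT <- G_ZT
  for (l in rev(seq_len(L))) {
    lc <- fw$layers[[l]]
    lay <- params$layers[[l]]
    if (isTRUE(lc$linear)) {
      G_SD <- G_HD
      G_ST <- G_HT
    } else {
      G_SD <- G_HD * (lc$S_D > 0)
      G_ST <- G_HT * (lc$S_T > 0)
    }
    HDp <- fw$H_D[[l]]
    HTp <- fw$H_T[[l]]
    M <- lapply(lc$ops, `[[`, "M")
    g$layers[[l]]$W_DD <- crossprod(M$DD %*% HDp, G_SD)
    g$layers[[l]]$W_DT <- crossprod(M$DT %*% HTp, G_SD)
    g$layers[[l]]$b_D <- colSums(G_SD)
    g$layers[[l]]$W_TT <- crossprod(M$TT %*% HTp, G_ST)
    g$layers[[l]]$W_TD <- crossprod(M$TD %*% HDp, G_ST)
    g$layers[[l]]$b_T <- colSums(G_ST)
    nG_HD <- crossprod(M$DD, G_SD %*% t(lay$W_DD)) +
             crossprod(M$TD, G_ST %*% t(lay$W_TD))
    nG_HT <- crossprod(M$TT, G_ST %*% t(lay$W_TT)) +
             crossprod(M$DT, G_SD %*% t(lay$W_DT))
    if (fw$use_attention) {
      G_M <- list(DD = G_SD %*% t(HDp %*% lay$W_DD),
                  DT = G_SD %*% t(HTp %*% lay$W_DT),
                  TT = G_ST %*% t(HTp %*% lay$W_TT),
                  TD = G_ST %*% t(HDp %*% lay$W_TD))
      for (bl in c("DD", "TT", "DT", "TD")) {
        edges <- graph$edges[[bl]]
        if (nrow(edges) == 0L) next
        op <- lc$ops[[bl]]
        ac <- lc$attn[[bl]]
        ap <- params$attn[[bl]]
        gM_e <- G_M[[bl]][edges]
        if (fw$renormalize) {
          M_e <- op$M[edges]
          # d/dB of M = B/s with s the row sum of B over support
          Trow <- rep(0, nrow(op$M))
          agg <- rowsum(gM_e * M_e, group = edges[, 1])
          Trow[as.integer(rownames(agg))] <- agg
          dB <- (gM_e - Trow[edges[, 1]]) / op$s[edges[, 1]]
        } else {
          dB <- gM_e
        }
        dalpha <- dB * op$abar
        g_O <- dalpha * ac$alpha * (1 - ac$alpha)
        g_hid <- outer(g_O, drop(ap$w2))
        g_pre <- g_hid * (ac$pre > 0)
        g$attn[[bl]]$w2 <- g$attn[[bl]]$w2 + crossprod(ac$hid, cbind(g_O))
        g$attn[[bl]]$b2 <- g$attn[[bl]]$b2 + sum(g_O)
        g$attn[[bl]]$W1 <- g$attn[[bl]]$W1 + crossprod(ac$feat, g_pre)
        g$attn[[bl]]$b1 <- g$attn[[bl]]$b1 + colSums(g_pre)
        g_feat <- g_pre %*% t(ap$W1)
        g_recv <- g_feat[, seq_len(h), drop = FALSE]
        g_send <- g_feat[, h + seq_len(h), drop = FALSE]
        if (bl == "DD") {
          nG_HD <- rowsum_add(nG_HD, edges[, 1], g_recv)
          nG_HD <- rowsum_add(nG_HD, edges[, 2], g_send)
        } else if (bl == "TT") {
          nG_HT <- rowsum_add(nG_HT, edges[, 1], g_recv)
          nG_HT <- rowsum_add(nG_HT, edges[, 2], g_send)
        } else if (bl == "DT") {
          nG_HD <- rowsum_add(nG_HD, edges[, 1], g_recv)
          nG_HT <- rowsum_add(nG_HT, edges[, 2], g_send)
        } else {
          nG_HT <- rowsum_add(nG_HT, edges[, 1], g_recv)
          nG_HD <- rowsum_add(nG_HD, edges[, 2], g_send)
        }
      }
    }
    G_HD <- nG_HD
    G_HT <- nG_HT
  }
  g$P_D <- crossprod(fw$X_D, G_HD)
  g$P_T <- crossprod(fw$X_T, G_HT)
  g
}

# decoder backward; returns parameter grads and the gradient wrt Z
decoder_backward <- function(Z, X, dec, cache) {
  G_out <- -2 * (X - cache$out)
  g_W2 <- crossprod(cache$hid, G_out)
  g_b2 <- colSums(G_out)
  G_hid <- G_out %*% t(dec$W2)
  G_pre <- G_hid * (cache$pre > 0)
  g_W1 <- crossprod(Z, G_pre)
  g_b1 <- colSums(G_pre)
  list(grads = list(W1 = g_W1, b1 = g_b1, W2 = g_W2, b2 = g_b2),
       G_Z = G_pre %*% t(dec$W1))
}

# gradient of the weighted interaction loss wrt Z_D and Z_T.
# pos: 2-col matrix (drug, target); neg: 2-col matrix + weights.
# pos_scale re-reduces the positive sum (training uses 1/|P| so the unit-mass
# importance-weighted negative term and the positive term balance).
interaction_grad <- function(Z_D, Z_T, pos, neg, neg_weights, pos_scale = 1) {
  G_ZD <- Z_D * 0
  G_ZT <- Z_T * 0
  loss <- 0
  if (nrow(pos)) {
    s <- rowSums(Z_D[pos[, 1], , drop = FALSE] * Z_T[pos[, 2], , drop = FALSE])
    loss <- loss + pos_scale * sum(log1p(exp(-s)))
    dydot <- -pos_scale * (1 - sigmoid(s))
    G_ZD <- rowsum_add(G_ZD, pos[, 1], dydot * Z_T[pos[, 2], , drop = FALSE])
    G_ZT <- rowsum_add(G_ZT, pos[, 2], dydot * Z_D[pos[, 1], , drop = FALSE])
  }
  if (nrow(neg)) {
    s <- rowSums(Z_D[neg[, 1], , drop = FALSE] * Z_T[neg[, 2], , drop = FALSE])
    loss <- loss + sum(neg_weights * log1p(exp(s)))
    dydot <- neg_weights * sigmoid(s)
    G_ZD <- rowsum_add(G_ZD, neg[, 1], dydot * Z_T[neg[, 2], , drop = FALSE])
    G_ZT <- rowsum_add(G_ZT, neg[, 2], dydot * Z_D[neg[, 1], , drop = FALSE])
  }
  list(loss = loss, G_ZD = G_ZD, G_ZT = G_ZT)
}

adam_init <- function(params) {
  list(m = zero_grads(params), v = zero_grads(params), t = 0L)
}

adam_leaf <- function(p, g, m, v, lr, b1, b2, eps, t, wd) {
  g <- g + wd * p
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

adam_walk <- function(p, g, m, v, lr, b1, b2, eps, t, wd) {
  if (is.list(p)) {
    out <- Map(adam_walk, p, g, m, v,
               MoreArgs = list(lr = lr, b1 = b1, b2 = b2, eps = eps, t = t, wd = wd))
    return(list(p = lapply(out, `[[`, "p"),
                m = lapply(out, `[[`, "m"),
                v = lapply(out, `[[`, "v")))
  }
  adam_leaf(p, g, m, v, lr, b1, b2, eps, t, wd)
}

# one Adam step over the trainable sub-structure of params
adam_step <- function(params, grads, state, lr = 1e-3, weight_decay = 5e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  out <- Map(adam_walk, params[TRAINABLE], grads, state$m, state$v,
             MoreArgs = list(lr = lr, b1 = beta1, b2 = beta2, eps = eps,
                             t = state$t, wd = weight_decay))
  params[TRAINABLE] <- lapply(out, `[[`, "p")
  state$m <- lapply(out, `[[`, "m")
  state$v <- lapply(out, `[[`, "v")
  list(params = params, state = state)
}
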