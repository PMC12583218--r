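# Multi-relational graph-convolutional encoder.
#
# Layer update (drug side; target side symmetric):
#   Z_D <- relu(M_DD Z_D W_DD + M_DT Z_T W_DT + 1 b_D')
# where M is the softmax-normalized block, optionally modulated entrywise by
# a learned per-edge attention weight and re-normalized over the structural
# support. All gradients are computed analytically by the matching backward
# pass in backprop.R and verified against finite differences in the tests.

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize encoder, decoder and knowledge-graph parameters
#'
#' Weight matrices use uniform Glorot initialization in
#' `+-sqrt(6/(fan_in+fan_out))`; biases start at zero. The attention MLP of
#' each block (DD, TT, DT, TD) has one hidden layer of width `h` with a
#' rectifier and a scalar sigmoid output, shared across layers. Relation
#' parameters are the diagonals of the bilinear scorer (one length-`h`
#' vector per relation) plus translation vectors for the alternative
#' translational scorer.
#'
#' @param d,t raw drug / target feature widths.
#' @param h embedding width.
#' @param L number of convolution layers.
#' @param relations character vector of KG relation names (may be empty).
#' @param n_free number of free (non-drug, non-target) KG entities.
#' @param seed integer seed for the initialization sub-stream.
#' @return a nested parameter list (`dti_params`).
#' @export
init_encoder_params <- function(d, t, h = 16L, L = 2L, relations = character(0),
                                n_free = 0L, seed = 1L) {
  stopifnot(h > 0, L >= 1)
  set.seed(substream_seed(seed, "init"))
  layers <- lapply(seq_len(L), function(l)
    list(W_DD = glorot(h, h), W_TT = glorot(h, h),
         W_DT = glorot(h, h), W_TD = glorot(h, h),
         b_D = numeric(h), b_T = numeric(h)))
  attn_block <- function()
    list(W1 = glorot(2L * h, h), b1 = numeric(h), w2 = glorot(h, 1L), b2 = 0)
  n_rel <- length(relations)
  params <- list(
    h = as.integer(h), L = as.integer(L), d = as.integer(d), t = as.integer(t),
    P_D = glorot(d, h), P_T = glorot(t, h),
    layers = layers,
    attn = list(DD = attn_block(), TT = attn_block(),
                DT = attn_block(), TD = attn_block()),
    dec_D = list(W1 = glorot(h, h), b1 = numeric(h),
                 W2 = glorot(h, d), b2 = numeric(d)),
    dec_T = list(W1 = glorot(h, h), b1 = numeric(h),
                 W2 = glorot(h, t), b2 = numeric(t)),
    kg = list(
      rel = if (n_rel) matrix(stats::runif(n_rel * h, -sqrt(6 / (2 * h)),
                                           sqrt(6 / (2 * h))),
                              n_rel, h, dimnames = list(relations, NULL))
            else matrix(0, 0, h),
      rel_vec = if (n_rel) matrix(stats::runif(n_rel * h, -sqrt(6 / (2 * h)),
                                               sqrt(6 / (2 * h))),
                                  n_rel, h, dimnames = list(relations, NULL))
                else matrix(0, 0, h),
      E_free = if (n_free) glorot(n_free, h) else matrix(0, 0, h)))
  class(params) <- "dti_params"
  params
}

# attention MLP forward over the edges of one block; returns per-edge alpha
# in (0,1) plus the intermediates the backward pass needs
attention_forward <- function(H_recv, H_send, ap, edges) {
  if (nrow(edges) == 0L)
    return(list(alpha = numeric(0), feat = NULL, pre = NULL, hid = NULL))
  feat <- cbind(H_recv[edges[, 1], , drop = FALSE],
                H_send[edges[, 2], , drop = FALSE])
  pre <- sweep(feat %*% ap$W1, 2, ap$b1, "+")
  hid <- relu(pre)
  out <- drop(hid %*% ap$w2) + ap$b2
  list(alpha = sigmoid(out), feat = feat, pre = pre, hid = hid)
}

#' Per-edge attention weights of one block
#'
#' Applies the block's attention MLP to the concatenated previous-layer
#' embeddings of the two endpoints of every structural edge and squashes
#' the scalar output through a sigmoid. Values exist only on supported
#' edges; unsupported entries of the message operator stay 0.
#'
#' @param state embedding state: list with `Z_D` (m x h) and `Z_T` (n x h).
#' @param graph a `dti_graph`.
#' @param params a `dti_params`.
#' @param block one of `"DD"`, `"TT"`, `"DT"`, `"TD"`.
#' @return numeric vector of attention weights, one per edge of the block
#'   (ordered as `graph$edges[[block]]`).
#' @export
attention_scores <- function(state, graph, params, block = "DD") {
  block <- match.arg(block, c("DD", "TT", "DT", "TD"))
  HH <- switch(block,
               DD = list(state$Z_D, state$Z_D),
               TT = list(state$Z_T, state$Z_T),
               DT = list(state$Z_D, state$Z_T),
               TD = list(state$Z_T, state$Z_D))
  attention_forward(HH[[1]], HH[[2]], params$attn[[block]],
                    graph$edges[[block]])$alpha
}

# effective message operator of one block: normalized adjacency, optionally
# modulated by attention and re-normalized over support
block_operator <- function(graph, block, alpha = NULL, renormalize = TRUE) {
  M0 <- graph$norm[[block]]
  if (is.null(alpha)) return(list(M = M0))
  edges <- graph$edges[[block]]
  B <- numeric(nrow(edges))
  abar <- M0[edges]
  B <- abar * alpha
  M <- matrix(0, nrow(M0), ncol(M0))
  if (renormalize) {
    s <- rep(0, nrow(M0))
    if (nrow(edges)) {
      agg <- rowsum(B, group = edges[, 1])
      s[as.integer(rownames(agg))] <- agg
      M[edges] <- B / s[edges[, 1]]
    }
    list(M = M, abar = abar, B = B, s = s)
  } else {
    if (nrow(edges)) M[edges] <- B
    list(M = M, abar = abar, B = B, s = NULL)
  }
}

#' One graph-convolution layer
#'
#' Computes the layer update from an embedding state. With attention on, the
#' normalized blocks are modulated entrywise by the per-edge attention
#' weights and (by default) re-normalized over the structural support so the
#' effective operator stays row-stochastic on supported rows.
#'
#' @inheritParams attention_scores
#' @param layer layer index in `1..L`.
#' @param use_attention logical.
#' @param renormalize re-normalize attention-modulated rows (default TRUE).
#' @param activation `"relu"` (default) or `"identity"`; the encoder uses a
#'   linear final layer so embeddings are signed and inner-product scores
#'   span the whole real line.
#' @return the updated state (list `Z_D`, `Z_T`, `layer`).
#' @export
conv_layer <- function(state, graph, params, layer = 1L, use_attention = FALSE,
                       renormalize = TRUE, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (layer > params$L) dti_stop("layer %d exceeds L = %d", layer, params$L)
  lay <- params$layers[[layer]]
  ops <- list()
  for (bl in c("DD", "TT", "DT", "TD")) {
    alpha <- if (use_attention) attention_scores(state, graph, params, bl) else NULL
    ops[[bl]] <- block_operator(graph, bl, alpha, renormalize)
  }
  S_D <- ops$DD$M %*% state$Z_D %*% lay$W_DD +
         ops$DT$M %*% state$Z_T %*% lay$W_DT
  S_D <- sweep(S_D, 2, lay$b_D, "+")
  S_T <- ops$TT$M %*% state$Z_T %*% lay$W_TT +
         ops$TD$M %*% state$Z_D %*% lay$W_TD
  S_T <- sweep(S_T, 2, lay$b_T, "+")
  act <- if (activation == "relu") relu else identity
  list(Z_D = act(S_D), Z_T = act(S_T), layer = layer)
}

# full forward pass with cached intermediates for backprop
encode_forward <- function(X_D, X_T, graph, params, use_attention = TRUE,
                           renormalize = TRUE) {
  H_D <- vector("list", params$L + 1L)
  H_T <- vector("list", params$L + 1L)
  H_D[[1]] <- X_D %*% params$P_D
  H_T[[1]] <- X_T %*% params$P_T
  layer_cache <- vector("list", params$L)
  for (l in seq_len(params$L)) {
    lay <- params$layers[[l]]
    ops <- list(); attn_cache <- list()
    for (bl in c("DD", "TT", "DT", "TD")) {
      if (use_attention) {
        HH <- switch(bl,
                     DD = list(H_D[[l]], H_D[[l]]),
                     TT = list(H_T[[l]], H_T[[l]]),
                     DT = list(H_D[[l]], H_T[[l]]),
                     TD = list(H_T[[l]], H_D[[l]]))
        ac <- attention_forward(HH[[1]], HH[[2]], params$attn[[bl]],
                                graph$edges[[bl]])
        attn_cache[[bl]] <- ac
        ops[[bl]] <- block_operator(graph, bl, ac$alpha, renormalize)
      } else {
        ops[[bl]] <- block_operator(graph, bl)
      }
    }
    S_D <- ops$DD$M %*% H_D[[l]] %*% lay$W_DD +
           ops$DT$M %*% H_T[[l]] %*% lay$W_DT
    S_D <- sweep(S_D, 2, lay$b_D, "+")
    S_T <- ops$TT$M %*% H_T[[l]] %*% lay$W_TT +
           ops$TD$M %*% H_D[[l]] %*% lay$W_TD
    S_T <- sweep(S_T, 2, lay$b_T, "+")
    if (!all(is.finite(S_D)) || !all(is.finite(S_T)))
      dti_stop("non-finite activations at layer %d", l)
    # rectifier on hidden layers; the final layer stays linear so the
    # embeddings (and their inner products) are signed
    is_final <- l == params$L
    H_D[[l + 1L]] <- if (is_final) S_D else relu(S_D)
    H_T[[l + 1L]] <- if (is_final) S_T else relu(S_T)
    layer_cache[[l]] <- list(ops = ops, attn = attn_cache, S_D = S_D, S_T = S_T,
                             linear = is_final)
  }
  list(Z_D = H_D[[params$L + 1L]], Z_T = H_T[[params$L + 1L]],
       H_D = H_D, H_T = H_T, layers = layer_cache,
       X_D = X_D, X_T = X_T,
       use_attention = use_attention, renormalize = renormalize)
}

#' Encode drugs and targets into a shared embedding space
#'
#' Projects raw features to width `h` with a learned linear map, then
#' applies `L` graph-convolution layers. Deterministic given parameters and
#' inputs.
#'
#' @param features_D m x d raw drug feature matrix.
#' @param features_T n x t raw target feature matrix.
#' @param graph a `dti_graph`.
#' @param params a `dti_params`.
#' @param use_attention logical.
#' @param renormalize see [conv_layer()].
#' @return embedding state: list with `Z_D` (m x h), `Z_T` (n x h), `layer`.
#' @export
encode <- function(features_D, features_T, graph, params, use_attention = TRUE,
                   renormalize = TRUE) {
  fw <- encode_forward(features_D, features_T, graph, params, use_attention,
                       renormalize)
  list(Z_D = fw$Z_D, Z_T = fw$Z_T, layer = params$L)
}

# decoder MLP forward: hidden relu layer then linear output
decoder_forward <- function(Z, dec) {
  pre <- sweep(Z %*% dec$W1, 2, dec$b1, "+")
  hid <- relu(pre)
  out <- sweep(hid %*% dec$W2, 2, dec$b2, "+")
  list(pre = pre, hid = hid, out = out)
}

#' Feature-reconstruction loss
#'
#' Squared reconstruction error of the raw features from the embeddings
#' through the drug / target decoder MLPs:
#' `sum_i ||x_Di - MLP_D(z_Di)||^2 + sum_j ||x_Tj - MLP_T(z_Tj)||^2`.
#'
#' @param state embedding state from [encode()].
#' @param features_D,features_T raw feature matrices.
#' @param params a `dti_params`.
#' @return nonnegative scalar.
#' @export
reconstruction_loss <- function(state, features_D, features_T, params) {
  rd <- decoder_forward(state$Z_D, params$dec_D)
  rt <- decoder_forward(state$Z_T, params$dec_T)
  sum((features_D - rd$out)^2) + sum((features_T - rt$out)^2)
}
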