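#' Threshold a similarity matrix into a binary adjacency
#'
#' `a_ij = 1` iff `S_ij >= threshold` and `i != j`; self-loops are removed
#' (self-information re-enters through the encoder bias term).
#'
#' @param S square similarity matrix.
#' @param threshold value in [0, 1] (or above 1 to produce an empty graph).
#' @return binary adjacency matrix of the same shape.
#' @export
threshold_adjacency <- function(S, threshold = 0.5) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  A <- (S >= threshold) * 1
  diag(A) <- 0
  dimnames(A) <- dimnames(S)
  A
}

#' Aggregate multiple edge types of one class into a weighted block
#'
#' Weighted sum of same-shape adjacency matrices: the drug-drug block uses
#' weights lambda_k, the target-target block mu_k, and the drug-target block
#' eta_k. Weights default to `1/K` for K edge types.
#'
#' @param adjacencies list of adjacency matrices sharing a shape.
#' @param weights nonnegative numeric vector, one per edge type; default
#'   uniform `1/K`.
#' @return the weighted-sum block matrix.
#' @export
aggregate_edge_types <- function(adjacencies, weights = NULL) {
  stopifnot(is.list(adjacencies), length(adjacencies) >= 1L)
  dims <- vapply(adjacencies, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    dti_stop("edge-type adjacency shapes differ")
  if (is.null(weights)) weights <- rep(1 / length(adjacencies), length(adjacencies))
  if (length(weights) != length(adjacencies))
    dti_stop("need one weight per edge type")
  if (any(weights < 0)) dti_stop("edge-type weights must be nonnegative")
  out <- matrix(0, dims[1, 1], dims[2, 1])
  for (k in seq_along(adjacencies)) out <- out + weights[k] * adjacencies[[k]]
  dimnames(out) <- dimnames(adjacencies[[1]])
  out
}

#' Row softmax over structural support
#'
#' Normalizes each row of a (possibly weighted) adjacency block with a
#' softmax restricted to the structurally supported entries. Applying the
#' softmax to full dense rows would hand uniform attention to non-neighbors
#' and destroy sparsity, so unsupported entries stay exactly 0 and rows with
#' empty support are all-zero (isolated nodes keep only their bias term).
#'
#' @param block numeric matrix of raw edge weights.
#' @param support_mask logical/0-1 matrix marking structural edges; defaults
#'   to `block != 0`.
#' @return matrix whose supported rows sum to 1 and whose unsupported
#'   entries are 0.
#' @export
row_softmax_normalize <- function(block, support_mask = NULL) {
  stopifnot(is.matrix(block))
  if (is.null(support_mask)) support_mask <- block != 0
  support_mask <- support_mask != 0
  stopifnot(identical(dim(support_mask), dim(block)))
  out <- matrix(0, nrow(block), ncol(block), dimnames = dimnames(block))
  for (i in seq_len(nrow(block))) {
    idx <- which(support_mask[i, ])
    if (length(idx) == 0L) next
    v <- block[i, idx]
    e <- exp(v - max(v))
    out[i, idx] <- e / sum(e)
  }
  out
}

#' Assemble the unified heterogeneous graph
#'
#' Builds the block adjacency `[[A_DD, A_DT], [A_TD, A_TT]]` with
#' `A_TD = t(A_DT)`, where the drug-target block is the (training)
#' interaction matrix. Each block is softmax-normalized over its structural
#' support, yielding the message-passing operators of the encoder.
#'
#' @param A_DD m x m drug-drug block (weighted or binary).
#' @param A_TT n x n target-target block.
#' @param A_DT m x n drug-target block (typically the interaction matrix Y
#'   restricted to training positives).
#' @return a `dti_graph` with raw blocks, support masks, normalized blocks
#'   and per-block edge lists.
#' @export
assemble_unified <- function(A_DD, A_TT, A_DT) {
  m <- nrow(A_DT); n <- ncol(A_DT)
  if (!identical(dim(A_DD), c(m, m)))
    dti_stop("A_DD must be %d x %d", m, m)
  if (!identical(dim(A_TT), c(n, n)))
    dti_stop("A_TT must be %d x %d", n, n)
  A_TD <- t(A_DT)
  blocks <- list(DD = A_DD, TT = A_TT, DT = A_DT, TD = A_TD)
  support <- lapply(blocks, function(B) B != 0)
  normalized <- Map(row_softmax_normalize, blocks, support)
  edges <- lapply(support, function(S) {
    w <- which(S, arr.ind = TRUE)
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
    dimnames(w) <- list(NULL, c("i", "j"))
    w
  })
  structure(list(m = m, n = n, A = blocks, support = support,
                 norm = normalized, edges = edges),
            class = "dti_graph")
}

#' Full unified adjacency as one (m+n) x (m+n) matrix
#' @param graph a `dti_graph`.
#' @param normalized use normalized blocks (default FALSE = raw).
#' @return dense square matrix.
#' @export
unified_matrix <- function(graph, normalized = FALSE) {
  src <- if (normalized) graph$norm else graph$A
  rbind(cbind(src$DD, src$DT), cbind(src$TD, src$TT))
}

#' Build the heterogeneous graph from a dataset
#'
#' Convenience wrapper: thresholds the drug and target similarity matrices,
#' aggregates any auxiliary edge types with the supplied (or uniform) class
#' weights, inserts the training interaction matrix as the drug-target
#' block, and assembles + normalizes the unified graph.
#'
#' @param sim_D,sim_T similarity matrices for drugs / targets.
#' @param Y_train m x n 0/1 training interaction matrix.
#' @param threshold similarity threshold for both similarity networks.
#' @param aux_DD,aux_TT optional lists of extra binary adjacency matrices.
#' @param lambda_DD,mu_TT optional edge-type weights (uniform by default).
#' @return a `dti_graph`.
#' @export
build_dti_graph <- function(sim_D, sim_T, Y_train, threshold = 0.5,
                            aux_DD = NULL, aux_TT = NULL,
                            lambda_DD = NULL, mu_TT = NULL) {
  dd_types <- c(list(threshold_adjacency(sim_D, threshold)), aux_DD)
  tt_types <- c(list(threshold_adjacency(sim_T, threshold)), aux_TT)
  A_DD <- aggregate_edge_types(dd_types, lambda_DD)
  A_TT <- aggregate_edge_types(tt_types, mu_TT)
  assemble_unified(A_DD, A_TT, Y_train * 1)
}
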