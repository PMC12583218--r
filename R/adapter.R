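# Dataset-specific network adaptation: subnetwork filtering, distribution-
# aware CDF edge reweighting, meta-learned combination weights and the
# Frobenius regularizer tying adapted networks back to their global
# references. Optional and off by default for single-dataset runs, where
# "global" simply means the unfiltered input networks.

#' Extract the subnetwork over an entity subset
#'
#' Exact submatrix on the subset ordering; no renormalization.
#'
#' @param global_adjacency square matrix with entity ids as dimnames.
#' @param entity_subset character vector of ids (order defines the output).
#' @return the `|subset| x |subset|` submatrix.
#' @export
filter_subnetwork <- function(global_adjacency, entity_subset) {
  ids <- rownames(global_adjacency)
  if (is.null(ids)) dti_stop("global adjacency needs entity ids as dimnames")
  missing_ids <- setdiff(entity_subset, ids)
  if (length(missing_ids))
    dti_stop("unknown entity id(s): %s", paste(missing_ids, collapse = ", "))
  global_adjacency[entity_subset, entity_subset, drop = FALSE]
}

# midpoint (average-tie) empirical CDF of `values` evaluated at `x`;
# this convention is invariant to duplicating the value list
ecdf_avg_ties <- function(x, values) {
  n <- length(values)
  vapply(x, function(v) (sum(values < v) + sum(values == v) / 2) / n,
         numeric(1))
}

#' Distribution-aware edge reweighting
#'
#' Maps each dataset edge weight through the global empirical CDF and back
#' through the dataset's empirical quantile function, then multiplies:
#' `w' = w * Q_D(F_global(w))`. The quantile function linearly interpolates
#' the knots `(F_D(w_(k)), w_(k))` built with the same average-tie CDF
#' convention, which makes the transform invariant to duplicating the
#' dataset weight list and reduces `Q_D(F_global(w))` to `w` itself when the
#' dataset and global distributions coincide. Rank order within the dataset
#' is preserved.
#'
#' @param edge_weights_dataset positive weights of the dataset's edges.
#' @param edge_weights_global pooled weights across all datasets.
#' @return reweighted values, same length as `edge_weights_dataset`.
#' @export
cdf_reweight <- function(edge_weights_dataset, edge_weights_global) {
  if (!length(edge_weights_dataset) || !length(edge_weights_global))
    dti_stop("empty weight collection")
  if (length(unique(edge_weights_global)) == 1L) {
    dti_warn("constant global edge weights; reweighting factor 1")
    return(edge_weights_dataset)
  }
  p <- ecdf_avg_ties(edge_weights_dataset, edge_weights_global)
  w_sorted <- sort(unique(edge_weights_dataset))
  knots_p <- ecdf_avg_ties(w_sorted, edge_weights_dataset)
  q <- if (length(w_sorted) == 1L) rep(w_sorted, length(p)) else
    stats::approx(knots_p, w_sorted, xout = p, rule = 2, ties = "ordered")$y
  edge_weights_dataset * q
}

#' Adapted adjacency matrix
#'
#' `sum_k lambda_k * (W_k elementwise* A_k)`: the weighted combination of
#' the reweighted, filtered network types.
#'
#' @param networks list of per-type lists with elements `A` (binary
#'   adjacency) and `W` (edge weights, same shape; defaults to all-ones).
#' @param lambdas nonnegative combination weights, one per type.
#' @return the adapted matrix.
#' @export
adapt_adjacency <- function(networks, lambdas) {
  stopifnot(length(networks) == length(lambdas), all(lambdas >= 0))
  dims <- vapply(networks, function(nw) dim(nw$A), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    dti_stop("network shapes differ")
  out <- matrix(0, dims[1, 1], dims[2, 1])
  for (k in seq_along(networks)) {
    W <- if (is.null(networks[[k]]$W)) 1 else networks[[k]]$W
    out <- out + lambdas[k] * (W * networks[[k]]$A)
  }
  dimnames(out) <- dimnames(networks[[1]]$A)
  out
}

#' Network-size regularization coefficients
#'
#' `alpha_k = |E_k| / |E_total|`, proportional to each network's edge count.
#'
#' @param networks list of binary adjacency matrices (or lists with `A`).
#' @return coefficients summing to 1.
#' @export
alpha_coefficients <- function(networks) {
  counts <- vapply(networks, function(nw) {
    A <- if (is.list(nw)) nw$A else nw
    sum(A != 0)
  }, numeric(1))
  total <- sum(counts)
  if (total == 0) dti_stop("no edges in any network")
  counts / total
}

#' Adaptation regularizer
#'
#' `sum_k alpha_k ||A_adapted_k - A_global_k||_F^2`, with the adapted
#' (dataset-scope) matrices zero-padded back onto the global index before
#' comparison.
#'
#' @param adapted_networks list of adapted matrices with entity dimnames.
#' @param global_networks list of matching global matrices with dimnames.
#' @param alphas regularization coefficients (default from
#'   [alpha_coefficients()] on the global networks).
#' @return nonnegative scalar.
#' @export
adaptation_regularizer <- function(adapted_networks, global_networks,
                                   alphas = NULL) {
  stopifnot(length(adapted_networks) == length(global_networks))
  if (is.null(alphas)) alphas <- alpha_coefficients(global_networks)
  total <- 0
  for (k in seq_along(adapted_networks)) {
    G <- global_networks[[k]]
    A <- adapted_networks[[k]]
    pad <- matrix(0, nrow(G), ncol(G), dimnames = dimnames(G))
    if (is.null(rownames(A)) || is.null(rownames(G))) {
      stopifnot(identical(dim(A), dim(G)))
      pad <- A
    } else {
      pad[rownames(A), colnames(A)] <- A
    }
    total <- total + alphas[k] * sum((pad - G)^2)
  }
  total
}

#' Meta-learn network combination weights
#'
#' Minimizes a validation objective over the nonnegative combination
#' weights by projected gradient descent; the gradient is estimated by
#' central finite differences on the objective. Learning rate decays
#' multiplicatively; early stopping on the objective with the stated
#' patience. Deterministic given the initial weights and objective.
#'
#' @param n_types number of network types (length of lambda).
#' @param validation_objective function(lambda) -> scalar loss to minimize.
#' @param lr initial meta learning rate.
#' @param decay multiplicative decay factor.
#' @param decay_every iterations between decays.
#' @param max_iter iteration cap.
#' @param patience early-stopping patience.
#' @param init initial weights (default uniform `1/n_types`).
#' @return list with `lambda`, `objective`, and the iteration `trace`.
#' @export
learn_combination_weights <- function(n_types, validation_objective,
                                      lr = 0.01, decay = 0.95,
                                      decay_every = 50L, max_iter = 500L,
                                      patience = 20L, init = NULL) {
  if (n_types == 1L) {
    lam <- 1
    return(list(lambda = lam, objective = validation_objective(lam),
                trace = data.frame(iter = 0L, objective = validation_objective(lam))))
  }
  lam <- if (is.null(init)) rep(1 / n_types, n_types) else init
  eps <- 1e-4
  best <- validation_objective(lam)
  best_lam <- lam
  since_best <- 0L
  trace <- data.frame(iter = 0L, objective = best)
  rate <- lr
  for (it in seq_len(max_iter)) {
    grad <- vapply(seq_len(n_types), function(j) {
      up <- lam; up[j] <- up[j] + eps
      dn <- lam; dn[j] <- max(0, dn[j] - eps)
      (validation_objective(up) - validation_objective(dn)) / (up[j] - dn[j])
    }, numeric(1))
    lam <- pmax(0, lam - rate * grad)
    if (all(lam == 0)) {
      dti_warn("all combination weights projected to zero; reset to uniform")
      lam <- rep(1 / n_types, n_types)
    }
    obj <- validation_objective(lam)
    trace <- rbind(trace, data.frame(iter = it, objective = obj))
    if (obj < best - 1e-10) {
      best <- obj; best_lam <- lam; since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= patience) break
    }
    if (it %% decay_every == 0L) rate <- rate * decay
  }
  list(lambda = best_lam, objective = best, trace = trace)
}
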