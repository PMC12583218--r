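# Knowledge-graph regularization: relation-diagonal bilinear scoring of
# triples, filtered corruption sampling, and the margin ranking loss.
# Entities that are drugs or targets share the encoder embeddings; pure
# ontology terms get free embedding vectors of the same width trained only
# through this loss — sharing is what lets the regularizer infuse
# biological context into the predictive embeddings.

#' Score a knowledge-graph triple
#'
#' Bilinear-diagonal score `sum_k z_h[k] * diag_r[k] * z_t[k]` (the default),
#' or the translational score `-||z_h + w_r - z_t||` with
#' `kg_score = "transe"`.
#'
#' @param z_h,z_t embedding vectors of the head and tail entities.
#' @param relation relation name (must index a row of the relation table).
#' @param params a `dti_params` (uses `params$kg$rel` / `params$kg$rel_vec`).
#' @param kg_score `"bilinear"` (default) or `"transe"`.
#' @return scalar plausibility score.
#' @export
score_triple <- function(z_h, relation, z_t, params, kg_score = "bilinear") {
  kg_score <- match.arg(kg_score, c("bilinear", "transe"))
  if (!(relation %in% rownames(params$kg$rel)))
    dti_stop("unknown relation '%s'", relation)
  if (kg_score == "bilinear") {
    sum(z_h * params$kg$rel[relation, ] * z_t)
  } else {
    -sqrt(sum((z_h + params$kg$rel_vec[relation, ] - z_t)^2))
  }
}

#' Sample corrupted triples (filtered)
#'
#' For each input triple, draws `k` corruptions by replacing the head or the
#' tail (chosen uniformly) with a random entity from the pool; corruptions
#' that collide with a known true triple are resampled. Deterministic for a
#' given seed.
#'
#' @param triples data.frame with columns head, relation, tail.
#' @param entity_pool character vector of candidate replacement entities.
#' @param k corruptions per triple.
#' @param known_triples data.frame of true triples used for filtering
#'   (defaults to `triples`).
#' @param seed integer seed.
#' @return data.frame of corrupted triples with a `source` column giving the
#'   row of the originating triple.
#' @export
corrupt_triples <- function(triples, entity_pool, k = 1L,
                            known_triples = triples, seed = 1L) {
  if (length(entity_pool) <= 1L) dti_stop("entity pool must exceed 1")
  set.seed(substream_seed(seed, "kg-corrupt"))
  known <- paste(known_triples$head, known_triples$relation,
                 known_triples$tail, sep = "\r")
  out <- vector("list", nrow(triples) * k)
  idx <- 0L
  for (i in seq_len(nrow(triples))) {
    for (rep_ in seq_len(k)) {
      found <- FALSE
      for (try_ in seq_len(50L * length(entity_pool))) {
        corrupt_head <- stats::runif(1) < 0.5
        repl <- sample(entity_pool, 1L)
        cand <- if (corrupt_head)
          c(repl, triples$relation[i], triples$tail[i])
        else
          c(triples$head[i], triples$relation[i], repl)
        key <- paste(cand[1], cand[2], cand[3], sep = "\r")
        if (!(key %in% known)) { found <- TRUE; break }
      }
      if (!found)
        dti_stop("entity pool exhausted: every corruption of triple %d is a known triple", i)
      idx <- idx + 1L
      out[[idx]] <- data.frame(head = cand[1], relation = cand[2],
                               tail = cand[3], source = i,
                               stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Margin-based ranking loss over knowledge-graph triples
#'
#' `sum max(0, margin + f(corrupt) - f(true))` over every (true, corruption)
#' pair; zero exactly when every true triple outscores each of its
#' corruptions by at least the margin.
#'
#' @param true_scores scores of the true triples.
#' @param corrupt_scores scores of the corruptions.
#' @param source integer vector mapping each corruption to its true triple.
#' @param margin positive margin.
#' @return nonnegative scalar.
#' @export
kg_ranking_loss <- function(true_scores, corrupt_scores, source, margin = 1.0) {
  stopifnot(margin > 0, length(corrupt_scores) == length(source))
  sum(pmax(0, margin + corrupt_scores - true_scores[source]))
}

#' Combined objective
#'
#' `L = L_rec + lambda_kg * L_kg`: the reconstruction loss plus the weighted
#' knowledge-graph ranking loss.
#'
#' @param L_rec,L_kg finite loss components.
#' @param lambda_kg nonnegative trade-off weight.
#' @return scalar.
#' @export
combined_loss <- function(L_rec, L_kg, lambda_kg = 0.1) {
  stopifnot(is.finite(L_rec), is.finite(L_kg), lambda_kg >= 0)
  L_rec + lambda_kg * L_kg
}

# --- internal indexed machinery used during training -----------------------

# Build an integer-indexed view of a KG against the drug/target id lists.
# Entities that are drugs or targets point into Z_D / Z_T; everything else
# gets a free-embedding row.
build_kg_index <- function(kg, drug_ids, target_ids) {
  ents <- names(kg$entity_map)[order(kg$entity_map)]
  type <- ifelse(ents %in% drug_ids, "drug",
                 ifelse(ents %in% target_ids, "target", "free"))
  idx <- integer(length(ents))
  idx[type == "drug"] <- match(ents[type == "drug"], drug_ids)
  idx[type == "target"] <- match(ents[type == "target"], target_ids)
  idx[type == "free"] <- seq_len(sum(type == "free"))
  entity_table <- data.frame(name = ents, type = type, idx = idx,
                             stringsAsFactors = FALSE)
  row_of <- stats::setNames(seq_along(ents), ents)
  triples <- cbind(h = row_of[kg$triples$head],
                   r = match(kg$triples$relation, kg$relations),
                   t = row_of[kg$triples$tail])
  known_key <- paste(triples[, "h"], triples[, "r"], triples[, "t"])
  list(entity_table = entity_table, triples = triples,
       relations = kg$relations, n_free = sum(type == "free"),
       known = known_key)
}

# dense entity-embedding matrix assembled from the shared and free rows
kg_entity_embeddings <- function(kgi, Z_D, Z_T, E_free) {
  et <- kgi$entity_table
  Z <- matrix(0, nrow(et), ncol(Z_D))
  isd <- et$type == "drug"; ist <- et$type == "target"; isf <- et$type == "free"
  if (any(isd)) Z[isd, ] <- Z_D[et$idx[isd], , drop = FALSE]
  if (any(ist)) Z[ist, ] <- Z_T[et$idx[ist], , drop = FALSE]
  if (any(isf)) Z[isf, ] <- E_free[et$idx[isf], , drop = FALSE]
  Z
}

# indexed corruption sampling (uniform head-or-tail, filtered), no strings
sample_corruptions_idx <- function(triples, n_entities, known, k = 1L) {
  nt <- nrow(triples)
  src <- rep(seq_len(nt), each = k)
  corr <- triples[src, , drop = FALSE]
  for (q in seq_along(src)) {
    for (try_ in seq_len(200L)) {
      repl <- sample.int(n_entities, 1L)
      cand <- triples[src[q], ]
      if (stats::runif(1) < 0.5) cand["h"] <- repl else cand["t"] <- repl
      if (!(paste(cand["h"], cand["r"], cand["t"]) %in% known)) {
        corr[q, ] <- cand
        break
      }
    }
  }
  list(corr = corr, source = src)
}

# loss + gradients of the margin ranking loss wrt entity embeddings and
# relation diagonals (bilinear scorer)
kg_loss_and_grad <- function(Z_ent, rel, triples, corr, source, margin) {
  f <- function(tr) rowSums(Z_ent[tr[, "h"], , drop = FALSE] *
                              rel[tr[, "r"], , drop = FALSE] *
                              Z_ent[tr[, "t"], , drop = FALSE])
  f_true <- f(triples)
  f_corr <- f(corr)
  viol <- margin + f_corr - f_true[source]
  active <- viol > 0
  loss <- sum(viol[active])
  G_Z <- Z_ent * 0
  G_rel <- rel * 0
  if (any(active)) {
    ta <- triples[source[active], , drop = FALSE]   # true triples, -d f_true
    ca <- corr[active, , drop = FALSE]              # corruptions, +d f_corr
    add_trip <- function(G_Z, G_rel, tr, sign) {
      zh <- Z_ent[tr[, "h"], , drop = FALSE]
      zt <- Z_ent[tr[, "t"], , drop = FALSE]
      rr <- rel[tr[, "r"], , drop = FALSE]
      G_Z <- rowsum_add(G_Z, tr[, "h"], sign * rr * zt)
      G_Z <- rowsum_add(G_Z, tr[, "t"], sign * rr * zh)
      G_rel <- rowsum_add(G_rel, tr[, "r"], sign * zh * zt)
      list(G_Z, G_rel)
    }
    res <- add_trip(G_Z, G_rel, ta, -1)
    res <- add_trip(res[[1]], res[[2]], ca, +1)
    G_Z <- res[[1]]; G_rel <- res[[2]]
  }
  list(loss = loss, G_Z = G_Z, G_rel = G_rel)
}

# scatter entity-embedding gradients back to Z_D / Z_T / E_free
kg_scatter_grad <- function(kgi, G_Zent, G_ZD, G_ZT, G_Efree) {
  et <- kgi$entity_table
  isd <- et$type == "drug"; ist <- et$type == "target"; isf <- et$type == "free"
  if (any(isd)) G_ZD <- rowsum_add(G_ZD, et$idx[isd], G_Zent[isd, , drop = FALSE])
  if (any(ist)) G_ZT <- rowsum_add(G_ZT, et$idx[ist], G_Zent[ist, , drop = FALSE])
  if (any(isf)) G_Efree <- rowsum_add(G_Efree, et$idx[isf], G_Zent[isf, , drop = FALSE])
  list(G_ZD = G_ZD, G_ZT = G_ZT, G_Efree = G_Efree)
}
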