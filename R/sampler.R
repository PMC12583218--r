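#' Negative-sampler configuration
#'
#' Parameters of the positive-unlabeled negative sampling scheme: the
#' reliability mixture weights `alpha` (chemical) and `beta` (sequence), the
#' softmax temperature `gamma_temp` of the importance weights, the sigmoid-
#' scale prediction threshold `theta_neg` and reliability threshold
#' `theta_rel` of the refinement rule, the refinement interval in epochs,
#' and the negatives-per-positive ratio.
#'
#' @param alpha,beta nonnegative reliability mixture weights.
#' @param gamma_temp nonnegative softmax temperature.
#' @param theta_neg,theta_rel thresholds in [0, 1].
#' @param refresh_interval epochs between refinements.
#' @param ratio negatives sampled per positive.
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(alpha = 0.5, beta = 0.5, gamma_temp = 1.0,
                           theta_neg = 0.5, theta_rel = 0.5,
                           refresh_interval = 50L, ratio = 1) {
  stopifnot(alpha >= 0, beta >= 0, gamma_temp >= 0,
            theta_neg >= 0, theta_neg <= 1, theta_rel >= 0, theta_rel <= 1,
            refresh_interval >= 1, ratio > 0)
  structure(list(alpha = alpha, beta = beta, gamma_temp = gamma_temp,
                 theta_neg = theta_neg, theta_rel = theta_rel,
                 refresh_interval = as.integer(refresh_interval), ratio = ratio),
            class = "sampler_config")
}

#' Chemical dissimilarity of a drug from the known binders of a target
#'
#' One minus the maximum Tanimoto similarity between the drug and any known
#' binder of the target. An empty binder set gives 1 (maximally dissimilar
#' by convention), so cold targets still admit reliable negatives.
#'
#' @param drug_fp `dti_fingerprint` of the candidate drug.
#' @param binder_fps list of fingerprints of the target's known binders.
#' @return dissimilarity in [0, 1].
#' @export
chem_dissim <- function(drug_fp, binder_fps) {
  if (length(binder_fps) == 0L) return(1)
  1 - max(vapply(binder_fps, function(fp) tanimoto(drug_fp, fp), numeric(1)))
}

#' Sequence dissimilarity of a target from the known targets of a drug
#'
#' One minus the maximum normalized Smith-Waterman similarity between the
#' target and any known partner of the drug; empty set gives 1.
#'
#' @param target_seq candidate target sequence.
#' @param partner_seqs character vector of sequences of the drug's known
#'   targets.
#' @param ... passed to [normalized_seq_similarity()].
#' @return dissimilarity in [0, 1].
#' @export
seq_dissim <- function(target_seq, partner_seqs, ...) {
  if (length(partner_seqs) == 0L) return(1)
  1 - max(vapply(partner_seqs, function(s)
    normalized_seq_similarity(target_seq, s, ...), numeric(1)))
}

#' Reliability score of one unlabeled pair
#'
#' `alpha * ChemDissim + beta * SeqDissim`; ranges over `[0, alpha + beta]`.
#'
#' @param chem_d,seq_d the two dissimilarities in [0, 1].
#' @param config a [sampler_config()].
#' @return reliability score.
#' @export
reliability_score <- function(chem_d, seq_d, config = sampler_config()) {
  config$alpha * chem_d + config$beta * seq_d
}

#' Reliability matrix over all pairs from precomputed similarity matrices
#'
#' Matrix form of the reliability score: for pair (i, j),
#' `alpha * (1 - max_{k in binders(j)} simD[i, k]) +
#'  beta  * (1 - max_{l in partners(i)} simT[j, l])`,
#' with empty sets contributing dissimilarity 1. Known positives get NA.
#'
#' @param sim_D m x m drug similarity matrix.
#' @param sim_T n x n target similarity matrix.
#' @param Y_train m x n 0/1 training interaction matrix defining binder /
#'   partner sets.
#' @param config a [sampler_config()].
#' @return m x n reliability matrix (NA at training positives).
#' @export
reliability_matrix <- function(sim_D, sim_T, Y_train, config = sampler_config()) {
  m <- nrow(Y_train); n <- ncol(Y_train)
  chem <- matrix(1, m, n)
  seqd <- matrix(1, m, n)
  for (j in seq_len(n)) {
    binders <- which(Y_train[, j] == 1)
    if (length(binders))
      chem[, j] <- 1 - apply(sim_D[, binders, drop = FALSE], 1, max)
  }
  for (i in seq_len(m)) {
    partners <- which(Y_train[i, ] == 1)
    if (length(partners))
      seqd[i, ] <- 1 - apply(sim_T[, partners, drop = FALSE], 1, max)
  }
  R <- config$alpha * chem + config$beta * seqd
  R[Y_train == 1] <- NA_real_
  R
}

#' Importance weights over a negative set
#'
#' Softmax of `gamma_temp * reliability` over the set; the weights sum to 1.
#' At `gamma_temp = 0` the weights are uniform regardless of reliability.
#'
#' @param reliabilities numeric vector of reliability scores.
#' @param gamma_temp temperature.
#' @return weights summing to 1.
#' @export
importance_weights <- function(reliabilities, gamma_temp = 1.0) {
  if (length(reliabilities) == 0L) dti_stop("empty negative set")
  z <- gamma_temp * reliabilities
  e <- exp(z - max(z))
  e / sum(e)
}

new_negative_set <- function(pairs, reliability, gamma_temp, generation) {
  structure(list(pairs = pairs,            # 2-col integer matrix (drug, target)
                 reliability = reliability,
                 weight = importance_weights(reliability, gamma_temp),
                 generation = as.integer(generation)),
            class = "dti_negative_set")
}

#' Initial reliability-ranked negative set
#'
#' Before any model predictions exist the refinement rule cannot be applied,
#' so round 0 selects the `ratio * |P|` unlabeled pairs with the highest
#' reliability (ties broken deterministically by pair index). With
#' `random = TRUE` the pairs are drawn uniformly from the unlabeled set and
#' weighted uniformly — the "random sampling" ablation arm.
#'
#' @param reliability m x n reliability matrix (NA at positives).
#' @param n_positives size of the positive set.
#' @param config a [sampler_config()].
#' @param random draw uniformly instead of by reliability.
#' @param seed integer seed (used by the random arm).
#' @param exclude optional 2-col matrix of extra pairs to exclude (e.g.
#'   held-out validation/test positives).
#' @return a `dti_negative_set` (generation 0).
#' @export
initial_negatives <- function(reliability, n_positives, config = sampler_config(),
                              random = FALSE, seed = 1L, exclude = NULL) {
  cand <- which(!is.na(reliability))
  if (!is.null(exclude) && nrow(exclude)) {
    excl_lin <- (exclude[, 2] - 1L) * nrow(reliability) + exclude[, 1]
    cand <- setdiff(cand, excl_lin)
  }
  if (length(cand) == 0L) dti_stop("no unlabeled pairs to sample from")
  k <- min(length(cand), max(1L, round(config$ratio * n_positives)))
  if (random) {
    set.seed(substream_seed(seed, "random-negatives"))
    sel <- sample(cand, k)
    pairs <- cbind(drug = ((sel - 1L) %% nrow(reliability)) + 1L,
                   target = ((sel - 1L) %/% nrow(reliability)) + 1L)
    return(structure(list(pairs = pairs,
                          reliability = reliability[sel],
                          weight = rep(1 / k, k),
                          generation = 0L),
                     class = "dti_negative_set"))
  }
  ord <- cand[order(-reliability[cand], cand)]
  sel <- ord[seq_len(k)]
  pairs <- cbind(drug = ((sel - 1L) %% nrow(reliability)) + 1L,
                 target = ((sel - 1L) %/% nrow(reliability)) + 1L)
  new_negative_set(pairs, reliability[sel], config$gamma_temp, 0L)
}

#' Weighted positive-unlabeled interaction loss
#'
#' `-sum_P log sigmoid(yhat) - sum_N w * log(1 - sigmoid(yhat))`: the binary
#' cross-entropy in which each negative contributes proportionally to its
#' importance weight.
#'
#' @param pos_scores raw (pre-sigmoid) scores of the positive pairs.
#' @param neg_scores raw scores of the sampled negative pairs.
#' @param neg_weights importance weights of the negatives (summing to 1).
#' @return nonnegative scalar loss.
#' @export
weighted_interaction_loss <- function(pos_scores, neg_scores = numeric(0),
                                      neg_weights = numeric(0)) {
  stopifnot(length(neg_scores) == length(neg_weights))
  # log(sigmoid(x)) = -log1p(exp(-x)), numerically stable both ways
  lpos <- if (length(pos_scores)) sum(log1p(exp(-pos_scores))) else 0
  lneg <- if (length(neg_scores)) sum(neg_weights * log1p(exp(neg_scores))) else 0
  lpos + lneg
}

#' Refine the negative set from current model confidence
#'
#' Re-evaluates all unlabeled pairs and keeps those the model scores below
#' `theta_neg` (on the sigmoid/probability scale) that are also reliably
#' dissimilar (`reliability > theta_rel`). If the selection is empty the
#' previous set is kept with a warning. Importance weights are recomputed
#' and the generation counter advances.
#'
#' @param probs m x n matrix of predicted interaction probabilities.
#' @param reliability m x n reliability matrix (NA at positives).
#' @param previous the current `dti_negative_set` (fallback).
#' @param config a [sampler_config()].
#' @param exclude optional 2-col matrix of pairs barred from selection.
#' @return a `dti_negative_set`.
#' @export
refine_negatives <- function(probs, reliability, previous,
                             config = sampler_config(), exclude = NULL) {
  keep <- !is.na(reliability) & probs < config$theta_neg &
    reliability > config$theta_rel
  if (!is.null(exclude) && nrow(exclude)) {
    keep[cbind(exclude[, 1], exclude[, 2])] <- FALSE
  }
  sel <- which(keep)
  if (length(sel) == 0L) {
    dti_warn("negative refinement selected no pairs; keeping previous set")
    out <- previous
    out$generation <- previous$generation + 1L
    return(out)
  }
  pairs <- cbind(drug = ((sel - 1L) %% nrow(probs)) + 1L,
                 target = ((sel - 1L) %/% nrow(probs)) + 1L)
  new_negative_set(pairs, reliability[sel], config$gamma_temp,
                   previous$generation + 1L)
}

#' Export a negative set for audit
#' @param negset a `dti_negative_set`.
#' @param drug_ids,target_ids id vectors indexed by the pair columns.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_negative_set <- function(negset, drug_ids, target_ids, path) {
  tab <- data.frame(drug_id = drug_ids[negset$pairs[, 1]],
                    target_id = target_ids[negset$pairs[, 2]],
                    reliability = negset$reliability,
                    weight = negset$weight,
                    generation = negset$generation)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
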