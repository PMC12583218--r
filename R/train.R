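#' Training configuration
#'
#' Defaults follow the method's stated constants: embedding width 128,
#' 3 convolution layers, Adam with learning rate 0.001 and weight decay
#' 0.0005, batch size 256, up to 1000 epochs with early stopping on
#' validation AUPR, knowledge-graph weight 0.1 and margin 1.0. Tests and
#' the bundled examples use the small-scale overrides (h = 16, L = 2, a few
#' hundred epochs) so everything runs in seconds.
#'
#' @param h embedding width.
#' @param L number of graph-convolution layers.
#' @param lr learning rate.
#' @param weight_decay L2 weight decay.
#' @param batch_size pairs per interaction mini-batch.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience (epochs without validation AUPR
#'   improvement).
#' @param lambda_rec weight of the reconstruction loss.
#' @param lambda_kg weight of the knowledge-graph loss.
#' @param margin KG ranking margin.
#' @param corruptions_per_triple corruptions sampled per triple per epoch.
#' @param kg_score `"bilinear"` or `"transe"`.
#' @param use_attention enable edge attention.
#' @param renormalize_attention re-normalize attention-modulated rows.
#' @param threshold similarity threshold for graph construction.
#' @param sampler a [sampler_config()].
#' @param adaptation enable dataset-specific network adaptation.
#' @param gamma_reg weight of the adaptation regularizer.
#' @param val_every epochs between validation evaluations.
#' @param seed master seed; every random draw derives from it via named
#'   sub-streams.
#' @return a `dti_config` list.
#' @export
dti_config <- function(h = 128L, L = 3L, lr = 1e-3, weight_decay = 5e-4,
                       batch_size = 256L, max_epochs = 1000L, patience = 30L,
                       lambda_rec = 1.0, lambda_kg = 0.1, margin = 1.0,
                       corruptions_per_triple = 1L, kg_score = "bilinear",
                       use_attention = TRUE, renormalize_attention = TRUE,
                       threshold = 0.5, sampler = sampler_config(),
                       adaptation = FALSE, gamma_reg = 0, val_every = 5L,
                       seed = 1L) {
  stopifnot(h > 0, L >= 1, lr > 0, weight_decay >= 0, batch_size > 0,
            max_epochs >= 1, patience >= 1, lambda_rec >= 0, lambda_kg >= 0,
            margin > 0, corruptions_per_triple >= 1, gamma_reg >= 0)
  structure(list(h = as.integer(h), L = as.integer(L), lr = lr,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 lambda_rec = lambda_rec, lambda_kg = lambda_kg, margin = margin,
                 corruptions_per_triple = as.integer(corruptions_per_triple),
                 kg_score = match.arg(kg_score, c("bilinear", "transe")),
                 use_attention = isTRUE(use_attention),
                 renormalize_attention = isTRUE(renormalize_attention),
                 threshold = threshold, sampler = sampler,
                 adaptation = isTRUE(adaptation), gamma_reg = gamma_reg,
                 val_every = as.integer(val_every), seed = as.integer(seed)),
            class = "dti_config")
}

#' Small-scale evaluation configuration
#'
#' The configuration used throughout the bundled examples, tests and the
#' acceptance script for desk-scale fixtures (tens of entities): h = 32,
#' L = 2, learning rate 0.01, negatives ratio 8, full-ish batches, 300
#' epochs with patience 100. These values were selected by validation AUPR
#' on the standard synthetic fixture; the full-scale defaults of
#' [dti_config()] remain the method's stated constants.
#'
#' @param seed master seed.
#' @param ... overrides passed through to [dti_config()].
#' @return a `dti_config`.
#' @export
dti_config_small <- function(seed = 1L, ...) {
  args <- list(h = 32L, L = 2L, lr = 1e-2, batch_size = 512L,
               max_epochs = 300L, patience = 100L, val_every = 5L,
               sampler = sampler_config(ratio = 8), seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(dti_config, args)
}

#' Precompute similarity matrices for a dataset
#'
#' Computes (once) the Tanimoto drug-drug and normalized Smith-Waterman
#' target-target similarity matrices a dataset needs for graph construction
#' and reliability scoring, and caches them on the dataset object.
#'
#' @param dataset a `dti_dataset`.
#' @param substitution,gap_open,gap_extend alignment scoring parameters.
#' @return the dataset with `sim_D` and `sim_T` fields populated.
#' @export
prepare_dataset <- function(dataset, substitution = "BLOSUM62",
                            gap_open = 11, gap_extend = 1) {
  if (is.null(dataset$sim_D))
    dataset$sim_D <- fingerprint_similarity_matrix(dataset$fingerprints)
  if (is.null(dataset$sim_T))
    dataset$sim_T <- sequence_similarity_matrix(dataset$sequences, substitution,
                                                gap_open, gap_extend)
  dataset
}

# positive pairs of an interaction matrix as a 2-col index matrix
positive_pairs <- function(Y) {
  w <- which(Y == 1L, arr.ind = TRUE)
  w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
  dimnames(w) <- list(NULL, c("drug", "target"))
  w
}

#' Combined training objective
#'
#' `L_weighted + lambda_rec * L_rec + lambda_kg * L_kg` (plus
#' `gamma_reg * L_reg` when adaptation is active). The individual
#' components are attached as the `"components"` attribute.
#'
#' @param state embedding state (list `Z_D`, `Z_T`).
#' @param params a `dti_params`.
#' @param batch list with `pos` / `neg` pair matrices, `neg_weights`,
#'   `X_D`, `X_T`, and optional KG pieces `kgi`, `kg_corr`, `kg_source`.
#' @param config a `dti_config`.
#' @param L_reg optional precomputed adaptation regularizer value.
#' @return scalar loss with a `components` attribute.
#' @export
total_loss <- function(state, params, batch, config, L_reg = 0) {
  score_of <- function(p) rowSums(state$Z_D[p[, 1], , drop = FALSE] *
                                    state$Z_T[p[, 2], , drop = FALSE])
  L_w <- weighted_interaction_loss(
    if (nrow(batch$pos)) score_of(batch$pos) else numeric(0),
    if (nrow(batch$neg)) score_of(batch$neg) else numeric(0),
    batch$neg_weights)
  L_rec <- if (config$lambda_rec > 0)
    reconstruction_loss(state, batch$X_D, batch$X_T, params) else 0
  L_kg <- 0
  if (config$lambda_kg > 0 && !is.null(batch$kgi)) {
    Zent <- kg_entity_embeddings(batch$kgi, state$Z_D, state$Z_T, params$kg$E_free)
    f <- function(tr) rowSums(Zent[tr[, "h"], , drop = FALSE] *
                                params$kg$rel[tr[, "r"], , drop = FALSE] *
                                Zent[tr[, "t"], , drop = FALSE])
    L_kg <- kg_ranking_loss(f(batch$kgi$triples), f(batch$kg_corr),
                            batch$kg_source, config$margin)
  }
  for (comp in c(L_w, L_rec, L_kg, L_reg))
    if (!is.finite(comp)) dti_stop("non-finite loss component")
  out <- L_w + config$lambda_rec * L_rec + config$lambda_kg * L_kg +
    config$gamma_reg * L_reg
  attr(out, "components") <- c(interaction = L_w, reconstruction = L_rec,
                               kg = L_kg, adaptation = L_reg)
  out
}

#' Train the full model
#'
#' Builds the training graph from the similarity networks and the training
#' positives, draws the initial reliability-ranked negative set, and runs
#' Adam over the combined objective with early stopping on validation AUPR.
#' The negative set is refined from model confidence every
#' `sampler$refresh_interval` epochs. Fully reproducible given
#' `config$seed`.
#'
#' @param data a prepared `dti_dataset` (see [prepare_dataset()]).
#' @param config a [dti_config()].
#' @param train_pairs 2-col index matrix of training positive pairs
#'   (default: all positives of `data$Y`).
#' @param val_pairs 2-col matrix of validation positives (used for early
#'   stopping and F1 threshold selection); if NULL a random 10% of
#'   `train_pairs` is carved out.
#' @param negatives_mode `"combined"` (reliability + importance weighting +
#'   refinement) or `"random"` (uniform sampling, uniform weights, no
#'   refinement) — the ablation arm.
#' @param use_kg override: set FALSE to drop the KG regularizer (ablation).
#' @param exclude_pairs 2-col matrix of pairs whose labels must not be
#'   visible during training (e.g. test positives); they are treated as
#'   unlabeled.
#' @return a `dti_model`: fitted parameters, the training graph, history of
#'   loss components and validation AUPR per epoch, the final negative set,
#'   the validation-chosen F1 threshold, and bookkeeping.
#' @export
train_dti <- function(data, config = dti_config(), train_pairs = NULL,
                      val_pairs = NULL, negatives_mode = c("combined", "random"),
                      use_kg = TRUE, exclude_pairs = NULL) {
  negatives_mode <- match.arg(negatives_mode)
  stopifnot(inherits(data, "dti_dataset"))
  if (is.null(data$sim_D) || is.null(data$sim_T))
    dti_stop("dataset not prepared; call prepare_dataset() first")
  m <- length(data$drug_ids); n <- length(data$target_ids)
  if (is.null(train_pairs)) train_pairs <- positive_pairs(data$Y)
  if (is.null(val_pairs)) {
    set.seed(substream_seed(config$seed, "val-carve"))
    vi <- sample(nrow(train_pairs), max(1L, round(0.1 * nrow(train_pairs))))
    val_pairs <- train_pairs[vi, , drop = FALSE]
    train_pairs <- train_pairs[-vi, , drop = FALSE]
  }

  Y_train <- matrix(0L, m, n)
  Y_train[train_pairs] <- 1L

  graph <- build_dti_graph(data$sim_D, data$sim_T, Y_train,
                           threshold = config$threshold,
                           aux_DD = data$aux_DD, aux_TT = data$aux_TT)

  lambda_kg_eff <- if (use_kg && !is.null(data$kg)) config$lambda_kg else 0
  kgi <- if (lambda_kg_eff > 0)
    build_kg_index(data$kg, data$drug_ids, data$target_ids) else NULL
  # scale-free effective weights: the optimizer sees mean-reduced components
  # (per positive pair, per entity, per triple) so the lambda trade-offs do
  # not depend on dataset size
  lam_rec <- config$lambda_rec / (m + n)
  lam_kg <- if (!is.null(kgi)) lambda_kg_eff / max(1L, nrow(kgi$triples)) else 0

  reliability <- reliability_matrix(data$sim_D, data$sim_T, Y_train,
                                    config$sampler)
  negs <- initial_negatives(reliability, nrow(train_pairs), config$sampler,
                            random = (negatives_mode == "random"),
                            seed = config$seed)

  params <- init_encoder_params(
    d = ncol(data$X_D), t = ncol(data$X_T), h = config$h, L = config$L,
    relations = if (!is.null(kgi)) kgi$relations else character(0),
    n_free = if (!is.null(kgi)) kgi$n_free else 0L,
    seed = config$seed)
  opt <- adam_init(params)

  # validation labels: val positives vs every pair unlabeled in training
  val_mask <- matrix(TRUE, m, n)
  val_mask[train_pairs] <- FALSE
  if (!is.null(exclude_pairs) && nrow(exclude_pairs))
    val_mask[exclude_pairs] <- FALSE
  val_lab <- matrix(0L, m, n)
  val_lab[val_pairs] <- 1L
  val_idx <- which(val_mask)
  val_labels <- val_lab[val_idx]

  set.seed(substream_seed(config$seed, "train"))
  cfg <- config; cfg$lambda_kg <- lambda_kg_eff
  history <- vector("list", config$max_epochs)
  best_aupr <- -Inf; best_params <- params; best_epoch <- 0L
  since_best <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    fw <- encode_forward(data$X_D, data$X_T, graph, params,
                         config$use_attention, config$renormalize_attention)
    # interaction mini-batch
    pos_b <- train_pairs; neg_b <- negs$pairs; w_b <- negs$weight
    if (nrow(pos_b) > config$batch_size) {
      sel <- sample(nrow(pos_b), config$batch_size)
      pos_b <- pos_b[sel, , drop = FALSE]
    }
    if (nrow(neg_b) > config$batch_size) {
      sel <- sample(nrow(neg_b), config$batch_size)
      neg_b <- neg_b[sel, , drop = FALSE]
      w_b <- w_b[sel] / sum(w_b[sel])
    }
    ig <- interaction_grad(fw$Z_D, fw$Z_T, pos_b, neg_b, w_b,
                           pos_scale = 1 / max(1L, nrow(pos_b)))
    G_ZD <- ig$G_ZD; G_ZT <- ig$G_ZT
    grads <- zero_grads(params)

    L_rec <- 0
    if (config$lambda_rec > 0) {
      cd <- decoder_forward(fw$Z_D, params$dec_D)
      ct <- decoder_forward(fw$Z_T, params$dec_T)
      L_rec <- sum((data$X_D - cd$out)^2) + sum((data$X_T - ct$out)^2)
      bd <- decoder_backward(fw$Z_D, data$X_D, params$dec_D, cd)
      bt <- decoder_backward(fw$Z_T, data$X_T, params$dec_T, ct)
      grads$dec_D <- lapply(bd$grads, function(x) lam_rec * x)
      grads$dec_T <- lapply(bt$grads, function(x) lam_rec * x)
      G_ZD <- G_ZD + lam_rec * bd$G_Z
      G_ZT <- G_ZT + lam_rec * bt$G_Z
    }

    L_kg <- 0
    if (lambda_kg_eff > 0) {
      corr <- sample_corruptions_idx(kgi$triples, nrow(kgi$entity_table),
                                     kgi$known, cfg$corruptions_per_triple)
      Zent <- kg_entity_embeddings(kgi, fw$Z_D, fw$Z_T, params$kg$E_free)
      kgl <- kg_loss_and_grad(Zent, params$kg$rel, kgi$triples, corr$corr,
                              corr$source, config$margin)
      L_kg <- kgl$loss
      sc <- kg_scatter_grad(kgi, lam_kg * kgl$G_Z,
                            matrix(0, m, config$h), matrix(0, n, config$h),
                            params$kg$E_free * 0)
      G_ZD <- G_ZD + sc$G_ZD
      G_ZT <- G_ZT + sc$G_ZT
      grads$kg$E_free <- sc$G_Efree
      grads$kg$rel <- lam_kg * kgl$G_rel
    }

    enc_g <- encoder_backward(fw, graph, params, G_ZD, G_ZT)
    grads$P_D <- enc_g$P_D; grads$P_T <- enc_g$P_T
    grads$layers <- enc_g$layers; grads$attn <- enc_g$attn

    step <- adam_step(params, grads, opt, lr = config$lr,
                      weight_decay = config$weight_decay)
    params <- step$params; opt <- step$state

    total <- ig$loss + lam_rec * L_rec + lam_kg * L_kg
    if (!is.finite(total))
      dti_stop("training diverged at epoch %d (non-finite loss)", epoch)

    # negative refinement on the model's current confidence
    if (negatives_mode == "combined" &&
        epoch %% config$sampler$refresh_interval == 0L) {
      probs <- sigmoid(fw$Z_D %*% t(fw$Z_T))
      negs <- refine_negatives(probs, reliability, negs, config$sampler)
    }

    val_aupr <- NA_real_
    if (epoch %% config$val_every == 0L || epoch == config$max_epochs) {
      scores <- fw$Z_D %*% t(fw$Z_T)
      val_aupr <- aupr(val_labels, scores[val_idx])
      if (val_aupr > best_aupr + 1e-12) {
        best_aupr <- val_aupr; best_params <- params; best_epoch <- epoch
        since_best <- 0L
      } else {
        since_best <- since_best + config$val_every
      }
    }
    history[[epoch]] <- data.frame(epoch = epoch, interaction = ig$loss,
                                   reconstruction = L_rec, kg = L_kg,
                                   total = total, val_aupr = val_aupr)
    if (since_best >= config$patience) break
  }
  history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])

  state <- encode(data$X_D, data$X_T, graph, best_params,
                  config$use_attention, config$renormalize_attention)
  val_scores <- rowSums(state$Z_D[val_pairs[, 1], , drop = FALSE] *
                          state$Z_T[val_pairs[, 2], , drop = FALSE])
  all_scores <- state$Z_D %*% t(state$Z_T)
  f1_thr <- best_f1_threshold(val_labels, all_scores[val_idx])

  structure(list(params = best_params, graph = graph, config = config,
                 data = data, history = history, negatives = negs,
                 train_pairs = train_pairs, val_pairs = val_pairs,
                 best_epoch = best_epoch, best_val_aupr = best_aupr,
                 f1_threshold = f1_thr, state = state,
                 negatives_mode = negatives_mode, use_kg = use_kg),
            class = "dti_model")
}

#' Predict interaction scores for drug-target pairs
#'
#' The interaction score of a pair is the inner product of the drug and
#' target embeddings; the probability is its sigmoid. Cold entities receive
#' embeddings through the encoder forward pass over the graph (their
#' similarity edges carry the information).
#'
#' @param model a fitted `dti_model`.
#' @param pairs 2-col index matrix (drug index, target index); default all
#'   m x n pairs.
#' @return data.frame with drug_id, target_id, score, probability.
#' @export
predict_scores <- function(model, pairs = NULL) {
  st <- model$state
  if (is.null(pairs)) {
    pairs <- as.matrix(expand.grid(drug = seq_len(nrow(st$Z_D)),
                                   target = seq_len(nrow(st$Z_T))))
  }
  s <- rowSums(st$Z_D[pairs[, 1], , drop = FALSE] *
                 st$Z_T[pairs[, 2], , drop = FALSE])
  data.frame(drug_id = model$data$drug_ids[pairs[, 1]],
             target_id = model$data$target_ids[pairs[, 2]],
             score = s, probability = sigmoid(s),
             stringsAsFactors = FALSE)
}

# score matrix over all pairs
score_matrix <- function(model) model$state$Z_D %*% t(model$state$Z_T)

# test metrics for a trained model: held-out positives vs pairs unlabeled
# everywhere (restricted to `restrict` rows/cols for cold-start scenarios)
evaluate_heldout <- function(model, test_pairs, all_positive_pairs, k = 10L,
                             restrict = NULL) {
  m <- length(model$data$drug_ids); n <- length(model$data$target_ids)
  lab <- matrix(NA_integer_, m, n)
  lab[] <- 0L
  lab[all_positive_pairs] <- NA_integer_   # positives outside test: ignored
  lab[test_pairs] <- 1L
  if (!is.null(restrict)) {
    keep <- matrix(FALSE, m, n)
    keep[restrict$drugs, restrict$targets] <- TRUE
    lab[!keep] <- NA_integer_
  }
  idx <- which(!is.na(lab))
  scores <- score_matrix(model)
  metric_report(lab[idx], scores[idx], k = k, f1_threshold = model$f1_threshold)
}

#' k-fold cross-validated evaluation
#'
#' For each rotation, trains on the training folds' positives, early-stops
#' on the validation fold, and reports test metrics where the test
#' positives are ranked against every pair that is positive nowhere.
#'
#' @param data prepared `dti_dataset`.
#' @param config a `dti_config`.
#' @param k number of folds.
#' @param seed split seed.
#' @param rotations which rotations to run (default all `k`).
#' @param k_at top-k cutoff for precision-at-k.
#' @param ... passed to [train_dti()] (e.g. `negatives_mode`, `use_kg`).
#' @return list with per-fold metric data.frame and mean/sd summary.
#' @export
evaluate_cv <- function(data, config = dti_config(), k = 10L, seed = 1L,
                        rotations = NULL, k_at = 10L, ...) {
  pos <- positive_pairs(data$Y)
  plan <- kfold_splits(nrow(pos), k = k, seed = seed)
  if (is.null(rotations)) rotations <- seq_len(k)
  rows <- lapply(rotations, function(r) {
    rot <- plan$rotations[[r]]
    model <- train_dti(data, config,
                       train_pairs = pos[rot$train, , drop = FALSE],
                       val_pairs = pos[rot$validation, , drop = FALSE],
                       exclude_pairs = pos[rot$test, , drop = FALSE], ...)
    met <- evaluate_heldout(model, pos[rot$test, , drop = FALSE], pos, k = k_at)
    data.frame(fold = r, auroc = met$auroc, aupr = met$aupr, f1 = met$f1,
               p_at_k = met$p_at_k)
  })
  folds <- do.call(rbind, rows)
  list(folds = folds,
       mean = colMeans(folds[, -1, drop = FALSE]),
       sd = apply(folds[, -1, drop = FALSE], 2, stats::sd))
}

#' Cold-start evaluation
#'
#' Scenario S1 holds out drugs (with all their pairs), S2 targets, S3 pairs
#' with both endpoints kept in training. Held-out entities keep their
#' similarity and auxiliary edges, which is how the encoder embeds them
#' without any interaction evidence.
#'
#' @inheritParams evaluate_cv
#' @param scenario `"S1"`, `"S2"` or `"S3"`.
#' @param fraction held-out fraction.
#' @return list with the metric report and the split plan.
#' @export
evaluate_cold_start <- function(data, config = dti_config(),
                                scenario = "S1", fraction = 0.2, seed = 1L,
                                k_at = 10L, ...) {
  pos <- positive_pairs(data$Y)
  plan <- cold_start_splits(pos, scenario, fraction, seed)
  model <- train_dti(data, config,
                     train_pairs = pos[plan$train, , drop = FALSE],
                     exclude_pairs = pos[plan$test, , drop = FALSE], ...)
  restrict <- switch(scenario,
    S1 = list(drugs = plan$held_out, targets = seq_along(data$target_ids)),
    S2 = list(drugs = seq_along(data$drug_ids), targets = plan$held_out),
    S3 = NULL)
  met <- evaluate_heldout(model, pos[plan$test, , drop = FALSE], pos,
                          k = k_at, restrict = restrict)
  list(metrics = met, plan = plan)
}
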