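#' k-fold split plan over interaction pairs
#'
#' Assigns the labeled pairs to `k` disjoint folds of near-equal size. In
#' rotation `r`, fold `r` is the test fold, the next fold cyclically is the
#' validation fold (used for early stopping and threshold selection), and
#' the remaining `k - 2` folds train the model — so every pair is used for
#' testing exactly once across the `k` rotations.
#'
#' @param n_pairs number of labeled pairs (or a 2-col pair matrix).
#' @param k number of folds (>= 2).
#' @param seed integer seed for the split sub-stream.
#' @return a `dti_split_plan`: integer `fold` per pair plus a `rotations`
#'   list with `train`, `validation`, `test` index vectors.
#' @export
kfold_splits <- function(n_pairs, k = 10L, seed = 1L) {
  if (is.matrix(n_pairs)) n_pairs <- nrow(n_pairs)
  if (k < 2L) dti_stop("k must be at least 2")
  if (n_pairs < k) dti_stop("fewer pairs (%d) than folds (%d)", n_pairs, k)
  set.seed(substream_seed(seed, "splits"))
  fold <- sample(rep(seq_len(k), length.out = n_pairs))
  rotations <- lapply(seq_len(k), function(r) {
    val <- (r %% k) + 1L
    list(test = which(fold == r),
         validation = which(fold == val),
         train = which(!(fold %in% c(r, val))))
  })
  structure(list(kind = "kfold", k = k, fold = fold, rotations = rotations,
                 seed = seed),
            class = "dti_split_plan")
}

#' Cold-start split plan
#'
#' Three scenarios: `"S1"` holds out a fraction of drugs with every pair
#' they appear in (cold drug); `"S2"` is symmetric for targets (cold
#' target); `"S3"` holds out a fraction of pairs subject to both endpoints
#' remaining in at least one training pair (cold pair).
#'
#' @param pairs 2-col integer matrix of (drug index, target index) positive
#'   pairs.
#' @param scenario `"S1"`, `"S2"` or `"S3"`.
#' @param fraction held-out fraction (default 0.2).
#' @param seed integer seed.
#' @return a `dti_split_plan` with `train` / `test` pair indices and, for
#'   S1/S2, the held-out entity list.
#' @export
cold_start_splits <- function(pairs, scenario = c("S1", "S2", "S3"),
                              fraction = 0.2, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(is.matrix(pairs), ncol(pairs) == 2L)
  set.seed(substream_seed(seed, paste0("cold-", scenario)))
  if (scenario %in% c("S1", "S2")) {
    col <- if (scenario == "S1") 1L else 2L
    ents <- sort(unique(pairs[, col]))
    n_hold <- max(1L, round(fraction * length(ents)))
    held <- sort(sample(ents, n_hold))
    test <- which(pairs[, col] %in% held)
    train <- setdiff(seq_len(nrow(pairs)), test)
    if (length(train) == 0L) dti_stop("cold-start split left no training pairs")
    return(structure(list(kind = scenario, train = train, test = test,
                          held_out = held, fraction = fraction, seed = seed),
                     class = "dti_split_plan"))
  }
  # S3: held-out pairs whose drug and target each survive in training
  n_hold <- max(1L, round(fraction * nrow(pairs)))
  ord <- sample(nrow(pairs))
  test <- integer(0)
  d_count <- table(factor(pairs[, 1], levels = sort(unique(pairs[, 1]))))
  t_count <- table(factor(pairs[, 2], levels = sort(unique(pairs[, 2]))))
  d_left <- as.integer(d_count); names(d_left) <- names(d_count)
  t_left <- as.integer(t_count); names(t_left) <- names(t_count)
  for (i in ord) {
    if (length(test) >= n_hold) break
    dk <- as.character(pairs[i, 1]); tk <- as.character(pairs[i, 2])
    if (d_left[dk] > 1L && t_left[tk] > 1L) {
      test <- c(test, i)
      d_left[dk] <- d_left[dk] - 1L
      t_left[tk] <- t_left[tk] - 1L
    }
  }
  if (length(test) < n_hold)
    dti_stop("cold-pair constraint unsatisfiable at fraction %.2f; try a smaller fraction",
             fraction)
  test <- sort(test)
  structure(list(kind = "S3", train = setdiff(seq_len(nrow(pairs)), test),
                 test = test, held_out = integer(0), fraction = fraction,
                 seed = seed),
            class = "dti_split_plan")
}
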