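# Independent oracles and shared fixtures. Everything here is deliberately
# brute-force and written without reference to the package internals it
# checks.

# Smith-Waterman with affine gaps (Gotoh), full DP table, score floor 0.
# A gap of length g costs gap_open + g * gap_extend.
sw_dp_oracle <- function(a, b, submat, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  M <- matrix(0, na + 1, nb + 1)   # match/mismatch ending
  X <- matrix(-Inf, na + 1, nb + 1) # gap in b (vertical)
  Y <- matrix(-Inf, na + 1, nb + 1) # gap in a (horizontal)
  best <- 0
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      s <- submat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(0,
                             s + max(M[i, j], X[i, j], Y[i, j]))
      best <- max(best, M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
    }
  }
  best
}

# all-pairs concordance AUROC: P(score_pos > score_neg) + 0.5 P(tie)
auroc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# threshold-sweep AUPR: operating points at each distinct score, step area
aupr_oracle <- function(labels, scores) {
  np <- sum(labels == 1)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  area <- 0
  for (th in thresholds) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / np
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

f1_oracle <- function(labels, scores, threshold) {
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

p_at_k_oracle <- function(labels, scores, k) {
  ord <- order(-scores, seq_along(scores))
  mean(labels[ord[seq_len(k)]])
}

# per-node aggregation loop for one convolution layer, attention off:
# z_i = act( sum_j M[i,j] z_j W  (over both blocks) + b )
conv_oracle <- function(Z_D, Z_T, graph, lay, activation = "relu") {
  m <- nrow(Z_D); n <- nrow(Z_T); h <- ncol(Z_D)
  out_D <- matrix(0, m, h); out_T <- matrix(0, n, h)
  for (i in seq_len(m)) {
    acc <- lay$b_D
    for (j in seq_len(m)) acc <- acc + graph$norm$DD[i, j] * drop(Z_D[j, ] %*% lay$W_DD)
    for (j in seq_len(n)) acc <- acc + graph$norm$DT[i, j] * drop(Z_T[j, ] %*% lay$W_DT)
    out_D[i, ] <- if (activation == "relu") pmax(acc, 0) else acc
  }
  for (i in seq_len(n)) {
    acc <- lay$b_T
    for (j in seq_len(n)) acc <- acc + graph$norm$TT[i, j] * drop(Z_T[j, ] %*% lay$W_TT)
    for (j in seq_len(m)) acc <- acc + graph$norm$TD[i, j] * drop(Z_D[j, ] %*% lay$W_TD)
    out_T[i, ] <- if (activation == "relu") pmax(acc, 0) else acc
  }
  list(Z_D = out_D, Z_T = out_T)
}

# random symmetric binary adjacency without self-loops
random_sym_adj <- function(q, p = 0.5) {
  A <- matrix(rbinom(q * q, 1, p), q, q)
  A <- ((A + t(A)) > 0) * 1
  diag(A) <- 0
  A
}

random_graph <- function(m, n, p = 0.5) {
  assemble_unified(random_sym_adj(m, p), random_sym_adj(n, p),
                   matrix(rbinom(m * n, 1, p), m, n))
}

toy_submat <- simple_substitution(match = 2, mismatch = -1,
                                  alphabet = c("A", "C", "G", "T"))

# the standard synthetic fixture, prepared once per test session
std_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- prepare_dataset(simulate_dti_dataset(seed = 7))
    }
    cache
  }
})

# small dataset for fast end-to-end training tests
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- prepare_dataset(simulate_dti_dataset(
        m = 24L, n = 18L, rank = 4L, n_drug_clusters = 3L,
        n_target_families = 3L, density = 0.2, noise = 0.05,
        seq_length_range = c(40L, 60L), seed = 11L))
    }
    cache
  }
})
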