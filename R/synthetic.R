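# Self-contained synthetic DTI datasets with the statistical structure the
# method assumes: clustered drugs and target families, a planted low-rank
# interaction matrix, cluster-structured fingerprints and sequences,
# co-membership auxiliary networks and a small ontology over the clusters.

#' Generate a synthetic drug-target interaction dataset
#'
#' Drugs and targets belong to latent clusters/families. Latent factors are
#' drawn around cluster centroids, interactions are the top `density`
#' fraction of the latent inner products `U V'` with balanced label noise
#' (a fraction `noise` of positives unlabeled and the same number of
#' negatives flipped positive, preserving density). Fingerprints are
#' cluster-prototype bit sets with per-drug bit flips; sequences are
#' family-prototype amino-acid strings with point mutations; auxiliary
#' edges follow cluster co-membership with edge noise; and the ontology is
#' a two-level tree (entity member_of cluster term, cluster term is_a root)
#' consistent with the planted clusters.
#'
#' @param m,n numbers of drugs and targets.
#' @param rank latent dimension of the planted factors.
#' @param density fraction of the m*n pairs planted positive.
#' @param noise fraction of planted labels swapped (see above).
#' @param n_drug_clusters,n_target_families cluster counts.
#' @param nbits fingerprint length.
#' @param bits_per_prototype set bits per cluster prototype fingerprint.
#' @param bit_flips per-drug random bit flips from the prototype.
#' @param seq_length_range sequence length range for family prototypes.
#' @param mutation_rate per-site mutation probability within a family.
#' @param p_within,p_between auxiliary edge probabilities within / between
#'   clusters.
#' @param centroid_sd,within_sd latent centroid and within-cluster spread.
#' @param seed integer seed; the dataset is a pure function of the
#'   arguments.
#' @return a `dti_dataset` list: ids, fingerprints, sequences, feature
#'   matrices `X_D`/`X_T`, observed `Y`, pre-noise `Y_clean`, latent `U`/`V`,
#'   cluster labels, auxiliary adjacency lists, ontology `kg`, and the
#'   generation config.
#' @export
simulate_dti_dataset <- function(m = 60L, n = 50L, rank = 8L, density = 0.15,
                                 noise = 0.05, n_drug_clusters = 5L,
                                 n_target_families = 5L, nbits = 64L,
                                 bits_per_prototype = 16L, bit_flips = 5L,
                                 seq_length_range = c(80L, 120L),
                                 mutation_rate = 0.10,
                                 p_within = 0.9, p_between = 0.02,
                                 centroid_sd = 1.0, within_sd = 0.4,
                                 seed = 7L) {
  if (density * m * n < 1) dti_stop("density too low: no positive pairs")
  set.seed(substream_seed(seed, "synthetic"))
  drug_ids <- sprintf("D%03d", seq_len(m))
  target_ids <- sprintf("T%03d", seq_len(n))
  d_cluster <- rep(seq_len(n_drug_clusters), length.out = m)
  t_family <- rep(seq_len(n_target_families), length.out = n)

  cent_D <- matrix(stats::rnorm(n_drug_clusters * rank, sd = centroid_sd),
                   n_drug_clusters, rank)
  cent_T <- matrix(stats::rnorm(n_target_families * rank, sd = centroid_sd),
                   n_target_families, rank)
  U <- cent_D[d_cluster, ] + matrix(stats::rnorm(m * rank, sd = within_sd), m, rank)
  V <- cent_T[t_family, ] + matrix(stats::rnorm(n * rank, sd = within_sd), n, rank)

  scores <- U %*% t(V)
  k_pos <- round(density * m * n)
  ord <- order(scores, decreasing = TRUE)
  Y_clean <- matrix(0L, m, n, dimnames = list(drug_ids, target_ids))
  Y_clean[ord[seq_len(k_pos)]] <- 1L
  Y <- Y_clean
  n_flip <- round(noise * k_pos)
  if (n_flip > 0L) {
    pos_idx <- which(Y == 1L)
    neg_idx <- which(Y == 0L)
    Y[sample(pos_idx, n_flip)] <- 0L
    Y[sample(neg_idx, n_flip)] <- 1L
  }

  protos <- lapply(seq_len(n_drug_clusters), function(cl)
    sort(sample.int(nbits, bits_per_prototype) - 1L))
  fingerprints <- vector("list", m)
  for (i in seq_len(m)) {
    v <- logical(nbits)
    v[protos[[d_cluster[i]]] + 1L] <- TRUE
    flip <- sample.int(nbits, bit_flips)
    v[flip] <- !v[flip]
    fingerprints[[i]] <- fingerprint(which(v) - 1L, nbits)
  }
  names(fingerprints) <- drug_ids

  seq_protos <- vapply(seq_len(n_target_families), function(fam) {
    len <- sample(seq(seq_length_range[1], seq_length_range[2]), 1L)
    paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
  }, character(1))
  sequences <- vapply(seq_len(n), function(j) {
    chars <- strsplit(seq_protos[t_family[j]], "")[[1]]
    mut <- stats::runif(length(chars)) < mutation_rate
    chars[mut] <- sample(AA_ALPHABET, sum(mut), replace = TRUE)
    paste(chars, collapse = "")
  }, character(1))
  names(sequences) <- target_ids

  co_adj <- function(labels, ids) {
    q <- length(labels)
    A <- matrix(0, q, q, dimnames = list(ids, ids))
    for (a in seq_len(q - 1L)) {
      for (b in seq(a + 1L, q)) {
        p <- if (labels[a] == labels[b]) p_within else p_between
        if (stats::runif(1) < p) { A[a, b] <- 1; A[b, a] <- 1 }
      }
    }
    A
  }
  aux_DD <- co_adj(d_cluster, drug_ids)
  aux_TT <- co_adj(t_family, target_ids)

  trip <- rbind(
    data.frame(head = drug_ids, relation = "member_of",
               tail = sprintf("DC%d", d_cluster), stringsAsFactors = FALSE),
    data.frame(head = target_ids, relation = "member_of",
               tail = sprintf("TF%d", t_family), stringsAsFactors = FALSE),
    data.frame(head = sprintf("DC%d", seq_len(n_drug_clusters)),
               relation = "is_a", tail = "DRUG_ROOT", stringsAsFactors = FALSE),
    data.frame(head = sprintf("TF%d", seq_len(n_target_families)),
               relation = "is_a", tail = "TARGET_ROOT", stringsAsFactors = FALSE))
  ents <- unique(c(rbind(trip$head, trip$tail)))
  kg <- structure(list(triples = trip,
                       relations = unique(trip$relation),
                       entity_map = stats::setNames(seq_along(ents) - 1L, ents)),
                  class = "dti_kg")

  X_D <- t(vapply(fingerprints, fingerprint_features, numeric(nbits)))
  rownames(X_D) <- drug_ids
  X_T <- t(vapply(sequences, target_features, numeric(420L)))
  rownames(X_T) <- target_ids

  structure(list(drug_ids = drug_ids, target_ids = target_ids,
                 fingerprints = fingerprints, sequences = sequences,
                 X_D = X_D, X_T = X_T,
                 Y = Y, Y_clean = Y_clean, U = U, V = V,
                 drug_cluster = d_cluster, target_family = t_family,
                 aux_DD = list(aux_DD), aux_TT = list(aux_TT), kg = kg,
                 config = list(m = m, n = n, rank = rank, density = density,
                               noise = noise,
                               n_drug_clusters = n_drug_clusters,
                               n_target_families = n_target_families,
                               nbits = nbits, seed = seed)),
            class = "dti_dataset")
}

#' Write a synthetic dataset in the package's on-disk formats
#'
#' Emits exactly the files the readers consume: `drugs.tsv` (id + feature
#' bit columns), `targets.fasta`, `interactions.tsv` (positive pairs;
#' unlisted pairs are unlabeled), `triples.tsv`, auxiliary edge lists, and a
#' `truth.json` manifest with the latent factors and pre-noise labels.
#'
#' @param dataset a `dti_dataset`.
#' @param directory output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixture <- function(dataset, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  X <- dataset$X_D
  drug_tab <- data.frame(id = dataset$drug_ids, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(X))) drug_tab[[paste0("f", j)]] <- X[, j]
  utils::write.table(drug_tab, file.path(directory, "drugs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste0(">", dataset$target_ids, "\n", dataset$sequences),
             file.path(directory, "targets.fasta"))
  pos <- which(dataset$Y == 1L, arr.ind = TRUE)
  pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE]
  utils::write.table(
    data.frame(drug_id = dataset$drug_ids[pos[, 1]],
               target_id = dataset$target_ids[pos[, 2]]),
    file.path(directory, "interactions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$kg$triples, file.path(directory, "triples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  edge_list <- function(A, ids) {
    w <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
    data.frame(a = ids[w[, 1]], b = ids[w[, 2]])
  }
  utils::write.table(edge_list(dataset$aux_DD[[1]], dataset$drug_ids),
                     file.path(directory, "aux_drug_drug.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(edge_list(dataset$aux_TT[[1]], dataset$target_ids),
                     file.path(directory, "aux_target_target.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(U = dataset$U, V = dataset$V,
                positives_clean = which(dataset$Y_clean == 1L),
                drug_cluster = dataset$drug_cluster,
                target_family = dataset$target_family,
                config = dataset$config)
  jsonlite::write_json(truth, file.path(directory, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

#' Load a dataset written by [write_fixture()]
#' @param directory fixture directory.
#' @return a `dti_dataset` (without latent truth unless `truth.json` is
#'   present).
#' @export
load_fixture <- function(directory) {
  drugs <- read_drug_table(file.path(directory, "drugs.tsv"))
  targets <- read_fasta_targets(file.path(directory, "targets.fasta"))
  inter <- read_interactions(file.path(directory, "interactions.tsv"),
                             drugs, targets)
  kg <- read_kg_triples(file.path(directory, "triples.tsv"))
  drug_ids <- vapply(drugs, `[[`, character(1), "id")
  target_ids <- vapply(targets, `[[`, character(1), "id")
  X_D <- do.call(rbind, lapply(drugs, `[[`, "features"))
  rownames(X_D) <- drug_ids
  fingerprints <- lapply(seq_len(nrow(X_D)), function(i)
    fingerprint(which(X_D[i, ] != 0) - 1L, ncol(X_D)))
  names(fingerprints) <- drug_ids
  sequences <- vapply(targets, `[[`, character(1), "sequence")
  names(sequences) <- target_ids
  X_T <- t(vapply(sequences, target_features, numeric(420L)))
  rownames(X_T) <- target_ids
  Y <- matrix(0L, length(drug_ids), length(target_ids),
              dimnames = list(drug_ids, target_ids))
  Y[cbind(match(inter$pairs$drug_id, drug_ids),
          match(inter$pairs$target_id, target_ids))] <- inter$pairs$label
  read_edges <- function(path, ids) {
    A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    if (file.exists(path)) {
      e <- utils::read.delim(path, stringsAsFactors = FALSE)
      A[cbind(match(e$a, ids), match(e$b, ids))] <- 1
      A[cbind(match(e$b, ids), match(e$a, ids))] <- 1
    }
    A
  }
  aux_DD <- read_edges(file.path(directory, "aux_drug_drug.tsv"), drug_ids)
  aux_TT <- read_edges(file.path(directory, "aux_target_target.tsv"), target_ids)
  out <- list(drug_ids = drug_ids, target_ids = target_ids,
              fingerprints = fingerprints, sequences = sequences,
              X_D = X_D, X_T = X_T, Y = Y, kg = kg,
              aux_DD = list(aux_DD), aux_TT = list(aux_TT))
  truth_path <- file.path(directory, "truth.json")
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    out$U <- truth$U; out$V <- truth$V
    out$drug_cluster <- truth$drug_cluster
    out$target_family <- truth$target_family
    out$config <- truth$config
    Yc <- matrix(0L, length(drug_ids), length(target_ids))
    Yc[truth$positives_clean] <- 1L
    out$Y_clean <- Yc
  }
  structure(out, class = "dti_dataset")
}
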