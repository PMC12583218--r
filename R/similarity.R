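#' Tanimoto coefficient between two fingerprints
#'
#' `|A intersect B| / |A union B|` over set-bit positions. Two empty
#' fingerprints have similarity 0 by convention (not 1), so featureless
#' molecules are never declared identical.
#'
#' @param fp_a,fp_b `dti_fingerprint` objects with equal `nbits`.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(fp_a, fp_b) {
  stopifnot(inherits(fp_a, "dti_fingerprint"), inherits(fp_b, "dti_fingerprint"))
  if (fp_a$nbits != fp_b$nbits)
    dti_stop("fingerprint length mismatch: %d vs %d", fp_a$nbits, fp_b$nbits)
  inter <- length(intersect(fp_a$bits, fp_b$bits))
  uni <- length(union(fp_a$bits, fp_b$bits))
  if (uni == 0L) return(0)
  inter / uni
}

#' Pairwise similarity matrix over one entity class
#'
#' Applies a symmetric pairwise measure to every entity pair and returns a
#' symmetric matrix with unit diagonal. The measure is only evaluated on the
#' upper triangle; failures are reported with the offending pair.
#'
#' @param entities list of entities (each must carry an `id`).
#' @param pairwise_measure function(entity_i, entity_j) -> similarity in [0,1].
#' @param measure_tag label stored on the result (`"chemical"`, `"sequence"`,
#'   or `"custom"`).
#' @return a numeric matrix with `measure` attribute and entity ids as
#'   dimnames.
#' @export
build_similarity_matrix <- function(entities, pairwise_measure,
                                    measure_tag = "custom") {
  n <- length(entities)
  if (n < 1L) dti_stop("need at least one entity")
  ids <- vapply(entities, function(e) e$id, character(1))
  S <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        v <- tryCatch(pairwise_measure(entities[[i]], entities[[j]]),
                      error = function(e)
                        dti_stop("similarity failed for pair (%s, %s): %s",
                                 ids[i], ids[j], conditionMessage(e)))
        if (!is.finite(v) || v < 0 || v > 1)
          dti_stop("similarity for pair (%s, %s) outside [0,1]", ids[i], ids[j])
        S[i, j] <- v
        S[j, i] <- v
      }
    }
  }
  dimnames(S) <- list(ids, ids)
  attr(S, "measure") <- measure_tag
  S
}

#' Chemical similarity matrix from fingerprints
#' @param fingerprints list of `dti_fingerprint`, with names used as ids.
#' @return symmetric Tanimoto matrix with unit diagonal.
#' @export
fingerprint_similarity_matrix <- function(fingerprints) {
  ids <- names(fingerprints)
  if (is.null(ids)) ids <- paste0("D", seq_along(fingerprints))
  ents <- Map(function(fp, id) list(id = id, fp = fp), fingerprints, ids)
  build_similarity_matrix(ents, function(a, b) tanimoto(a$fp, b$fp),
                          measure_tag = "chemical")
}

#' Sequence similarity matrix from target sequences
#' @param sequences character vector of sequences, names used as ids.
#' @inheritParams smith_waterman
#' @return symmetric normalized Smith-Waterman matrix with unit diagonal.
#' @export
sequence_similarity_matrix <- function(sequences, substitution = "BLOSUM62",
                                       gap_open = 11, gap_extend = 1) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("T", seq_along(sequences))
  n <- length(sequences)
  # precompute self-alignment scores once: SWmax = min(self_i, self_j)
  selfs <- vapply(seq_len(n), function(i)
    smith_waterman(sequences[[i]], sequences[[i]], substitution,
                   gap_open, gap_extend), numeric(1))
  S <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        sw_max <- min(selfs[i], selfs[j])
        v <- if (sw_max <= 0) 0 else
          min(1, max(0, smith_waterman(sequences[[i]], sequences[[j]],
                                       substitution, gap_open, gap_extend) / sw_max))
        S[i, j] <- v; S[j, i] <- v
      }
    }
  }
  dimnames(S) <- list(ids, ids)
  attr(S, "measure") <- "sequence"
  S
}
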