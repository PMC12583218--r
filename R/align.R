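#' Smith-Waterman local alignment score
#'
#' Optimal local-alignment score with affine gap penalties (a gap of length
#' `g` costs `gap_open + g * gap_extend`). The substitution model is either
#' `"BLOSUM62"` or an explicit symmetric scoring matrix with single-letter
#' row/column names (e.g. a toy +2/-1 matrix). Scores are floored at zero,
#' the local-alignment convention.
#'
#' @param seq_a,seq_b sequences (character strings).
#' @param substitution `"BLOSUM62"` (default) or a numeric scoring matrix.
#' @param gap_open,gap_extend nonnegative gap penalties.
#' @return nonnegative alignment score.
#' @export
smith_waterman <- function(seq_a, seq_b, substitution = "BLOSUM62",
                           gap_open = 11, gap_extend = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    dti_warn("empty sequence in smith_waterman; score 0")
    return(0)
  }
  submat <- resolve_substitution(substitution)
  score <- Biostrings::pairwiseAlignment(
    Biostrings::BString(toupper(seq_a)), Biostrings::BString(toupper(seq_b)),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local", scoreOnly = TRUE)
  max(0, score)
}

resolve_substitution <- function(substitution) {
  if (is.matrix(substitution)) return(substitution)
  if (identical(substitution, "BLOSUM62")) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    return(env$BLOSUM62)
  }
  dti_stop("unknown substitution model '%s'", substitution)
}

#' Simple match/mismatch scoring matrix over an alphabet
#' @param match,mismatch scores; @param alphabet letters.
#' @return square scoring matrix.
#' @export
simple_substitution <- function(match = 2, mismatch = -1,
                                alphabet = c("A", "C", "G", "T")) {
  m <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

#' Normalized sequence similarity in [0, 1]
#'
#' `SW(a, b) / SWmax` where `SWmax = min(SW(a, a), SW(b, b))`, the smaller
#' of the two self-alignment scores; this guarantees self-similarity 1 and
#' values in `[0, 1]` (clipped). If `SWmax` is 0 the similarity is 0.
#'
#' @inheritParams smith_waterman
#' @return similarity in [0, 1].
#' @export
normalized_seq_similarity <- function(seq_a, seq_b, substitution = "BLOSUM62",
                                      gap_open = 11, gap_extend = 1) {
  saa <- smith_waterman(seq_a, seq_a, substitution, gap_open, gap_extend)
  sbb <- smith_waterman(seq_b, seq_b, substitution, gap_open, gap_extend)
  sw_max <- min(saa, sbb)
  if (sw_max <= 0) return(0)
  sab <- smith_waterman(seq_a, seq_b, substitution, gap_open, gap_extend)
  min(1, max(0, sab / sw_max))
}
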