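#' Construct a fingerprint object from set-bit positions
#'
#' @param bits integer vector of set-bit positions (0-based, in `[0, nbits)`).
#' @param nbits total fingerprint length.
#' @return a `dti_fingerprint` object.
#' @export
fingerprint <- function(bits, nbits = 2048L) {
  bits <- sort(unique(as.integer(bits)))
  if (length(bits) && (min(bits) < 0L || max(bits) >= nbits))
    dti_stop("fingerprint bit positions must lie in [0, nbits)")
  structure(list(bits = bits, nbits = as.integer(nbits)), class = "dti_fingerprint")
}

# FNV-1a style string hash into [0, nbits)
hash_token <- function(token, nbits) {
  h <- 2166136261
  for (code in utf8ToInt(token)) {
    h <- bitwXor(as.integer(h %% 2147483647), code)
    h <- (as.double(h) * 16777619) %% 2147483647
  }
  as.integer(h %% nbits)
}

#' Hashed circular fingerprint of a molecule
#'
#' Computes a hashed substructure fingerprint from a SMILES string. The
#' default `"kmer"` backend hashes all overlapping character k-mers
#' (k = radius + 1) of the canonicalized SMILES text into `nbits` buckets;
#' it is deterministic, dependency-free and preserves the property that
#' structurally similar strings share many set bits, which is all the
#' similarity pipeline relies on. Synthetic datasets carry explicit bit-set
#' fingerprints and bypass this function.
#'
#' @param smiles SMILES string.
#' @param radius neighborhood radius (k-mer length = radius + 1).
#' @param nbits fingerprint length.
#' @param backend currently `"kmer"`.
#' @param id optional drug id used in error messages.
#' @return a `dti_fingerprint`.
#' @export
circular_fingerprint <- function(smiles, radius = 2L, nbits = 2048L,
                                 backend = "kmer", id = NULL) {
  backend <- match.arg(backend, "kmer")
  if (is.null(smiles) || is.na(smiles) || !nzchar(smiles))
    dti_stop("cannot fingerprint drug %s: missing or empty SMILES",
             if (is.null(id)) "<unnamed>" else id)
  k <- radius + 1L
  s <- gsub("\\s+", "", smiles)
  n <- nchar(s)
  toks <- character(0)
  # include shorter prefixes so molecules shorter than k still hash
  for (kk in seq_len(min(k, n))) {
    starts <- seq_len(n - kk + 1L)
    toks <- c(toks, substring(s, starts, starts + kk - 1L))
  }
  bits <- vapply(unique(toks), hash_token, integer(1), nbits = nbits)
  fingerprint(bits, nbits)
}

#' Amino-acid composition + dipeptide frequency features for a target
#'
#' The default raw target feature vector: the 20 amino-acid frequencies
#' followed by the 400 dipeptide (2-mer) frequencies, each block summing to
#' one for a non-empty sequence. `X` residues are ignored.
#'
#' @param sequence amino-acid sequence string.
#' @return numeric vector of length 420.
#' @export
target_features <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  chars <- chars[chars %in% AA_ALPHABET]
  comp <- table(factor(chars, levels = AA_ALPHABET))
  comp <- as.numeric(comp) / max(1L, length(chars))
  dimer_levels <- as.vector(outer(AA_ALPHABET, AA_ALPHABET, paste0))
  if (length(chars) >= 2L) {
    dimers <- paste0(chars[-length(chars)], chars[-1L])
    dim_tab <- table(factor(dimers, levels = dimer_levels))
    dim_freq <- as.numeric(dim_tab) / length(dimers)
  } else {
    dim_freq <- numeric(400L)
  }
  c(comp, dim_freq)
}

#' Fingerprint bit vector as a dense 0/1 feature row
#' @param fp a `dti_fingerprint`.
#' @return numeric vector of length `fp$nbits`.
#' @export
fingerprint_features <- function(fp) {
  stopifnot(inherits(fp, "dti_fingerprint"))
  v <- numeric(fp$nbits)
  v[fp$bits + 1L] <- 1
  v
}
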