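#' Read a drug table
#'
#' Reads a tab-separated drug table with a header. The file must contain an
#' `id` column and either a `smiles` column, numeric feature columns
#' (any column whose name starts with `f`followed by digits, e.g. `f1..f64`),
#' or both. Entities are indexed in file order (0-based), which fixes the row
#' meaning of every downstream matrix.
#'
#' @param path path to a TSV file with header columns `id`, `smiles` and/or
#'   feature columns.
#' @return a list of `dti_drug` objects, each with fields `id`, `smiles`
#'   (possibly `NA`), `features` (numeric vector or `NULL`) and 0-based
#'   `index`.
#' @export
read_drug_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"id" %in% names(tab)) dti_stop("drug table %s lacks an 'id' column", path)
  ids <- as.character(tab$id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) dti_stop("duplicate drug id(s): %s", paste(dup, collapse = ", "))
  feat_cols <- grep("^f[0-9]+$", names(tab), value = TRUE)
  if (!("smiles" %in% names(tab)) && length(feat_cols) == 0L && nrow(tab) > 0L)
    dti_stop("drug table needs a 'smiles' column or feature columns f1..fk")
  drugs <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    feats <- if (length(feat_cols)) as.numeric(tab[i, feat_cols]) else NULL
    if (!is.null(feats)) check_finite(feats, sprintf("features of drug %s", ids[i]))
    drugs[[i]] <- structure(
      list(id = ids[i],
           smiles = if ("smiles" %in% names(tab)) as.character(tab$smiles[i]) else NA_character_,
           features = feats,
           index = i - 1L),
      class = "dti_drug")
  }
  drugs
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read target sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header line.
#' Sequences are uppercased; characters outside the 20-letter amino-acid
#' alphabet are kept as `X` (with a warning naming the record).
#'
#' @param path path to a FASTA file.
#' @return a list of `dti_target` objects with fields `id`, `sequence`,
#'   `features` (`NULL` until featurized) and 0-based `index`.
#' @export
read_fasta_targets <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) && any(Biostrings::width(seqs) == 0L)) {
    bad <- names(seqs)[Biostrings::width(seqs) == 0L][1]
    dti_stop("FASTA record '%s' has an empty sequence", bad)
  }
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) dti_stop("duplicate target id(s): %s", paste(dup, collapse = ", "))
  targets <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- toupper(as.character(seqs[[i]]))
    chars <- strsplit(s, "")[[1]]
    illegal <- !(chars %in% c(AA_ALPHABET, "X"))
    if (any(illegal)) {
      dti_warn("target %s: %d non-amino-acid character(s) replaced by X",
               ids[i], sum(illegal))
      chars[illegal] <- "X"
      s <- paste(chars, collapse = "")
    }
    targets[[i]] <- structure(
      list(id = ids[i], sequence = s, features = NULL, index = i - 1L),
      class = "dti_target")
  }
  targets
}

#' Read a drug-target interaction edge list
#'
#' Reads a TSV with header columns `drug_id`, `target_id` and optional
#' `label` and `confidence` columns. A missing label column means every
#' listed pair is a positive; unlisted pairs are unlabeled (the
#' positive-unlabeled framing). The confidence column is parsed and stored
#' but not consumed by any loss.
#'
#' @param path path to the TSV file.
#' @param drugs,targets entity lists from [read_drug_table()] /
#'   [read_fasta_targets()] used to resolve ids.
#' @return a `dti_interactions` object: data.frame `pairs` with columns
#'   `drug_id`, `target_id`, `label`, plus optional `confidence`.
#' @export
read_interactions <- function(path, drugs, targets) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("drug_id", "target_id")
  if (!all(need %in% names(tab)))
    dti_stop("interaction table %s needs columns drug_id, target_id", path)
  drug_ids <- vapply(drugs, `[[`, character(1), "id")
  target_ids <- vapply(targets, `[[`, character(1), "id")
  bad_d <- which(!(tab$drug_id %in% drug_ids))
  if (length(bad_d))
    dti_stop("unknown drug id '%s' at row %d", tab$drug_id[bad_d[1]], bad_d[1])
  bad_t <- which(!(tab$target_id %in% target_ids))
  if (length(bad_t))
    dti_stop("unknown target id '%s' at row %d", tab$target_id[bad_t[1]], bad_t[1])
  label <- if ("label" %in% names(tab)) as.integer(tab$label) else rep(1L, nrow(tab))
  if (length(label) && !all(label %in% c(0L, 1L)))
    dti_stop("labels must be 0/1 in %s", path)
  key <- paste(tab$drug_id, tab$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    conflicting <- tapply(label, key, function(v) length(unique(v)) > 1L)
    if (any(conflicting))
      dti_stop("pair listed with conflicting labels: %s",
               gsub("\r", " / ", names(conflicting)[conflicting][1]))
    keep <- !duplicated(key)
    tab <- tab[keep, , drop = FALSE]
    label <- label[keep]
  }
  out <- list(pairs = data.frame(drug_id = tab$drug_id,
                                 target_id = tab$target_id,
                                 label = label,
                                 stringsAsFactors = FALSE),
              confidence = if ("confidence" %in% names(tab)) as.numeric(tab$confidence) else NULL)
  if (!is.null(out$confidence) &&
      any(out$confidence < 0 | out$confidence > 1, na.rm = TRUE))
    dti_stop("confidence values must lie in [0,1]")
  structure(out, class = "dti_interactions")
}

#' Read knowledge-graph triples
#'
#' Reads a TSV with header columns `head`, `relation`, `tail`. Duplicated
#' triples are collapsed; the entity map covers every mentioned head and
#' tail entity in first-appearance order.
#'
#' @param path path to the TSV file.
#' @return a `dti_kg` object: data.frame `triples`, character `relations`,
#'   named integer `entity_map` (0-based embedding indices).
#' @export
read_kg_triples <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("head", "relation", "tail") %in% names(tab)))
    dti_stop("triple table %s needs columns head, relation, tail", path)
  blank <- which(tab$head == "" | tab$relation == "" | tab$tail == "" |
                   is.na(tab$head) | is.na(tab$relation) | is.na(tab$tail))
  if (length(blank)) dti_stop("blank field in triple file at row %d", blank[1])
  key <- paste(tab$head, tab$relation, tab$tail, sep = "\r")
  tab <- tab[!duplicated(key), , drop = FALSE]
  ents <- unique(c(rbind(tab$head, tab$tail)))
  entity_map <- stats::setNames(seq_along(ents) - 1L, ents)
  structure(list(triples = data.frame(head = tab$head, relation = tab$relation,
                                      tail = tab$tail, stringsAsFactors = FALSE),
                 relations = unique(tab$relation),
                 entity_map = entity_map),
            class = "dti_kg")
}

#' Write scored predictions
#'
#' Writes a TSV of `(drug_id, target_id, score)` rows sorted by descending
#' score; ties are broken by `(drug_id, target_id)` lexicographic order so
#' output is deterministic.
#'
#' @param scored_pairs data.frame with columns `drug_id`, `target_id`, `score`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_predictions <- function(scored_pairs, path) {
  stopifnot(all(c("drug_id", "target_id", "score") %in% names(scored_pairs)))
  if (!all(is.finite(scored_pairs$score)))
    dti_stop("non-finite prediction score(s)")
  ord <- order(-scored_pairs$score, scored_pairs$drug_id, scored_pairs$target_id)
  utils::write.table(scored_pairs[ord, c("drug_id", "target_id", "score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an interaction table (round-trip partner of [read_interactions()])
#' @param interactions a `dti_interactions` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  tab <- interactions$pairs
  if (!is.null(interactions$confidence)) tab$confidence <- interactions$confidence
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
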