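AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Apply a missense mutation to a protein sequence
#'
#' Substitutes a single residue, checking that the reference residue at the
#' stated 1-based position matches before substituting.
#'
#' @param protein amino-acid sequence (single string, 20-letter alphabet).
#' @param position 1-based residue index.
#' @param ref_aa,alt_aa single-letter reference and alternate residues
#'   (must differ).
#' @return the mutant sequence (same length).
#' @export
apply_missense <- function(protein, position, ref_aa, alt_aa) {
  if (!ref_aa %in% AA_ALPHABET || !alt_aa %in% AA_ALPHABET)
    stop("ref_aa and alt_aa must be single-letter amino acids", call. = FALSE)
  if (ref_aa == alt_aa) stop("ref_aa and alt_aa must differ", call. = FALSE)
  n <- nchar(protein)
  if (position < 1L || position > n)
    stop(sprintf("position %d out of range for protein of length %d", position, n),
         call. = FALSE)
  found <- substr(protein, position, position)
  if (found != ref_aa)
    stop(sprintf("reference mismatch at position %d: expected '%s', found '%s'",
                 position, ref_aa, found), call. = FALSE)
  paste0(substr(protein, 1L, position - 1L), alt_aa,
         substr(protein, position + 1L, n))
}

#' Enumerate candidate neo-antigen peptides around a mutated residue
#'
#' Generates every peptide of the requested lengths (9-11 by default, the
#' MHC class I range) that lies fully inside the mutant protein and
#' contains the mutated residue, so the variant appears in each possible
#' position of each window. Candidates are ordered by length then start
#' position, and duplicates are kept once per (sequence, length).
#'
#' @param mutant_protein the mutated amino-acid sequence.
#' @param position 1-based index of the mutated residue.
#' @param lengths peptide lengths to enumerate.
#' @param mutation_id optional identifier carried into the output.
#' @return data frame: \code{sequence}, \code{length},
#'   \code{mutated_offset} (1-based position of the variant within the
#'   peptide), \code{start} (1-based within the protein),
#'   \code{mutation_id}. Zero rows (with a warning) when the protein is
#'   shorter than the smallest requested length.
#' @export
enumerate_mutant_peptides <- function(mutant_protein, position,
                                      lengths = c(9L, 10L, 11L),
                                      mutation_id = NA_character_) {
  n <- nchar(mutant_protein)
  if (position < 1L || position > n)
    stop(sprintf("position %d out of range for protein of length %d", position, n),
         call. = FALSE)
  empty <- data.frame(sequence = character(), length = integer(),
                      mutated_offset = integer(), start = integer(),
                      mutation_id = character(), stringsAsFactors = FALSE)
  if (n < min(lengths)) {
    warning(sprintf("protein length %d is below the minimum peptide length %d",
                    n, min(lengths)), call. = FALSE)
    return(empty)
  }
  out <- list()
  for (k in sort(lengths)) {
    if (n < k) next
    starts <- max(1L, position - k + 1L):min(position, n - k + 1L)
    for (st in starts) {
      out[[length(out) + 1L]] <- data.frame(
        sequence = substr(mutant_protein, st, st + k - 1L),
        length = k, mutated_offset = position - st + 1L, start = st,
        mutation_id = mutation_id, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out, list(empty)))
  res[!duplicated(res[, c("sequence", "length")]), , drop = FALSE]
}

#' Enumerate mutant and wild-type peptides for a mutation table
#'
#' Applies each missense mutation to its protein and enumerates candidate
#' windows; the corresponding wild-type peptide for each window is emitted
#' alongside the mutant for downstream affinity prediction of both.
#'
#' @param proteins named character vector of protein sequences (names are
#'   protein ids), e.g. from [read_protein_fasta()].
#' @param mutations data frame with columns \code{protein_id},
#'   \code{position}, \code{ref_aa}, \code{alt_aa}.
#' @return data frame with the columns of [enumerate_mutant_peptides()]
#'   plus \code{wt_sequence} and \code{protein_id}.
#' @export
enumerate_neoantigen_candidates <- function(proteins, mutations) {
  stopifnot(all(c("protein_id", "position", "ref_aa", "alt_aa") %in% names(mutations)))
  out <- vector("list", nrow(mutations))
  for (i in seq_len(nrow(mutations))) {
    m <- mutations[i, ]
    wt <- proteins[[m$protein_id]]
    if (is.null(wt) || is.na(wt))
      stop(sprintf("protein '%s' not found", m$protein_id), call. = FALSE)
    mut <- apply_missense(wt, m$position, m$ref_aa, m$alt_aa)
    cand <- enumerate_mutant_peptides(mut, m$position,
                                      mutation_id = sprintf("%s:%s%d%s", m$protein_id,
                                                            m$ref_aa, m$position, m$alt_aa))
    if (nrow(cand)) {
      cand$wt_sequence <- substr(rep(wt, nrow(cand)), cand$start,
                                 cand$start + cand$length - 1L)
      cand$protein_id <- m$protein_id
    }
    out[[i]] <- cand
  }
  do.call(rbind, out)
}

#' Filter predicted binders
#'
#' Keeps the affinity records with predicted IC50 strictly below the
#' threshold (default 500 nM), the criterion for candidate neo-antigens.
#'
#' @param records data frame with a \code{predicted_ic50} column (nM, > 0).
#' @param threshold_nM strict upper bound.
#' @return the qualifying rows.
#' @export
filter_binders <- function(records, threshold_nM = 500) {
  stopifnot(is.data.frame(records), "predicted_ic50" %in% names(records))
  if (nrow(records) && any(records$predicted_ic50 <= 0))
    stop("predicted IC50 values must be positive", call. = FALSE)
  records[records$predicted_ic50 < threshold_nM, , drop = FALSE]
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return named character vector (first word of each header as the id).
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1L), 1L)
  seqs
}

#' Read a missense-mutation table
#'
#' TSV with columns \code{protein_id}, \code{position}, \code{ref_aa},
#' \code{alt_aa}.
#'
#' @param path TSV file path.
#' @return validated data frame.
#' @export
read_mutations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("protein_id", "position", "ref_aa", "alt_aa") %in% names(df)))
  ok <- df$ref_aa %in% AA_ALPHABET & df$alt_aa %in% AA_ALPHABET & df$ref_aa != df$alt_aa
  if (!all(ok))
    stop(sprintf("invalid mutation row(s): %s", paste(which(!ok), collapse = ", ")),
         call. = FALSE)
  df
}
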