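# Sequence input, validation and composition features.

#' The 20 standard amino acids, alphabetical by one-letter code
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The 400 ordered dipeptides
#'
#' All ordered pairs XY over the 20 standard amino acids, in row-major
#' alphabetical order (AA, AC, ..., YY). This ordering is the gene order of a
#' scoring card and the column order of every dipeptide-composition vector.
#' @export
DIPEPTIDES400 <- as.vector(t(outer(AA_ALPHABET20, AA_ALPHABET20, paste0)))

#' Validate protein sequences
#'
#' Upper-cases input and checks that every residue is one of the 20 standard
#' one-letter codes and that each sequence has length >= 2 (so at least one
#' dipeptide exists).
#'
#' @param seqs character vector of sequences (possibly named by id).
#' @return list with `seqs` (upper-cased), `valid` (logical), and
#'   `bad_char` (first offending character per sequence, NA if none).
#' @keywords internal
validate_sequences <- function(seqs) {
  seqs <- toupper(seqs)
  bad_char <- vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- ch[!ch %in% AA_ALPHABET20]
    if (length(bad)) bad[1] else NA_character_
  }, character(1), USE.NAMES = FALSE)
  valid <- is.na(bad_char) & nchar(seqs) >= 2L
  list(seqs = seqs, valid = valid, bad_char = bad_char)
}

#' Read protein sequences from a FASTA file
#'
#' Reads a (possibly multi-line) amino-acid FASTA file. Record ids are the
#' header token before the first whitespace. Sequences are upper-cased and
#' validated against the 20 standard one-letter codes; records shorter than
#' two residues or containing non-standard letters (B, J, O, U, X, Z, `*`,
#' gaps, ...) are invalid.
#'
#' @param path path to a FASTA file.
#' @param policy `"reject"` (default) errors on the first invalid record,
#'   naming the id and the offending character; `"skip"` drops invalid
#'   records, recording how many under `attr(, "n_skipped")` and their ids
#'   under `attr(, "skipped_ids")`.
#' @return named character vector of sequences, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 a heme protein", "MCHACP", ">p2", "GGAVLK"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, policy = c("reject", "skip")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  v <- validate_sequences(as.character(set))
  seqs <- stats::setNames(v$seqs, ids)
  if (all(v$valid)) return(seqs)
  if (policy == "reject") {
    i <- which(!v$valid)[1]
    if (!is.na(v$bad_char[i]))
      stop("invalid record '", ids[i], "': non-standard amino acid character '",
           v$bad_char[i], "'")
    stop("invalid record '", ids[i], "': sequence shorter than 2 residues")
  }
  out <- seqs[v$valid]
  attr(out, "n_skipped") <- sum(!v$valid)
  attr(out, "skipped_ids") <- ids[!v$valid]
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

count_dipeptides <- function(seq) {
  l <- nchar(seq)
  if (l < 2L) stop("sequence shorter than 2 residues")
  di <- paste0(substring(seq, 1:(l - 1L), 1:(l - 1L)),
               substring(seq, 2:l, 2:l))
  tab <- table(factor(di, levels = DIPEPTIDES400))
  stats::setNames(as.numeric(tab), DIPEPTIDES400)
}

count_residues <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  tab <- table(factor(ch, levels = AA_ALPHABET20))
  stats::setNames(as.numeric(tab), AA_ALPHABET20)
}

#' Dipeptide composition (DPC) of a sequence
#'
#' Frequencies of the L-1 overlapping adjacent residue pairs of a sequence of
#' length L, over the 400 ordered dipeptides. Values are non-negative and sum
#' to 1.
#'
#' @param seq a single validated sequence (length >= 2).
#' @return named numeric vector of length 400 in [`DIPEPTIDES400`] order.
#' @examples
#' dipeptide_composition("ACAC")[c("AC", "CA")]  # 2/3, 1/3
#' @export
dipeptide_composition <- function(seq) {
  cnt <- count_dipeptides(toupper(seq))
  cnt / sum(cnt)
}

#' Amino-acid composition (AAC) of a sequence
#'
#' @param seq a single non-empty validated sequence.
#' @return named numeric vector of length 20, summing to 1.
#' @export
amino_acid_composition <- function(seq) {
  if (nchar(seq) < 1L) stop("empty sequence")
  cnt <- count_residues(toupper(seq))
  cnt / sum(cnt)
}

#' Class-level dipeptide composition of a sequence set
#'
#' The class "content" used to seed an initial scoring card. With
#' `method = "pooled"` (default) dipeptide counts are pooled over all
#' sequences before normalizing, so long sequences carry proportionally more
#' weight, matching compositions reported over total residue counts. With
#' `method = "mean"` the per-sequence DPC fractions are averaged instead.
#'
#' @param seqs character vector of sequences.
#' @param method `"pooled"` or `"mean"`.
#' @return named numeric vector of length 400 summing to 1.
#' @export
pooled_dipeptide_composition <- function(seqs, method = c("pooled", "mean")) {
  method <- match.arg(method)
  if (length(seqs) == 0L) stop("no sequences")
  if (method == "pooled") {
    cnt <- rowSums(vapply(seqs, count_dipeptides, numeric(400)))
    cnt / sum(cnt)
  } else {
    rowMeans(vapply(seqs, dipeptide_composition, numeric(400)))
  }
}

#' Class-level amino-acid composition of a sequence set
#'
#' @inheritParams pooled_dipeptide_composition
#' @return named numeric vector of length 20 summing to 1.
#' @export
pooled_amino_acid_composition <- function(seqs, method = c("pooled", "mean")) {
  method <- match.arg(method)
  if (length(seqs) == 0L) stop("no sequences")
  if (method == "pooled") {
    cnt <- rowSums(vapply(seqs, count_residues, numeric(20)))
    cnt / sum(cnt)
  } else {
    rowMeans(vapply(seqs, amino_acid_composition, numeric(20)))
  }
}

#' Dipeptide-composition matrix of a sequence set
#'
#' One row per sequence, one column per dipeptide; each row sums to 1. This
#' is the design matrix used by scoring and by the optimizer (scoring a whole
#' dataset against a card is then a single matrix-vector product).
#'
#' @param seqs character vector of sequences.
#' @return numeric matrix `length(seqs)` x 400 with dipeptide column names.
#' @export
dpc_matrix <- function(seqs) {
  m <- t(vapply(seqs, dipeptide_composition, numeric(400)))
  rownames(m) <- names(seqs)
  m
}
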