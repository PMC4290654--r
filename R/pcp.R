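# AAindex parsing and physicochemical-property (PCP) analysis of amino-acid
# propensities.

# canonical AAindex value order within a record
AAINDEX_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Parse an AAindex1 flat file
#'
#' Records are delimited by `//`; the accession follows `H`, the description
#' follows `D`, and the 20 per-amino-acid values sit on the two lines after
#' the `I` header in A/R/N/D/C/Q/E/G/H/I then L/K/M/F/P/S/T/W/Y/V order.
#' `NA` tokens mark missing values and set `complete = FALSE`. Values are
#' re-indexed alphabetically by one-letter code.
#'
#' @param path path to an AAindex1-format file.
#' @return list of entries, each a list with `accession`, `description`,
#'   `values` (named 20-vector, alphabetical), `complete`.
#' @export
parse_aaindex <- function(path) {
  if (!file.exists(path)) stop("AAindex file not found: ", path)
  lines <- readLines(path)
  rec_end <- which(lines == "//")
  start <- 1L
  entries <- list()
  for (end in rec_end) {
    rec <- lines[start:(end - 1L)]
    start <- end + 1L
    if (!length(rec)) next
    acc_line <- grep("^H ", rec, value = TRUE)
    acc <- if (length(acc_line)) sub("^H +", "", acc_line[1]) else "<unknown>"
    desc_line <- grep("^D ", rec, value = TRUE)
    desc <- if (length(desc_line)) sub("^D +", "", desc_line[1]) else ""
    i_at <- grep("^I", rec)
    if (!length(i_at) || i_at[1] + 2L > length(rec))
      stop("malformed AAindex record '", acc, "': missing value lines")
    toks <- unlist(strsplit(trimws(rec[i_at[1] + 1:2]), "\\s+"))
    if (length(toks) != 20L)
      stop("malformed AAindex record '", acc, "': expected 20 values, got ",
           length(toks))
    vals <- suppressWarnings(as.numeric(ifelse(toks == "NA", NA, toks)))
    if (any(is.na(vals) & toks != "NA"))
      stop("malformed AAindex record '", acc, "': non-numeric value")
    names(vals) <- AAINDEX_ORDER
    vals <- vals[AA_ALPHABET20]
    entries[[length(entries) + 1L]] <-
      list(accession = acc, description = desc, values = vals,
           complete = !anyNA(vals))
  }
  entries
}

#' Correlate amino-acid propensities against AAindex entries
#'
#' Pearson R between a 20-vector of amino-acid propensities (or
#' compositions) and every complete AAindex entry, ranked by |R| descending
#' (ties by accession). Entries with zero variance are skipped with a
#' message; incomplete entries are skipped silently.
#'
#' @param propensities named 20-vector (amino-acid one-letter names).
#' @param entries output of [parse_aaindex()].
#' @param candidate_cutoff |R| above which an entry is flagged as a
#'   candidate informative property (default 0.5).
#' @return data.frame with `accession`, `description`, `r`, `candidate`.
#' @export
correlate_propensities <- function(propensities, entries,
                                   candidate_cutoff = 0.5) {
  p <- align_aa_vector(propensities, "propensities")
  if (stats::sd(p) == 0) stop("zero-variance propensities")
  rows <- lapply(entries, function(e) {
    if (!e$complete) return(NULL)
    if (stats::sd(e$values) == 0) {
      message("skipping zero-variance AAindex entry ", e$accession)
      return(NULL)
    }
    data.frame(accession = e$accession, description = e$description,
               r = pearson_r(p, e$values[AA_ALPHABET20]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(accession = character(), description = character(),
                                      r = numeric(), candidate = logical()))
  out <- out[order(-abs(out$r), out$accession), , drop = FALSE]
  out$candidate <- abs(out$r) > candidate_cutoff
  rownames(out) <- NULL
  out
}

align_aa_vector <- function(v, what) {
  if (length(v) != 20L) stop(what, " must have 20 values")
  if (!is.null(names(v))) {
    if (!all(AA_ALPHABET20 %in% names(v)))
      stop(what, " is missing amino acids: ",
           paste(setdiff(AA_ALPHABET20, names(v)), collapse = ", "))
    v <- v[AA_ALPHABET20]
  } else names(v) <- AA_ALPHABET20
  v
}

#' Sum a composition over a residue subset
#'
#' Sums the entries of an amino-acid composition (fractions or percentages)
#' over a named subset of residues, e.g. the aromatic set `c("F","H","W","Y")`.
#' The result is on the same scale as the input.
#'
#' @param composition named amino-acid vector (any subset of the 20 codes).
#' @param residues character vector of one-letter codes.
#' @return scalar sum.
#' @export
subset_composition_sum <- function(composition, residues) {
  if (length(residues) == 0L) return(0)
  residues <- toupper(residues)
  bad <- setdiff(residues, AA_ALPHABET20)
  if (length(bad)) stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  if (is.null(names(composition))) stop("composition must be named by residue")
  sum(composition[residues])
}

#' Mean per-residue property value of a sequence
#'
#' Averages an AAindex entry's values over the residues of a sequence (in the
#' entry's units). Permutation-invariant: depends only on composition.
#'
#' @param seq a single validated sequence.
#' @param entry an entry from [parse_aaindex()] (must be complete).
#' @return scalar mean property value.
#' @export
mean_sequence_property <- function(seq, entry) {
  if (!isTRUE(entry$complete)) stop("incomplete AAindex entry ", entry$accession)
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- setdiff(ch, AA_ALPHABET20)
  if (length(bad)) stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  mean(entry$values[ch])
}

#' Compare a per-sequence property between two groups
#'
#' Computes the per-sequence mean property ([mean_sequence_property()]) for
#' both groups and tests the shift with the two-sided Mann-Whitney test.
#'
#' @param group_a,group_b character vectors of sequences.
#' @param entry a complete AAindex entry.
#' @return list with `mean_a`, `mean_b`, `U`, `p`.
#' @export
compare_group_property <- function(group_a, group_b, entry) {
  a <- vapply(group_a, mean_sequence_property, numeric(1), entry = entry)
  b <- vapply(group_b, mean_sequence_property, numeric(1), entry = entry)
  mw <- mann_whitney(a, b)
  list(mean_a = mean(a), mean_b = mean(b), U = mw$U, p = mw$p)
}

#' Correlate amino-acid scores against a per-amino-acid table
#'
#' Thin wrapper over [pearson_r()] that joins the two vectors on the
#' one-letter amino-acid code before correlating, e.g. propensity scores
#' against mean crystallographic B-factors.
#'
#' @param aa_scores named 20-vector of amino-acid scores.
#' @param table named per-amino-acid vector covering all 20 residues.
#' @return Pearson R.
#' @export
score_vs_table_correlation <- function(aa_scores, table) {
  s <- align_aa_vector(aa_scores, "aa_scores")
  t <- align_aa_vector(table, "table")
  pearson_r(s, t)
}
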