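# Synthetic two-class sequence generator with controlled dipeptide
# enrichment, and accessors for the packaged reference tables.

#' Specification of a synthetic two-class sequence dataset
#'
#' Negatives are i.i.d. draws from the background residue distribution.
#' Positives use the same emission process except that, at each position,
#' with probability `beta` a dipeptide drawn uniformly from
#' `enriched_dipeptides` is emitted as the next two residues. The signal is
#' therefore genuinely dipeptide-level: single-residue composition shifts
#' alone cannot explain class separation at small `beta`.
#'
#' @param n_pos,n_neg sequence counts per class (defaults 200/200).
#' @param length_min,length_max uniform integer length bounds (default 300,
#'   a typical protein length; `length_min` must be >= 10).
#' @param background named 20-vector of residue probabilities summing to 1;
#'   default uniform 0.05 (see [aa_background()] for a natural-frequency
#'   preset).
#' @param enriched_dipeptides ordered dipeptides enriched in the positive
#'   class (default `c("CP","CH","FF","WH","PM")`, heme-motif-like pairs).
#' @param beta per-position insertion probability in [0, 0.5] (default 0.05).
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos = 200L, n_neg = 200L,
                           length_min = 300L, length_max = 300L,
                           background = NULL,
                           enriched_dipeptides = c("CP", "CH", "FF", "WH", "PM"),
                           beta = 0.05, seed = 1L) {
  background <- background %||% stats::setNames(rep(0.05, 20), AA_ALPHABET20)
  background <- align_aa_vector(background, "background")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  if (beta < 0 || beta > 0.5) stop("beta must lie in [0, 0.5]")
  if (length_min < 10L) stop("length_min must be >= 10")
  if (length_max < length_min) stop("length_max < length_min")
  if (beta > 0) {
    if (length(enriched_dipeptides) == 0L)
      stop("beta > 0 requires a non-empty enriched dipeptide set")
    if (!all(enriched_dipeptides %in% DIPEPTIDES400))
      stop("invalid enriched dipeptides")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 background = background,
                 enriched_dipeptides = enriched_dipeptides,
                 beta = beta, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Natural or uniform amino-acid background frequencies
#'
#' `"uniform"` gives 0.05 everywhere (analytically transparent null);
#' `"natural"` gives frequencies close to those observed over well-annotated
#' protein databases, normalized to sum to 1.
#'
#' @param type `"uniform"` or `"natural"`.
#' @return named 20-vector of probabilities.
#' @export
aa_background <- function(type = c("uniform", "natural")) {
  type <- match.arg(type)
  if (type == "uniform")
    return(stats::setNames(rep(0.05, 20), AA_ALPHABET20))
  v <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.64, T = 5.35, V = 6.86,
         W = 1.10, Y = 2.92)
  v / sum(v)
}

emit_sequence <- function(len, background, enriched, beta) {
  out <- character(len + 1L)
  i <- 1L
  while (i <= len) {
    if (beta > 0 && stats::runif(1) < beta) {
      di <- enriched[sample.int(length(enriched), 1L)]
      out[i] <- substr(di, 1, 1)
      if (i + 1L <= len + 1L) out[i + 1L] <- substr(di, 2, 2)
      i <- i + 2L
    } else {
      out[i] <- sample(AA_ALPHABET20, 1L, prob = background)
      i <- i + 1L
    }
  }
  paste(out[seq_len(len)], collapse = "")
}

#' Generate a labeled synthetic dataset
#'
#' Deterministic given `spec$seed`: the same spec yields byte-identical
#' sequences. Ids are `pos_0001 ...` / `neg_0001 ...`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `seqs` (named character) and `labels`
#'   (`"pos"`/`"neg"` character vector in the same order).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  gen <- function(n, prefix, beta) {
    lens <- if (spec$length_max > spec$length_min)
      sample(spec$length_min:spec$length_max, n, replace = TRUE)
    else rep(spec$length_min, n)
    seqs <- vapply(lens, emit_sequence, character(1),
                   background = spec$background,
                   enriched = spec$enriched_dipeptides, beta = beta)
    stats::setNames(seqs, sprintf("%s_%04d", prefix, seq_len(n)))
  }
  pos <- gen(spec$n_pos, "pos", spec$beta)
  neg <- gen(spec$n_neg, "neg", 0)
  list(seqs = c(pos, neg),
       labels = rep(c("pos", "neg"), c(spec$n_pos, spec$n_neg)))
}

#' Write a labeled dataset as FASTA plus an id-to-label table
#'
#' @param dataset output of [generate_dataset()].
#' @param fasta_path,labels_path output paths (labels are written as a
#'   two-column tab-separated id/label table without header).
#' @return invisibly, a list of the two paths.
#' @export
write_dataset <- function(dataset, fasta_path, labels_path) {
  write_fasta(dataset$seqs, fasta_path)
  utils::write.table(data.frame(id = names(dataset$seqs), label = dataset$labels),
                     labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(fasta = fasta_path, labels = labels_path))
}

read_ref_table <- function(file) {
  path <- system.file("extdata", file, package = "scmseq", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df <- df[order(df$aa), , drop = FALSE]
  rownames(df) <- df$aa
  df
}

#' Published heme-binding-protein reference tables
#'
#' Packaged machine-readable copies of published per-amino-acid reference
#' values from a heme-binding-protein study, re-indexed alphabetically by
#' one-letter code (20 rows each):
#' \describe{
#'   \item{`hbp_propensity_table()`}{trained amino-acid propensity `score`
#'     plus class compositions `comp_hbp` / `comp_nonhbp` in percent.}
#'   \item{`hbp_pcp_table()`}{`score` plus the three informative
#'     physicochemical scales `snep` (aromaticity principal component),
#'     `takk` (side-chain stability contribution, kJ/mol) and `karp`
#'     (flexibility parameter).}
#'   \item{`hbp_bfactor_table()`}{`score` plus mean/sd of C-alpha B-factors
#'     for the HBP and non-HBP structure sets.}
#' }
#'
#' @return data.frame with 20 rows keyed by `aa`.
#' @export
hbp_propensity_table <- function() read_ref_table("hbp_propensity.tsv")

#' @rdname hbp_propensity_table
#' @export
hbp_pcp_table <- function() read_ref_table("hbp_pcp.tsv")

#' @rdname hbp_propensity_table
#' @export
hbp_bfactor_table <- function() read_ref_table("hbp_bfactor.tsv")

#' Path to the packaged AAindex1 excerpt
#'
#' An AAindex1-format flat file holding the three scales of
#' [hbp_pcp_table()] (SNEP660103, TAKK010101, KARP850101) plus two synthetic
#' records used by tests (one complete, one with a missing value).
#'
#' @return file path.
#' @export
aaindex_excerpt_path <- function() {
  system.file("extdata", "aaindex_excerpt.txt", package = "scmseq",
              mustWork = TRUE)
}
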