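# The scoring card: 400 dipeptide propensity scores in [0, 1000], the 20
# derived amino-acid propensities, and a decision threshold on S(P).

new_scoring_card <- function(scores, threshold = NA_real_,
                             provenance = "initial", meta = list(),
                             aa_method = c("literal40", "distinct39")) {
  aa_method <- match.arg(aa_method)
  stopifnot(length(scores) == 400L)
  if (is.null(names(scores))) names(scores) <- DIPEPTIDES400
  scores <- scores[DIPEPTIDES400]
  if (anyNA(scores)) stop("malformed score vector: missing dipeptides")
  if (any(scores < 0 | scores > 1000)) stop("scores must lie in [0, 1000]")
  structure(
    list(scores = scores,
         aa_propensities = derive_aa_propensities(scores, method = aa_method),
         threshold = threshold,
         provenance = provenance,
         meta = meta),
    class = "scoring_card")
}

#' @export
print.scoring_card <- function(x, ...) {
  cat("Scoring card (", x$provenance, ")\n", sep = "")
  cat("  dipeptide scores: 400 in [",
      format(min(x$scores), digits = 4), ", ",
      format(max(x$scores), digits = 4), "]\n", sep = "")
  top <- sort(x$scores, decreasing = TRUE)[1:5]
  cat("  top dipeptides:  ",
      paste(sprintf("%s=%.1f", names(top), top), collapse = ", "), "\n")
  ap <- sort(x$aa_propensities, decreasing = TRUE)
  cat("  aa propensities: ", sprintf("%s=%.1f (max) ... %s=%.1f (min)",
      names(ap)[1], ap[1], names(ap)[20], ap[20]), "\n")
  cat("  threshold:        ",
      if (is.na(x$threshold)) "unset" else format(x$threshold, digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Build an initial scoring card from class compositions
#'
#' The raw score of each dipeptide is its content in the positive class minus
#' its content in the negative class; raw scores are then linearly min-max
#' mapped onto [0, 1000] (min -> 0, max -> 1000). If every raw difference is
#' equal (no signal), all scores are set to 500. The default threshold is the
#' median of the 400 scores; training replaces it via [select_threshold()].
#'
#' @param pos_dpc,neg_dpc dipeptide-composition vectors (length 400, summing
#'   to 1) for the positive and negative class, e.g. from
#'   [pooled_dipeptide_composition()].
#' @param aa_method how amino-acid propensities are averaged; see
#'   [derive_aa_propensities()].
#' @return a `scoring_card` with provenance `"initial"`.
#' @export
build_initial_card <- function(pos_dpc, neg_dpc,
                               aa_method = c("literal40", "distinct39")) {
  check_dpc <- function(v, what) {
    if (length(v) != 400L || anyNA(v) || any(v < 0))
      stop("malformed ", what, ": need 400 non-negative frequencies")
    if (abs(sum(v) - 1) > 1e-6)
      stop("malformed ", what, ": frequencies must sum to 1")
    if (!is.null(names(v))) v <- v[DIPEPTIDES400]
    if (anyNA(v)) stop("malformed ", what, ": bad dipeptide names")
    v
  }
  pos_dpc <- check_dpc(pos_dpc, "pos_dpc")
  neg_dpc <- check_dpc(neg_dpc, "neg_dpc")
  raw <- pos_dpc - neg_dpc
  rng <- range(raw)
  scores <- if (rng[1] == rng[2]) rep(500, 400)
            else (raw - rng[1]) / (rng[2] - rng[1]) * 1000
  names(scores) <- DIPEPTIDES400
  new_scoring_card(scores, threshold = stats::median(scores),
                   provenance = "initial", aa_method = match.arg(aa_method))
}

#' Derive amino-acid propensities from dipeptide scores
#'
#' The propensity of amino acid X averages the scores of the dipeptides that
#' contain X. With `method = "literal40"` (default) the homodipeptide XX is
#' counted twice -- once as X-leading and once as X-trailing -- giving a
#' 40-term average; `method = "distinct39"` averages the 39 distinct
#' dipeptides containing X instead.
#'
#' @param scores a `scoring_card` or a named 400-vector of dipeptide scores.
#' @param method `"literal40"` or `"distinct39"`.
#' @return named numeric vector of 20 amino-acid propensities.
#' @export
derive_aa_propensities <- function(scores, method = c("literal40", "distinct39")) {
  method <- match.arg(method)
  if (inherits(scores, "scoring_card")) scores <- scores$scores
  stopifnot(length(scores) == 400L)
  if (is.null(names(scores))) names(scores) <- DIPEPTIDES400
  scores <- scores[DIPEPTIDES400]
  if (anyNA(scores)) stop("malformed score vector: missing dipeptides")
  first <- substring(DIPEPTIDES400, 1, 1)
  second <- substring(DIPEPTIDES400, 2, 2)
  vapply(AA_ALPHABET20, function(x) {
    lead <- scores[first == x]
    trail <- scores[second == x]
    if (method == "literal40") (sum(lead) + sum(trail)) / 40
    else (sum(lead) + sum(trail) - scores[paste0(x, x)]) / 39
  }, numeric(1))
}

#' Score a sequence with a card
#'
#' The sequence score S(P) is the dipeptide-composition-weighted sum of the
#' card's 400 propensity scores. Because the weights sum to 1 and scores lie
#' in [0, 1000], S(P) also lies in [0, 1000].
#'
#' @param card a `scoring_card`.
#' @param seq a single sequence (length >= 2), or a character vector of
#'   sequences (scored element-wise).
#' @return numeric vector of S(P) values.
#' @export
score_sequence <- function(card, seq) {
  stopifnot(inherits(card, "scoring_card"))
  as.vector(dpc_matrix(seq) %*% card$scores)
}

#' Select the accuracy-maximizing decision threshold
#'
#' Scans every midpoint between adjacent distinct sorted score values, plus
#' -Inf/+Inf sentinels, under the strict rule "positive iff score >
#' threshold". Returns the candidate maximizing training accuracy; ties are
#' broken by the smaller |sensitivity - specificity|, then by the smaller
#' threshold.
#'
#' @param scores numeric scores.
#' @param labels logical (TRUE = positive) or a factor/character vector with
#'   values `"pos"`/`"neg"`.
#' @return the selected threshold (may be infinite when no cut helps).
#' @export
select_threshold <- function(scores, labels) {
  y <- as_pos_logical(labels)
  if (length(scores) != length(y)) stop("scores/labels length mismatch")
  if (!any(y) || all(y)) stop("both classes required to select a threshold")
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2, Inf)
  np <- sum(y); nn <- sum(!y)
  best <- NULL
  for (t in cand) {
    pred <- scores > t
    acc <- (sum(pred & y) + sum(!pred & !y)) / length(y)
    bal <- abs(sum(pred & y) / np - sum(!pred & !y) / nn)
    key <- c(acc, -bal, -t)
    if (is.null(best) || keys_greater(key, best$key)) best <- list(key = key, t = t)
  }
  best$t
}

keys_greater <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}

as_pos_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  l <- as.character(labels)
  if (!all(l %in% c("pos", "neg"))) stop("labels must be 'pos'/'neg' or logical")
  l == "pos"
}

#' Set the decision threshold on a card
#'
#' @param card a `scoring_card`.
#' @param threshold numeric cutoff on S(P).
#' @return the updated card.
#' @export
set_threshold <- function(card, threshold) {
  stopifnot(inherits(card, "scoring_card"), is.numeric(threshold))
  card$threshold <- threshold
  card
}

#' Classify sequences with a thresholded card
#'
#' A sequence is called positive iff S(P) strictly exceeds the card's
#' threshold; S(P) equal to the threshold is negative.
#'
#' @param card a `scoring_card` with its threshold set.
#' @param seq sequence(s) to classify.
#' @return character vector of `"pos"`/`"neg"`.
#' @export
classify <- function(card, seq) {
  stopifnot(inherits(card, "scoring_card"))
  if (is.na(card$threshold)) stop("card threshold is unset")
  ifelse(score_sequence(card, seq) > card$threshold, "pos", "neg")
}

#' Rank sequences by card score
#'
#' @param card a `scoring_card`.
#' @param seqs named character vector of sequences.
#' @param top_k number of top entries to return (capped at the input size).
#' @return data.frame with columns `id`, `score`, sorted by descending score;
#'   ties keep input order.
#' @export
rank_sequences <- function(card, seqs, top_k = length(seqs)) {
  if (length(seqs) == 0L) stop("no sequences to rank")
  if (top_k < 1L) stop("top_k must be >= 1")
  s <- score_sequence(card, seqs)
  ids <- if (is.null(names(seqs))) as.character(seq_along(seqs)) else names(seqs)
  ord <- order(-s, seq_along(s))
  k <- min(top_k, length(seqs))
  data.frame(id = ids[ord][1:k], score = s[ord][1:k],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a scoring card to a tab-separated file
#'
#' Three sections: 400 `dipeptide<TAB>score` rows, 20 `aa<TAB>propensity`
#' rows, and one `threshold<TAB>value` row. Values are written with full
#' double precision and round-trip bit-exactly through [read_card()].
#'
#' @param card a `scoring_card`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_card <- function(card, path) {
  stopifnot(inherits(card, "scoring_card"))
  num <- function(x) sprintf("%.17g", x)
  lines <- c(paste(names(card$scores), num(card$scores), sep = "\t"),
             paste(names(card$aa_propensities), num(card$aa_propensities), sep = "\t"),
             paste("threshold", num(card$threshold), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a scoring card written by [write_card()]
#'
#' @param path path to a card file.
#' @return a `scoring_card` with provenance `"file"`.
#' @export
read_card <- function(path) {
  if (!file.exists(path)) stop("card file not found: ", path)
  # na.strings: the dipeptide NA (Asn-Ala) is a legitimate key
  f <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("key", "value"),
                         colClasses = c("character", "numeric"),
                         na.strings = character(0))
  if (nrow(f) != 421L) stop("malformed card file: expected 421 rows, got ", nrow(f))
  scores <- stats::setNames(f$value[1:400], f$key[1:400])
  thr <- f$value[f$key == "threshold"]
  card <- new_scoring_card(scores, threshold = thr, provenance = "file")
  # prefer the stored propensities (they encode the aa averaging choice)
  stored <- stats::setNames(f$value[401:420], f$key[401:420])
  card$aa_propensities <- stored[AA_ALPHABET20]
  card
}
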