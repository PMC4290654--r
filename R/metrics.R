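# Classification and association statistics shared by training, the GA
# fitness and the property analyses.

#' Confusion-matrix summary at a threshold
#'
#' Counts are taken under the strict rule "predicted positive iff
#' score > threshold". Ratios with a zero denominator are reported as 0 and
#' flagged via `undefined`.
#'
#' @param scores numeric scores.
#' @param labels `"pos"`/`"neg"` or logical (TRUE = positive).
#' @param threshold decision cutoff.
#' @return list with `tp`, `fp`, `tn`, `fn`, `accuracy`, `sensitivity`,
#'   `specificity`, `mcc`, and `undefined` (names of ratios whose
#'   denominator was zero).
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  y <- as_pos_logical(labels)
  if (length(scores) != length(y)) stop("scores/labels length mismatch")
  pred <- scores > threshold
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)
  n <- length(y)
  undefined <- character(0)
  ratio <- function(num, den, what) {
    if (den == 0) { undefined <<- c(undefined, what); 0 } else num / den
  }
  sens <- ratio(tp, tp + fn, "sensitivity")
  spec <- ratio(tn, tn + fp, "specificity")
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) { undefined <- c(undefined, "mcc"); 0 }
         else (tp * tn - fp * fn) / denom
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / n, sensitivity = sens, specificity = spec,
       mcc = mcc, undefined = undefined)
}

#' Rank-based ROC AUC
#'
#' The Mann-Whitney form of the area under the ROC curve:
#' (concordant pairs + 0.5 * tied pairs) / (n_pos * n_neg), computed from
#' midranks, so it is exact under ties and invariant under strictly
#' increasing score transforms.
#'
#' @inheritParams confusion_metrics
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  y <- as_pos_logical(labels)
  if (length(scores) != length(y)) stop("scores/labels length mismatch")
  np <- sum(y); nn <- sum(!y)
  if (np == 0L || nn == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[y]) - np * (np + 1) / 2) / (np * nn)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over `stats::cor` adding the contracts used throughout the
#' package: equal lengths >= 3 and nonzero variance in both arguments.
#'
#' @param x,y numeric vectors.
#' @return correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  stats::cor(x, y)
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from midrank sums (ties contribute 1/2). For small problems
#' (`n_a * n_b <= exact_limit`) the two-sided p-value is exact over all
#' group-label assignments -- computed by a shift-algorithm dynamic program
#' over doubled midranks, which remains correct under ties; otherwise a
#' normal approximation with the standard tie-corrected variance is used (no
#' continuity correction). The permutation distribution of U is symmetric
#' about `n_a * n_b / 2`, so the two-sided p-value is
#' P(|U - n_a n_b / 2| >= |u - n_a n_b / 2|).
#'
#' @param a,b numeric samples.
#' @param exact_limit switch to the normal approximation above this
#'   `n_a * n_b` (default 200).
#' @return list with `U` (statistic for group `a`) and `p`.
#' @export
mann_whitney <- function(a, b, exact_limit = 200L) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty")
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (na * nb <= exact_limit) {
    d <- as.integer(round(2 * r))          # doubled midranks are integers
    smax <- sum(d)
    # cnt[k+1, s+1] = number of size-k subsets with doubled rank sum s
    cnt <- matrix(0, nrow = na + 1L, ncol = smax + 1L)
    cnt[1L, 1L] <- 1
    for (di in d) {
      for (k in na:1L) cnt[k + 1L, ] <-
          cnt[k + 1L, ] + c(rep(0, di), cnt[k, seq_len(smax + 1L - di)])
    }
    s_vals <- (seq_len(smax + 1L) - 1L) / 2           # subset rank sums
    u_vals <- s_vals - na * (na + 1) / 2
    w <- cnt[na + 1L, ]
    p <- sum(w[abs(u_vals - mu) >= abs(u - mu) - 1e-9]) / sum(w)
  } else {
    n <- na + nb
    t <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(t^3 - t) / (n * (n - 1)))
    p <- if (sig2 == 0) 1 else 2 * stats::pnorm(-abs(u - mu) / sqrt(sig2))
    p <- min(p, 1)
  }
  list(U = u, p = p)
}
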