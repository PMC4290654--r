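# Intelligent genetic algorithm (IGA) for scoring-card optimization.
#
# The fitness of a candidate card is W1 * AUC + W2 * R, where AUC is the mean
# held-out ROC AUC over stratified cross-validation folds and R is the
# Pearson correlation between the candidate's derived amino-acid
# propensities and those of the frozen initial card. Crossover samples
# gene-group combinations of the two parents with a two-level orthogonal
# array and composes an additional child from per-factor main effects.

#' Fitness weights for card optimization
#'
#' @param w1 weight on the cross-validated AUC term (default 0.9).
#' @param w2 weight on the propensity-correlation term (default 0.1).
#' @return list of class `fitness_weights`.
#' @export
fitness_weights <- function(w1 = 0.9, w2 = 0.1) {
  stopifnot(w1 >= 0, w2 >= 0)
  structure(list(w1 = w1, w2 = w2), class = "fitness_weights")
}

#' Cross-validation configuration
#'
#' @param folds number of folds (default 10).
#' @param stratified keep the class ratio in every fold (default TRUE).
#' @param seed integer seed for the one-off fold shuffle.
#' @param auc how the AUC term aggregates folds: `"mean"` of per-fold
#'   held-out AUCs (default) or `"pooled"` over concatenated held-out scores.
#' @return list of class `cv_config`.
#' @export
cv_config <- function(folds = 10L, stratified = TRUE, seed = 1L,
                      auc = c("mean", "pooled")) {
  stopifnot(folds >= 2L)
  structure(list(folds = as.integer(folds), stratified = isTRUE(stratified),
                 seed = as.integer(seed), auc = match.arg(auc)),
            class = "cv_config")
}

#' IGA configuration
#'
#' Defaults are desk-scale reconstructions chosen for observable optimization
#' gain within minutes on one CPU; none of them is a published constant.
#'
#' @param population_size individuals per generation (>= 4; default 20).
#' @param generations generational loop count (default 50).
#' @param crossover_groups number k of contiguous gene groups (factors) the
#'   400 dipeptides are partitioned into for orthogonal-array crossover
#'   (default 15, hosted by an L16 array).
#' @param mutation_rate per-gene mutation probability (default 0.02).
#' @param mutation_step maximum absolute uniform perturbation of a mutated
#'   gene, in score units (default 100).
#' @param init_noise maximum absolute uniform noise added to the initial card
#'   when seeding the population (default 50).
#' @param elitism individuals copied unchanged each generation (default 2).
#' @param seed integer seed for all optimizer randomness.
#' @return list of class `iga_config`.
#' @export
iga_config <- function(population_size = 20L, generations = 50L,
                       crossover_groups = 15L, mutation_rate = 0.02,
                       mutation_step = 100, init_noise = 50,
                       elitism = 2L, seed = 1L) {
  stopifnot(population_size >= 4L, crossover_groups >= 2L, generations >= 1L,
            mutation_rate >= 0, mutation_rate <= 1,
            elitism >= 0L, elitism < population_size)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_groups = as.integer(crossover_groups),
                 mutation_rate = mutation_rate, mutation_step = mutation_step,
                 init_noise = init_noise, elitism = as.integer(elitism),
                 seed = as.integer(seed)),
            class = "iga_config")
}

clamp01k <- function(x) {
  x[x < 0] <- 0
  x[x > 1000] <- 1000
  x
}

# Stratified fold assignment, shuffled once with the CV seed and then frozen,
# so fitness is a deterministic function of the chromosome.
make_folds <- function(y, cv) {
  assign_one <- function(idx) {
    k <- cv$folds
    if (length(idx) < k) stop("fewer sequences than folds in one class")
    f <- rep_len(seq_len(k), length(idx))
    split(idx[sample.int(length(idx))], f)
  }
  set.seed(cv$seed)
  if (cv$stratified) {
    fp <- assign_one(which(y)); fn <- assign_one(which(!y))
    lapply(seq_len(cv$folds), function(i) sort(c(fp[[i]], fn[[i]])))
  } else {
    assign_one(seq_along(y))
  }
}

# Vectorized fitness: S is a 400 x m matrix of candidate score vectors.
fitness_matrix <- function(S, X, y, folds, weights, init_prop) {
  sc <- X %*% S                                  # n x m sequence scores
  m <- ncol(S)
  auc <- numeric(m)
  if ((attr(folds, "auc_mode") %||% "mean") == "pooled") {
    for (j in seq_len(m)) auc[j] <- roc_auc(sc[, j], y)
  } else {
    for (j in seq_len(m)) {
      a <- vapply(folds, function(te) roc_auc(sc[te, j], y[te]), numeric(1))
      auc[j] <- mean(a)
    }
  }
  props <- apply(S, 2, derive_aa_propensities)
  r <- as.vector(suppressWarnings(stats::cor(init_prop, props)))
  r[is.na(r)] <- 0                               # zero-variance candidate
  weights$w1 * auc + weights$w2 * r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validated fitness of a scoring card
#'
#' Computes `w1 * AUC + w2 * R`: AUC is the mean ROC AUC over held-out CV
#' folds of the data scored with the card; R is the Pearson correlation
#' between `init_propensities` (from the frozen initial card) and the card's
#' derived amino-acid propensities.
#'
#' @param card a `scoring_card` (or named 400-vector of scores).
#' @param seqs sequences, or a precomputed [dpc_matrix()].
#' @param labels `"pos"`/`"neg"` or logical labels.
#' @param weights a [fitness_weights()].
#' @param cv a [cv_config()].
#' @param init_propensities 20 reference amino-acid propensities; defaults to
#'   the card's own (giving R = 1).
#' @return the scalar fitness.
#' @export
cross_validated_fitness <- function(card, seqs, labels,
                                    weights = fitness_weights(),
                                    cv = cv_config(),
                                    init_propensities = NULL) {
  s <- if (inherits(card, "scoring_card")) card$scores else card[DIPEPTIDES400]
  X <- if (is.matrix(seqs)) seqs else dpc_matrix(seqs)
  y <- as_pos_logical(labels)
  folds <- make_folds(y, cv)
  attr(folds, "auc_mode") <- cv$auc
  ip <- init_propensities %||% derive_aa_propensities(s)
  if (stats::sd(ip) == 0) stop("zero-variance reference propensities")
  fitness_matrix(matrix(s, ncol = 1), X, y, folds, weights, ip)
}

# Contiguous near-equal partition of the 400 genes into k factor groups.
factor_groups <- function(k, n_genes = 400L) {
  sizes <- rep(n_genes %/% k, k)
  extra <- n_genes %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(seq_len(n_genes), rep(seq_len(k), sizes))
}

#' Two-level orthogonal array
#'
#' Standard construction: `n = 2^ceiling(log2(k + 1))` rows; column `j`
#' (for `j = 1 .. n-1`) holds `parity(bitwAnd(i, j)) + 1` for rows
#' `i = 0 .. n-1`. Every column is balanced and every column pair is
#' orthogonal; the first row is all level 1. The first `k` columns are used.
#'
#' @param k number of factors.
#' @return an `n x k` integer matrix of levels 1/2.
#' @export
orthogonal_array <- function(k) {
  if (k < 1) stop("need at least 1 factor")
  n <- 2^ceiling(log2(k + 1))
  if (k >= n) stop("array cannot host ", k, " factors")
  parity <- function(x) {
    p <- 0L
    while (any(x > 0)) { p <- bitwXor(p, bitwAnd(x, 1L)); x <- bitwShiftR(x, 1L) }
    p
  }
  oa <- matrix(0L, n, k)
  for (i in 0:(n - 1)) for (j in 1:k)
    oa[i + 1, j] <- parity(bitwAnd(i, j)) + 1L
  oa
}

#' Orthogonal-array crossover
#'
#' The 400 genes are partitioned into `k` contiguous groups. A two-level
#' orthogonal array samples `n` group-wise recombinations of the parents
#' (level 1 = group from `parent_a`, level 2 = from `parent_b`); these and
#' `parent_b` are evaluated. `child_best` is the best evaluated candidate
#' (the all-level-1 row is `parent_a` and `parent_b` is evaluated explicitly,
#' so `child_best` is never worse than either parent). `child_main_effects`
#' takes, for each factor, the level whose main-effect mean fitness is
#' higher.
#'
#' @param parent_a,parent_b named 400-vectors of dipeptide scores.
#' @param k number of factor groups.
#' @param evaluate function taking a 400 x m score matrix and returning m
#'   fitnesses.
#' @return list with `child_best`, `child_main_effects`, `fitness_best`.
#' @export
oa_crossover <- function(parent_a, parent_b, k, evaluate) {
  groups <- factor_groups(k)
  oa <- orthogonal_array(k)
  n <- nrow(oa)
  cand <- matrix(rep(parent_a, n + 1L), nrow = 400L)
  for (row in seq_len(n)) for (f in seq_len(k))
    if (oa[row, f] == 2L) cand[groups[[f]], row] <- parent_b[groups[[f]]]
  cand[, n + 1L] <- parent_b
  cand <- clamp01k(cand)
  fit <- evaluate(cand)
  best <- which.max(fit)
  child_me <- parent_a
  for (f in seq_len(k)) {
    m1 <- mean(fit[seq_len(n)][oa[, f] == 1L])
    m2 <- mean(fit[seq_len(n)][oa[, f] == 2L])
    if (m2 > m1) child_me[groups[[f]]] <- parent_b[groups[[f]]]
  }
  list(child_best = stats::setNames(cand[, best], DIPEPTIDES400),
       child_main_effects = clamp01k(child_me),
       fitness_best = fit[best])
}

#' Optimize a scoring card with the intelligent genetic algorithm
#'
#' Starts from the initial card built on `seqs`/`labels` and runs an elitist
#' generational loop: tournament pair selection, orthogonal-array crossover
#' (both children enter the pool), then per-gene uniform mutation, with all
#' scores clamped to [0, 1000] after every step. Fitness is
#' [cross_validated_fitness()] against the frozen initial propensities, on
#' folds fixed once from the CV seed, so the best-ever fitness is
#' non-decreasing and the run is reproducible bit-for-bit given the seeds.
#'
#' @param seqs sequences (named character) or a precomputed [dpc_matrix()].
#' @param labels `"pos"`/`"neg"` or logical labels.
#' @param iga an [iga_config()].
#' @param weights a [fitness_weights()].
#' @param cv a [cv_config()].
#' @param trace if TRUE, attach a per-generation best/mean fitness data.frame
#'   in the returned card's `meta`.
#' @param init_card optional initial `scoring_card`. When `seqs` are raw
#'   sequences the default is [build_initial_card()] on pooled class
#'   compositions; when `seqs` is a precomputed composition matrix (sequence
#'   lengths unknown) the per-sequence-averaged composition is used instead.
#' @return an optimized `scoring_card` with its threshold set by
#'   [select_threshold()] on the full training data.
#' @export
run_iga <- function(seqs, labels, iga = iga_config(),
                    weights = fitness_weights(), cv = cv_config(),
                    trace = TRUE, init_card = NULL) {
  X <- if (is.matrix(seqs)) seqs else dpc_matrix(seqs)
  y <- as_pos_logical(labels)
  if (!any(y) || all(y)) stop("both classes required for training")

  init <- init_card %||% if (is.matrix(seqs)) {
    build_initial_card(colMeans(X[y, , drop = FALSE]),
                       colMeans(X[!y, , drop = FALSE]))
  } else {
    build_initial_card(pooled_dipeptide_composition(seqs[y]),
                       pooled_dipeptide_composition(seqs[!y]))
  }

  folds <- make_folds(y, cv)
  attr(folds, "auc_mode") <- cv$auc
  init_prop <- init$aa_propensities
  evaluate <- function(S) fitness_matrix(S, X, y, folds, weights, init_prop)

  set.seed(iga$seed)
  p <- iga$population_size
  pop <- matrix(rep(init$scores, p), nrow = 400L)
  if (p > 1L)
    pop[, -1L] <- clamp01k(pop[, -1L] +
      matrix(stats::runif(400 * (p - 1L), -iga$init_noise, iga$init_noise),
             nrow = 400L))
  fit <- evaluate(pop)
  best_scores <- pop[, which.max(fit)]
  best_fit <- max(fit)
  tr <- data.frame(generation = 0L, best = best_fit, mean = mean(fit))

  for (g in seq_len(iga$generations)) {
    ord <- order(fit, decreasing = TRUE)
    nextpop <- pop[, ord[seq_len(iga$elitism)], drop = FALSE]
    nextfit <- fit[ord[seq_len(iga$elitism)]]
    while (ncol(nextpop) < p) {
      pa <- tournament(fit); pb <- tournament(fit)
      cx <- oa_crossover(pop[, pa], pop[, pb], iga$crossover_groups, evaluate)
      kids <- cbind(cx$child_best, cx$child_main_effects)
      kids <- mutate_genes(kids, iga)
      nextpop <- cbind(nextpop, kids[, seq_len(min(2L, p - ncol(nextpop))),
                                     drop = FALSE])
    }
    newidx <- seq.int(iga$elitism + 1L, p)
    fit <- c(nextfit, evaluate(nextpop[, newidx, drop = FALSE]))
    pop <- nextpop
    if (max(fit) > best_fit) {
      best_fit <- max(fit)
      best_scores <- pop[, which.max(fit)]
    }
    tr <- rbind(tr, data.frame(generation = g, best = best_fit, mean = mean(fit)))
  }

  card <- new_scoring_card(stats::setNames(best_scores, DIPEPTIDES400),
                           provenance = "optimized",
                           meta = list(seed = iga$seed, fitness = best_fit,
                                       trace = if (trace) tr else NULL,
                                       init_propensities = init_prop))
  card$threshold <- select_threshold(as.vector(X %*% card$scores), y)
  card
}

tournament <- function(fit, size = 2L) {
  idx <- sample.int(length(fit), size)
  idx[which.max(fit[idx])]
}

mutate_genes <- function(S, iga) {
  hit <- matrix(stats::runif(length(S)) < iga$mutation_rate, nrow = nrow(S))
  if (any(hit))
    S[hit] <- S[hit] + stats::runif(sum(hit), -iga$mutation_step, iga$mutation_step)
  clamp01k(S)
}

#' Train a card from positive and negative sequence sets
#'
#' Convenience wrapper: featurizes, optionally optimizes with the IGA, and
#' reports training metrics at the selected threshold.
#'
#' @param pos,neg character vectors of validated sequences.
#' @param optimize run the IGA (TRUE) or stop at the initial card with a
#'   trained threshold (FALSE).
#' @param iga,weights,cv configurations, see [run_iga()].
#' @return list with `card` and `report` (accuracy, mcc, sensitivity,
#'   specificity, cv_auc, threshold).
#' @export
train_card <- function(pos, neg, optimize = TRUE, iga = iga_config(),
                       weights = fitness_weights(), cv = cv_config()) {
  seqs <- c(pos, neg)
  y <- rep(c(TRUE, FALSE), c(length(pos), length(neg)))
  X <- dpc_matrix(seqs)
  ic <- build_initial_card(pooled_dipeptide_composition(pos),
                           pooled_dipeptide_composition(neg))
  card <- if (optimize) {
    run_iga(X, y, iga = iga, weights = weights, cv = cv, init_card = ic)
  } else {
    ic$threshold <- select_threshold(as.vector(X %*% ic$scores), y)
    ic
  }
  sc <- as.vector(X %*% card$scores)
  cm <- confusion_metrics(sc, y, card$threshold)
  folds <- make_folds(y, cv); attr(folds, "auc_mode") <- cv$auc
  cvauc <- mean(vapply(folds, function(te) roc_auc(sc[te], y[te]), numeric(1)))
  list(card = card,
       report = data.frame(accuracy = cm$accuracy, mcc = cm$mcc,
                           sensitivity = cm$sensitivity,
                           specificity = cm$specificity,
                           cv_auc = cvauc, threshold = card$threshold))
}

#' Negative-subset resampling protocol
#'
#' Draws `n_subsets` seeded random subsets of the negative pool, trains a
#' card on each balanced set, reports per-subset training metrics
#' (resubstitution at the selected threshold) and their mean, and returns the
#' card with the highest training accuracy.
#'
#' @param pos positive-class sequences (named character).
#' @param neg_pool negative-pool sequences to subsample.
#' @param n_subsets number of candidate negative subsets (default 10).
#' @param subset_size negatives per subset (default `length(pos)`).
#' @param seed integer; subset `i` is drawn with seed `seed + i`.
#' @param optimize,iga,weights,cv passed to [train_card()].
#' @return list with `card` (best), `best_subset`, and `report` (one row per
#'   subset plus a final `"mean"` row).
#' @export
train_with_negative_resampling <- function(pos, neg_pool, n_subsets = 10L,
                                           subset_size = length(pos),
                                           seed = 1L, optimize = TRUE,
                                           iga = iga_config(),
                                           weights = fitness_weights(),
                                           cv = cv_config()) {
  if (length(neg_pool) < subset_size) stop("negative pool smaller than subset_size")
  rows <- vector("list", n_subsets)
  cards <- vector("list", n_subsets)
  for (i in seq_len(n_subsets)) {
    set.seed(seed + i)
    neg <- neg_pool[sample.int(length(neg_pool), subset_size)]
    fit <- train_card(pos, neg, optimize = optimize, iga = iga,
                      weights = weights, cv = cv)
    cards[[i]] <- fit$card
    rows[[i]] <- cbind(subset = i, fit$report)
  }
  rep <- do.call(rbind, rows)
  mean_row <- cbind(subset = NA, as.data.frame(t(colMeans(rep[-1]))))
  rep$subset <- as.character(rep$subset)
  mean_row$subset <- "mean"
  best <- which.max(rep$accuracy)
  list(card = cards[[best]], best_subset = best,
       report = rbind(rep, mean_row))
}
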