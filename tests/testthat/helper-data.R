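# Shared fixtures built in code at test time.

tiny_dataset <- function(seed = 42L, n = 30L, len = 120L, beta = 0.05) {
  generate_dataset(synthetic_spec(n_pos = n, n_neg = n, length_min = len,
                                  length_max = len, beta = beta, seed = seed))
}

write_tmp_fasta <- function(seqs, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = envir)
  write_fasta(seqs, path)
  path
}

# a small deterministic card with scores spread over [0, 1000]
toy_card <- function(threshold = NA_real_) {
  set.seed(99)
  s <- stats::setNames(round(stats::runif(400, 0, 1000), 3), DIPEPTIDES400)
  card <- build_initial_card(rep(1 / 400, 400), rep(1 / 400, 400))
  card$scores <- s
  card$aa_propensities <- derive_aa_propensities(s)
  card$threshold <- threshold
  card
}

# brute-force AUC oracle: explicit loop over all pos x neg pairs
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == "pos"]
  neg <- scores[labels == "neg"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exhaustive Mann-Whitney enumeration oracle (tiny n only)
mw_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  idx <- utils::combn(na + nb, na)
  us <- apply(idx, 2, function(i) sum(r[i])) - na * (na + 1) / 2
  list(U = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}
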