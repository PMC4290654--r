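test_that("initial card maps composition differences onto [0, 1000]", {
  u <- rep(1 / 400, 400)
  expect_equal(unname(build_initial_card(u, u)$scores), rep(500, 400))

  pos <- stats::setNames(numeric(400), DIPEPTIDES400); pos["AA"] <- 1
  neg <- stats::setNames(numeric(400), DIPEPTIDES400); neg["CC"] <- 1
  card <- build_initial_card(pos, neg)
  expect_equal(card$scores[["AA"]], 1000)
  expect_equal(card$scores[["CC"]], 0)
  expect_equal(unname(card$scores[setdiff(DIPEPTIDES400, c("AA", "CC"))]),
               rep(500, 398))

  ds <- tiny_dataset(seed = 3)
  c2 <- build_initial_card(pooled_dipeptide_composition(ds$seqs[ds$labels == "pos"]),
                           pooled_dipeptide_composition(ds$seqs[ds$labels == "neg"]))
  expect_equal(min(c2$scores), 0)
  expect_equal(max(c2$scores), 1000)
  expect_equal(c2$threshold, stats::median(c2$scores))
  expect_error(build_initial_card(rep(0.5, 400), u), "sum to 1")
  expect_error(build_initial_card(u[-1], u), "400")
})

test_that("amino-acid propensities follow the 40-term average with XX twice", {
  expect_equal(unname(derive_aa_propensities(rep(777, 400))), rep(777, 20))

  s <- stats::setNames(numeric(400), DIPEPTIDES400)
  s["AA"] <- 1000
  expect_equal(derive_aa_propensities(s)[["A"]], 2000 / 40)
  expect_equal(derive_aa_propensities(s, method = "distinct39")[["A"]], 1000 / 39)

  # pure and idempotent
  card <- toy_card()
  p1 <- derive_aa_propensities(card)
  expect_identical(p1, derive_aa_propensities(card))
  expect_identical(p1, card$aa_propensities)
})

test_that("S(P) is the composition-weighted card score", {
  const <- toy_card(); const$scores[] <- 321
  expect_equal(score_sequence(const, "MCHACPGG"), 321)

  card <- toy_card()
  card$scores[c("AC", "CA")] <- c(600, 400)
  expect_equal(score_sequence(card, "ACA"), 500)
  card$scores[c("AA", "AC")] <- c(300, 900)
  expect_equal(score_sequence(card, "AAAC"), (2 / 3) * 300 + (1 / 3) * 900)

  # bounds: min Si <= S(P) <= max Si for random records
  ds <- tiny_dataset(seed = 8, n = 10, len = 60)
  s <- score_sequence(card, ds$seqs)
  expect_true(all(s >= min(card$scores) & s <= max(card$scores)))
  expect_true(all(s >= 0 & s <= 1000))
})

test_that("ranking is affine-invariant in the card scores", {
  card <- toy_card()
  ds <- tiny_dataset(seed = 9, n = 15, len = 80)
  s1 <- score_sequence(card, ds$seqs)
  card2 <- card
  card2$scores <- 0.37 * card$scores + 210   # a > 0 affine map, stays in range
  s2 <- score_sequence(card2, ds$seqs)
  expect_identical(order(s1), order(s2))
  expect_equal(roc_auc(s1, ds$labels), roc_auc(s2, ds$labels))
})

test_that("select_threshold scans midpoints and maximizes accuracy", {
  expect_equal(select_threshold(c(600, 700, 400, 500),
                                c("pos", "pos", "neg", "neg")), 550)
  cm <- confusion_metrics(c(600, 700, 400, 500), c("pos", "pos", "neg", "neg"), 550)
  expect_equal(cm$accuracy, 1)

  # all scores equal: no separating cut; accuracy is the majority fraction
  t0 <- select_threshold(rep(5, 6), c("pos", "pos", "neg", "neg", "neg", "neg"))
  expect_equal(confusion_metrics(rep(5, 6),
               c("pos", "pos", "neg", "neg", "neg", "neg"), t0)$accuracy, 4 / 6)

  # inverted single pair: best achievable accuracy is 0.5
  t1 <- select_threshold(c(10, 20), c("pos", "neg"))
  expect_equal(confusion_metrics(c(10, 20), c("pos", "neg"), t1)$accuracy, 0.5)
  expect_error(select_threshold(c(1, 2), c("pos", "pos")), "both classes")
})

test_that("classification is strict at the threshold", {
  card <- toy_card(threshold = 550)
  card$scores[] <- 600
  expect_identical(classify(card, "ACDEF"), "pos")
  card$scores[] <- 550
  expect_identical(classify(card, "ACDEF"), "neg")

  # consistency with sign of S(P) - threshold on random records
  card <- toy_card(threshold = 500)
  ds <- tiny_dataset(seed = 10, n = 50, len = 60)
  s <- score_sequence(card, ds$seqs)
  expect_identical(classify(card, ds$seqs),
                   ifelse(s > card$threshold, "pos", "neg"))
  expect_error(classify(toy_card(), "ACDEF"), "unset")
})

test_that("rank_sequences sorts by score with stable ties", {
  card <- toy_card()
  ds <- tiny_dataset(seed = 11, n = 6, len = 60)
  r <- rank_sequences(card, ds$seqs, top_k = 4)
  s <- score_sequence(card, ds$seqs)
  ord <- order(-s)
  expect_identical(r$id, names(ds$seqs)[ord][1:4])
  expect_equal(r$score, sort(s, decreasing = TRUE)[1:4])

  expect_equal(nrow(rank_sequences(card, ds$seqs, top_k = 999)), 12L)
  expect_error(rank_sequences(card, ds$seqs, top_k = 0), "top_k")

  # ties keep input order
  tie <- toy_card(); tie$scores[] <- 400
  rt <- rank_sequences(tie, c(a = "AC", b = "CA", c = "AC"))
  expect_identical(rt$id, c("a", "b", "c"))
})

test_that("card files round-trip bit-exactly", {
  card <- toy_card(threshold = 537.123456789012345)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_card(card, f)
  back <- read_card(f)
  expect_identical(back$scores, card$scores)
  expect_identical(back$aa_propensities, card$aa_propensities)
  expect_identical(back$threshold, card$threshold)
  expect_error(read_card(withr::local_tempfile()), "not found")
})
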