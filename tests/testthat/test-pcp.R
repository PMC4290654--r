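test_that("parse_aaindex reads the packaged excerpt", {
  entries <- parse_aaindex(aaindex_excerpt_path())
  acc <- vapply(entries, `[[`, character(1), "accession")
  expect_identical(acc, c("SNEP660103", "TAKK010101", "KARP850101",
                          "SYNTH000001", "SYNTH000002"))

  snep <- entries[[1]]
  expect_true(snep$complete)
  expect_equal(snep$values[c("F", "W", "Y", "H")],
               c(F = 0.438, W = 0.493, Y = 0.381, H = 0.320))

  # missing value flags the record incomplete
  expect_false(entries[[5]]$complete)
  expect_true(is.na(entries[[5]]$values[["A"]]))
  expect_true(entries[[4]]$complete)

  # malformed record errors with the accession
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("H BAD0000001", "D broken", "I  A/L", " 1 2 3", " 4 5 6", "//"), bad)
  expect_error(parse_aaindex(bad), "BAD0000001")
})

test_that("correlate_propensities ranks by |R| and flags candidates", {
  entries <- parse_aaindex(aaindex_excerpt_path())
  tab <- hbp_pcp_table()
  prop <- stats::setNames(tab$score, tab$aa)

  hits <- correlate_propensities(prop, entries)
  expect_identical(sort(hits$accession),
                   sort(c("SNEP660103", "TAKK010101", "KARP850101", "SYNTH000001")))
  expect_true(all(diff(abs(hits$r)) <= 1e-12))          # |R| descending
  expect_identical(hits$candidate, abs(hits$r) > 0.5)

  # an entry identical to the propensity vector ranks first with R = 1
  self <- list(list(accession = "SELF000001", description = "self",
                    values = prop, complete = TRUE))
  expect_equal(correlate_propensities(prop, self)$r, 1)

  # cutoff above 1 flags nothing
  expect_false(any(correlate_propensities(prop, entries,
                                          candidate_cutoff = 1.01)$candidate))
  # incomplete entries are dropped from the output
  expect_false("SYNTH000002" %in% hits$accession)
})

test_that("subset_composition_sum adds named entries on the input scale", {
  comp <- stats::setNames(hbp_propensity_table()$comp_hbp,
                          hbp_propensity_table()$aa)
  expect_identical(subset_composition_sum(comp, character(0)), 0)
  expect_equal(subset_composition_sum(comp, c("F", "H", "W", "Y")), 12.18)
  expect_equal(subset_composition_sum(comp, AA_ALPHABET20), 100.01)

  # partition property: two halves sum to the total
  half <- AA_ALPHABET20[1:10]
  expect_equal(subset_composition_sum(comp, half) +
                 subset_composition_sum(comp, setdiff(AA_ALPHABET20, half)),
               subset_composition_sum(comp, AA_ALPHABET20))
  expect_error(subset_composition_sum(comp, "Z"), "unknown")
})

test_that("mean_sequence_property averages per-residue values", {
  entries <- parse_aaindex(aaindex_excerpt_path())
  takk <- entries[[2]]
  expect_equal(mean_sequence_property("GG", takk), 0.0)
  expect_equal(mean_sequence_property("FW", takk), (23.0 + 24.2) / 2)
  expect_equal(mean_sequence_property(strrep("M", 17), takk), 11.9)

  # permutation invariance
  expect_equal(mean_sequence_property("ACDEF", takk),
               mean_sequence_property("FEDCA", takk))
  expect_error(mean_sequence_property("AC", entries[[5]]), "incomplete")
})

test_that("compare_group_property detects a known shift", {
  entries <- parse_aaindex(aaindex_excerpt_path())
  takk <- entries[[2]]

  same <- compare_group_property(c("ACDEF", "GHIKL"), c("ACDEF", "GHIKL"), takk)
  expect_equal(same$mean_a, same$mean_b)
  expect_gt(same$p, 0.5)

  # homopolymers of the extreme residues: extreme U, minimal p
  hi <- rep(strrep("W", 30), 5)   # W has the max TAKK value
  lo <- rep(strrep("G", 30), 5)   # G has the min
  ext <- compare_group_property(hi, lo, takk)
  expect_equal(ext$U, 25)
  expect_equal(ext$mean_a, 24.2)
  expect_lt(ext$p, 0.05)

  # seeded simulation with a known composition shift
  set.seed(44)
  mk <- function(n, p_f) vapply(seq_len(n), function(i)
    paste(sample(c("F", "G"), 200, replace = TRUE, prob = c(p_f, 1 - p_f)),
          collapse = ""), character(1))
  ga <- mk(40, 0.6); gb <- mk(40, 0.4)
  res <- compare_group_property(ga, gb, takk)
  delta_true <- (0.6 - 0.4) * (23.0 - 0.0)
  # per-sequence mean is 23 * Binomial(200, p)/200; SE of the group-mean
  # difference follows directly
  se_diff <- sqrt(23^2 * 0.6 * 0.4 / 200 / 40 + 23^2 * 0.4 * 0.6 / 200 / 40)
  expect_lt(abs((res$mean_a - res$mean_b) - delta_true), 2 * se_diff)
  expect_lt(res$p, 0.05)
})

test_that("score_vs_table_correlation joins on amino-acid code", {
  tab <- hbp_bfactor_table()
  scores <- stats::setNames(tab$score, tab$aa)
  expect_equal(score_vs_table_correlation(scores, scores), 1)
  expect_equal(score_vs_table_correlation(scores, -scores), -1)

  # join order must not matter
  shuffled <- stats::setNames(tab$bfactor_hbp_mean, tab$aa)[sample(20)]
  expect_equal(score_vs_table_correlation(scores, shuffled),
               pearson_r(tab$score, tab$bfactor_hbp_mean))
  expect_error(score_vs_table_correlation(scores, shuffled[-1]), "20")
})
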