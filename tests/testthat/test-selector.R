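test_that("length penalty follows ln(d^2 + 1) with seed halving", {
  expect_equal(length_penalty(100, 100), 0)
  expect_equal(length_penalty(112, 100), log(145))
  expect_equal(round(length_penalty(112, 100)), 5)
  expect_equal(trunc(length_penalty(200, 100)), 9)
  # half penalty for sequences longer than a present seed
  expect_equal(length_penalty(200, 100, longer_than_seed = TRUE,
                              seed_present = TRUE), log(10001) / 2)
  # no halving for shorter-than-seed sequences
  expect_equal(length_penalty(0, 100, longer_than_seed = FALSE,
                              seed_present = TRUE), log(10001))
})

test_that("annotation penalties accumulate keyword and provenance biases", {
  tbl <- penalty_table()
  rec <- seq_records(
    c("q1", "1abc_A", "sp|P12345|YFG", "xSEEDx", "m_seed_1", "q2"),
    rep("ACDE", 6),
    c("hypothetical protein, fragment", "structure", "Uncharacterised MUTANT",
      "", "", "probable precursor"))
  p <- annotation_penalty(rec, tbl)
  expect_equal(p, c(5 + 50, -60, -20 + 5 + 40, -100, -50, 1 + 2))
  # user-marked codes add their own bias
  p2 <- annotation_penalty(rec, tbl, user_bias = c(q1 = -500))
  expect_equal(p2[1], 55 - 500)
  expect_error(penalty_table(bogus = 1), "unknown")
  expect_equal(penalty_table(fragment = 99)[["fragment"]], 99)
})

test_that("representative selection minimises length plus annotation penalty", {
  # A: clean length-100; B: length-40 'fragment'; mean length 70
  mini <- seq_records(c("A", "B"), c(strrep("A", 100), strrep("C", 40)),
                      c("", "fragment"), n_represented = c(2L, 3L))
  rep1 <- select_representative(mini)
  expect_equal(rep1$code, "A")
  expect_equal(rep1$n_represented, 5L)
  # a SEED member always wins regardless of length
  mini <- seq_records(c("long", "xSEEDx"), c(strrep("A", 200), strrep("A", 10)))
  expect_equal(select_representative(mini)$code, "xSEEDx")
  # singleton passes through unchanged, de-gapped
  one <- seq_records("solo", "AC-DE", n_represented = 4L)
  out <- select_representative(one)
  expect_equal(out$residues, "ACDE")
  expect_equal(out$n_represented, 4L)
})

test_that("selection ties break by larger represented count then input order", {
  mini <- seq_records(c("a", "b", "c"), rep("ACDEACDE", 3),
                      n_represented = c(1L, 7L, 7L))
  expect_equal(select_representative(mini)$code, "b")
  mini$n_represented <- rep(2L, 3)
  expect_equal(select_representative(mini)$code, "a")
})

test_that("selection works on mini-alignments from the condensation engine", {
  rec <- seq_records(c("s1", "s2SEED", "s3"), rep("GLEAFERLKEGLEAFERLKE", 3))
  minis <- condense_once(rec, align_config(cutoff = 50))
  expect_length(minis, 1)
  out <- select_representative(minis[[1]])
  expect_equal(out$code, "s2SEED")
  expect_equal(out$n_represented, 3L)
})
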