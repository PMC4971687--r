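test_that("generator is deterministic and respects the composition floor", {
  a <- make_families(200, rng_seed = 21)
  b <- make_families(200, rng_seed = 21)
  expect_identical(a, b)
  c2 <- make_families(200, rng_seed = 22)
  expect_false(identical(a$residues, c2$residues))
  # composition floor holds for every emitted sequence across several seeds
  for (sd in 1:4) {
    rec <- make_families(200, rng_seed = sd)
    frac <- mapply(function(s, f) {
      v <- strsplit(s, "")[[1]]
      sum(v == f) / length(v)
    }, rec$residues, rec$family)
    expect_true(all(frac > 1 / 3))
    expect_false(any(grepl("-", rec$residues, fixed = TRUE)))
  }
})

test_that("families span near-identical to strongly diverged members", {
  rec <- make_families(400, rng_seed = 30)
  fam <- split(rec, rec$family)
  for (f in names(fam)[c(1, 10, 20)]) {
    frac <- vapply(fam[[f]]$residues, function(s) {
      v <- strsplit(s, "")[[1]]
      sum(v == f) / length(v)
    }, 1)
    expect_gt(max(frac), 0.9)   # near-homopolymer end
    expect_lt(min(frac), 0.5)   # diverged end
  }
})

test_that("within-family pairs align while cross-family pairs do not", {
  withr::local_seed(31)
  rec <- make_families(200, rng_seed = 31)
  cfg <- align_config(cutoff = 30)
  fams <- split(seq_len(nrow(rec)), rec$family)
  # saturated members of different families stay near zero
  cross <- replicate(30, {
    f2 <- sample(names(fams), 2)
    i <- sample(fams[[f2[1]]], 1)
    j <- sample(fams[[f2[2]]], 1)
    profile_pair_score(rec$residues[i], rec$residues[j], cfg)
  })
  expect_lt(max(cross), 25)
  expect_lt(mean(cross), 15)
})

test_that("dopplegangers reverse residues, double the set and keep labels", {
  rec <- make_records(c("GLEAFERLKE", "ACDE"))
  both <- make_dopplegangers(rec, rng_seed = 2)
  expect_equal(nrow(both), 4)
  expect_setequal(both$code, c("s01", "s02", "s01_rev", "s02_rev"))
  expect_equal(both$residues[both$code == "s01_rev"], "EKLREFAELG")
  expect_equal(sum(both$native), 2)
  # reversal is an involution
  again <- make_dopplegangers(both[both$code == "s01_rev", ], rng_seed = 2)
  expect_equal(again$residues[again$code == "s01_rev_rev"], "GLEAFERLKE")
  # palindromes are flagged
  expect_warning(make_dopplegangers(make_records("ACA")), "palindromic")
})

test_that("segregation scoring counts label switches and purity", {
  rec <- make_records(rep("ACDE", 6))
  rec$native <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  s <- segregation_score(rec, "native")
  expect_true(s$pure)
  expect_equal(s$n_switches, 1)
  rec$native <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  s <- segregation_score(rec, "native")
  expect_false(s$pure)
  expect_equal(s$n_switches, 4)
  expect_equal(unname(as.vector(s$counts)), c(2, 4))
  expect_error(segregation_score(rec, c("x" = "a")), "missing|cover")
})

test_that("markov family generator is deterministic and family-coherent", {
  a <- make_markov_family(20, len = 60, rng_seed = 4)
  b <- make_markov_family(20, len = 60, rng_seed = 4)
  expect_identical(a, b)
  # trajectory snapshots of one ancestor stay alignable
  cfg <- align_config(cutoff = 30)
  expect_gt(profile_pair_score(a$residues[1], a$residues[2], cfg), 50)
})
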