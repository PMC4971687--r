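test_that("profile score anchors: identity 100, disjoint 0, half-identical 50", {
  expect_equal(profile_pair_score("GLEAFERLKE", "GLEAFERLKE"), 100)
  expect_equal(profile_pair_score(strrep("A", 30), strrep("E", 30)), 0)
  s1 <- paste(rep(c("A", "D"), 15), collapse = "")
  s2 <- paste(rep(c("A", "E"), 15), collapse = "")
  expect_equal(profile_pair_score(s1, s2), 50)
})

test_that("pair scores match an independent affine-gap DP oracle (<= 12 aa)", {
  withr::local_seed(404)
  cfg <- align_config(cutoff = 50)  # band off at cutoffs <= 60
  for (rep in 1:150) {
    s1 <- random_seq(sample(3:12, 1), letters = c("A", "C", "D", "E", "G"))
    s2 <- random_seq(sample(3:12, 1), letters = c("A", "C", "D", "E", "G"))
    expect_equal(profile_pair_score(s1, s2, cfg), oracle_pair_score(s1, s2),
                 tolerance = 1e-9, info = paste(s1, s2))
  }
})

test_that("column scores average member cross-pairs, gaps scoring zero", {
  # profile of A/C in one column vs single A: that column averages 0.5
  prof <- make_records(c("AAAA", "CAAA"))
  expect_equal(profile_pair_score(prof, "AAAA"), 100 * (0.5 + 3) / 4)
  # a gapped member contributes nothing at its gap column
  gapped <- make_records(c("AAAA", "-AAA"))
  expect_equal(profile_pair_score(gapped, "AAAA"), 100 * (0.5 + 3) / 4)
})

test_that("condensation merges identical sequences and respects the span", {
  rec <- make_records(rep("GLEAFERLKEGLEAFERLKE", 3))
  minis <- condense_once(rec, align_config(cutoff = 50))
  expect_length(minis, 1)
  expect_length(minis[[1]]$gapped, 3)
  # order distance beyond the span is never compared
  rec <- make_records(c("GLEAFERLKEGLEAFERLKE",
                        replicate(50, random_seq(20)),
                        "GLEAFERLKEGLEAFERLKE"))
  minis <- condense_once(rec, align_config(cutoff = 95, span = 50,
                                           n_iterations = 1))
  expect_length(minis, 52)   # the twins at distance 51 stay apart
  minis <- condense_once(rec, align_config(cutoff = 95, span = 51,
                                           n_iterations = 1))
  expect_length(minis, 51)
})

test_that("acid-rich families never merge across families at cutoff 50", {
  withr::local_seed(505)
  fams <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- unlist(lapply(fams, function(f) {
    base <- strsplit(strrep(f, 60), "")[[1]]
    vapply(1:3, function(i) {
      mut <- base
      at <- sample(60, 25)
      mut[at] <- sample(fams, 25, replace = TRUE)
      paste(mut, collapse = "")
    }, "")
  }))
  rec <- make_records(seqs)
  rec$family <- rep(fams, each = 3)
  minis <- condense_once(rec, align_config(cutoff = 50, span = Inf))
  for (m in minis)
    expect_length(unique(m$records$family), 1)
})

test_that("de-gapping any mini-alignment member returns its original residues", {
  withr::local_seed(606)
  base <- random_seq(40)
  variants <- vapply(1:6, function(i) {
    v <- strsplit(base, "")[[1]]
    v[sample(40, 4)] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 4,
                               replace = TRUE)
    paste(v[sample(40) > 3], collapse = "")   # also drop a few positions
  }, "")
  rec <- make_records(c(base, variants))
  minis <- condense_once(rec, align_config(cutoff = 60, span = Inf))
  for (m in minis)
    expect_equal(gsub("-", "", m$gapped, fixed = TRUE),
                 gsub("-", "", m$records$residues, fixed = TRUE))
})

test_that("raising the cutoff never produces larger mini-alignments", {
  withr::local_seed(707)
  base <- random_seq(50)
  seqs <- c(base, vapply(1:9, function(i) {
    v <- strsplit(base, "")[[1]]
    v[sample(50, i * 3)] <- "A"
    paste(v, collapse = "")
  }, ""))
  rec <- make_records(seqs)
  sizes <- vapply(c(95, 80, 65, 50), function(cut) {
    max(lengths(lapply(condense_once(rec, align_config(cutoff = cut, span = Inf)),
                       `[[`, "gapped")))
  }, 1)
  expect_true(all(diff(sizes) >= 0))
})

test_that("condensation with unlimited span reproduces exhaustive single linkage", {
  withr::local_seed(808)
  # three well-separated identity groups
  groups <- replicate(3, random_seq(30))
  seqs <- rep(groups, times = c(4, 3, 5))[sample(12)]
  rec <- make_records(seqs)
  minis <- condense_once(rec, align_config(cutoff = 90, span = Inf,
                                           n_iterations = 10))
  expect_length(minis, 3)
  got <- sort(vapply(minis, function(m) length(m$gapped), 1L))
  expect_equal(got, c(3L, 4L, 5L))
})

test_that("final alignment groups survivors into family blocks", {
  rec <- make_records(c(strrep("A", 40), strrep("A", 40),
                        strrep("E", 40), strrep("E", 40)))
  msa <- final_align(rec)
  expect_equal(msa$n_families, 2)
  expect_equal(sort(vapply(msa$blocks, function(b) length(b$gapped), 1L)),
               c(2L, 2L))
  # a single sequence is its own family
  one <- final_align(make_records("GLEAFERLKE"))
  expect_equal(one$n_families, 1)
  expect_match(one$dendrogram, "s01")
})

test_that("subfamily counting by adjacency at a cutoff", {
  fams <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rec <- make_records(unlist(lapply(fams, function(f) rep(strrep(f, 30), 3))))
  expect_equal(count_subfamilies(rec, 50), 20)
  expect_equal(count_subfamilies(make_records(rep(strrep("A", 30), 5)), 50), 1)
  withr::local_seed(909)
  rnd <- make_records(replicate(8, random_seq(40)))
  expect_equal(count_subfamilies(rnd, 90), 8)
})
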