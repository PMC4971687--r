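test_that("tree-sorted peptide list matches the worked tri-peptide example", {
  expect_equal(build_peptide_list("GLEAFERLKE", 3, as_strings = TRUE),
               c("AFE", "EAF", "ERL", "FER", "GLE", "LEA", "LKE", "RLK"))
  expect_equal(build_peptide_list("AAAA", 3, as_strings = TRUE), "AAA")
  expect_length(build_peptide_list("AC", 3), 0)
})

test_that("peptide lists equal sorted unique k-mers (oracle, random cases)", {
  withr::local_seed(101)
  for (rep in 1:200) {
    k <- sample(3:7, 1)
    s <- random_seq(sample(c(1, 5, 20, 80), 1))
    expect_equal(build_peptide_list(s, k, as_strings = TRUE), oracle_kmers(s, k))
  }
})

test_that("common-peptide score equals brute-force set intersection", {
  expect_equal(common_peptide_score(build_peptide_list("GLEAFERLKE", 3),
                                    build_peptide_list("GLEAFERLKE", 3)), 8)
  expect_equal(common_peptide_score(build_peptide_list("GLEAFERLKE", 3),
                                    build_peptide_list("GLESFERLKE", 3)), 5)
  expect_equal(common_peptide_score(build_peptide_list("AAAA", 3),
                                    build_peptide_list("EEEE", 3)), 0)
  withr::local_seed(202)
  for (rep in 1:1000) {
    k <- sample(3:5, 1)
    # small alphabet so intersections are non-trivial
    s1 <- random_seq(sample(10:60, 1), letters = c("A", "C", "D", "E"))
    s2 <- random_seq(sample(10:60, 1), letters = c("A", "C", "D", "E"))
    a <- build_peptide_list(s1, k)
    b <- build_peptide_list(s2, k)
    truth <- length(intersect(oracle_kmers(s1, k), oracle_kmers(s2, k)))
    expect_identical(common_peptide_score(a, b), truth)
    expect_identical(common_peptide_score(b, a), truth)       # symmetric
    expect_lte(truth, min(length(a), length(b)))
  }
})

test_that("pair store keeps at most M partners above the score cutoff", {
  # focal sequence with three partners of distinct scores, each partner
  # having an identical twin so its own top slot is taken by the twin
  withr::local_seed(77)
  focal <- random_seq(30, letters = setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                     "")[[1]], "W"))
  # guard: all 28 overlapping tri-peptides distinct, so each substitution
  # removes exactly three shared peptides
  expect_length(build_peptide_list(focal, 3), 28)
  mutate <- function(s, at) {
    v <- strsplit(s, "")[[1]]
    v[at] <- "W"
    paste(v, collapse = "")
  }
  p1 <- mutate(focal, 4)
  p2 <- mutate(focal, c(4, 14))
  p3 <- mutate(focal, c(4, 14, 24))
  seqs <- c(focal, p1, p2, p3, p1, p2, p3)
  lists <- lapply(seqs, build_peptide_list, k = 3)
  st1 <- score_all_pairs(lists, presort_config(k = 3, M = 1, min_score = 0,
                                               adjacency_bonus = 0))
  got <- paste(st1$i, st1$j)
  # focal (1) retains only its best partner p1; weaker focal pairs are
  # skipped because one higher-scoring pair exists on both endpoints
  expect_true("1 2" %in% got)
  expect_false(any(c("1 3", "1 4") %in% got))
  # every twin pair survives (it is each partner's own best)
  expect_true(all(c("2 5", "3 6", "4 7") %in% got))
  # a larger M readmits the next-best focal pair
  st3 <- score_all_pairs(lists, presort_config(k = 3, M = 3, min_score = 0,
                                               adjacency_bonus = 0))
  expect_true(all(c("1 2", "1 3") %in% paste(st3$i, st3$j)))
  expect_gt(nrow(st3), nrow(st1))
})

test_that("min_score discards weak pairs and the adjacency bonus is applied", {
  lists <- lapply(c("AAAAAA", "AAAAAA", "CCCCCC"), build_peptide_list, k = 3)
  # homopolymer pair scores 1; below the default cutoff of 10
  st <- score_all_pairs(lists, presort_config(k = 3))
  expect_equal(nrow(st), 0)
  # adjacency bonus lifts only the (1,2) neighbour pair over a cutoff of 2
  st <- score_all_pairs(lists, presort_config(k = 3, min_score = 2,
                                              adjacency_bonus = 2))
  expect_equal(nrow(st), 1)
  expect_equal(c(st$i, st$j, st$score), c(1, 2, 3))
})

test_that("blocked-diagonal partitioning never scores cross-block pairs", {
  seqs <- rep("GLEAFERLKEGLEAFERLKE", 4)
  lists <- lapply(seqs, build_peptide_list, k = 3)
  st <- score_all_pairs(lists, presort_config(k = 3, M = 3, min_score = 0,
                                              n_blocks = 2))
  got <- paste(st$i, st$j)
  expect_true(all(got %in% c("1 2", "3 4")))
})

test_that("presort order puts single-linkage clusters contiguously, ranked", {
  st <- data.frame(i = c(1, 6), j = c(6, 10), score = c(40, 35))
  ord <- presort_order(st, 10)
  expect_equal(ord[1:3], c(1, 6, 10))
  expect_equal(presort_order(data.frame(i = integer(), j = integer(),
                                        score = numeric()), 5), 1:5)
  # higher-scoring cluster precedes, remaining sequences keep input order
  st <- data.frame(i = c(3, 1), j = c(4, 2), score = c(30, 20))
  expect_equal(presort_order(st, 5), c(3, 4, 1, 2, 5))
})

test_that("presort cluster memberships match a naive single-linkage oracle", {
  withr::local_seed(303)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    seqs <- replicate(n, random_seq(30, letters = c("A", "C", "D")))
    lists <- lapply(seqs, build_peptide_list, k = 3)
    st <- score_all_pairs(lists, presort_config(k = 3, M = 3, min_score = 5,
                                                adjacency_bonus = 0))
    ord <- presort_order(st, n)
    expect_setequal(ord, 1:n)
    truth <- oracle_single_linkage(st, n)
    # each oracle cluster must be contiguous in the presort order
    pos <- match(1:n, ord)
    for (cl in unique(truth)) {
      at <- sort(pos[truth == cl])
      expect_equal(at, seq(min(at), length.out = length(at)))
    }
  }
})

test_that("alphabet softening is idempotent and monotonically coarsening", {
  expect_equal(soften_alphabet("GLEAFERLKE", 0), "GLEAFERLKE")
  expect_equal(soften_alphabet("ILVK", 1), "IIIK")
  all20 <- paste(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], collapse = "")
  sizes <- vapply(0:4, function(l)
    length(unique(strsplit(soften_alphabet(all20, l), "")[[1]])), 1L)
  expect_true(all(diff(sizes) < 0))
  for (l in 0:4) {
    once <- soften_alphabet(all20, l)
    expect_equal(soften_alphabet(once, l), once)
  }
  expect_error(soften_alphabet("AC", 9), "level")
})
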