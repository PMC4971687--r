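NON_AA <- c("B", "J", "O", "U", "X", "Z")

#' Generate artificial acid-rich sequence families
#'
#' Builds the 20-family benchmark used to validate segregation. Each family
#' starts from a homopolymer of one amino-acid type and undergoes successive
#' random single-position substitutions drawn uniformly from the 26 letters,
#' the non-amino-acid codes B, J, O, U, X, Z being replaced by the gap
#' character. Whenever the (gap-excluded) composition of the starting residue
#' falls to 1/3 or below, random positions are substituted back to it until
#' the composition is again above 1/3 -- 33 % being close to the limit at
#' which sequence similarity can be detected, so members of one family align
#' with each other but not with another family. Sequences are snapshotted at
#' geometrically spaced points along the mutation trajectory (so each family
#' spans near-identical to maximally diverged members), shuffled into random
#' order, and their gap characters removed.
#'
#' @param n_seqs total sequences (split equally over the 20 families).
#' @param seed_len homopolymer length (residues); default 100.
#' @param min_frac minimum retained fraction of the starting residue;
#'   default 1/3.
#' @param rng_seed integer seed; identical seeds give identical sets.
#' @param n_events nominal mutation-trajectory length per family (events);
#'   default 250, which carries each family well past the composition floor.
#' @return a [seq_records] frame with an extra `family` column (the true
#'   family letter) for scoring segregation.
#' @export
make_families <- function(n_seqs = 2000L, seed_len = 100L, min_frac = 1 / 3,
                          rng_seed = 1L, n_events = 250L) {
  stopifnot(n_seqs >= 20, seed_len >= 10)
  set.seed(rng_seed)
  per_fam <- ceiling(n_seqs / 20)
  snap <- round(exp(seq(log(1), log(n_events), length.out = per_fam)))
  for (i in seq_along(snap)[-1])
    snap[i] <- max(snap[i], snap[i - 1] + 1L)
  residues <- character(0)
  family <- character(0)
  for (f in AA_LETTERS) {
    s <- rep(f, seed_len)
    out <- character(length(snap))
    k <- 1L
    for (t in seq_len(max(snap))) {
      s[sample.int(seed_len, 1)] <- {
        ch <- LETTERS[sample.int(26, 1)]
        if (ch %in% NON_AA) "-" else ch
      }
      repeat {
        ng <- sum(s != "-")
        if (ng > 0 && sum(s == f) / ng > min_frac) break
        s[sample.int(seed_len, 1)] <- f
      }
      if (t == snap[k]) {
        out[k] <- paste(s, collapse = "")
        k <- k + 1L
      }
    }
    residues <- c(residues, out)
    family <- c(family, rep(f, length(out)))
  }
  code <- paste0(family, sprintf("%04d", sequence(rep(per_fam, 20))))
  ord <- order(runif(length(residues)))   # shuffle by a random number
  rec <- seq_records(code[ord], degap(residues[ord]))
  rec$family <- family[ord]
  rec[seq_len(min(n_seqs, nrow(rec))), , drop = FALSE]
}

#' Reversed-sequence dopplegangers
#'
#' For every record, adds a partner whose residue string is reversed (code
#' suffixed `_rev`). Reversed sequences keep the length distribution and
#' composition of the originals, making them hard negative controls: a clean
#' reduction should segregate natives from their dopplegangers. The combined
#' set is shuffled; the `native` column retains the true label.
#'
#' @param records a [seq_records] frame.
#' @param rng_seed seed for the interleaving shuffle.
#' @return a [seq_records] frame of `2 * nrow(records)` rows with a `native`
#'   logical column.
#' @export
make_dopplegangers <- function(records, rng_seed = 1L) {
  stopifnot(nrow(records) >= 1)
  rev_str <- vapply(strsplit(records$residues, ""),
                    function(x) paste(rev(x), collapse = ""), "")
  if (any(rev_str == records$residues))
    warning("palindromic sequence(s): doppleganger identical to original")
  twin <- records
  twin$code <- paste0(records$code, "_rev")
  twin$residues <- rev_str
  records$native <- TRUE
  twin$native <- FALSE
  both <- rbind(records, twin)
  class(both) <- c("seq_records", "data.frame")
  set.seed(rng_seed)
  both <- both[order(runif(nrow(both))), , drop = FALSE]
  rownames(both) <- NULL
  both
}

#' Score the segregation of a reduced collection
#'
#' Checks whether the final sequence order splits into label-pure contiguous
#' blocks (e.g. natives vs dopplegangers, or true families).
#'
#' @param records ordered [seq_records] frame (or `family_msa`).
#' @param labels label per final record: a vector aligned with the records, a
#'   named vector keyed by code, or the name of a column of `records` (e.g.
#'   `"native"` or `"family"`).
#' @return list with `pure` (do labels form contiguous blocks?),
#'   `n_switches` (label changes along the order) and `counts` (surviving
#'   representatives per label).
#' @export
segregation_score <- function(records, labels = "family") {
  if (inherits(records, "family_msa")) records <- records$records
  lab <- if (length(labels) == 1 && is.character(labels) &&
             labels %in% names(records)) {
    records[[labels]]
  } else if (!is.null(names(labels))) {
    labels[records$code]
  } else {
    if (length(labels) != nrow(records))
      stop("labels do not cover every final record")
    labels
  }
  if (anyNA(lab)) stop("labels missing for some final records")
  lab <- as.character(lab)
  switches <- sum(lab[-1] != lab[-length(lab)])
  list(pure = switches == length(unique(lab)) - 1L,
       n_switches = switches,
       counts = table(lab))
}

#' Synthetic "native-like" family from a high-order Markov chain
#'
#' Stand-in for a real protein family when none is available: an ancestor is
#' emitted by a randomly parameterised order-`order` Markov chain over the 20
#' amino acids (giving it directional local statistics, which real sequences
#' have and uniform random strings lack), and family members are snapshots of
#' a random substitution trajectory from that ancestor. Useful together with
#' [make_dopplegangers()] as a smoke test of native/reversed segregation.
#'
#' @param n family size.
#' @param len sequence length.
#' @param order Markov order of the ancestor chain (default 2).
#' @param rng_seed integer seed.
#' @param n_events substitution-trajectory length (default `len`).
#' @return a [seq_records] frame with a `family` column set to `"markov"`.
#' @export
make_markov_family <- function(n = 50L, len = 80L, order = 2L, rng_seed = 1L,
                               n_events = len) {
  set.seed(rng_seed)
  # sparse preferred-successor table: each context strongly favours 3 residues
  n_ctx <- 20L^order
  pref <- matrix(sample.int(20, 3 * n_ctx, replace = TRUE), ncol = 3)
  emit <- function(ctx) {
    if (runif(1) < 0.8) pref[ctx, sample.int(3, 1)] else sample.int(20, 1)
  }
  anc <- integer(len)
  anc[seq_len(order)] <- sample.int(20, order, replace = TRUE)
  for (i in (order + 1):len) {
    ctx <- 1L + sum((anc[(i - order):(i - 1)] - 1L) * 20L^(seq_len(order) - 1L))
    anc[i] <- emit(ctx)
  }
  s <- AA_LETTERS[anc]
  snap <- round(seq(1, n_events, length.out = n))
  for (i in seq_along(snap)[-1]) snap[i] <- max(snap[i], snap[i - 1] + 1L)
  out <- character(n)
  k <- 1L
  for (t in seq_len(max(snap))) {
    s[sample.int(len, 1)] <- AA_LETTERS[sample.int(20, 1)]
    if (t == snap[k]) {
      out[k] <- paste(s, collapse = "")
      k <- k + 1L
    }
  }
  rec <- seq_records(sprintf("mkv%04d", seq_len(n)), out)
  rec$family <- "markov"
  rec
}
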