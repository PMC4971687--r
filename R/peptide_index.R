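#' Presort configuration
#'
#' Parameters of the alignment-free peptide presort.
#'
#' @param k peptide (k-mer) length; default 4 (a tetra-peptide).
#' @param soften alphabet-reduction level 0-4 (see [soften_alphabet()]);
#'   default 0 (no reduction).
#' @param M maximum number of top-scoring partners retained per sequence;
#'   default 3.
#' @param min_score minimum common-peptide score for a pair to be stored;
#'   default 10.
#' @param adjacency_bonus small score added to pairs adjacent in the input
#'   order, preserving pre-existing order in the absence of stronger signal;
#'   default 2 (below `min_score`, so it never rescues a zero-score pair).
#' @param n_blocks number of contiguous blocks of the current order within
#'   which pairs are evaluated (blocked-diagonal partitioning); 1 evaluates
#'   all pairs.
#' @return a `presort_config` list.
#' @export
presort_config <- function(k = 4L, soften = 0L, M = 3L, min_score = 10,
                           adjacency_bonus = 2, n_blocks = 1L) {
  stopifnot(k >= 1, M >= 1, n_blocks >= 1, soften %in% 0:4)
  structure(list(k = as.integer(k), soften = as.integer(soften),
                 M = as.integer(M), min_score = min_score,
                 adjacency_bonus = adjacency_bonus,
                 n_blocks = as.integer(n_blocks)),
            class = "presort_config")
}

#' Ordered list of distinct k-peptides of a sequence
#'
#' Every overlapping k-length substring is hashed to a numeric code and
#' inserted once into an unbalanced binary search tree; a depth-first
#' left-right traversal then emits the distinct peptides in ascending order
#' (the tree-sort takes O(L log L) in the sequence length). Sequences shorter
#' than `k` yield an empty list.
#'
#' @param residues residue string (gaps allowed; softening is applied first).
#' @param k peptide length.
#' @param soften alphabet-reduction level 0-4.
#' @param as_strings return peptide strings rather than numeric encodings.
#' @return ascending vector of distinct peptide encodings (or strings).
#' @export
build_peptide_list <- function(residues, k = 4L, soften = 0L,
                               as_strings = FALSE) {
  keys <- cpp_peptide_list(soften_alphabet(residues, soften), as.integer(k))
  if (as_strings) cpp_decode_peptides(keys, as.integer(k)) else keys
}

#' Count of peptides common to two ordered peptide lists
#'
#' A single two-pointer pass over the two sorted lists (linear time). The
#' score is symmetric, equals the list length on self-comparison, and is the
#' alignment-free similarity used by the presort.
#'
#' @param a,b ascending numeric peptide lists from [build_peptide_list()].
#' @return integer count of shared peptides.
#' @export
common_peptide_score <- function(a, b) cpp_common_count(a, b)

#' Score all sequence pairs, keeping the top M per sequence
#'
#' Evaluates common-peptide scores for pairs within the same contiguous block
#' of the current order (all pairs when `n_blocks = 1`). Pairs adjacent in
#' the input order get `adjacency_bonus` before thresholding; scores below
#' `min_score` are discarded and only each sequence's `M` best partners are
#' retained, so storage is O(N M), never O(N^2).
#'
#' @param lists list of peptide lists in current order.
#' @param cfg a [presort_config()].
#' @return a `pair_store`: data frame of stored pairs (`i`, `j`, `score`,
#'   1-based indices, `i < j`) rank-sorted by descending score, ties by
#'   smaller index.
#' @export
score_all_pairs <- function(lists, cfg = presort_config()) {
  ps <- cpp_score_pairs(lists, cfg$M, cfg$min_score, cfg$adjacency_bonus,
                        cfg$n_blocks)
  attr(ps, "n") <- length(lists)
  class(ps) <- c("pair_store", "data.frame")
  ps
}

#' Single-linkage ordering from a ranked pair store
#'
#' Grows clusters by single linkage in one pass over the rank-sorted pair
#' list (highest score first). Members of each cluster occupy contiguous
#' positions in linkage-accretion order; clusters are placed in descending
#' order of their best pair score (ties by smallest original index);
#' sequences with no stored pairs keep their relative input order at the end.
#'
#' @param store a pair store from [score_all_pairs()] (or any data frame of
#'   `i`, `j`, `score` sorted by rank).
#' @param n number of sequences.
#' @return integer permutation of `1:n`.
#' @export
presort_order <- function(store, n) {
  if (nrow(store) == 0) return(seq_len(n))
  si <- as.integer(store$i)
  sj <- as.integer(store$j)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  members <- vector("list", n)   # accretion-ordered members per cluster root
  best <- rep(-Inf, n)           # best pair score seen per cluster root
  first <- seq_len(n)            # smallest original index per cluster root
  for (q in seq_len(nrow(store))) {
    i <- si[q]; j <- sj[q]; s <- store$score[q]
    ri <- find(i); rj <- find(j)
    if (ri == rj) next
    mi <- if (is.null(members[[ri]])) ri else members[[ri]]
    mj <- if (is.null(members[[rj]])) rj else members[[rj]]
    # the cluster with the higher established best score keeps the front;
    # ties resolved by smaller original index
    keep_i <- if (best[ri] != best[rj]) best[ri] > best[rj] else first[ri] < first[rj]
    merged <- if (keep_i) c(mi, mj) else c(mj, mi)
    parent[rj] <- ri
    members[[ri]] <- merged
    members[rj] <- list(NULL)
    best[ri] <- max(best[ri], best[rj], s)
    first[ri] <- min(first[ri], first[rj])
  }
  roots <- unique(vapply(seq_len(n), find, 1L))
  clustered <- roots[!vapply(members[roots], is.null, TRUE)]
  ord <- order(-best[clustered], first[clustered])
  out <- unlist(members[clustered[ord]], use.names = FALSE)
  c(out, setdiff(seq_len(n), out))
}

#' One or more presort passes over a record collection
#'
#' Builds peptide lists once, then repeatedly scores pairs under the blocked
#' partition and reorders by [presort_order()]. Blocks are contiguous slices
#' of the *current* order, so successive passes mix previously separated
#' blocks.
#'
#' @param records a [seq_records] frame.
#' @param cfg a [presort_config()].
#' @param passes number of score/reorder passes.
#' @return the reordered [seq_records] frame.
#' @export
presort <- function(records, cfg = presort_config(), passes = 1L) {
  lists <- lapply(degap(records$residues), build_peptide_list,
                  k = cfg$k, soften = cfg$soften)
  for (p in seq_len(passes)) {
    store <- score_all_pairs(lists, cfg)
    ord <- presort_order(store, length(lists))
    lists <- lists[ord]
    records <- records[ord, , drop = FALSE]
  }
  records
}
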