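#' Alignment configuration
#'
#' Parameters of the span-limited profile/profile condensation engine.
#'
#' @param cutoff similarity threshold on the 0-100 identity scale above which
#'   pairs are clustered and aligned.
#' @param span maximum separation in the current order within which pairs are
#'   compared (default 50); `Inf` compares all pairs.
#' @param gap_open,gap_extend affine gap penalties in points on the 0-100
#'   similarity scale (defaults 10 and 1).
#' @param max_insert half-width of the dynamic-programming band used at
#'   early, high-cutoff stages (cutoff > 60), constraining insertions to a
#'   few positions; the band is dropped at cutoffs <= 60.
#' @param matrix 21 x 21 residue exchange matrix ([identity_matrix()] by
#'   default; [blosum_matrix()] for real proteins). Gaps always score 0.
#' @param n_iterations alignment cycles per condensation, bounding
#'   mini-alignment size at `2^n_iterations` members (default 3, so 8).
#' @return an `align_config` list.
#' @export
align_config <- function(cutoff = 50, span = 50, gap_open = 10,
                         gap_extend = 1, max_insert = 10L,
                         matrix = identity_matrix(), n_iterations = 3L) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == 21), gap_open >= 0,
            gap_extend >= 0, n_iterations >= 1)
  structure(list(cutoff = cutoff, span = span, gap_open = gap_open,
                 gap_extend = gap_extend, max_insert = as.integer(max_insert),
                 matrix = matrix, n_iterations = as.integer(n_iterations)),
            class = "align_config")
}

cfg_band <- function(cfg) if (cfg$cutoff > 60) cfg$max_insert else -1L
cfg_span <- function(cfg) if (is.finite(cfg$span)) as.integer(cfg$span) else -1L

profile_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "seq_records")) {
    stopifnot(nrow(x) >= 1)
    len <- unique(nchar(x$residues))
    if (length(len) > 1) stop("ragged residue strings cannot form a profile")
    return(do.call(rbind, lapply(x$residues, encode_residues)))
  }
  if (is.character(x))
    return(do.call(rbind, lapply(x, encode_residues)))
  stop("cannot interpret profile input")
}

#' Profile/profile similarity score
#'
#' Globally aligns two profiles by affine-gap dynamic programming. Each
#' column pair scores the average of `matrix[a, b]` over all member
#' cross-pairs (gaps scoring 0); the reported similarity is 100 times the sum
#' of column-pair scores along the optimal path divided by the shorter
#' profile length. Two identical sequences under the identity matrix score
#' 100 and a 50 %-identical pair scores 50, which anchors all cutoffs.
#'
#' @param a,b profiles: residue strings, [seq_records] frames (gapped strings
#'   of equal length), or integer code matrices.
#' @param cfg an [align_config()].
#' @return similarity score on the 0-100 scale.
#' @export
profile_pair_score <- function(a, b, cfg = align_config()) {
  r <- cpp_align_profiles(profile_matrix(a), profile_matrix(b), cfg$matrix,
                          cfg$gap_open, cfg$gap_extend, cfg_band(cfg), FALSE)
  r$score
}

#' Align two profiles and merge them
#'
#' @inheritParams profile_pair_score
#' @return a list with `score` and `mat`, the merged member-by-column code
#'   matrix (members of `a` first).
#' @export
align_pair <- function(a, b, cfg = align_config()) {
  A <- profile_matrix(a); B <- profile_matrix(b)
  r <- cpp_align_profiles(A, B, cfg$matrix, cfg$gap_open, cfg$gap_extend,
                          cfg_band(cfg), TRUE)
  L <- length(r$a_path)
  m <- matrix(CODE_GAP, nrow = nrow(A) + nrow(B), ncol = L)
  ia <- r$a_path > 0
  ib <- r$b_path > 0
  m[seq_len(nrow(A)), ia] <- A[, r$a_path[ia], drop = FALSE]
  m[nrow(A) + seq_len(nrow(B)), ib] <- B[, r$b_path[ib], drop = FALSE]
  list(score = r$score, mat = m)
}

new_mini_alignment <- function(records, mat, idx) {
  structure(list(records = records[idx, , drop = FALSE],
                 gapped = vapply(seq_len(nrow(mat)),
                                 function(r) decode_residues(mat[r, ]), ""),
                 idx = idx),
            class = "mini_alignment")
}

#' @export
print.mini_alignment <- function(x, ...) {
  cat(sprintf("mini_alignment: %d members x %d columns\n",
              length(x$gapped), nchar(x$gapped[1])))
  for (i in seq_along(x$gapped))
    cat(sprintf("%-12s %s\n", substr(x$records$code[i], 1, 12), x$gapped[i]))
  invisible(x)
}

# internal condensation over units (list of list(mat, idx, node)); returns
# units after `cycles` rounds of span-limited single-linkage merging.
condense_units <- function(units, cfg, cycles = cfg$n_iterations) {
  band <- cfg_band(cfg)
  for (cyc in seq_len(cycles)) {
    if (length(units) < 2) break
    pairs <- cpp_span_pair_scores(lapply(units, `[[`, "mat"), cfg_span(cfg),
                                  cfg$matrix, cfg$gap_open, cfg$gap_extend,
                                  band, cfg$cutoff)
    if (nrow(pairs) == 0) break
    n <- length(units)
    # each unit joins at most one merge per cycle, taken in rank order, so a
    # mini-alignment can at most double each cycle (2^n_iterations bound)
    used <- rep(FALSE, n)
    keep <- rep(TRUE, n)
    for (q in seq_len(nrow(pairs))) {
      a <- pairs$i[q]; b <- pairs$j[q]    # a < b: earlier unit keeps the front
      if (used[a] || used[b]) next
      merged <- align_pair(units[[a]]$mat, units[[b]]$mat, cfg)
      units[[a]] <- list(mat = merged$mat,
                         idx = c(units[[a]]$idx, units[[b]]$idx),
                         node = list(score = pairs$score[q],
                                     left = units[[a]]$node,
                                     right = units[[b]]$node))
      used[a] <- TRUE; used[b] <- TRUE
      keep[b] <- FALSE
    }
    if (all(keep)) break
    units <- units[keep]
  }
  units
}

records_to_units <- function(records) {
  lapply(seq_len(nrow(records)), function(i)
    list(mat = matrix(encode_residues(records$residues[i]), nrow = 1),
         idx = i, node = records$code[i]))
}

#' One condensation round
#'
#' Scores all pairs of units within `span` of each other in the current
#' order; pairs at or above `cutoff` are single-linkage clustered and each
#' cluster merged by progressive profile/profile alignment in descending
#' pair-score order. The cycle repeats `n_iterations` times so that
#' mini-alignments can themselves pair up (size at most `2^n_iterations`).
#' Output keeps each cluster at the position of its first member.
#'
#' @param records a [seq_records] frame in current order.
#' @param cfg an [align_config()].
#' @return list of `mini_alignment` objects (untouched
#'   singletons appear as one-member alignments).
#' @export
condense_once <- function(records, cfg = align_config()) {
  units <- condense_units(records_to_units(records), cfg)
  lapply(units, function(u) new_mini_alignment(records, u$mat, u$idx))
}

#' Final multiple alignment of a reduced collection
#'
#' Computes all pairwise sequence similarities among the survivors, joins
#' pairs at or above `floor` by single-linkage clustering, and merges each
#' cluster by progressive profile/profile alignment in descending pair-score
#' order (ranked merging is the stepwise lowering of the cutoff from `from`
#' to `floor`). Surviving representatives of the same family merge into one
#' block while unrelated families stay as separate blocks; no representative
#' selection is performed, so all records survive into the final alignment.
#' Clustering uses the similarity of the member *sequences*, not the merged
#' profiles, so a diverse family is not split by profile averaging.
#'
#' @param records a [seq_records] frame (at most a few hundred rows).
#' @param cfg an [align_config()]; its `cutoff` and `span` are ignored.
#' @param from,floor,step cutoff schedule (defaults 50 down to 25 by 5);
#'   `from` and `step` only affect the dendrogram ordering, `floor` decides
#'   what merges.
#' @return a `family_msa`: list with `blocks` (list of
#'   mini-alignments, one per family), `records` (ordered), `n_families`,
#'   and `dendrogram` (indented text of the linkage tree per block).
#' @export
final_align <- function(records, cfg = align_config(), from = 50, floor = 25,
                        step = 5) {
  stopifnot(nrow(records) >= 1)
  ccfg <- cfg
  ccfg$cutoff <- floor   # band dropped at low cutoffs
  units <- records_to_units(records)
  n <- length(units)
  pairs <- cpp_span_pair_scores(lapply(units, `[[`, "mat"), -1L, ccfg$matrix,
                                ccfg$gap_open, ccfg$gap_extend,
                                cfg_band(ccfg), floor)
  where <- seq_len(n)   # unit currently holding each original record slot
  if (nrow(pairs) > 0) {
    for (q in seq_len(nrow(pairs))) {
      a <- where[pairs$i[q]]; b <- where[pairs$j[q]]
      if (a == b) next
      if (a > b) { tmp <- a; a <- b; b <- tmp }   # earlier unit keeps the front
      merged <- align_pair(units[[a]]$mat, units[[b]]$mat, ccfg)
      units[[a]] <- list(mat = merged$mat,
                         idx = c(units[[a]]$idx, units[[b]]$idx),
                         node = list(score = pairs$score[q],
                                     left = units[[a]]$node,
                                     right = units[[b]]$node))
      where[where == b] <- a
      units[b] <- list(NULL)
    }
    units <- units[!vapply(units, is.null, TRUE)]
  }
  blocks <- lapply(units, function(u) new_mini_alignment(records, u$mat, u$idx))
  ord <- unlist(lapply(units, `[[`, "idx"))
  structure(list(blocks = blocks,
                 records = records[ord, , drop = FALSE],
                 n_families = length(units),
                 dendrogram = vapply(units, function(u)
                   render_dendrogram(u$node), "")),
            class = "family_msa")
}

render_dendrogram <- function(node, depth = 0) {
  pad <- strrep("  ", depth)
  if (is.character(node)) return(paste0(pad, node, "\n"))
  paste0(pad, sprintf("+-[%.1f]\n", node$score),
         render_dendrogram(node$left, depth + 1),
         render_dendrogram(node$right, depth + 1))
}

#' @export
print.family_msa <- function(x, ...) {
  cat(sprintf("family_msa: %d families, %d sequences\n",
              x$n_families, nrow(x$records)))
  for (b in seq_along(x$blocks))
    cat(sprintf("  family %d: %d members x %d columns\n", b,
                length(x$blocks[[b]]$gapped), nchar(x$blocks[[b]]$gapped[1])))
  invisible(x)
}

#' Count subfamilies by sequence adjacency
#'
#' Number of maximal runs of adjacent records, in the given order, in which
#' every consecutive pair scores at or above `cutoff`
#' ([profile_pair_score()] on the single de-gapped sequences). On the
#' artificial benchmark a fully successful reduction gives one run per
#' acid-rich family, i.e. a count of 20.
#'
#' @param records ordered [seq_records] frame (or a `family_msa`, whose
#'   record order is used).
#' @param cutoff adjacency threshold on the 0-100 scale.
#' @param cfg an [align_config()].
#' @return integer subfamily count.
#' @export
count_subfamilies <- function(records, cutoff, cfg = align_config()) {
  if (inherits(records, "family_msa")) records <- records$records
  n <- nrow(records)
  if (n <= 1) return(n)
  res <- degap(records$residues)
  breaks <- vapply(seq_len(n - 1), function(i)
    profile_pair_score(res[i], res[i + 1], cfg) < cutoff, TRUE)
  1L + sum(breaks)
}
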