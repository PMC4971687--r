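#' Annotation penalty table
#'
#' Biases applied when choosing the representative of a mini-alignment; the
#' lowest total penalty wins. Negative values favour retention. Defaults:
#' PDB-coded sequences -60, UniProt -20; title keywords "mutant" +40,
#' "fragment" +50, "probable" +1, "precursor" +2, "uncharacterised" +5,
#' "hypothetical" +5; a SEED sequence (upper-case `SEED` in the code) -100 so
#' it is always kept; members of a seed alignment (lower-case `seed`) -50.
#' Keyword matching over the title is case-insensitive; multiple keywords
#' accumulate. The penalty units are nominally common-peptide counts, summed
#' as raw numbers with the log-scale length penalty.
#'
#' @param ... named overrides of the defaults listed above.
#' @return named numeric vector of biases.
#' @export
penalty_table <- function(...) {
  tbl <- c(pdb_bias = -60, uniprot_bias = -20, mutant = 40, fragment = 50,
           probable = 1, precursor = 2, uncharacterised = 5, hypothetical = 5,
           seed_upper = -100, seed_lower = -50)
  over <- c(...)
  if (length(over)) {
    if (is.null(names(over)) || !all(names(over) %in% names(tbl)))
      stop("unknown penalty name")
    tbl[names(over)] <- over
  }
  tbl
}

#' Length-deviation penalty
#'
#' `p = ln(d^2 + 1)` where `d` is the deviation of the sequence length from
#' the target length (the seed length when a SEED sequence is present in the
#' mini-alignment, otherwise the mean member length). The penalty is about 5
#' at a deviation of 12 residues and rises to about 9 by 100 residues. When a
#' seed is present, sequences *longer* than the seed incur only half the
#' penalty, directing selection away from fragments and countering terminal
#' shrinkage.
#'
#' @param seq_len sequence length (residues, gaps excluded).
#' @param target_len target length.
#' @param longer_than_seed is this sequence longer than the seed?
#' @param seed_present is a SEED sequence present in the mini-alignment?
#' @return penalty value (natural log scale).
#' @export
length_penalty <- function(seq_len, target_len, longer_than_seed = FALSE,
                           seed_present = FALSE) {
  d <- abs(seq_len - target_len)
  p <- log(d^2 + 1)
  ifelse(seed_present & longer_than_seed, p / 2, p)
}

pdb_coded <- function(code) {
  grepl("pdb|", code, fixed = TRUE) |
    grepl("^[0-9][A-Za-z0-9]{3}(_[A-Za-z0-9])?$", code)
}

uniprot_coded <- function(code) {
  grepl("sp|", code, fixed = TRUE) | grepl("tr|", code, fixed = TRUE)
}

#' Annotation penalty of a record
#'
#' Sum of all biases triggered by a record's code and title (see
#' [penalty_table()]), plus any user-supplied per-code bias.
#'
#' @param record one-row [seq_records] frame (vectorised over rows).
#' @param table a [penalty_table()].
#' @param user_bias optional named numeric vector, names being codes of
#'   user-marked sequences and values the bias to add.
#' @return numeric penalty per record.
#' @export
annotation_penalty <- function(record, table = penalty_table(),
                               user_bias = NULL) {
  title <- tolower(record$title)
  p <- ifelse(pdb_coded(record$code), table[["pdb_bias"]], 0) +
    ifelse(uniprot_coded(record$code), table[["uniprot_bias"]], 0) +
    ifelse(grepl("mutant", title), table[["mutant"]], 0) +
    ifelse(grepl("fragment", title), table[["fragment"]], 0) +
    ifelse(grepl("probable", title), table[["probable"]], 0) +
    ifelse(grepl("precursor", title), table[["precursor"]], 0) +
    ifelse(grepl("uncharacteri[sz]ed", title), table[["uncharacterised"]], 0) +
    ifelse(grepl("hypothetical", title), table[["hypothetical"]], 0) +
    ifelse(record$is_seed, table[["seed_upper"]], 0) +
    ifelse(record$is_seed_member, table[["seed_lower"]], 0)
  if (!is.null(user_bias)) {
    hit <- match(record$code, names(user_bias))
    p <- p + ifelse(is.na(hit), 0, user_bias[hit])
  }
  unname(p)
}

#' Select the representative of a mini-alignment
#'
#' Each member's score is its length penalty (see [length_penalty()]) plus
#' its annotation penalty; the member with the lowest total is written to the
#' next sequence collection, de-gapped, with its `n_represented` set to the
#' sum over all members (so represented counts are conserved end-to-end).
#' Ties are broken by larger `n_represented`, then smaller member index.
#'
#' @param mini a `mini_alignment` (or any [seq_records] frame).
#' @param table a [penalty_table()].
#' @param user_bias optional named per-code bias vector.
#' @return one-row [seq_records] frame: the de-gapped representative.
#' @export
select_representative <- function(mini, table = penalty_table(),
                                  user_bias = NULL) {
  rec <- if (inherits(mini, "mini_alignment")) mini$records else mini
  stopifnot(nrow(rec) >= 1)
  lens <- nchar(degap(rec$residues))
  seed_at <- which(rec$is_seed)
  seed_present <- length(seed_at) > 0
  target <- if (seed_present) lens[seed_at[1]] else mean(lens)
  pen <- length_penalty(lens, target, longer_than_seed = lens > target,
                        seed_present = seed_present) +
    annotation_penalty(rec, table, user_bias)
  best <- order(pen, -rec$n_represented, seq_len(nrow(rec)))[1]
  out <- rec[best, , drop = FALSE]
  out$residues <- degap(out$residues)
  out$n_represented <- sum(rec$n_represented)
  out
}
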