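# Independent oracles used by the property tests. These deliberately share no
# code with the package internals they check.

# brute-force distinct-k-mer list via substring + sort
oracle_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  sort(unique(vapply(seq_len(L - k + 1), function(i)
    substr(seq, i, i + k - 1), "")))
}

# plain-R Gotoh alignment of two single sequences; same scoring conventions
# as the engine (identity matrix unless given, free terminal gaps, penalties
# in points on the final 0-100 scale) but coded independently with full
# matrices and explicit loops. Returns the 0-100 similarity.
oracle_pair_score <- function(s1, s2, go = 10, ge = 1, mat = NULL) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  La <- length(a); Lb <- length(b); Lmin <- min(La, Lb)
  colscore <- function(x, y) {
    if (is.null(mat)) 100 * (x == y && x != "-") else 100 * mat[x, y]
  }
  NEG <- -1e18
  M <- Ix <- Iy <- matrix(NEG, La + 1, Lb + 1)
  Mm <- Xm <- Ym <- matrix(0, La + 1, Lb + 1)
  M[1, 1] <- 0
  Ix[2:(La + 1), 1] <- 0   # free leading gaps in b
  Iy[1, 2:(Lb + 1)] <- 0   # free leading gaps in a
  gopen <- (go + ge) * Lmin
  gext <- ge * Lmin
  for (i in 2:(La + 1)) {
    for (j in 2:(Lb + 1)) {
      s <- colscore(a[i - 1], b[j - 1])
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      prem <- c(Mm[i - 1, j - 1], Xm[i - 1, j - 1], Ym[i - 1, j - 1])
      w <- which.max(prev)
      if (prev[w] > NEG / 2) {
        M[i, j] <- prev[w] + s
        Mm[i, j] <- prem[w] + s
      }
      op <- if (j - 1 == Lb) 0 else gopen
      ex <- if (j - 1 == Lb) 0 else gext
      cand <- c(M[i - 1, j] - op, Ix[i - 1, j] - ex)
      cm <- c(Mm[i - 1, j], Xm[i - 1, j])
      w <- which.max(cand)
      if (cand[w] > NEG / 2) { Ix[i, j] <- cand[w]; Xm[i, j] <- cm[w] }
      op <- if (i - 1 == La) 0 else gopen
      ex <- if (i - 1 == La) 0 else gext
      cand <- c(M[i, j - 1] - op, Iy[i, j - 1] - ex)
      cm <- c(Mm[i, j - 1], Ym[i, j - 1])
      w <- which.max(cand)
      if (cand[w] > NEG / 2) { Iy[i, j] <- cand[w]; Ym[i, j] <- cm[w] }
    }
  }
  # free leading-gap rows feed row/col 2; handle j = 1 column feeding
  best <- which.max(c(M[La + 1, Lb + 1], Ix[La + 1, Lb + 1], Iy[La + 1, Lb + 1]))
  c(Mm[La + 1, Lb + 1], Xm[La + 1, Lb + 1], Ym[La + 1, Lb + 1])[best] / Lmin
}

# naive single-linkage memberships from a ranked pair list
oracle_single_linkage <- function(pairs, n) {
  comp <- seq_len(n)
  if (nrow(pairs)) {
    for (q in seq_len(nrow(pairs))) {
      ci <- comp[pairs$i[q]]; cj <- comp[pairs$j[q]]
      if (ci != cj) comp[comp == cj] <- ci
    }
  }
  match(comp, unique(comp))
}

random_seq <- function(len, letters = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

make_records <- function(residues, code = sprintf("s%02d", seq_along(residues)),
                         title = "") {
  seq_records(code, residues, title)
}
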