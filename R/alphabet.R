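#' Amino-acid alphabet and residue coding
#'
#' Residues are coded internally as integers: the 20 amino acids in the fixed
#' order `ACDEFGHIKLMNPQRSTVWY` take codes 0-19, `X` (unknown) 20 and the gap
#' `-` 21. Scoring matrices cover the 21 non-gap states; gaps always score 0.
#' @name alphabet
NULL

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
ALL_LETTERS <- c(AA_LETTERS, "X", "-")
CODE_X <- 20L
CODE_GAP <- 21L

encode_residues <- function(residues) cpp_encode(residues)
decode_residues <- function(codes) cpp_decode(as.integer(codes))

#' Identity substitution matrix
#'
#' 21 x 21 matrix (20 amino acids + X) with 1 on the diagonal and 0
#' elsewhere. Under this matrix the profile/profile similarity of two single
#' sequences is their percentage identity, the normalisation anchor used by
#' all the artificial-data experiments.
#'
#' @return numeric 21 x 21 matrix with residue-letter dimnames.
#' @export
identity_matrix <- function() {
  m <- diag(21)
  dimnames(m) <- list(c(AA_LETTERS, "X"), c(AA_LETTERS, "X"))
  m
}

#' BLOSUM62-derived substitution matrix on the identity scale
#'
#' Takes BLOSUM62 (from Biostrings), clamps negative entries to zero and
#' divides by the mean amino-acid self-score, so that the average self-score
#' is 1 and profile similarities stay on the same 0-100 scale anchored by
#' [identity_matrix()]. Intended for real protein families; the identity
#' matrix remains the default for benchmark data.
#'
#' @return numeric 21 x 21 matrix with residue-letter dimnames.
#' @export
blosum_matrix <- function() {
  b <- get_blosum62()
  keep <- c(AA_LETTERS, "X")
  m <- b[keep, keep]
  m[m < 0] <- 0
  m <- m / mean(diag(m[AA_LETTERS, AA_LETTERS]))
  m
}

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

# Nested alphabet 'softening' groups. Levels strictly coarsen: each level's
# classes are unions of the previous level's, so softening is monotone and
# idempotent (every class maps to its alphabetically first member, which maps
# to itself).
soften_groups <- list(
  level1 = list(c("I", "L", "V"), c("K", "R"), c("D", "E"), c("S", "T"),
                c("F", "Y")),
  level2 = list(c("I", "L", "V"), c("K", "R"), c("D", "E"), c("S", "T"),
                c("F", "W", "Y"), c("N", "Q")),
  level3 = list(c("I", "L", "V"), c("H", "K", "R"), c("D", "E"),
                c("S", "T"), c("F", "W", "Y"), c("N", "Q"), c("A", "G")),
  level4 = list(c("A", "G", "I", "L", "M", "V"), c("F", "W", "Y"),
                c("H", "K", "R"), c("D", "E"), c("N", "Q", "S", "T"),
                c("C", "P"))
)

soften_map <- function(level) {
  stopifnot(length(level) == 1, level %in% 0:4)
  map <- stats::setNames(ALL_LETTERS, ALL_LETTERS)
  if (level == 0) return(map)
  for (grp in soften_groups[[level]]) map[grp] <- sort(grp)[1]
  map
}

#' Reduce the amino-acid alphabet ("softening")
#'
#' Applies a many-to-one residue mapping before peptide extraction so that
#' similar residues count as shared peptides. Level 0 is the identity; levels
#' 1-4 apply progressively coarser physico-chemical merges (level 1 merges
#' I/L/V, K/R, D/E, S/T, F/Y; level 4 reduces to six classes). Levels nest,
#' so coarsening is monotone and the operation is idempotent. `X` and `-` are
#' never remapped.
#'
#' @param residues character string of residues (may contain `X` and `-`).
#' @param level integer 0-4.
#' @return softened residue string of the same length.
#' @export
soften_alphabet <- function(residues, level = 0L) {
  if (!(length(level) == 1 && level %in% 0:4)) stop("unknown softening level")
  if (level == 0) return(residues)
  map <- soften_map(level)
  chartr(paste(names(map), collapse = ""), paste(map, collapse = ""), residues)
}
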