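#' Sequence record collections
#'
#' A `seq_records` object is a data frame with one row per sequence and
#' columns:
#' \describe{
#'   \item{code}{identifier: header text up to the first whitespace.}
#'   \item{title}{free-text remainder of the header (without the
#'     `[+n+]` represented-count marker, which is parsed out).}
#'   \item{residues}{uppercase residue string over the 20 amino-acid letters
#'     plus `X` and (for gapped input) `-`.}
#'   \item{is_seed}{`TRUE` when the header (code or title) contains the
#'     string `SEED` (upper case): a user-designated sequence that must
#'     survive every reduction stage.}
#'   \item{is_seed_member}{`TRUE` when the code contains lower-case `seed`
#'     (restricted to the code because titles often contain the English
#'     word).}
#'   \item{n_represented}{number of original sequences this record stands
#'     for; serialised in the title as `[+n+]`, absent meaning 1.}
#' }
#'
#' @param code character vector of identifiers.
#' @param residues character vector of residue strings.
#' @param title character vector of free-text annotations.
#' @param n_represented integer vector of represented counts.
#' @return a `seq_records` data frame.
#' @export
seq_records <- function(code, residues, title = "", n_represented = 1L) {
  residues <- toupper(residues)
  bad <- grepl(sprintf("[^%sX-]", paste(AA_LETTERS, collapse = "")), residues)
  if (any(bad))
    stop("residues contain characters outside the amino-acid alphabet, 'X', '-': ",
         paste(head(code[bad], 3), collapse = ", "))
  df <- data.frame(
    code = as.character(code),
    title = rep_len(as.character(title), length(code)),
    residues = residues,
    # upper-case SEED anywhere in the header marks the seed; lower-case
    # "seed" is only meaningful inside the code (titles often contain the word)
    is_seed = grepl("SEED", code, fixed = TRUE) |
      grepl("SEED", title, fixed = TRUE),
    is_seed_member = grepl("seed", code, fixed = TRUE),
    n_represented = rep_len(as.integer(n_represented), length(code)),
    stringsAsFactors = FALSE
  )
  if (any(df$n_represented < 1L)) stop("n_represented must be >= 1")
  class(df) <- c("seq_records", "data.frame")
  df
}

#' @export
print.seq_records <- function(x, n = 8L, ...) {
  if (is.null(x$residues) || is.null(x$n_represented)) {
    print(as.data.frame(x), ...)   # column subset: plain frame
    return(invisible(x))
  }
  cat(sprintf("seq_records: %d sequences (representing %d), lengths %d-%d\n",
              nrow(x), sum(x$n_represented),
              if (nrow(x)) min(nchar(gsub("-", "", x$residues))) else 0L,
              if (nrow(x)) max(nchar(gsub("-", "", x$residues))) else 0L))
  shown <- utils::head(as.data.frame(x), n)
  shown$residues <- paste0(substr(shown$residues, 1, 24),
                           ifelse(nchar(shown$residues) > 24, "...", ""))
  print(shown, ...)
  if (nrow(x) > n) cat(sprintf("# ... %d more sequences\n", nrow(x) - n))
  invisible(x)
}

degap <- function(residues) gsub("-", "", residues, fixed = TRUE)

parse_represented <- function(title) {
  m <- regmatches(title, regexec("\\[\\+([0-9]+)\\+\\]", title))
  n <- vapply(m, function(x) if (length(x) == 2) as.integer(x[2]) else 1L, 1L)
  title <- trimws(gsub("\\s*\\[\\+[0-9]+\\+\\]", "", title))
  list(title = title, n = pmax(n, 1L))
}

#' Read sequences from a FASTA file
#'
#' Reads plain (or gapped) FASTA into a [seq_records] frame. Residues are
#' upper-cased; in `alphabet = "protein"` mode the non-amino-acid letters
#' B, J, O, U, Z are replaced by `X`; in `"nucleotide"` mode `U` (uracil) is
#' recoded as `T` so nucleotide sequences live in the amino-acid alphabet.
#' Gap characters (`-` or `.`) are removed unless `keep_gaps = TRUE`.
#' A `[+n+]` marker in the title is parsed into `n_represented`. Duplicate
#' codes are disambiguated with a `_2`, `_3`, ... suffix (with a warning).
#'
#' @param path FASTA file path.
#' @param keep_gaps keep alignment gaps (`-`) in the residue strings.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return a [seq_records] data frame in file order.
#' @export
read_fasta <- function(path, keep_gaps = FALSE,
                       alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no sequences in ", path)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  if (any(nchar(gsub("[-.]", "", seqs)) == 0)) stop("empty sequence in ", path)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (!keep_gaps) seqs <- degap(seqs)
  if (alphabet == "nucleotide") {
    seqs <- chartr("U", "T", seqs)
  } else {
    seqs <- chartr("BJOUZ", "XXXXX", seqs)
  }
  bad <- regmatches(seqs, regexpr(sprintf("[^%sX-]", paste(AA_LETTERS, collapse = "")), seqs))
  if (length(unlist(bad)))
    stop("non-residue characters in ", path, ": ",
         paste(unique(unlist(bad)), collapse = " "))
  code <- sub("\\s.*$", "", headers)
  title <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(code)) {
    warning("duplicate sequence codes in ", path, "; suffix-disambiguated")
    for (cd in unique(code[duplicated(code)])) {
      at <- which(code == cd)
      code[at[-1]] <- paste0(cd, "_", seq_along(at[-1]) + 1L)
    }
  }
  pr <- parse_represented(title)
  seq_records(code, seqs, pr$title, pr$n)
}

#' Write sequences to a FASTA file
#'
#' Headers are `>code title [+n+]`, the represented-count marker being
#' written only when `n_represented > 1`. Sequences are wrapped at 60
#' columns.
#'
#' @param records a [seq_records] frame (residues may be gapped).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  title <- ifelse(records$n_represented > 1,
                  trimws(paste(records$title,
                               sprintf("[+%d+]", records$n_represented))),
                  records$title)
  hdr <- trimws(paste(records$code, title))
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Freeze an externally supplied alignment
#'
#' Replaces every gap character by `X` so a pre-aligned family passes through
#' the reduction engine un-realigned when combined with a high gap penalty
#' (the `X` columns then match each other under the identity matrix).
#' [thaw_alignment()] is the exact inverse, returning the `X`s to gaps before
#' visualisation. The mapping is only safe on input that contains no real
#' `X` residues; frozen records are marked so the round trip is exact.
#'
#' @param records a [seq_records] frame of equal gapped length.
#' @return the frame with `-` replaced by `X`.
#' @export
freeze_alignment <- function(records) {
  len <- nchar(records$residues)
  if (length(unique(len)) > 1)
    stop("ragged input: aligned records must all have the same gapped length")
  if (any(grepl("X", records$residues, fixed = TRUE)))
    stop("input already contains 'X' residues; freezing would be ambiguous")
  records$residues <- chartr("-", "X", records$residues)
  records
}

#' @rdname freeze_alignment
#' @export
thaw_alignment <- function(records) {
  records$residues <- chartr("X", "-", records$residues)
  records
}
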