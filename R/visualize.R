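#' Colour schemes for alignment panels
#'
#' Per-character RGB maps (values in 0-1). Amino acids follow a
#' physico-chemical convention: hydrophobic residues pure green, acidic (D,
#' E) pure red, basic (K, R) pure blue, with neutral polar residues
#' interpolated between the charge extremes; nucleotides (recoded into the
#' amino-acid alphabet) are G red, A green, C yellow, T blue. Track states:
#' alpha helix (H) red, beta strand (E) green; transmembrane (M) adds a blue
#' component (over a red helix this gives the purple hue marking TM
#' segments); RNA stems are green descending into a hairpin, red ascending.
#' Gaps render white and are excluded from column averages. Every map is a
#' plain named list and can be overridden.
#'
#' @param mode `"protein"`, `"tm"` or `"rna"`.
#' @return a `colour_scheme` list with `mode`, `residue` and `track` maps
#'   (named 3-vectors of RGB in 0-1).
#' @export
colour_scheme <- function(mode = c("protein", "tm", "rna")) {
  mode <- match.arg(mode)
  rgb3 <- function(r, g, b) c(r, g, b)
  phobic <- rgb3(0, 1, 0)
  residue <- list(
    A = phobic, C = phobic, F = phobic, I = phobic, L = phobic,
    M = phobic, V = phobic, W = phobic,
    D = rgb3(1, 0, 0), E = rgb3(1, 0, 0),
    K = rgb3(0, 0, 1), R = rgb3(0, 0, 1), H = rgb3(0.3, 0, 0.7),
    N = rgb3(0.6, 0, 0.4), Q = rgb3(0.6, 0, 0.4),
    S = rgb3(0.5, 0, 0.5), T = rgb3(0.5, 0, 0.5), Y = rgb3(0.4, 0.4, 0.2),
    G = rgb3(0.6, 0.6, 0.6), P = rgb3(0.6, 0.6, 0.6),
    X = rgb3(0.7, 0.7, 0.7), `-` = rgb3(1, 1, 1)
  )
  if (mode == "rna")
    residue <- list(G = rgb3(1, 0, 0), A = rgb3(0, 1, 0),
                    C = rgb3(1, 1, 0), T = rgb3(0, 0, 1),
                    X = rgb3(0.7, 0.7, 0.7), `-` = rgb3(1, 1, 1))
  track <- switch(mode,
    protein = ,
    tm = list(H = rgb3(1, 0, 0), E = rgb3(0, 1, 0), C = rgb3(0.85, 0.85, 0.85),
              M = rgb3(0, 0, 1), `-` = rgb3(1, 1, 1), `.` = rgb3(1, 1, 1)),
    rna = list(D = rgb3(0, 1, 0), A = rgb3(1, 0, 0), `.` = rgb3(0.85, 0.85, 0.85),
               `-` = rgb3(1, 1, 1))
  )
  structure(list(mode = mode, residue = residue, track = track),
            class = "colour_scheme")
}

as_gapped <- function(msa) {
  g <- if (inherits(msa, "mini_alignment")) msa$gapped
  else if (inherits(msa, "seq_records")) msa$residues
  else if (is.character(msa)) msa
  else stop("cannot interpret alignment input")
  if (length(unique(nchar(g))) != 1) stop("ragged alignment")
  g
}

#' Load per-residue annotation tracks
#'
#' Reads plain-text state strings, one line per alignment member, in member
#' order (`>`-prefixed name lines are ignored). Valid states are `H`/`E`/`C`
#' (secondary structure), `M`/`-` (transmembrane), and `(`/`)`/`.` (RNA
#' base-pairing, mapped to `D`escending / `A`scending stem states). A track
#' whose length equals the member's de-gapped length is projected onto the
#' alignment columns, gap columns inheriting the neutral `-` state; a track
#' already at full alignment width is used as is.
#'
#' @param path text file of state strings.
#' @param msa the alignment (`mini_alignment`, [seq_records] with gapped
#'   residues, or character vector).
#' @return character vector of aligned state strings, one per member.
#' @export
load_tracks <- function(path, msa) {
  gapped <- as_gapped(msa)
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^>", lines) & nzchar(trimws(lines))])
  if (length(lines) != length(gapped))
    stop("track file has ", length(lines), " tracks for ", length(gapped),
         " alignment members")
  bad <- grepl("[^HECM().-]", lines)
  if (any(bad)) stop("unknown state characters in track file")
  lines <- chartr("()", "DA", lines)
  vapply(seq_along(lines), function(i) project_track(lines[i], gapped[i]), "")
}

project_track <- function(track, gapped_member) {
  W <- nchar(gapped_member)
  if (nchar(track) == W) return(track)
  res_at <- which(strsplit(gapped_member, "")[[1]] != "-")
  if (nchar(track) != length(res_at))
    stop("track length ", nchar(track), " does not match de-gapped member ",
         "length ", length(res_at))
  out <- rep("-", W)
  out[res_at] <- strsplit(track, "")[[1]]
  paste(out, collapse = "")
}

chars_to_colours <- function(strings, map) {
  n <- length(strings)
  W <- nchar(strings[1])
  arr <- array(1, dim = c(n, W, 3))
  ch <- do.call(rbind, strsplit(strings, ""))
  for (key in unique(as.vector(ch))) {
    col <- map[[key]]
    if (is.null(col)) stop("no colour mapped for character '", key, "'")
    hit <- ch == key
    for (c3 in 1:3) arr[, , c3][hit] <- col[c3]
  }
  arr
}

#' Per-cell colour layers of an alignment
#'
#' `residue_colours` maps each alignment cell to its residue colour;
#' `track_colours` does the same for a state track, optionally adding the
#' transmembrane blue component where a TM track reads `M`;
#' `average_colours` replaces every cell by the arithmetic mean of the member
#' colours in its column (gap cells excluded from the mean but rendered
#' white), which paints conserved positions as saturated bands.
#'
#' @param msa alignment (see [load_tracks()] for accepted forms).
#' @param scheme a [colour_scheme()].
#' @param tracks aligned state strings from [load_tracks()].
#' @param tm_tracks optional aligned TM state strings (`M` / `-`).
#' @param arr an `n x W x 3` colour array.
#' @param gapped the gapped member strings (defines which cells are gaps).
#' @return `n x W x 3` numeric array of RGB in 0-1.
#' @export
residue_colours <- function(msa, scheme = colour_scheme()) {
  chars_to_colours(as_gapped(msa), scheme$residue)
}

#' @rdname residue_colours
#' @export
track_colours <- function(tracks, scheme = colour_scheme(), tm_tracks = NULL) {
  arr <- chars_to_colours(tracks, scheme$track)
  if (!is.null(tm_tracks)) {
    tm <- do.call(rbind, strsplit(tm_tracks, "")) == "M"
    arr[, , 3][tm] <- pmin(1, arr[, , 3][tm] + 0.7)
    arr[, , 1][tm] <- arr[, , 1][tm] * 0.8
    arr[, , 2][tm] <- arr[, , 2][tm] * 0.8
  }
  arr
}

#' @rdname residue_colours
#' @export
average_colours <- function(arr, gapped) {
  ch <- do.call(rbind, strsplit(as_gapped(gapped), ""))
  gap <- ch == "-"
  out <- arr
  for (j in seq_len(ncol(ch))) {
    live <- !gap[, j]
    for (c3 in 1:3) {
      m <- if (any(live)) mean(arr[live, j, c3]) else 1
      out[, j, c3] <- m
    }
    out[gap[, j], j, ] <- 1
  }
  out
}

svg_hex <- function(v) sprintf("#%02X%02X%02X", round(255 * v[1]),
                               round(255 * v[2]), round(255 * v[3]))

#' Render coloured alignment panels to an SVG file
#'
#' Draws up to four stacked panels: per-residue track colouring, per-residue
#' identity colouring, and their column-averaged "reflections" emphasising
#' conservation. Output is plain SVG markup written deterministically, so
#' identical inputs give byte-identical files.
#'
#' @param msa the alignment (see [load_tracks()] for accepted forms).
#' @param tracks optional aligned state strings ([load_tracks()]).
#' @param tm_tracks optional aligned TM state strings.
#' @param scheme a [colour_scheme()].
#' @param file output SVG path.
#' @param cell cell width and height in pixels.
#' @return `file`, invisibly.
#' @export
render_panels <- function(msa, tracks = NULL, tm_tracks = NULL,
                          scheme = colour_scheme(), file, cell = c(6, 9)) {
  gapped <- as_gapped(msa)
  if (!is.null(tracks) && (length(tracks) != length(gapped) ||
                           any(nchar(tracks) != nchar(gapped[1]))))
    stop("track dimensions do not match the alignment")
  layers <- list()
  if (!is.null(tracks)) layers$track <- track_colours(tracks, scheme, tm_tracks)
  layers$residue <- residue_colours(msa, scheme)
  if (!is.null(tracks))
    layers$track_avg <- average_colours(layers$track, gapped)
  layers$residue_avg <- average_colours(layers$residue, gapped)

  n <- length(gapped)
  W <- nchar(gapped[1])
  gap_px <- cell[2]
  panel_h <- n * cell[2]
  height <- length(layers) * (panel_h + gap_px) - gap_px
  width <- W * cell[1]
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%d" height="%d">'), width, height))
  y0 <- 0
  for (layer in layers) {
    for (i in seq_len(n)) {
      run_start <- 1
      row <- vapply(seq_len(W), function(j) svg_hex(layer[i, j, ]), "")
      for (j in seq_len(W)) {
        if (j < W && row[j + 1] == row[j]) next
        out <- c(out, sprintf(
          '<rect x="%d" y="%d" width="%d" height="%d" fill="%s"/>',
          (run_start - 1) * cell[1], y0 + (i - 1) * cell[2],
          (j - run_start + 1) * cell[1], cell[2], row[j]))
        run_start <- j + 1
      }
    }
    y0 <- y0 + panel_h + gap_px
  }
  out <- c(out, "</svg>")
  writeLines(out, file)
  invisible(file)
}
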