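# Degenerate consensus patterns and position-specific probability matrices
# (PSPMs) for the four conserved dehydrin segments.
#
# K segment (15 positions): X K X G X X (D/E) K (I/V) K (D/E) K X P G
#   core (must match exactly): G at 3, K at 7, I/V at 8, K at 9, P at 13,
#   G at 14 (0-based) -- the Lys-Ile-Lys core plus the Gly/Pro-Gly anchors.
# Y segment (7 positions):  D (D/E) (Y/H/F) G N P X ; core D0, G3, N4, P5.
# S segment (variable width 12-16): anchor L H R (S/T) G, a maximal serine
#   tract of 4-8 residues (the core), then a 3-residue acidic tail
#   ((S/D/E) then (D/E) (D/E)).
# F segment (12 positions): E X X D R G X F D F X (G/K); core = the Phe dyad
#   at 7 and 9. The conserved hydrophobic core around the dyad (Leu-Phe-Asp-
#   Phe-Leu) enters only as PSPM score weighting at the X positions 6 and 10.

.SEGMENT_CLASSES <- c("K", "Y", "S", "F")

.set <- function(...) c(...)
.ANY <- .AA  # an X position in the pattern: any canonical residue

#' Degenerate consensus pattern for a segment class
#'
#' Returns the per-position allowed residue sets of the class's consensus
#' pattern, with core positions (which the scanner requires to match exactly)
#' flagged. The S segment is variable-width: its pattern is an anchor, a
#' serine-tract length range, and an acidic tail.
#'
#' @param segment_class one of `"K"`, `"Y"`, `"S"`, `"F"`.
#' @return an object of class `segment_pattern`: a list with elements
#'   `class`, `type` (`"fixed"` or `"s_tract"`), `positions` (list of allowed
#'   residue sets; for the S segment split into `anchor` and `tail`), `core`
#'   (logical per position; for the S segment the tract is the core), and
#'   `width` (fixed width, or the `c(min, max)` range for S).
#' @export
default_pattern <- function(segment_class) {
  segment_class <- match.arg(segment_class, .SEGMENT_CLASSES)
  pat <- switch(segment_class,
    K = list(
      type = "fixed",
      positions = list(.ANY, "K", .ANY, "G", .ANY, .ANY, .set("D", "E"),
                       "K", .set("I", "V"), "K", .set("D", "E"), "K",
                       .ANY, "P", "G"),
      core = seq_len(15L) %in% c(4L, 8L, 9L, 10L, 14L, 15L),
      width = 15L),
    Y = list(
      type = "fixed",
      positions = list("D", .set("D", "E"), .set("Y", "H", "F"),
                       "G", "N", "P", .ANY),
      core = seq_len(7L) %in% c(1L, 4L, 5L, 6L),
      width = 7L),
    S = list(
      type = "s_tract",
      positions = list(
        anchor = list("L", "H", "R", .set("S", "T"), "G"),
        tail = list(.set("S", "D", "E"), .set("D", "E"), .set("D", "E"))),
      tract_range = c(4L, 8L),
      core = NA,  # the serine tract is the core
      width = c(12L, 16L)),
    F = list(
      type = "fixed",
      positions = list("E", .ANY, .ANY, "D", "R", "G", .ANY, "F", "D", "F",
                       .ANY, .set("G", "K")),
      core = seq_len(12L) %in% c(8L, 10L),
      width = 12L)
  )
  structure(c(list(class = segment_class), pat), class = "segment_pattern")
}

# Build one PSPM column: quoted frequencies are kept exactly; the remaining
# probability mass is spread uniformly over the pattern's other allowed
# residues (or over all other residues when the allowed set is exhausted);
# finally a small uniform floor guarantees no residue has probability zero.
.pspm_column <- function(allowed, seeds = NULL, pseudocount = 0.002) {
  p <- setNames(numeric(20L), .AA)
  seeded <- character(0)
  if (!is.null(seeds)) {
    p[names(seeds)] <- seeds
    seeded <- names(seeds)
  }
  rest <- 1 - sum(p)
  stopifnot(rest > -1e-12)
  targets <- setdiff(allowed, seeded)
  if (!length(targets)) targets <- setdiff(.AA, seeded)
  p[targets] <- p[targets] + rest / length(targets)
  (1 - pseudocount) * p + pseudocount / 20
}

#' Position-specific probability matrix for a segment class
#'
#' Returns the class's PSPM: per-position residue probabilities seeded from
#' the conserved-position frequencies observed across woody-plant dehydrins
#' (e.g. Lys at 81-90% through the K segment core, Asp/Gly/Asn above 90% in
#' the Y segment), with the remaining mass spread over the residues the
#' degenerate pattern allows and a small uniform pseudocount floor so no
#' residue has probability zero. Every column sums to 1.
#'
#' The S-segment PSPM is laid out at its canonical width of 15 (anchor 5,
#' serine tract 7, tail 3); when the scanner scores a match with a different
#' tract length it reuses the representative tract column once per tract
#' residue.
#'
#' @inheritParams default_pattern
#' @param pseudocount uniform floor mixed into every column.
#' @return an object of class `pspm`: a 20 x width probability matrix
#'   (rows = residues) with attributes `segment_class`, `pseudocount` and,
#'   for S, `anchor_cols`, `tract_cols`, `tail_cols`.
#' @export
default_pspm <- function(segment_class, pseudocount = 0.002) {
  segment_class <- match.arg(segment_class, .SEGMENT_CLASSES)
  pat <- default_pattern(segment_class)
  seeds <- switch(segment_class,
    K = list(`2` = c(K = 0.81), `3` = c(K = 0.81), `4` = c(G = 0.91),
             `8` = c(K = 0.90), `9` = c(V = 0.12), `10` = c(K = 0.90),
             `12` = c(K = 0.86), `14` = c(P = 0.84), `15` = c(G = 0.91)),
    Y = list(`1` = c(D = 0.96), `2` = c(E = 0.65), `3` = c(Y = 0.62),
             `4` = c(G = 0.91), `5` = c(N = 0.92)),
    S = list(`1` = c(L = 0.87), `2` = c(H = 0.81), `3` = c(R = 0.86),
             `4` = c(S = 0.80)),
    F = list(`1` = c(E = 0.94), `5` = c(R = 0.92), `6` = c(G = 0.97),
             `7` = c(L = 0.40), `8` = c(F = 0.98), `10` = c(F = 0.81),
             `11` = c(L = 0.40), `12` = c(K = 0.97))
  )
  if (segment_class == "S") {
    sets <- c(pat$positions$anchor, rep(list("S"), 7L), pat$positions$tail)
  } else {
    sets <- pat$positions
  }
  w <- length(sets)
  probs <- vapply(seq_len(w), function(j) {
    .pspm_column(sets[[j]], seeds[[as.character(j)]], pseudocount)
  }, numeric(20L))
  rownames(probs) <- .AA
  attrs <- list(segment_class = segment_class, pseudocount = pseudocount)
  if (segment_class == "S") {
    attrs <- c(attrs, list(anchor_cols = 1:5, tract_cols = 6:12,
                           tail_cols = 13:15))
  }
  structure(probs, class = c("pspm", class(probs)),
            segment_class = attrs$segment_class,
            pseudocount = attrs$pseudocount,
            anchor_cols = attrs$anchor_cols,
            tract_cols = attrs$tract_cols,
            tail_cols = attrs$tail_cols)
}

# Log-odds (base 2) of a residue vector against the PSPM columns `cols`,
# versus a uniform 1/20 background. X residues contribute 0 bits.
.pspm_logodds <- function(pspm, residues, cols) {
  stopifnot(length(residues) == length(cols))
  lo <- numeric(length(residues))
  known <- residues %in% .AA
  idx <- cbind(match(residues[known], .AA), cols[known])
  lo[known] <- log2(pspm[idx] / 0.05)
  sum(lo)
}

# Score one window: fixed-width classes use all columns; the S segment uses
# anchor columns, the representative tract column repeated, then the tail.
.score_window <- function(pspm, residues, tract_len = NULL) {
  cls <- attr(pspm, "segment_class")
  if (cls != "S") {
    return(.pspm_logodds(pspm, residues, seq_along(residues)))
  }
  r <- tract_len
  stopifnot(length(residues) == 8L + r)
  cols <- c(1:5, rep(attr(pspm, "tract_cols")[1L], r),
            attr(pspm, "tail_cols"))
  .pspm_logodds(pspm, residues, cols)
}

#' Serialize a PSPM as a minimal plain-text matrix block
#'
#' Writes the matrix in a MEME-minimal-format-like layout: a `MOTIF` line
#' with the segment class, an alphabet line, then one row per position with
#' 20 probabilities in canonical residue order.
#'
#' @param pspm a [default_pspm()] object.
#' @param path output path; when `NULL` the lines are returned invisibly
#'   without writing.
#' @return the text lines, invisibly.
#' @export
write_pspm <- function(pspm, path = NULL) {
  lines <- c(
    sprintf("MOTIF %s_segment", attr(pspm, "segment_class")),
    paste("ALPHABET", paste(.AA, collapse = " ")),
    sprintf("letter-probability matrix: alength= 20 w= %d", ncol(pspm)),
    vapply(seq_len(ncol(pspm)),
           function(j) paste(sprintf("%.6f", pspm[, j]), collapse = " "),
           character(1L))
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
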