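# Segment scanning: every window matching a class's degenerate pattern with
# at most `max_mismatch` mismatches at non-core positions (core positions
# must match exactly) is scored by PSPM log-odds against a uniform background
# and kept when the score reaches `min_score` bits.

#' Scanner parameters
#'
#' @param max_mismatch mismatch budget at non-core pattern positions
#'   (core positions always match exactly).
#' @param min_score minimum PSPM log-odds score, in bits versus a uniform
#'   1/20 background, for a window to be reported.
#' @return a list of class `scan_params`.
#' @export
scan_params <- function(max_mismatch = 2L, min_score = 0) {
  stopifnot(max_mismatch >= 0L, is.numeric(min_score))
  structure(list(max_mismatch = as.integer(max_mismatch),
                 min_score = min_score),
            class = "scan_params")
}

.empty_matches <- function() {
  data.frame(class = character(0), start = integer(0), end = integer(0),
             matched_seq = character(0), score = numeric(0),
             source = character(0), tract_len = integer(0),
             stringsAsFactors = FALSE)
}

# membership lookup over the 21-letter alphabet (20 residues + X); an X in
# the sequence matches only unconstrained ("any residue") pattern positions
.allowed_lookup <- function(set) {
  v <- .AAX %in% set
  v[21L] <- length(set) == 20L
  v
}

#' Scan a protein sequence for one segment class
#'
#' Slides the class's degenerate consensus over the sequence; windows whose
#' core positions match exactly and whose non-core mismatches stay within the
#' budget are scored by PSPM log-odds and reported when the score reaches the
#' threshold. The variable-width S segment is matched by anchoring
#' `LHR(S/T)G`, consuming the maximal serine run of 4-8 residues, then the
#' acidic tail. Matches may overlap; see [resolve_overlaps()].
#'
#' @param sequence a protein sequence string (canonical residues plus X).
#' @param segment_class one of `"K"`, `"Y"`, `"S"`, `"F"`.
#' @param params a [scan_params()] object.
#' @param pspm optional PSPM overriding [default_pspm()] for the class.
#' @return a data.frame with columns `class`, `start`, `end` (0-based,
#'   half-open), `matched_seq`, `score` (bits), `source`, `tract_len`
#'   (observed serine-run length, `NA` for fixed-width classes), sorted by
#'   `start`.
#' @export
scan_segment <- function(sequence, segment_class, params = scan_params(),
                         pspm = NULL) {
  segment_class <- match.arg(segment_class, .SEGMENT_CLASSES)
  stopifnot(inherits(params, "scan_params"), is.character(sequence),
            length(sequence) == 1L)
  pat <- default_pattern(segment_class)
  if (is.null(pspm)) pspm <- default_pspm(segment_class)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  codes <- match(chars, .AAX)
  if (anyNA(codes)) {
    stop("illegal residue letter '", chars[which(is.na(codes))[1L]],
         "' in sequence", call. = FALSE)
  }
  if (pat$type == "fixed") {
    out <- .scan_fixed(chars, codes, pat, pspm, params)
  } else {
    out <- .scan_s_tract(chars, codes, pat, pspm, params)
  }
  out[order(out$start), , drop = FALSE]
}

.scan_fixed <- function(chars, codes, pat, pspm, params) {
  w <- pat$width
  L <- length(codes)
  if (L < w) return(.empty_matches())
  nwin <- L - w + 1L
  mm <- integer(nwin)
  core_ok <- rep(TRUE, nwin)
  for (j in seq_len(w)) {
    ok <- .allowed_lookup(pat$positions[[j]])[codes[j:(j + nwin - 1L)]]
    if (pat$core[j]) core_ok <- core_ok & ok else mm <- mm + !ok
  }
  starts <- which(core_ok & mm <= params$max_mismatch)
  if (!length(starts)) return(.empty_matches())
  score <- vapply(starts, function(i) {
    .score_window(pspm, chars[i:(i + w - 1L)])
  }, numeric(1L))
  keep <- score >= params$min_score
  starts <- starts[keep]; score <- score[keep]
  if (!length(starts)) return(.empty_matches())
  data.frame(class = pat$class, start = starts - 1L, end = starts - 1L + w,
             matched_seq = substring(paste(chars, collapse = ""),
                                     starts, starts + w - 1L),
             score = score, source = "PSPM", tract_len = NA_integer_,
             stringsAsFactors = FALSE)
}

.scan_s_tract <- function(chars, codes, pat, pspm, params) {
  L <- length(codes)
  anchor <- pat$positions$anchor
  tail_sets <- pat$positions$tail
  rng <- pat$tract_range
  min_w <- 5L + rng[1L] + 3L
  if (L < min_w) return(.empty_matches())
  nwin <- L - 5L + 1L
  mm_anchor <- integer(nwin)
  for (j in 1:5) {
    mm_anchor <- mm_anchor +
      !.allowed_lookup(anchor[[j]])[codes[j:(j + nwin - 1L)]]
  }
  is_s <- chars == "S"
  rows <- list()
  seqstr <- paste(chars, collapse = "")
  for (i in which(mm_anchor <= params$max_mismatch)) {
    t0 <- i + 5L
    if (t0 > L || !is_s[t0]) next
    r_full <- 0L
    while (t0 + r_full <= L && is_s[t0 + r_full]) r_full <- r_full + 1L
    r <- min(r_full, rng[2L])
    if (r < rng[1L]) next
    tail0 <- t0 + r
    if (tail0 + 2L > L) next
    mm <- mm_anchor[i]
    for (j in 0:2) {
      if (!.allowed_lookup(tail_sets[[j + 1L]])[codes[tail0 + j]]) mm <- mm + 1L
    }
    if (mm > params$max_mismatch) next
    w <- 5L + r + 3L
    sc <- .score_window(pspm, chars[i:(i + w - 1L)], tract_len = r)
    if (sc < params$min_score) next
    rows[[length(rows) + 1L]] <- data.frame(
      class = "S", start = i - 1L, end = i - 1L + w,
      matched_seq = substring(seqstr, i, i + w - 1L),
      score = sc, source = "PSPM", tract_len = r, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.empty_matches())
  do.call(rbind, rows)
}

#' Resolve overlapping segment matches
#'
#' Greedy selection by descending score with ties broken by the smaller
#' start: a match is kept only if it does not overlap any already-retained
#' match of any class (one residue belongs to one segment).
#'
#' @param matches a data.frame of matches from one sequence, as returned by
#'   [scan_segment()] (possibly row-bound across classes).
#' @return the non-overlapping subset, sorted by `start`.
#' @export
resolve_overlaps <- function(matches) {
  if (nrow(matches) < 2L) return(matches)
  ord <- order(-matches$score, matches$start)
  kept <- integer(0)
  for (i in ord) {
    s <- matches$start[i]; e <- matches$end[i]
    if (!any(s < matches$end[kept] & matches$start[kept] < e)) {
      kept <- c(kept, i)
    }
  }
  out <- matches[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of protein records for all four segment classes
#'
#' Runs [scan_segment()] for K, Y, S and F on every record and resolves
#' overlaps within each sequence.
#'
#' @param records protein records from [read_fasta_proteins()].
#' @inheritParams scan_segment
#' @return a data.frame of resolved matches with a leading `accession`
#'   column.
#' @export
scan_proteins <- function(records, params = scan_params()) {
  per_record <- lapply(seq_len(nrow(records)), function(i) {
    m <- do.call(rbind, lapply(.SEGMENT_CLASSES, function(cl) {
      scan_segment(records$sequence[i], cl, params)
    }))
    m <- resolve_overlaps(m)
    if (nrow(m)) cbind(accession = records$accession[i], m,
                       stringsAsFactors = FALSE)
    else cbind(accession = character(0), .empty_matches())
  })
  out <- do.call(rbind, per_record)
  rownames(out) <- NULL
  out
}
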