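# Architecture typing: the N-to-C order of resolved segments defines the
# dehydrin's architectural type. The seven canonical types form a strict
# grammar; any other arrangement (Y after K, S inside the K block, F
# co-occurring with Y, two or more F with an S, ...) is atypical, as are the
# handful of published interleaved architectures like YSK2(KS)SK3Y2SK3.

.ARCH_TYPES <- c("Kn", "KnS", "SKn", "YnKn", "YnSKn", "FSKn", "FnKn",
                 "ATYPICAL")

#' Architecture string and compact formula from resolved matches
#'
#' Emits the one-letter segment classes in ascending start order and the
#' compact formula in which maximal runs are compressed (`YYSKKK` ->
#' `Y2SK3`; run length 1 omits the digit).
#'
#' @param matches non-overlapping matches of one sequence, from
#'   [resolve_overlaps()].
#' @return a list with `ordered_letters` and `formula`.
#' @export
architecture_string <- function(matches) {
  if (nrow(matches) == 0L) {
    stop("no segments: a sequence without a K segment is not a dehydrin",
         call. = FALSE)
  }
  letters <- matches$class[order(matches$start)]
  list(ordered_letters = paste(letters, collapse = ""),
       formula = .compress_formula(letters))
}

.compress_formula <- function(letters) {
  r <- rle(letters)
  paste0(r$values, ifelse(r$lengths > 1L, r$lengths, ""), collapse = "")
}

# expand a compact formula ("Y2SK3") back to a letters vector
.expand_formula <- function(formula) {
  m <- gregexpr("[KYSF][0-9]*", formula)[[1L]]
  if (m[1L] == -1L || sum(attr(m, "match.length")) != nchar(formula)) {
    stop("invalid architecture formula: ", formula, call. = FALSE)
  }
  parts <- regmatches(formula, gregexpr("[KYSF][0-9]*", formula))[[1L]]
  unlist(lapply(parts, function(p) {
    n <- if (nchar(p) > 1L) as.integer(substring(p, 2L)) else 1L
    rep(substring(p, 1L, 1L), n)
  }))
}

#' Classify an ordered segment string into an architectural type
#'
#' The ordered letters are matched against the seven canonical architectures
#' in turn: `K+` (Kn), `SK+` (SKn), `K+S` (KnS), `Y+K+` (YnKn), `Y+SK+`
#' (YnSKn), `FSK+` (FSKn, exactly one F and one S), `F+K+` (FnKn). Anything
#' else -- including `F+SK+` with two or more F copies -- is `ATYPICAL`.
#' A string without a K segment is an error: such a sequence is not a
#' dehydrin.
#'
#' @param ordered_letters a string over `{K,Y,S,F}` in N-to-C segment order.
#' @return one of `"Kn"`, `"KnS"`, `"SKn"`, `"YnKn"`, `"YnSKn"`, `"FSKn"`,
#'   `"FnKn"`, `"ATYPICAL"`.
#' @export
classify_architecture <- function(ordered_letters) {
  stopifnot(is.character(ordered_letters), length(ordered_letters) == 1L)
  if (!grepl("^[KYSF]*$", ordered_letters)) {
    stop("architecture string may only contain K, Y, S, F", call. = FALSE)
  }
  if (!grepl("K", ordered_letters, fixed = TRUE)) {
    stop("no K segment: not a classifiable dehydrin", call. = FALSE)
  }
  if (grepl("^K+$", ordered_letters))    return("Kn")
  if (grepl("^SK+$", ordered_letters))   return("SKn")
  if (grepl("^K+S$", ordered_letters))   return("KnS")
  if (grepl("^Y+K+$", ordered_letters))  return("YnKn")
  if (grepl("^Y+SK+$", ordered_letters)) return("YnSKn")
  if (grepl("^FSK+$", ordered_letters))  return("FSKn")
  if (grepl("^F+K+$", ordered_letters))  return("FnKn")
  "ATYPICAL"
}

#' Detect the rare dehydrin motifs
#'
#' Three rare motifs are censused across dehydrin sequences: K segments
#' flanked on both sides by His-His dipeptides, the exact poly-lysine 8-mer
#' `KKKKKEKK` that accompanies some S segments, His-His richness (four or
#' more non-overlapping `HH` occurrences) and the metal-binding
#' `HH-X3-HH` arrangement (literally `HHSGDHH`). One-sided His-His flanking
#' is reported in the `hh_one_sided` diagnostic but does not set the flag,
#' and a relaxed poly-K count (`K{4,}EK{1,3}`) is carried alongside the exact
#' 8-mer for diagnostics only.
#'
#' @param sequence the protein sequence.
#' @param k_matches resolved K-segment matches of that sequence (rows with
#'   `class == "K"` are used).
#' @return a list with `hh_flanked_k` (0-based indices of the flanked K
#'   matches), `hh_one_sided` (indices flanked on exactly one side),
#'   `poly_k` (exact `KKKKKEKK` present), `poly_k_relaxed_count`,
#'   `hh_count` (non-overlapping `HH` occurrences), `hh_rich`
#'   (`hh_count >= 4`), and `hh_x3_hh` (`HHSGDHH` present).
#' @export
detect_rare_motifs <- function(sequence, k_matches) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  k <- k_matches[k_matches$class == "K", , drop = FALSE]
  L <- nchar(sequence)
  both <- integer(0); one <- integer(0)
  for (i in seq_len(nrow(k))) {
    s <- k$start[i]; e <- k$end[i]  # 0-based half-open
    left  <- s >= 2L && substring(sequence, s - 1L, s) == "HH"
    right <- e + 2L <= L && substring(sequence, e + 1L, e + 2L) == "HH"
    if (left && right) both <- c(both, i - 1L)
    else if (left || right) one <- c(one, i - 1L)
  }
  hh <- gregexpr("HH", sequence, fixed = TRUE)[[1L]]  # non-overlapping
  hh_count <- if (hh[1L] == -1L) 0L else length(hh)
  relaxed <- gregexpr("K{4,}EK{1,3}", sequence)[[1L]]
  list(
    hh_flanked_k = both,
    hh_one_sided = one,
    poly_k = grepl("KKKKKEKK", sequence, fixed = TRUE),
    poly_k_relaxed_count = if (relaxed[1L] == -1L) 0L else length(relaxed),
    hh_count = hh_count,
    hh_rich = hh_count >= 4L,
    hh_x3_hh = grepl("HHSGDHH", sequence, fixed = TRUE)
  )
}

#' Build architecture profiles for a set of records
#'
#' Combines [architecture_string()], [classify_architecture()] and
#' [detect_rare_motifs()] for every record that has at least one K segment.
#' Records without a K segment are excluded (they are not dehydrins) and
#' returned in the `rejects` attribute.
#'
#' @param records protein records.
#' @param matches resolved matches from [scan_proteins()].
#' @return a data.frame with columns `accession`, `group`, `ordered_letters`,
#'   `formula`, `arch_type`, `nK`, `nY`, `nS`, `nF`, `hh_flanked_k_count`,
#'   `poly_k`, `hh_count`, `hh_rich`, `hh_x3_hh`; the accessions rejected for
#'   lacking a K segment are in `attr(, "rejects")`.
#' @export
architecture_profiles <- function(records, matches) {
  rows <- list(); rejects <- character(0)
  for (i in seq_len(nrow(records))) {
    acc <- records$accession[i]
    m <- matches[matches$accession == acc, , drop = FALSE]
    if (!any(m$class == "K")) { rejects <- c(rejects, acc); next }
    arch <- architecture_string(m)
    letters <- strsplit(arch$ordered_letters, "")[[1L]]
    rare <- detect_rare_motifs(records$sequence[i], m)
    rows[[length(rows) + 1L]] <- data.frame(
      accession = acc, group = records$group[i],
      ordered_letters = arch$ordered_letters, formula = arch$formula,
      arch_type = classify_architecture(arch$ordered_letters),
      nK = sum(letters == "K"), nY = sum(letters == "Y"),
      nS = sum(letters == "S"), nF = sum(letters == "F"),
      hh_flanked_k_count = length(rare$hh_flanked_k),
      poly_k = rare$poly_k, hh_count = rare$hh_count,
      hh_rich = rare$hh_rich, hh_x3_hh = rare$hh_x3_hh,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(0), group = character(0),
               ordered_letters = character(0), formula = character(0),
               arch_type = character(0), nK = integer(0), nY = integer(0),
               nS = integer(0), nF = integer(0),
               hh_flanked_k_count = integer(0), poly_k = logical(0),
               hh_count = integer(0), hh_rich = logical(0),
               hh_x3_hh = logical(0), stringsAsFactors = FALSE)
  attr(out, "rejects") <- rejects
  out
}

#' Architectural-type distribution per taxon group
#'
#' Percentage of each architectural type within each group; every group's
#' percentages sum to 100. Empty groups are omitted with a warning.
#'
#' @param profiles a data.frame from [architecture_profiles()] (columns
#'   `arch_type` and `group`).
#' @return a data.frame with columns `group`, `arch_type`, `n`, `percent`.
#' @export
type_distribution <- function(profiles) {
  groups <- unique(profiles$group)
  if (nrow(profiles) == 0L) {
    warning("no profiles: empty distribution", call. = FALSE)
  }
  rows <- list()
  for (g in groups) {
    sub <- profiles[profiles$group == g, , drop = FALSE]
    tab <- table(factor(sub$arch_type, levels = .ARCH_TYPES))
    rows[[g]] <- data.frame(group = g, arch_type = names(tab),
                            n = as.integer(tab),
                            percent = 100 * as.integer(tab) / nrow(sub),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
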