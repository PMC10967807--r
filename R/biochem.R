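# Per-sequence biochemical properties computed from first principles:
# average-mass molecular weight, Henderson-Hasselbalch isoelectric point by
# bisection, Kyte-Doolittle GRAVY, the charge/hydropathy fold index, and
# residue percentages. X residues are retained by the scanner but excluded
# from every biochemical denominator (no physical constants exist for X).

.residue_counts <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), .AAX)
  if (length(bad)) {
    stop("illegal residue letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  table(factor(chars[chars != "X"], levels = .AA))
}

#' Molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.0153 Da). X residues are
#' excluded from the sum.
#'
#' @param sequence protein sequence string.
#' @return molecular weight in daltons.
#' @export
molecular_weight <- function(sequence) {
  cnt <- .residue_counts(sequence)
  if (sum(cnt) == 0L) stop("empty effective sequence", call. = FALSE)
  sum(cnt * .mass_table()[names(cnt)]) + 18.0153
}

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch sum over the termini and the ionizable side chains
#' (D, E, C, Y negative; H, K, R positive). Strictly decreasing in pH.
#'
#' @param sequence protein sequence string.
#' @param ph the pH at which to evaluate the charge.
#' @param pka a pKa table from [pka_set()].
#' @return the net charge in elementary-charge units.
#' @export
protein_charge <- function(sequence, ph, pka = pka_set()) {
  cnt <- .residue_counts(sequence)
  pos_sites <- pka[pka$group %in% c("positive", "nterm"), , drop = FALSE]
  neg_sites <- pka[pka$group %in% c("negative", "cterm"), , drop = FALSE]
  n_of <- function(site, group) {
    if (group %in% c("nterm", "cterm")) 1 else as.numeric(cnt[site])
  }
  pos <- sum(mapply(function(s, g, k) n_of(s, g) / (1 + 10^(ph - k)),
                    pos_sites$site, pos_sites$group, pos_sites$pka))
  neg <- sum(mapply(function(s, g, k) n_of(s, g) / (1 + 10^(k - ph)),
                    neg_sites$site, neg_sites$group, neg_sites$pka))
  pos - neg
}

#' Isoelectric point by bisection
#'
#' Finds the pH in `[0, 14]` at which the Henderson-Hasselbalch net charge
#' crosses zero. The charge is strictly decreasing in pH, so bisection
#' converges; iteration stops when `|charge| < 1e-4` (or after 100 halvings).
#' The pKa convention defaults to the Bjellqvist (ProtParam) set; pass
#' `pka_set("emboss")` for the EMBOSS values.
#'
#' @param sequence protein sequence string.
#' @param pka a pKa table from [pka_set()].
#' @return the isoelectric point (pH units).
#' @export
isoelectric_point <- function(sequence, pka = pka_set()) {
  lo <- 0; hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- protein_charge(sequence, mid, pka)
    if (abs(q) < 1e-4) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' GRAVY score
#'
#' Grand average of hydropathicity: the arithmetic mean of Kyte-Doolittle
#' hydropathy values over non-X residues. Negative values indicate a
#' hydrophilic protein; every dehydrin scores negative.
#'
#' @param sequence protein sequence string.
#' @return the GRAVY score (range -4.5 to 4.5).
#' @export
gravy <- function(sequence) {
  cnt <- .residue_counts(sequence)
  n <- sum(cnt)
  if (n == 0L) stop("empty effective sequence", call. = FALSE)
  sum(cnt * .kd_table()[names(cnt)]) / n
}

#' Fold index
#'
#' Whole-sequence disorder predictor `2.785 * <H> - |<R>| - 1.151`, where
#' `<H>` is the mean scaled Kyte-Doolittle hydrophobicity `(KD + 4.5) / 9`
#' and `<R>` the mean net charge (K, R = +1; D, E = -1; His neutral, the
#' standard convention -- noted because dehydrins are His-variable), both
#' over non-X residues. Negative values predict intrinsic disorder. The
#' headline value is this global index; [fold_index_profile()] gives the
#' windowed variant.
#'
#' @param sequence protein sequence string.
#' @return the fold index (range -1.151 to 1.634 by construction).
#' @export
fold_index <- function(sequence) {
  cnt <- .residue_counts(sequence)
  n <- sum(cnt)
  if (n == 0L) stop("empty effective sequence", call. = FALSE)
  h <- sum(cnt * (.kd_table()[names(cnt)] + 4.5) / 9) / n
  charge <- setNames(numeric(20L), .AA)
  charge[c("K", "R")] <- 1; charge[c("D", "E")] <- -1
  r <- sum(cnt * charge[names(cnt)]) / n
  2.785 * h - abs(r) - 1.151
}

#' @rdname fold_index
#' @param window odd window width for the sliding profile.
#' @return `fold_index_profile()`: a numeric vector of per-window fold
#'   indexes (one value per window start, 0-based).
#' @export
fold_index_profile <- function(sequence, window = 51L) {
  L <- nchar(sequence)
  if (L < window) return(fold_index(sequence))
  starts <- seq_len(L - window + 1L)
  vapply(starts, function(i) {
    fold_index(substring(sequence, i, i + window - 1L))
  }, numeric(1L))
}

#' Residue percentage
#'
#' `100 * count / length` over non-X residues.
#'
#' @param sequence protein sequence string.
#' @param residue a single one-letter residue code.
#' @return percent of non-X residues equal to `residue`.
#' @export
residue_percent <- function(sequence, residue) {
  stopifnot(nchar(residue) == 1L, residue %in% .AA)
  cnt <- .residue_counts(sequence)
  n <- sum(cnt)
  if (n == 0L) return(0)
  100 * as.numeric(cnt[residue]) / n
}

#' Biochemical profiles for a set of records
#'
#' Computes length, molecular weight, isoelectric point, GRAVY, fold index
#' and Lys/His percentages for every record.
#'
#' @param records protein records from [read_fasta_proteins()].
#' @param pka pKa table for the isoelectric point.
#' @return a data.frame with columns `accession`, `group`, `length`, `mw`,
#'   `pi`, `gravy`, `fold_index`, `lys_pct`, `his_pct`.
#' @export
biochem_profiles <- function(records, pka = pka_set()) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    s <- records$sequence[i]
    data.frame(
      accession = records$accession[i], group = records$group[i],
      length = nchar(gsub("X", "", s, fixed = TRUE)),
      mw = molecular_weight(s), pi = isoelectric_point(s, pka),
      gravy = gravy(s), fold_index = fold_index(s),
      lys_pct = residue_percent(s, "K"), his_pct = residue_percent(s, "H"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
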