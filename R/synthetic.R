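# Synthetic dehydrins and promoters with known ground truth.
#
# Proteins are built as planted segments sampled from the class PSPMs
# (restricted to the degenerate pattern, core positions sampled within the
# core sets) separated by disordered phi-background linkers drawn from the
# shipped Gly/Thr-rich composition, so that every generated protein is
# hydrophilic (negative GRAVY) and predicted disordered (negative fold
# index) like real dehydrins. Optional mutations touch only non-core segment
# positions, keeping planted segments recoverable within the scanner's
# mismatch budget. All generation is reproducible from (spec, seed); no
# hidden global randomness.

.sample_residue <- function(prob) sample(.AA, 1L, prob = prob)

# sample one segment string from the class PSPM restricted to the pattern:
# core positions stay inside their core sets, constrained non-core positions
# inside their allowed sets, unconstrained positions follow the background
.sample_segment <- function(segment_class, background = phi_background()) {
  pat <- default_pattern(segment_class)
  pspm <- default_pspm(segment_class)
  sample_col <- function(col, allowed) {
    p <- pspm[, col]
    p[!names(p) %in% allowed] <- 0
    .sample_residue(p / sum(p))
  }
  if (pat$type == "fixed") {
    res <- vapply(seq_len(pat$width), function(j) {
      set <- pat$positions[[j]]
      if (length(set) == 20L) .sample_residue(background)
      else sample_col(j, set)
    }, character(1L))
    noncore <- which(!pat$core)
  } else {
    r <- sample(4:8, 1L, prob = c(0.05, 0.10, 0.15, 0.45, 0.25))
    anchor <- vapply(1:5, function(j) sample_col(j, pat$positions$anchor[[j]]),
                     character(1L))
    tail_cols <- attr(pspm, "tail_cols")
    tail_sets <- pat$positions$tail
    # keep the tract/tail boundary unambiguous: an S opening the tail would
    # extend the serine run, so it is only generated at the 8-residue cap
    if (r < 8L) tail_sets[[1L]] <- setdiff(tail_sets[[1L]], "S")
    tail <- vapply(1:3, function(j) sample_col(tail_cols[j], tail_sets[[j]]),
                   character(1L))
    res <- c(anchor, rep("S", r), tail)
    noncore <- c(1:5, (5L + r + 1L):(5L + r + 3L))
  }
  list(seq = paste(res, collapse = ""), noncore = noncore)
}

.sample_linker <- function(range, background = phi_background()) {
  n <- sample(range[1L]:range[2L], 1L)
  paste(sample(.AA, n, replace = TRUE, prob = background), collapse = "")
}

# substitute `n_mut` random non-core positions with a random other residue
.mutate_segment <- function(seg, n_mut) {
  if (n_mut == 0L || !length(seg$noncore)) return(seg$seq)
  chars <- strsplit(seg$seq, "", fixed = TRUE)[[1L]]
  pos <- sample(seg$noncore, min(n_mut, length(seg$noncore)))
  for (p in pos) chars[p] <- sample(setdiff(.AA, chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Generate one synthetic dehydrin
#'
#' Builds a protein whose segments follow the given architecture formula,
#' with phi-background linkers between (and flanking) the segments, and
#' returns both the record and the ground truth of planted coordinates.
#'
#' @param arch_formula compact architecture formula over `{Y,S,K,F}`, e.g.
#'   `"Y2SK3"`; it must contain at least one K (or the sequence would not be
#'   a dehydrin).
#' @param accession identifier for the generated record.
#' @param group taxon group label.
#' @param linker_range `c(min, max)` linker length in residues.
#' @param mutations_per_segment non-core substitutions applied to each
#'   planted segment.
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (as [synth_cohort()] does).
#' @return a list with `record` (one-row protein data.frame) and `truth`
#'   (data.frame `accession`, `class`, `start`, `end`, `planted_seq`,
#'   0-based half-open coordinates).
#' @export
synth_dehydrin <- function(arch_formula, accession = "SYN0001",
                           group = "UNASSIGNED", linker_range = c(10L, 60L),
                           mutations_per_segment = 0L, seed = NULL) {
  letters_vec <- .expand_formula(arch_formula)
  if (!"K" %in% letters_vec) {
    stop("formula contains no K segment: not a dehydrin", call. = FALSE)
  }
  gen <- function() {
    background <- phi_background()
    parts <- character(0)
    truth <- list()
    pos <- 0L
    append_part <- function(s) {
      parts[[length(parts) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    append_part(.sample_linker(linker_range, background))
    for (cl in letters_vec) {
      seg <- .sample_segment(cl, background)
      seg_seq <- .mutate_segment(seg, mutations_per_segment)
      truth[[length(truth) + 1L]] <- data.frame(
        accession = accession, class = cl, start = pos,
        end = pos + nchar(seg_seq), planted_seq = seg_seq,
        stringsAsFactors = FALSE)
      append_part(seg_seq)
      append_part(.sample_linker(linker_range, background))
    }
    list(
      record = data.frame(accession = accession, description = arch_formula,
                          group = group,
                          sequence = paste(parts, collapse = ""),
                          stringsAsFactors = FALSE),
      truth = do.call(rbind, truth))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Cohort specification for the synthetic generator
#'
#' Defaults mirror the woody-plant dehydrin study design: 32 gymnosperm
#' (tree), 185 angiosperm (tree/shrub) and 36 angiosperm (vine) sequences;
#' architectural-type weights per group follow the reported type
#' distribution (gymnosperms dominated by FSKn 56.3% and FnKn 21%, with no
#' Y-containing types; tree/shrub angiosperms led by FSKn 39.5%; vines led
#' by YnSKn 69.4% with no Kn, YnKn or FnKn); K-segment copy number ranges
#' over 1-9 with small counts most likely.
#'
#' @param n named integer vector: cohort size per group.
#' @param type_weights named list (per group) of named numeric vectors of
#'   architectural-type weights, each summing to 1.
#' @param k_weights sampling weights for the K-segment copy number 1-9.
#' @param y_weights sampling weights for the Y-segment copy number 1-3.
#' @param f_weights sampling weights for the F-segment copy number (FnKn
#'   type) 1-2.
#' @param linker_range,mutations_per_segment see [synth_dehydrin()].
#' @param seed mandatory seed for reproducibility.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = c(GYMNOSPERM_TREE = 32L,
                              ANGIOSPERM_TREE_SHRUB = 185L,
                              ANGIOSPERM_VINE = 36L),
                        type_weights = list(
                          GYMNOSPERM_TREE = c(FSKn = 0.563, FnKn = 0.21,
                                              Kn = 0.08, KnS = 0.067,
                                              SKn = 0.08),
                          ANGIOSPERM_TREE_SHRUB = c(FSKn = 0.395,
                                                    YnSKn = 0.25,
                                                    YnKn = 0.10, KnS = 0.09,
                                                    SKn = 0.08, Kn = 0.05,
                                                    FnKn = 0.035),
                          ANGIOSPERM_VINE = c(YnSKn = 0.694, FSKn = 0.15,
                                              SKn = 0.10, KnS = 0.056)),
                        k_weights = c(0.30, 0.22, 0.16, 0.11, 0.08,
                                      0.05, 0.04, 0.02, 0.02),
                        y_weights = c(0.6, 0.3, 0.1),
                        f_weights = c(0.8, 0.2),
                        linker_range = c(10L, 60L),
                        mutations_per_segment = 0L,
                        seed) {
  if (missing(seed)) stop("cohort_spec requires a seed", call. = FALSE)
  stopifnot(!is.null(names(n)), all(names(n) %in% .GROUPS),
            all(names(n) %in% names(type_weights)))
  for (g in names(n)) {
    w <- type_weights[[g]]
    if (abs(sum(w) - 1) > 1e-9) {
      stop("type weights for group ", g, " do not sum to 1", call. = FALSE)
    }
    if (!all(names(w) %in% setdiff(.ARCH_TYPES, "ATYPICAL"))) {
      stop("unknown architectural type in weights for group ", g,
           call. = FALSE)
    }
  }
  structure(list(n = n, type_weights = type_weights, k_weights = k_weights,
                 y_weights = y_weights, f_weights = f_weights,
                 linker_range = linker_range,
                 mutations_per_segment = mutations_per_segment,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# instantiate a compact formula for an architectural type
.formula_for_type <- function(type, spec) {
  nk <- sample(1:9, 1L, prob = spec$k_weights)
  ny <- sample(1:3, 1L, prob = spec$y_weights)
  nf <- sample(1:2, 1L, prob = spec$f_weights)
  letters_vec <- switch(type,
    Kn    = rep("K", nk),
    KnS   = c(rep("K", nk), "S"),
    SKn   = c("S", rep("K", nk)),
    YnKn  = c(rep("Y", ny), rep("K", nk)),
    YnSKn = c(rep("Y", ny), "S", rep("K", nk)),
    FSKn  = c("F", "S", rep("K", nk)),
    FnKn  = c(rep("F", nf), rep("K", nk)),
    stop("cannot instantiate type ", type, call. = FALSE))
  .compress_formula(letters_vec)
}

#' Generate a synthetic dehydrin cohort
#'
#' Draws an architectural type per sequence from the group's type weights,
#' instantiates a formula and generates the protein with [synth_dehydrin()].
#' Deterministic given the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return a list with `records` (protein records data.frame), `truth`
#'   (planted-segment coordinates) and `assignments` (data.frame `accession`,
#'   `group`, `arch_type`, `formula`).
#' @export
synth_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    records <- list(); truths <- list(); assign_rows <- list()
    idx <- 0L
    for (g in names(spec$n)) {
      ng <- spec$n[[g]]
      if (ng == 0L) next
      w <- spec$type_weights[[g]]
      types <- sample(names(w), ng, replace = TRUE, prob = w)
      for (t in types) {
        idx <- idx + 1L
        acc <- sprintf("SYN%04d", idx)
        formula <- .formula_for_type(t, spec)
        out <- synth_dehydrin(formula, accession = acc, group = g,
                              linker_range = spec$linker_range,
                              mutations_per_segment =
                                spec$mutations_per_segment)
        records[[idx]] <- out$record
        truths[[idx]] <- out$truth
        assign_rows[[idx]] <- data.frame(accession = acc, group = g,
                                         arch_type = t, formula = formula,
                                         stringsAsFactors = FALSE)
      }
    }
    if (idx == 0L) {
      return(list(records = data.frame(accession = character(0),
                                       description = character(0),
                                       group = character(0),
                                       sequence = character(0),
                                       stringsAsFactors = FALSE),
                  truth = NULL, assignments = NULL))
    }
    list(records = do.call(rbind, records),
         truth = do.call(rbind, truths),
         assignments = do.call(rbind, assign_rows))
  })
}

.IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.instantiate_iupac <- function(consensus) {
  paste(vapply(strsplit(consensus, "", fixed = TRUE)[[1L]],
               function(l) sample(.IUPAC_EXPAND[[l]], 1L), character(1L)),
        collapse = "")
}

#' Generate a synthetic promoter with planted cis-elements
#'
#' Builds a uniform-ACGT background of the requested length and inserts one
#' instantiation of each planned element (reverse-complemented for
#' minus-strand plantings) at the planned start. Plan intervals must fit in
#' the promoter and must not overlap.
#'
#' @param length promoter length in bases (2000 is the conventional upstream
#'   window).
#' @param plan a data.frame with columns `element`, `start` (0-based) and
#'   `strand` (`"+"` or `"-"`); element names must exist in `catalog`.
#' @param catalog a [load_catalog()] catalog supplying consensus strings
#'   (the first variant of each element is planted).
#' @param gene_id identifier for the generated promoter.
#' @param seed optional seed (`NULL`: current RNG stream).
#' @return a list with `record` (one-row promoter data.frame) and `truth`
#'   (data.frame `gene_id`, `element`, `start`, `end`, `strand`,
#'   `planted_seq`, forward-strand coordinates).
#' @export
synth_promoter <- function(length = 2000L, plan, catalog = load_catalog(),
                           gene_id = "synprom1", seed = NULL) {
  stopifnot(is.data.frame(plan),
            all(c("element", "start", "strand") %in% names(plan)))
  bad <- setdiff(plan$element, catalog$name)
  if (length(bad)) {
    stop("plan element(s) not in catalog: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  gen <- function() {
    cons <- vapply(plan$element, function(e) {
      catalog$consensus[[match(e, catalog$name)]][1L]
    }, character(1L))
    widths <- nchar(cons)
    starts <- as.integer(plan$start)
    ends <- starts + widths
    if (any(starts < 0L) || any(ends > length)) {
      stop("plan interval outside the promoter", call. = FALSE)
    }
    ord <- order(starts)
    if (any(starts[ord][-1L] < ends[ord][-length(ord)])) {
      stop("overlapping plan intervals", call. = FALSE)
    }
    seq <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    planted <- character(nrow(plan))
    for (i in seq_len(nrow(plan))) {
      ins <- .instantiate_iupac(cons[i])
      if (plan$strand[i] == "-") {
        ins <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(ins)))
      }
      seq[(starts[i] + 1L):ends[i]] <- strsplit(ins, "", fixed = TRUE)[[1L]]
      planted[i] <- ins
    }
    list(
      record = data.frame(gene_id = gene_id, species = "synthetic",
                          sequence = paste(seq, collapse = ""),
                          stringsAsFactors = FALSE),
      truth = data.frame(gene_id = rep(gene_id, nrow(plan)),
                         element = plan$element,
                         start = starts, end = ends, strand = plan$strand,
                         planted_seq = planted, stringsAsFactors = FALSE))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Write ground truth as a BED-like TSV
#'
#' @param truth a truth data.frame from [synth_dehydrin()], [synth_cohort()]
#'   or [synth_promoter()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  if (!"strand" %in% names(out)) out$strand <- "."
  write_tsv(out, path)
}
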