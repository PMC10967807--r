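# Promoter cis-element scanning against an editable IUPAC catalog, and the
# presence-frequency profile (percentage of promoters containing each
# element at least once, on either strand).

.IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")

#' Load a cis-element catalog
#'
#' The catalog is a tab-separated file with columns `name`, `category`
#' (`LIGHT`, `HORMONE`, `STRESS`, `DEVELOPMENT`) and `consensus`
#' (comma-separated IUPAC DNA strings; several variants per element are
#' allowed, with union semantics for presence). Duplicate names and non-IUPAC
#' letters are errors. The package ships a default catalog of canonical
#' PlantCARE-style consensus strings (see
#' `system.file("extdata", "cis_elements.tsv", package = "dehydrinr")`).
#'
#' @param path path to the catalog TSV; defaults to the shipped catalog.
#' @return a data.frame of class `cis_catalog` with columns `name`,
#'   `category`, `consensus` (a list column of character vectors).
#' @export
load_catalog <- function(path = .extdata("cis_elements.tsv")) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, quote = "")
  if (nrow(tab) == 0L) {
    warning("empty cis-element catalog", call. = FALSE)
    out <- data.frame(name = character(0), category = character(0))
    out$consensus <- list()
    class(out) <- c("cis_catalog", class(out))
    return(out)
  }
  stopifnot(all(c("name", "category", "consensus") %in% names(tab)))
  if (anyDuplicated(tab$name)) {
    stop("duplicate element name(s): ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "),
         call. = FALSE)
  }
  bad_cat <- setdiff(unique(tab$category),
                     c("LIGHT", "HORMONE", "STRESS", "DEVELOPMENT"))
  if (length(bad_cat)) {
    stop("unknown category: ", paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  cons <- lapply(strsplit(tab$consensus, ",", fixed = TRUE), function(v) {
    v <- toupper(trimws(v))
    if (!length(v) || any(!nzchar(v))) {
      stop("empty consensus string in catalog", call. = FALSE)
    }
    v
  })
  for (i in seq_along(cons)) {
    letters_used <- unique(strsplit(paste(cons[[i]], collapse = ""), "")[[1L]])
    bad <- setdiff(letters_used, .IUPAC)
    if (length(bad)) {
      stop("non-IUPAC letter '", bad[1L], "' in consensus for element '",
           tab$name[i], "'", call. = FALSE)
    }
  }
  out <- data.frame(name = tab$name, category = tab$category,
                    stringsAsFactors = FALSE)
  out$consensus <- cons
  class(out) <- c("cis_catalog", class(out))
  out
}

# IUPAC matches of one consensus on one strand; forward-strand 0-based
# half-open coordinates; hits overlapping an N in the promoter are dropped
# (N matches nothing).
.match_consensus <- function(subject, consensus, strand) {
  pat <- if (strand == "+") consensus else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(consensus)))
  hits <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
  if (length(hits) == 0L) return(NULL)
  seqs <- as.character(hits)
  keep <- !grepl("N", seqs, fixed = TRUE)
  if (!any(keep)) return(NULL)
  data.frame(start = Biostrings::start(hits)[keep] - 1L,
             end = Biostrings::end(hits)[keep],
             strand = strand, matched_seq = seqs[keep],
             stringsAsFactors = FALSE)
}

#' Scan one promoter against a cis-element catalog
#'
#' Tests every position of the promoter, on both strands, against every
#' consensus variant of every catalog element by IUPAC set matching (exact
#' degenerate matching; no scores or thresholds). `N` in the promoter matches
#' nothing. Coordinates are forward-strand, 0-based, half-open; for
#' minus-strand hits the reverse complement of `matched_seq` satisfies the
#' consensus. Palindromic consensi yield paired +/- hits at the same locus.
#'
#' @param promoter a single-row promoter record (from [read_fasta_dna()]) or
#'   a plain sequence string.
#' @param catalog a [load_catalog()] catalog.
#' @return a data.frame with columns `gene_id`, `element`, `start`, `end`,
#'   `strand`, `matched_seq`, sorted by `start`.
#' @export
scan_promoter <- function(promoter, catalog) {
  if (is.character(promoter)) {
    promoter <- data.frame(gene_id = "promoter", sequence = toupper(promoter),
                           stringsAsFactors = FALSE)
  }
  stopifnot(nrow(promoter) == 1L, inherits(catalog, "cis_catalog"))
  subject <- Biostrings::DNAString(promoter$sequence)
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    for (cons in catalog$consensus[[i]]) {
      for (strand in c("+", "-")) {
        h <- .match_consensus(subject, cons, strand)
        if (!is.null(h)) {
          rows[[length(rows) + 1L]] <-
            cbind(gene_id = promoter$gene_id, element = catalog$name[i], h,
                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(0), element = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), matched_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$element, out$strand), , drop = FALSE]
  # identical variant matches at the same locus count once
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Scan a set of promoters
#'
#' @param promoters promoter records from [read_fasta_dna()].
#' @inheritParams scan_promoter
#' @return row-bound [scan_promoter()] results for all promoters.
#' @export
scan_promoters <- function(promoters, catalog) {
  out <- do.call(rbind, lapply(seq_len(nrow(promoters)), function(i) {
    scan_promoter(promoters[i, , drop = FALSE], catalog)
  }))
  if (is.null(out)) out <- scan_promoter("A", catalog)[0, , drop = FALSE]
  out
}

#' Presence-frequency profile
#'
#' For every catalog element, the percentage of promoters containing at least
#' one hit (on either strand, any consensus variant), rounded to one decimal.
#' Presence is per promoter: multiple hits, and paired +/- hits of a
#' palindromic consensus, count once. A derived `MeJA-responsive` row reports
#' the union presence of the `CGTCA-motif` and `TGACG-motif` elements when
#' both are in the catalog.
#'
#' @param hits a data.frame from [scan_promoters()].
#' @param promoters the promoter records the hits were computed from.
#' @param catalog the catalog used.
#' @return a data.frame with columns `element`, `category`,
#'   `promoters_with_hit`, `total_promoters`, `percent`.
#' @export
presence_frequency <- function(hits, promoters, catalog) {
  total <- nrow(promoters)
  if (nrow(catalog) == 0L) {
    return(data.frame(element = character(0), category = character(0),
                      promoters_with_hit = integer(0),
                      total_promoters = integer(0), percent = numeric(0),
                      stringsAsFactors = FALSE))
  }
  count_for <- function(elements) {
    length(unique(hits$gene_id[hits$element %in% elements]))
  }
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    with_hit <- count_for(catalog$name[i])
    data.frame(element = catalog$name[i], category = catalog$category[i],
               promoters_with_hit = with_hit, total_promoters = total,
               percent = round(100 * with_hit / max(total, 1L), 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  meja <- c("CGTCA-motif", "TGACG-motif")
  if (all(meja %in% catalog$name)) {
    with_hit <- count_for(meja)
    out <- rbind(out, data.frame(
      element = "MeJA-responsive", category = "HORMONE",
      promoters_with_hit = with_hit, total_promoters = total,
      percent = round(100 * with_hit / max(total, 1L), 1L),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Per-promoter category rollup
#'
#' Counts hits per functional category (light, hormone, stress, development)
#' for every promoter.
#'
#' @inheritParams presence_frequency
#' @return a data.frame with one row per promoter and one column per
#'   category, holding hit counts.
#' @export
category_rollup <- function(hits, promoters, catalog) {
  cats <- c("LIGHT", "HORMONE", "STRESS", "DEVELOPMENT")
  cat_of <- setNames(catalog$category, catalog$name)
  rows <- lapply(promoters$gene_id, function(id) {
    h <- hits[hits$gene_id == id, , drop = FALSE]
    tab <- table(factor(cat_of[h$element], levels = cats))
    cbind(data.frame(gene_id = id, stringsAsFactors = FALSE),
          as.data.frame.matrix(t(as.matrix(tab))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
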