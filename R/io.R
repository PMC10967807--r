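# FASTA / table input-output and the shared record model.
#
# Protein and promoter records are kept as plain data.frames (one row per
# sequence) so that every downstream table operation stays ordinary R.
# Coordinates in all outputs are 0-based, half-open, and every TSV written by
# the package carries a header comment saying so.

.COORD_COMMENT <- "# coordinates: 0-based, half-open"

# Read a FASTA file into (header, sequence) pairs using Biostrings, with the
# record order preserved. Empty files give zero records, not an error.
.read_fasta_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) {
    return(list(header = character(0), sequence = character(0)))
  }
  set <- Biostrings::readBStringSet(path)
  list(header = names(set), sequence = toupper(as.character(set)))
}

# Validate a sequence against an allowed alphabet; report the record and the
# first offending 0-based position on failure.
.check_alphabet <- function(seq, allowed, id, what) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% allowed)
  if (length(bad)) {
    stop(sprintf(
      "illegal %s letter '%s' in record '%s' at position %d (0-based)",
      what, chars[bad[1L]], id, bad[1L] - 1L), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read protein sequences from FASTA
#'
#' Parses a protein FASTA file into a data.frame of records. The accession is
#' the first whitespace-delimited token of the header; the rest is kept as
#' the description. Sequences are uppercased and must use the 20 canonical
#' amino-acid letters plus `X`; any other letter is a parse error naming the
#' record and the offending position. An optional group table (see
#' [read_group_table()]) assigns each accession to a taxon group; accessions
#' absent from the table are labelled `UNASSIGNED` with a warning.
#'
#' @param path path to a FASTA file.
#' @param group_table optional named character vector mapping accession to
#'   group token, as returned by [read_group_table()].
#' @return a data.frame with columns `accession`, `description`, `group`,
#'   `sequence`, one row per FASTA entry, input order preserved.
#' @export
read_fasta_proteins <- function(path, group_table = NULL) {
  raw <- .read_fasta_raw(path)
  n <- length(raw$header)
  acc  <- sub("\\s.*$", "", raw$header)
  desc <- ifelse(grepl("\\s", raw$header),
                 sub("^\\S+\\s+", "", raw$header), "")
  for (i in seq_len(n)) {
    if (!nzchar(acc[i])) stop("malformed FASTA header (empty accession) at record ",
                              i, call. = FALSE)
    if (nchar(raw$sequence[i]) < 1L)
      stop("empty sequence in record '", acc[i], "'", call. = FALSE)
    .check_alphabet(raw$sequence[i], .AAX, acc[i], "residue")
  }
  group <- rep("UNASSIGNED", n)
  if (!is.null(group_table) && n > 0L) {
    hit <- match(acc, names(group_table))
    group <- ifelse(is.na(hit), "UNASSIGNED", unname(group_table[hit]))
    if (anyNA(hit)) {
      warning("accessions missing from group table set to UNASSIGNED: ",
              paste(acc[is.na(hit)], collapse = ", "), call. = FALSE)
    }
  }
  data.frame(accession = acc, description = desc, group = group,
             sequence = raw$sequence, stringsAsFactors = FALSE)
}

#' Read promoter DNA sequences from FASTA
#'
#' Sequences are uppercased on read and must use the `A,C,G,T,N` alphabet;
#' anything else (including RNA `U`) is a parse error naming the record and
#' position. The header's first token is the gene id; the second token, if
#' present, is kept as the species label.
#'
#' @param path path to a DNA FASTA file.
#' @return a data.frame with columns `gene_id`, `species`, `sequence`.
#' @export
read_fasta_dna <- function(path) {
  raw <- .read_fasta_raw(path)
  n <- length(raw$header)
  id <- sub("\\s.*$", "", raw$header)
  species <- ifelse(grepl("\\s", raw$header),
                    sub("^\\S+\\s+", "", raw$header), "")
  for (i in seq_len(n)) {
    if (!nzchar(id[i])) stop("malformed FASTA header (empty id) at record ",
                             i, call. = FALSE)
    if (nchar(raw$sequence[i]) < 1L)
      stop("empty sequence in record '", id[i], "'", call. = FALSE)
    .check_alphabet(raw$sequence[i], c("A", "C", "G", "T", "N"),
                    id[i], "nucleotide")
  }
  data.frame(gene_id = id, species = species, sequence = raw$sequence,
             stringsAsFactors = FALSE)
}

#' Read an accession-to-group assignment table
#'
#' A two-column tab-separated file (accession, group token). Group tokens are
#' restricted to `GYMNOSPERM_TREE`, `ANGIOSPERM_TREE_SHRUB`,
#' `ANGIOSPERM_VINE` and `UNASSIGNED`; unknown tokens and duplicate
#' accessions are errors.
#'
#' @param path path to the TSV file.
#' @return a named character vector: `names` are accessions, values group
#'   tokens.
#' @export
read_group_table <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, col.names = c("accession", "group"),
                    colClasses = "character")
  if (anyDuplicated(tab$accession)) {
    stop("duplicate accession(s) in group table: ",
         paste(unique(tab$accession[duplicated(tab$accession)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(tab$group), .GROUPS)
  if (length(bad)) {
    stop("unknown group token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  setNames(tab$group, tab$accession)
}

#' @rdname read_group_table
#' @param records protein records with `accession` and `group` columns.
#' @export
write_group_table <- function(records, path) {
  write.table(records[, c("accession", "group")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write records as FASTA
#'
#' @param records a data.frame with either `accession`/`description` (protein)
#'   or `gene_id`/`species` (promoter) columns plus `sequence`.
#' @param path output path.
#' @param width line-wrap width for sequences.
#' @return the path, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  id <- if ("accession" %in% names(records)) records$accession else records$gene_id
  extra <- if ("description" %in% names(records)) records$description
           else if ("species" %in% names(records)) records$species
           else rep("", nrow(records))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(extra[i])) paste(id[i], extra[i]) else id[i]
    writeLines(paste0(">", header), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Remove exact duplicate sequences
#'
#' Keeps the first record of every identical sequence string. Fragment
#' detection (partial sequences of a longer entry) is intentionally not
#' attempted and is left to the user.
#'
#' @param records protein records from [read_fasta_proteins()].
#' @return the records with exact-sequence duplicates removed.
#' @export
dedupe_records <- function(records) {
  records[!duplicated(records$sequence), , drop = FALSE]
}

#' Write a per-sequence report
#'
#' Joins records with their per-sequence profiles (one profile row per
#' record, matched by the shared id column) and writes a tab-separated or
#' JSON report with a stable column order. The report round-trips through
#' [read_report()].
#'
#' @param records data.frame of records (must share an id column with
#'   `profiles`: `accession` or `gene_id`).
#' @param profiles data.frame of per-sequence values, one row per record.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return the path, invisibly.
#' @export
write_report <- function(records, profiles, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  id_col <- if ("accession" %in% names(records)) "accession" else "gene_id"
  if (!id_col %in% names(profiles)) {
    stop("profiles lack the id column '", id_col, "'", call. = FALSE)
  }
  if (nrow(profiles) != nrow(records) ||
      !all(records[[id_col]] %in% profiles[[id_col]])) {
    stop("need exactly one profile per record", call. = FALSE)
  }
  prof <- profiles[match(records[[id_col]], profiles[[id_col]]), , drop = FALSE]
  out <- cbind(records[setdiff(names(records), "sequence")],
               prof[setdiff(names(prof), id_col)])
  rownames(out) <- NULL
  ok <- tryCatch({
    if (format == "tsv") write_tsv(out, path) else {
      jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                           auto_unbox = TRUE, pretty = TRUE)
    }
    TRUE
  }, error = function(e) {
    stop("failed to write report to '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    read.table(path, header = TRUE, sep = "\t", comment.char = "#",
               stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

# TSV writer used for every tabular output: leading coordinate-convention
# comment, header row, no quoting surprises.
write_tsv <- function(df, path, comment = .COORD_COMMENT) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(comment, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
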