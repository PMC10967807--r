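# End-to-end orchestration. The pipeline is a pure composition of the module
# operations: running the stages by hand with the same configuration yields
# identical files. Sequences with no K segment are not dehydrins; they are
# excluded from every downstream table but retained, auditable, in a rejects
# file.

#' Pipeline run configuration
#'
#' Collects input paths and tunables for [run_protein_pipeline()] and
#' [run_promoter_pipeline()]. All referenced paths must exist at run start.
#' The configuration is serializable to a plain-text key-value file and is
#' echoed into the output directory of every run.
#'
#' @param proteins path to a protein FASTA (protein pipeline).
#' @param promoters path to a promoter FASTA (promoter pipeline).
#' @param group_table optional path to a group-assignment TSV.
#' @param catalog optional path to a cis-element catalog TSV (default: the
#'   shipped catalog).
#' @param out_dir output directory (created if missing).
#' @param max_mismatch,min_score scanner parameters, see [scan_params()].
#' @param seed seed recorded with the run (the analysis stages are
#'   deterministic; the seed matters when the inputs were generated).
#' @return a list of class `run_config`.
#' @export
run_config <- function(proteins = NULL, promoters = NULL, group_table = NULL,
                       catalog = NULL, out_dir = ".", max_mismatch = 2L,
                       min_score = 0, seed = 1L) {
  for (p in c(proteins, promoters, group_table, catalog)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input path does not exist: ", p, call. = FALSE)
    }
  }
  structure(list(proteins = proteins, promoters = promoters,
                 group_table = group_table, catalog = catalog,
                 out_dir = out_dir, max_mismatch = as.integer(max_mismatch),
                 min_score = min_score, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config` object.
#' @param path destination of the key-value file.
#' @export
write_config <- function(config, path) {
  keys <- c("proteins", "promoters", "group_table", "catalog", "out_dir",
            "max_mismatch", "min_score", "seed")
  lines <- vapply(keys, function(k) {
    v <- config[[k]]
    sprintf("%s=%s", k, if (is.null(v)) "" else as.character(v))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# config hash recorded in the log: plain sum over the serialized bytes, so
# reruns of the same configuration are recognizable without extra packages
.config_hash <- function(config) {
  tmp <- tempfile(); on.exit(unlink(tmp))
  write_config(config, tmp)
  bytes <- as.integer(charToRaw(paste(readLines(tmp), collapse = "\n")))
  sprintf("%08x", sum(bytes * seq_along(bytes)) %% .Machine$integer.max)
}

.write_log <- function(config, path, extra = character(0)) {
  writeLines(c(
    sprintf("dehydrinr version: %s", as.character(packageVersion("dehydrinr"))),
    sprintf("config hash: %s", .config_hash(config)),
    sprintf("seed: %d", config$seed),
    extra), path)
}

# run `expr`; on any error remove the files created so far and rethrow with
# the stage name
.stage <- function(name, created, expr) {
  tryCatch(expr, error = function(e) {
    unlink(created, force = TRUE)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the protein pipeline
#'
#' Reads the protein FASTA (and optional group table), scans all four
#' segment classes, resolves overlaps, drops sequences with no K segment
#' into a rejects file, builds architecture and biochemical profiles, and
#' writes group summaries plus Games-Howell pairwise results for the six
#' standard variables. Outputs (all TSV, in `out_dir`): `segments.tsv`,
#' `architecture.tsv`, `biochem.tsv`, `rejects.tsv`, `type_distribution.tsv`,
#' `group_summaries.tsv`, `games_howell.tsv`, plus `config.txt` and
#' `run.log`. Reruns with the same configuration produce byte-identical
#' reports. On error, partial outputs are removed.
#'
#' @param config a [run_config()] with `proteins` set.
#' @return invisibly, a list with the computed tables and output paths.
#' @export
run_protein_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"), !is.null(config$proteins))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  created <- character(0)
  note <- function(f) { created <<- c(created, f); f }
  params <- scan_params(config$max_mismatch, config$min_score)

  groups <- if (!is.null(config$group_table)) {
    .stage("group_table", created, read_group_table(config$group_table))
  } else NULL
  records <- .stage("read_proteins", created,
                    read_fasta_proteins(config$proteins, groups))
  matches <- .stage("scan", created, scan_proteins(records, params))
  profiles <- .stage("architecture", created,
                     architecture_profiles(records, matches))
  rejects <- attr(profiles, "rejects")
  kept <- records[records$accession %in% profiles$accession, , drop = FALSE]
  biochem <- .stage("biochem", created, if (nrow(kept)) biochem_profiles(kept)
                    else NULL)

  .stage("write_segments", created, {
    write_tsv(matches[matches$accession %in% profiles$accession, ,
                      drop = FALSE], note(out("segments.tsv")))
    write_tsv(data.frame(accession = rejects,
                         reason = rep("no K segment", length(rejects)),
                         stringsAsFactors = FALSE),
              note(out("rejects.tsv")))
    write_tsv(profiles, note(out("architecture.tsv")))
    if (!is.null(biochem)) write_tsv(biochem, note(out("biochem.tsv")))
    if (nrow(profiles)) {
      write_tsv(type_distribution(profiles), note(out("type_distribution.tsv")))
    }
  })

  comparison <- NULL
  if (!is.null(biochem) && nrow(biochem)) {
    comparison <- .stage("group_stats", created, {
      cmp <- withCallingHandlers(
        compare_groups(biochem),
        warning = function(w) invokeRestart("muffleWarning"))
      write_tsv(cmp$summaries, note(out("group_summaries.tsv")))
      if (!is.null(cmp$pairwise)) {
        write_tsv(cmp$pairwise, note(out("games_howell.tsv")))
      }
      cmp
    })
  }
  write_config(config, out("config.txt"))
  .write_log(config, out("run.log"),
             sprintf("records: %d, kept: %d, rejected: %d",
                     nrow(records), nrow(profiles), length(rejects)))
  invisible(list(records = records, matches = matches, profiles = profiles,
                 rejects = rejects, biochem = biochem,
                 comparison = comparison, out_dir = config$out_dir))
}

#' Run the promoter pipeline
#'
#' Reads the promoter FASTA and the cis-element catalog, scans every
#' promoter on both strands, and writes the hits, the presence-frequency
#' profile, and the per-promoter category rollup. Outputs (in `out_dir`):
#' `cis_hits.tsv`, `cis_frequency.tsv`, `category_rollup.tsv`, `config.txt`,
#' `run.log`. An empty catalog yields empty outputs with a warning, not an
#' error.
#'
#' @param config a [run_config()] with `promoters` set.
#' @return invisibly, a list with the computed tables and output paths.
#' @export
run_promoter_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"), !is.null(config$promoters))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  created <- character(0)
  note <- function(f) { created <<- c(created, f); f }

  catalog <- .stage("catalog", created, {
    if (is.null(config$catalog)) load_catalog() else
      load_catalog(config$catalog)
  })
  promoters <- .stage("read_promoters", created,
                      read_fasta_dna(config$promoters))
  hits <- .stage("scan_promoters", created, scan_promoters(promoters, catalog))
  freq <- .stage("frequency", created,
                 presence_frequency(hits, promoters, catalog))
  rollup <- .stage("rollup", created, category_rollup(hits, promoters, catalog))
  .stage("write_promoter_outputs", created, {
    write_tsv(hits, note(out("cis_hits.tsv")))
    write_tsv(freq, note(out("cis_frequency.tsv")))
    write_tsv(rollup, note(out("category_rollup.tsv")))
  })
  write_config(config, out("config.txt"))
  .write_log(config, out("run.log"),
             sprintf("promoters: %d, elements: %d, hits: %d",
                     nrow(promoters), nrow(catalog), nrow(hits)))
  invisible(list(promoters = promoters, catalog = catalog, hits = hits,
                 frequency = freq, rollup = rollup,
                 out_dir = config$out_dir))
}
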