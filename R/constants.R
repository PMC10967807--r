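#' Amino-acid constants tables
#'
#' The package ships its physical constants as plain-text tables under
#' `inst/extdata/` and loads them on first use. `aa_constants()` returns the
#' average residue masses (Da) and Kyte-Doolittle hydropathy values;
#' `pka_set()` returns one of the shipped pKa conventions used by the
#' isoelectric-point calculation; `phi_background()` returns the disordered
#' linker amino-acid composition used by the synthetic generator.
#'
#' @return `aa_constants()`: a data.frame with columns `residue`, `avg_mass`,
#'   `kd_hydropathy` (one row per canonical residue). `pka_set()`: a
#'   data.frame with columns `site`, `group`, `pka`. `phi_background()`: a
#'   named numeric vector of residue frequencies summing to 1.
#' @param name which pKa convention to load: `"bjellqvist"` (the ProtParam
#'   default) or `"emboss"`.
#' @export
aa_constants <- function() {
  if (is.null(.dhn_cache$aa)) {
    tab <- read.table(.extdata("aa_constants.tsv"), header = TRUE,
                      sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
    stopifnot(nrow(tab) == 20L, setequal(tab$residue, .AA))
    .dhn_cache$aa <- tab[match(.AA, tab$residue), , drop = FALSE]
  }
  .dhn_cache$aa
}

#' @rdname aa_constants
#' @export
pka_set <- function(name = c("bjellqvist", "emboss")) {
  name <- match.arg(name)
  key <- paste0("pka_", name)
  if (is.null(.dhn_cache[[key]])) {
    tab <- read.table(.extdata(paste0(key, ".tsv")), header = TRUE,
                      sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
    stopifnot(all(c("site", "group", "pka") %in% names(tab)))
    .dhn_cache[[key]] <- tab
  }
  .dhn_cache[[key]]
}

#' @rdname aa_constants
#' @export
phi_background <- function() {
  if (is.null(.dhn_cache$phi)) {
    tab <- read.table(.extdata("phi_background.tsv"), header = TRUE,
                      sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
    freq <- setNames(tab$freq, tab$residue)[.AA]
    stopifnot(!anyNA(freq), abs(sum(freq) - 1) < 1e-9)
    .dhn_cache$phi <- freq
  }
  .dhn_cache$phi
}

# named lookup vectors used throughout the biochem module
.mass_table <- function() setNames(aa_constants()$avg_mass, .AA)
.kd_table   <- function() setNames(aa_constants()$kd_hydropathy, .AA)
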