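# Group summaries and the Games-Howell pairwise post-hoc test.
#
# Games-Howell compares every pair of groups with Welch's standard error and
# Welch-Satterthwaite degrees of freedom, referring the statistic
# q = |mean_i - mean_j| / sqrt(SE^2 / 2) to the studentized-range
# distribution with k groups, which controls the familywise error under
# unequal variances without assuming equal group sizes. (The procedure is
# sometimes loosely labelled non-parametric; it is the Welch/studentized-
# range construction, which drops the equal-variance assumption, not the
# normality assumption.) No further multiple-testing correction is applied:
# familywise control is built into the studentized-range reference.

# normalize the two accepted input forms to a named list of numeric vectors
.as_groups <- function(values, groups = NULL) {
  if (is.list(values)) {
    stopifnot(!is.null(names(values)), all(nzchar(names(values))))
    return(lapply(values, as.numeric))
  }
  stopifnot(!is.null(groups), length(values) == length(groups))
  split(as.numeric(values), as.character(groups))
}

#' Five-number summaries per group
#'
#' Median, quartiles (linear interpolation, the default quantile type) and
#' range for every group.
#'
#' @param values a named list of numeric vectors (one per group), or a
#'   numeric vector accompanied by `groups`.
#' @param groups optional group labels parallel to `values`.
#' @return a data.frame with columns `group`, `n`, `min`, `q1`, `median`,
#'   `q3`, `max`.
#' @export
summarize_groups <- function(values, groups = NULL) {
  by_group <- .as_groups(values, groups)
  rows <- lapply(names(by_group), function(g) {
    x <- by_group[[g]]
    if (length(x) == 0L) stop("empty group: ", g, call. = FALSE)
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(group = g, n = length(x), min = min(x), q1 = q[1L],
               median = q[2L], q3 = q[3L], max = max(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Games-Howell pairwise comparisons
#'
#' For every pair of groups (i, j): the standard error is
#' `sqrt(s_i^2/n_i + s_j^2/n_j)`, the degrees of freedom follow
#' Welch-Satterthwaite, the statistic is
#' `q = |m_i - m_j| / sqrt(SE^2 / 2)`, and the p-value comes from the
#' studentized-range distribution with `k` groups and those degrees of
#' freedom. With `k = 2` the procedure reduces to Welch's two-sided t test
#' (`q = t * sqrt(2)`).
#'
#' @inheritParams summarize_groups
#' @param alpha familywise significance level used for the `significant`
#'   flag.
#' @return a data.frame with one row per unordered pair: `group_a`,
#'   `group_b`, `mean_diff` (`m_a - m_b`), `se`, `df`, `q`, `p_value`,
#'   `significant`.
#' @export
games_howell <- function(values, groups = NULL, alpha = 0.05) {
  by_group <- .as_groups(values, groups)
  k <- length(by_group)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  n <- vapply(by_group, length, integer(1L))
  if (any(n < 2L)) {
    stop("degenerate group (n < 2): ",
         paste(names(by_group)[n < 2L], collapse = ", "), call. = FALSE)
  }
  m <- vapply(by_group, mean, numeric(1L))
  v <- vapply(by_group, var, numeric(1L))
  if (any(v == 0)) {
    stop("degenerate group (zero variance): ",
         paste(names(by_group)[v == 0], collapse = ", "), call. = FALSE)
  }
  gn <- names(by_group)
  pairs <- utils::combn(k, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    se2 <- v[i] / n[i] + v[j] / n[j]
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1L) +
                   (v[j] / n[j])^2 / (n[j] - 1L))
    q <- abs(m[i] - m[j]) / sqrt(se2 / 2)
    pval <- ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    data.frame(group_a = gn[i], group_b = gn[j], mean_diff = m[i] - m[j],
               se = sqrt(se2), df = df, q = q, p_value = pval,
               significant = pval < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group summaries and pairwise tests for every biochemical property
#'
#' Convenience wrapper running [summarize_groups()] and [games_howell()] for
#' each of the six standard dehydrin variables (mw, pi, gravy, fold_index,
#' lys_pct, his_pct) of a biochemical profile table. Properties for which the
#' pairwise test is degenerate (fewer than two usable groups) are summarized
#' only, with a warning.
#'
#' @param profiles a data.frame from [biochem_profiles()] with a `group`
#'   column.
#' @param properties which numeric columns to analyze.
#' @param alpha significance level.
#' @return a list with data.frames `summaries` (with a `property` column) and
#'   `pairwise` (idem).
#' @export
compare_groups <- function(profiles,
                           properties = c("mw", "pi", "gravy", "fold_index",
                                          "lys_pct", "his_pct"),
                           alpha = 0.05) {
  stopifnot(all(properties %in% names(profiles)))
  summaries <- list(); pairwise <- list()
  for (p in properties) {
    by_group <- split(profiles[[p]], profiles$group)
    summaries[[p]] <- cbind(property = p, summarize_groups(by_group),
                            stringsAsFactors = FALSE)
    usable <- vapply(by_group, function(x) length(x) >= 2L && var(x) > 0,
                     logical(1L))
    if (sum(usable) >= 2L) {
      pairwise[[p]] <- cbind(property = p,
                             games_howell(by_group[usable], alpha = alpha),
                             stringsAsFactors = FALSE)
    } else {
      warning("property '", p, "': fewer than two usable groups, ",
              "pairwise test skipped", call. = FALSE)
    }
  }
  list(summaries = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
       pairwise = if (length(pairwise))
         do.call(rbind, c(pairwise, list(make.row.names = FALSE))) else NULL)
}
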