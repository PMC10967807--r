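# Independent oracles used across the test files. These deliberately share no
# matching / integration code with the package internals they check.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

random_protein <- function(n, residues = AA20) {
  paste(sample(residues, n, replace = TRUE), collapse = "")
}

# --- brute-force segment matcher -------------------------------------------
# Tests every window by direct set membership against the degenerate pattern
# definition (core exact, <= m mismatches elsewhere), with no PSPM and no
# vectorized bookkeeping.
brute_force_matches <- function(sequence, segment_class, max_mismatch = 2L) {
  pat <- default_pattern(segment_class)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  hits <- list()
  window_ok <- function(win, sets, core) {
    mm <- 0L
    for (j in seq_along(sets)) {
      in_set <- win[j] %in% sets[[j]]
      if (core[j] && !in_set) return(NA)
      if (!core[j] && !in_set) mm <- mm + 1L
    }
    mm
  }
  if (pat$type == "fixed") {
    w <- pat$width
    for (i in seq_len(max(L - w + 1L, 0L))) {
      mm <- window_ok(chars[i:(i + w - 1L)], pat$positions, pat$core)
      if (!is.na(mm) && mm <= max_mismatch) {
        hits[[length(hits) + 1L]] <- c(start = i - 1L, end = i - 1L + w)
      }
    }
  } else {
    for (i in seq_len(max(L - 11L, 0L))) {
      mm <- window_ok(chars[i:(i + 4L)], pat$positions$anchor, rep(FALSE, 5L))
      if (is.na(mm) || mm > max_mismatch) next
      t0 <- i + 5L
      r <- 0L
      while (t0 + r <= L && chars[t0 + r] == "S") r <- r + 1L
      r <- min(r, 8L)
      if (r < 4L || t0 + r + 2L > L) next
      mm2 <- window_ok(chars[(t0 + r):(t0 + r + 2L)], pat$positions$tail,
                       rep(FALSE, 3L))
      if (is.na(mm2) || mm + mm2 > max_mismatch) next
      hits[[length(hits) + 1L]] <- c(start = i - 1L, end = i - 1L + 5L + r + 3L)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  as.data.frame(do.call(rbind, hits))
}

# --- isoelectric-point charge-scan oracle -----------------------------------
# Scans the net charge curve at 0.01-pH steps and returns the first pH where
# it crosses zero.
pi_scan_oracle <- function(sequence) {
  phs <- seq(0, 14, by = 0.01)
  q <- vapply(phs, function(p) dehydrinr::protein_charge(sequence, p),
              numeric(1L))
  i <- which(q <= 0)[1L]
  # linear interpolation between the bracketing grid points
  if (i == 1L) return(phs[1L])
  p0 <- phs[i - 1L]; p1 <- phs[i]
  q0 <- q[i - 1L]; q1 <- q[i]
  p0 + (0 - q0) * (p1 - p0) / (q1 - q0)
}

# --- studentized-range CDF by direct numerical integration ------------------
# P(Q <= q) for k means and df degrees of freedom, via the classical double
# integral over the range of k normal scores and the scaled-chi density of
# the pooled standard deviation (log-space to stay finite at large df).
ptukey_oracle <- function(q, k, df) {
  p_given_s <- function(qq) {
    inner <- function(z) {
      stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - qq))^(k - 1L)
    }
    k * stats::integrate(inner, -Inf, Inf)$value
  }
  log_fs <- function(s) {
    (df / 2) * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2) +
      (df - 1) * log(s) - df * s^2 / 2
  }
  stats::integrate(function(s) {
    vapply(s, function(si) exp(log_fs(si)) * p_given_s(q * si), numeric(1L))
  }, 0, Inf, rel.tol = 1e-8)$value
}

# segment-truth comparison key
truth_key <- function(df) paste(df$accession, df$class, df$start, df$end)
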