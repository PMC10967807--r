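test_that("degenerate patterns match the published consensus definitions", {
  k <- default_pattern("K")
  expect_equal(k$width, 15L)
  expect_equal(k$positions[[7L]], c("D", "E"))   # 0-based position 6
  expect_equal(k$positions[[11L]], c("D", "E"))  # 0-based position 10
  expect_equal(k$positions[[9L]], c("I", "V"))   # Ile core, Val tolerated
  expect_true(all(which(k$core) == c(4L, 8L, 9L, 10L, 14L, 15L)))

  y <- default_pattern("Y")
  expect_equal(y$width, 7L)
  expect_equal(y$positions[[1L]], "D")
  expect_equal(unlist(y$positions[4:6]), c("G", "N", "P"))
  expect_equal(y$positions[[3L]], c("Y", "H", "F"))

  f <- default_pattern("F")
  expect_equal(f$width, 12L)
  # the name-giving Phe dyad at 0-based positions 7 and 9
  expect_equal(f$positions[[8L]], "F")
  expect_equal(f$positions[[10L]], "F")

  s <- default_pattern("S")
  expect_equal(s$tract_range, c(4L, 8L))
  expect_equal(s$width, c(12L, 16L))
})

test_that("PSPMs carry the observed conserved-position frequencies", {
  for (cl in c("K", "Y", "S", "F")) {
    p <- default_pspm(cl)
    expect_true(all(abs(colSums(p) - 1) < 1e-9), label = paste("cols", cl))
    expect_true(all(p > 0), label = paste("floor", cl))
  }
  k <- default_pspm("K")
  expect_equal(unname(k["K", 2L]), 0.81, tolerance = 0.003)  # 0-based pos 1
  expect_equal(unname(k["K", 8L]), 0.90, tolerance = 0.003)
  expect_equal(unname(k["V", 9L]), 0.12, tolerance = 0.003)
  y <- default_pspm("Y")
  expect_equal(unname(y["Y", 3L]), 0.62, tolerance = 0.003)  # 0-based pos 2
  expect_equal(unname(y["D", 1L]), 0.96, tolerance = 0.003)

  block <- write_pspm(k)
  expect_match(block[1L], "MOTIF K_segment")
  expect_length(block, 3L + ncol(k))
})

test_that("the textbook consensus sequences are matched at full width", {
  mk <- scan_segment("EKKGIMDKIKEKLPG", "K")
  expect_equal(nrow(mk), 1L)
  expect_equal(mk$start, 0L)
  expect_equal(mk$end, 15L)
  expect_gt(mk$score, 0)

  my <- scan_segment("DEYGNPV", "Y")
  expect_equal(my$start, 0L)
  expect_equal(my$end, 7L)
})

test_that("core positions are exact; non-core mismatches respect the budget", {
  k_cons <- "EKKGIMDKIKEKLPG"
  # two non-core substitutions (positions 1 and 11, 0-based) still match
  two_mm <- "EWKGIMDKIKEWLPG"
  expect_equal(nrow(scan_segment(two_mm, "K", scan_params(max_mismatch = 2))),
               1L)
  expect_equal(nrow(scan_segment(two_mm, "K", scan_params(max_mismatch = 1))),
               0L)
  # a single core violation kills the match regardless of budget
  core_mm <- sub("PG$", "PW", k_cons)
  expect_equal(nrow(scan_segment(core_mm, "K", scan_params(max_mismatch = 5))),
               0L)
  # Val for Ile inside the core is tolerated by the pattern itself
  val <- sub("KIK", "KVK", k_cons)
  expect_equal(nrow(scan_segment(val, "K")), 1L)
})

test_that("S segments match serine tracts of 4-8 with widths 12-16", {
  for (r in 3:10) {
    s <- paste0("AA", "LHRSG", strrep("S", r), "DDE", "AA")
    m <- scan_segment(s, "S")
    if (r < 4) {
      expect_equal(nrow(m), 0L, label = paste("run", r))
    } else {
      expect_equal(nrow(m), 1L, label = paste("run", r))
      expect_equal(m$tract_len, min(r, 8L))
      expect_equal(m$end - m$start, 5L + min(r, 8L) + 3L)
      expect_equal(m$start, 2L)
    }
  }
})

test_that("random uniform sequences are essentially never matched", {
  set.seed(991)
  windows <- 0L
  fp <- c(K = 0L, Y = 0L, S = 0L, F = 0L)
  for (i in 1:55) {
    s <- random_protein(200L)
    windows <- windows + 186L
    for (cl in names(fp)) fp[cl] <- fp[cl] + nrow(scan_segment(s, cl))
  }
  expect_gt(windows, 10000L)
  # false-positive rate below 1e-3 per window for every class
  expect_true(all(fp / windows < 1e-3))
})

test_that("matches shift with non-matching flanks and are otherwise invariant", {
  set.seed(17)
  base <- synth_dehydrin("YSK2", seed = 41)$record$sequence
  m0 <- do.call(rbind, lapply(c("K", "Y", "S", "F"),
                              function(cl) scan_segment(base, cl)))
  flank <- strrep("W", 23L)  # Trp appears in no segment pattern core
  m1 <- do.call(rbind, lapply(c("K", "Y", "S", "F"), function(cl) {
    scan_segment(paste0(flank, base, flank), cl)
  }))
  expect_equal(nrow(m1), nrow(m0))
  expect_equal(m1$start, m0$start + 23L)
  expect_equal(m1$matched_seq, m0$matched_seq)
})

test_that("scanner agrees with the brute-force set-membership oracle", {
  set.seed(330)
  seeds <- c(
    "EKKGIMDKIKEKLPG", "DEYGNPV", "LHRSGSSSSSSSDDE", "EAADRGAFDFAK")
  for (trial in 1:40) {
    # short sequences with partial/complete consensi embedded in random flanks
    s <- paste0(random_protein(sample(0:15, 1L)),
                substring(sample(seeds, 1L), 1L, sample(5:16, 1L)),
                random_protein(sample(0:20, 1L)))
    s <- substring(s, 1L, 60L)
    for (cl in c("K", "Y", "S", "F")) {
      got <- scan_segment(s, cl, scan_params(max_mismatch = 2,
                                             min_score = -Inf))
      want <- brute_force_matches(s, cl, max_mismatch = 2L)
      expect_equal(got$start, want$start,
                   label = paste("class", cl, "seq", s))
      expect_equal(got$end, want$end)
    }
  }
})

test_that("overlap resolution is greedy by score with start tie-break", {
  mk <- function(class, start, end, score) {
    data.frame(class = class, start = start, end = end,
               matched_seq = "x", score = score, source = "PSPM",
               tract_len = NA_integer_, stringsAsFactors = FALSE)
  }
  # identical scores, overlapping -> keep the earlier start
  two <- rbind(mk("K", 0L, 15L, 10), mk("K", 5L, 20L, 10))
  expect_equal(resolve_overlaps(two)$start, 0L)
  # disjoint matches of different classes are both kept
  disj <- rbind(mk("K", 0L, 15L, 10), mk("S", 30L, 42L, 8))
  expect_equal(nrow(resolve_overlaps(disj)), 2L)
  # cross-class overlap: the higher-scoring F wins
  cross <- rbind(mk("K", 0L, 15L, 10), mk("F", 10L, 22L, 20))
  expect_equal(resolve_overlaps(cross)$class, "F")
})
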