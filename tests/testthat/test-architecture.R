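mk_match <- function(class, start, width = 15L) {
  data.frame(class = class, start = start, end = start + width,
             matched_seq = "x", score = 1, source = "PSPM",
             tract_len = NA_integer_, stringsAsFactors = FALSE)
}

test_that("architecture strings follow start order and compress runs", {
  m <- do.call(rbind, Map(mk_match,
                          c("Y", "Y", "S", "K", "K", "K"),
                          c(5L, 20L, 40L, 80L, 120L, 160L)))
  arch <- architecture_string(m)
  expect_equal(arch$ordered_letters, "YYSKKK")
  expect_equal(arch$formula, "Y2SK3")

  expect_equal(architecture_string(mk_match("K", 0L))$formula, "K")
  m2 <- do.call(rbind, Map(mk_match, c("F", "S", "K"), c(0L, 30L, 60L)))
  expect_equal(architecture_string(m2)$formula, "FSK")

  # discovery order is irrelevant: letters come from coordinates
  shuffled <- m[c(4L, 1L, 6L, 3L, 2L, 5L), ]
  expect_equal(architecture_string(shuffled)$ordered_letters, "YYSKKK")

  expect_error(architecture_string(mk_match("K", 0L)[0, ]), "not a dehydrin")
})

test_that("the canonical grammar classifies the seven types and atypicals", {
  expect_equal(classify_architecture("K"), "Kn")
  expect_equal(classify_architecture("KKKKKKKKK"), "Kn")
  expect_equal(classify_architecture("KKS"), "KnS")
  expect_equal(classify_architecture("SKK"), "SKn")
  expect_equal(classify_architecture("YYKK"), "YnKn")
  expect_equal(classify_architecture("YYSKKK"), "YnSKn")
  expect_equal(classify_architecture("FSKKK"), "FSKn")
  expect_equal(classify_architecture("FFKKK"), "FnKn")  # two F copies allowed
  expect_equal(classify_architecture("FK"), "FnKn")

  # interleavings route to ATYPICAL (Y after K, S interior to the K block,
  # F with Y, two F with an S)
  expect_equal(classify_architecture("YSKKKSSKKKYYSKKK"), "ATYPICAL")
  expect_equal(classify_architecture("KY"), "ATYPICAL")
  expect_equal(classify_architecture("KSK"), "ATYPICAL")
  expect_equal(classify_architecture("FYK"), "ATYPICAL")
  expect_equal(classify_architecture("FFSKK"), "ATYPICAL")
  expect_equal(classify_architecture("SKS"), "ATYPICAL")

  expect_error(classify_architecture("YS"), "no K segment")
  expect_error(classify_architecture("QK"), "K, Y, S, F")
})

test_that("every letters string maps to exactly one type (grammar exclusivity)", {
  grammars <- c(Kn = "^K+$", SKn = "^SK+$", KnS = "^K+S$", YnKn = "^Y+K+$",
                YnSKn = "^Y+SK+$", FSKn = "^FSK+$", FnKn = "^F+K+$")
  set.seed(55)
  for (i in 1:500) {
    s <- paste(sample(c("K", "Y", "S", "F"), sample(1:12, 1L),
                      replace = TRUE), collapse = "")
    if (!grepl("K", s)) next
    hits <- names(grammars)[vapply(grammars, grepl, logical(1L), x = s)]
    expect_lte(length(hits), 1L)
    got <- classify_architecture(s)
    expect_equal(got, if (length(hits)) hits else "ATYPICAL", label = s)
  }
})

test_that("rare-motif detectors fire on the printed literals only", {
  k_cons <- "EKKGIMDKIKEKLPG"
  flanked <- paste0("GGG", "HH", k_cons, "HH", "GGG")
  km <- mk_match("K", 5L)
  r <- detect_rare_motifs(flanked, km)
  expect_equal(r$hh_flanked_k, 0L)

  one_side <- paste0("GGG", "HH", k_cons, "GG", "GGG")
  r1 <- detect_rare_motifs(one_side, km)
  expect_equal(r1$hh_flanked_k, integer(0))
  expect_equal(r1$hh_one_sided, 0L)

  r2 <- detect_rare_motifs("GGGKKKKKEKKGGG", km[0, ])
  expect_true(r2$poly_k)
  expect_false(detect_rare_motifs("GGGKKKKEKKGGG", km[0, ])$poly_k)
  expect_equal(r2$poly_k_relaxed_count, 1L)

  # the metal-binding His arrangement, as in the citrus dehydrin sequence
  r3 <- detect_rare_motifs("GGHKGEHHSGDHHGG", km[0, ])
  expect_true(r3$hh_x3_hh)
  expect_false(detect_rare_motifs("GGHKGEHHSGEHHGG", km[0, ])$hh_x3_hh)

  # HH counting is non-overlapping: HHH counts once, HHHH twice
  expect_equal(detect_rare_motifs("GHHHG", km[0, ])$hh_count, 1L)
  expect_equal(detect_rare_motifs("GHHHHG", km[0, ])$hh_count, 2L)
  expect_true(detect_rare_motifs("HHGHHGHHGHH", km[0, ])$hh_rich)
  expect_false(detect_rare_motifs("HHGHHGHH", km[0, ])$hh_rich)
})

test_that("type distribution percentages sum to 100 within each group", {
  prof <- data.frame(
    accession = sprintf("A%02d", 1:14),
    group = rep(c("GYMNOSPERM_TREE", "ANGIOSPERM_VINE"), c(10L, 4L)),
    arch_type = c(rep("FSKn", 10L), rep("YnSKn", 3L), "SKn"),
    stringsAsFactors = FALSE)
  dist <- type_distribution(prof)
  gym <- dist[dist$group == "GYMNOSPERM_TREE", ]
  expect_equal(gym$percent[gym$arch_type == "FSKn"], 100)
  # disjoint types across groups give zero off-diagonal cells
  expect_equal(gym$percent[gym$arch_type == "YnSKn"], 0)
  sums <- tapply(dist$percent, dist$group, sum)
  expect_true(all(abs(sums - 100) < 0.1))
})

test_that("planted architecture equals classified architecture on a cohort", {
  spec <- cohort_spec(n = c(GYMNOSPERM_TREE = 40L,
                            ANGIOSPERM_TREE_SHRUB = 60L,
                            ANGIOSPERM_VINE = 40L), seed = 404)
  coh <- synth_cohort(spec)
  matches <- scan_proteins(coh$records)
  prof <- architecture_profiles(coh$records, matches)
  merged <- merge(prof[, c("accession", "arch_type")], coh$assignments,
                  by = "accession")
  expect_gte(mean(merged$arch_type.x == merged$arch_type.y), 0.99)
})
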