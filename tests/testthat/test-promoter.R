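test_that("catalog loading validates names, categories and IUPAC letters", {
  catalog <- load_catalog()
  expect_s3_class(catalog, "cis_catalog")
  expect_true("G-box" %in% catalog$name)
  expect_false(anyDuplicated(catalog$name) > 0)

  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tcategory\tconsensus", "G-box\tLIGHT\tCACGTG"), tmp)
  one <- load_catalog(tmp)
  expect_equal(nrow(one), 1L)
  expect_equal(one$consensus[[1L]], "CACGTG")

  writeLines(c("name\tcategory\tconsensus", "bad\tLIGHT\tCACJTG"), tmp)
  expect_error(load_catalog(tmp), "non-IUPAC letter 'J'")

  writeLines(c("name\tcategory\tconsensus", "A\tLIGHT\tCACGTG",
               "A\tSTRESS\tTTGACC"), tmp)
  expect_error(load_catalog(tmp), "duplicate")

  writeLines("name\tcategory\tconsensus", tmp)
  expect_warning(empty <- load_catalog(tmp), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("planted elements are recovered on the correct strand", {
  catalog <- load_catalog()
  plan <- data.frame(element = c("G-box", "LTR", "ABRE"),
                     start = c(412L, 900L, 100L),
                     strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  p <- synth_promoter(2000L, plan, catalog, seed = 5)
  hits <- scan_promoter(p$record, catalog)
  for (i in seq_len(nrow(p$truth))) {
    t <- p$truth[i, ]
    found <- hits[hits$element == t$element & hits$start == t$start &
                    hits$end == t$end & hits$strand == t$strand, ]
    expect_equal(nrow(found), 1L, label = t$element)
  }
  # the matched forward slice reverse-complements to the consensus for '-'
  minus <- hits[hits$element == "ABRE" & hits$strand == "-" &
                  hits$start == 100L, ]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(minus$matched_seq)))
  expect_equal(rc, "ACGTG")
})

test_that("N in the promoter matches nothing", {
  catalog <- load_catalog()
  expect_equal(nrow(scan_promoter(strrep("N", 300L), catalog)), 0L)
  # an N inside an otherwise perfect site kills that hit
  s <- paste0(strrep("T", 50L), "CACNTG", strrep("T", 50L))
  h <- scan_promoter(s, catalog)
  expect_false(any(h$element == "G-box"))
})

test_that("palindromic consensi give paired strand hits but count once", {
  catalog <- load_catalog()
  s <- paste0(strrep("T", 40L), "CACGTG", strrep("T", 40L))
  h <- scan_promoter(s, catalog)
  gbox <- h[h$element == "G-box", ]
  expect_equal(nrow(gbox), 2L)
  expect_setequal(gbox$strand, c("+", "-"))
  expect_equal(unique(gbox$start), 40L)
  prom <- data.frame(gene_id = "p1", species = "", sequence = s,
                     stringsAsFactors = FALSE)
  freq <- presence_frequency(h, prom, catalog)
  expect_equal(freq$promoters_with_hit[freq$element == "G-box"], 1L)
  expect_equal(freq$percent[freq$element == "G-box"], 100)
})

test_that("the frequency profile is invariant to reverse-complementation", {
  catalog <- load_catalog()
  set.seed(19)
  proms <- do.call(rbind, lapply(1:8, function(i) {
    plan <- data.frame(
      element = sample(catalog$name, 3L),
      start = c(100L, 600L, 1200L),
      strand = sample(c("+", "-"), 3L, replace = TRUE))
    synth_promoter(1500L, plan, catalog, gene_id = paste0("p", i))$record
  }))
  f1 <- presence_frequency(scan_promoters(proms, catalog), proms, catalog)
  rc <- proms
  rc$sequence <- vapply(proms$sequence, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1L))
  f2 <- presence_frequency(scan_promoters(rc, catalog), rc, catalog)
  expect_equal(f1, f2)
})

test_that("presence frequency equals the planting incidence matrix", {
  catalog <- load_catalog()
  # long consensi (10+ bases), so chance background occurrences are
  # vanishingly unlikely and presence must equal the planting plan
  elements <- c("SARE", "TC-rich repeats")
  incidence <- matrix(FALSE, nrow = 10L, ncol = length(elements),
                      dimnames = list(NULL, elements))
  set.seed(27)
  proms <- list()
  for (i in 1:10) {
    planted <- elements[runif(length(elements)) < 0.5]
    incidence[i, planted] <- TRUE
    plan <- if (length(planted)) {
      data.frame(element = planted,
                 start = seq(50L, by = 300L, length.out = length(planted)),
                 strand = sample(c("+", "-"), length(planted),
                                 replace = TRUE))
    } else {
      data.frame(element = character(0), start = integer(0),
                 strand = character(0))
    }
    proms[[i]] <- synth_promoter(1000L, plan, catalog,
                                 gene_id = paste0("p", i))$record
  }
  proms <- do.call(rbind, proms)
  freq <- presence_frequency(scan_promoters(proms, catalog), proms, catalog)
  for (e in elements) {
    expect_equal(freq$promoters_with_hit[freq$element == e],
                 sum(incidence[, e]), label = e)
    expect_equal(freq$percent[freq$element == e],
                 round(100 * sum(incidence[, e]) / 10L, 1L), label = e)
  }
})

test_that("33 of 34 promoters with a planted element give 97.1 percent", {
  catalog <- load_catalog()
  set.seed(31)
  proms <- do.call(rbind, lapply(1:34, function(i) {
    plan <- if (i <= 33L) {
      data.frame(element = "SARE", start = 700L, strand = "+")
    } else {
      data.frame(element = character(0), start = integer(0),
                 strand = character(0))
    }
    synth_promoter(1500L, plan, catalog, gene_id = paste0("p", i))$record
  }))
  freq <- presence_frequency(scan_promoters(proms, catalog), proms, catalog)
  expect_equal(freq$percent[freq$element == "SARE"], 97.1)
})

test_that("category rollup counts hits per functional class", {
  catalog <- load_catalog()
  plan <- data.frame(element = c("G-box", "SARE", "RY-element"),
                     start = c(100L, 400L, 800L), strand = "+")
  p <- synth_promoter(1200L, plan, catalog, seed = 6)
  hits <- scan_promoter(p$record, catalog)
  roll <- category_rollup(hits, p$record, catalog)
  expect_gte(roll$LIGHT, 1L)
  expect_gte(roll$HORMONE, 1L)
  expect_gte(roll$DEVELOPMENT, 1L)
  expect_equal(roll$LIGHT + roll$HORMONE + roll$STRESS + roll$DEVELOPMENT,
               nrow(hits))
})
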