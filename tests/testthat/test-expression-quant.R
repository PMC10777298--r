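test_that("normalized expression is the ppm ratio and is scale invariant", {
  expect_equal(normalizedExpression(100, 1e6, 50, 1e6), 2.0)
  expect_equal(normalizedExpression(0, 1e6, 50, 1e6), 0.0)
  # proportional counts give exactly 1 everywhere
  nc <- c(10, 40, 200); ec <- nc * 7
  v <- normalizedExpression(ec, sum(ec), nc, sum(nc))
  expect_equal(v, rep(1, 3))
  # multiplying all expression counts by 10 changes nothing
  v10 <- normalizedExpression(ec * 10, sum(ec) * 10, nc, sum(nc))
  expect_equal(v, v10)
})

test_that("silence classification follows the threshold exactly", {
  rec <- data.frame(normalized_expression = c(0, 0.01, 5))
  out <- classifySilent(rec)
  expect_identical(out$is_silent, c(TRUE, FALSE, FALSE))
  out2 <- classifySilent(rec, silenceThreshold = 0.02)
  expect_identical(out2$is_silent, c(TRUE, TRUE, FALSE))
})

test_that("the three reliability filters retain exactly the hand-enumerated subset", {
  # ten hand-built records spanning every boundary of
  # (norm >= 5, reads_r >= 10, freq1_r > 0.60)
  fix <- data.frame(
    promoter = "mPGK",
    barcode = sprintf("BC%02d", 1:10),
    norm_count = c(5L, 5L, 4L, 100L, 5L, 20L, 4L, 50L, 5L, 12L),
    normalized_expression = 1,
    stringsAsFactors = FALSE)
  calls <- data.frame(
    promoter = "mPGK",
    barcode = sprintf("BC%02d", 1:9),     # BC10 is unmapped
    chrom = "c1", position = 1L, strand = "+",
    reads_r = c(10L, 10L, 100L, 9L, 50L, 10L, 10L, 200L, 11L),
    freq1_r = c(0.61, 0.60, 1.00, 1.00, 0.59, 0.80, 0.70, 0.605, 0.601))
  # hand enumeration: pass = BC01 (5,10,.61), BC06 (20,10,.8),
  # BC08 (50,200,.605), BC09 (5,11,.601); BC02 fails freq1 = 0.60 (strict),
  # BC03/BC07 fail norm = 4, BC04 fails reads_r = 9, BC05 fails freq1,
  # BC10 unmapped
  out <- applyTripFilters(fix, calls)
  expect_identical(out$transgenes$barcode, c("BC01", "BC06", "BC08", "BC09"))
  expect_identical(
    out$dropped$drop_reason[out$dropped$barcode == "BC10"], "unmapped")
})

test_that("duplicate insertion calls for one barcode are a hard error", {
  rec <- data.frame(promoter = "mPGK", barcode = "B", norm_count = 10L,
                    normalized_expression = 1)
  calls <- data.frame(promoter = "mPGK", barcode = c("B", "B"),
                      chrom = "c1", position = c(1L, 2L), strand = "+",
                      reads_r = 20L, freq1_r = 1)
  expect_error(applyTripFilters(rec, calls), "duplicate")
})

test_that("raising any threshold never enlarges the retained set", {
  run <- defaultRun()
  rec <- run$result$records
  calls <- run$result$calls
  base <- nrow(applyTripFilters(rec, calls)$transgenes)
  expect_gte(nrow(applyTripFilters(rec, calls, freq1Min = 0.50)$transgenes),
             base)
  expect_lte(nrow(applyTripFilters(rec, calls, normMin = 10)$transgenes),
             base)
  expect_lte(nrow(applyTripFilters(rec, calls, readsRMin = 15)$transgenes),
             base)
  expect_lte(nrow(applyTripFilters(rec, calls, freq1Min = 0.9)$transgenes),
             base)
})

test_that("promoter summary computes medians, fold ratios and the top share", {
  rec <- data.frame(
    promoter = rep(c("long_EF1a", "short_EF1a"), each = 10),
    barcode = sprintf("B%02d", 1:20),
    normalized_expression = c(seq(3.0, 5.0, length.out = 10),
                              seq(0.2, 0.6, length.out = 10)),
    is_silent = FALSE)
  s <- promoterSummary(rec, topFraction = 0.10)
  expect_identical(s$n, c(10L, 10L))
  expect_equal(s$median_expr[s$promoter == "long_EF1a"], 4.0)
  expect_equal(s$median_expr[s$promoter == "short_EF1a"], 0.4)
  expect_equal(s$fold_vs_reference[s$promoter == "short_EF1a"], 10)
  # top set size = ceiling(0.10 * 20) = 2, both from the stronger promoter
  expect_equal(s$top_decile_share[s$promoter == "long_EF1a"], 1)
  expect_equal(sum(s$top_decile_share * 2), 2)
})

test_that("per-promoter activity factors are recovered from a simulated cohort", {
  run <- defaultRun()
  tg <- run$result$transgenes
  expressed <- tg[!tg$is_silent, ]
  s <- promoterSummary(tg)
  meds <- setNames(s$median_expr, s$promoter)
  # generator factors are (10, 1, 0.5, 0.3) for long/short/mPGK/PGK;
  # compare recovered median ratios to the true ratios on the log scale
  truthRatio <- c(short_EF1a = 1 / 10, mPGK = 0.5 / 10, PGK = 0.3 / 10)
  for (p in names(truthRatio)) {
    if (is.na(meds[p]) || s$n_expressed[s$promoter == p] < 5) next
    got <- meds[[p]] / meds[["long_EF1a"]]
    expect_lt(abs(log2(got / truthRatio[[p]])), log2(3),
              label = paste("median ratio for", p))
  }
})

test_that("true and measured activities agree in rank on the default run", {
  run <- defaultRun()
  tg <- run$result$transgenes
  m <- merge(tg[!tg$is_silent, ], run$truth, by = "barcode")
  rho <- cor(m$true_activity, m$normalized_expression, method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("equal activities calibrate to median normalized expression 1", {
  g <- fixture("nullGenome", function()
    makeGenome(c(chr1 = 100000L, chr2 = 100000L), seed = 41L))
  tr <- plantInsertions(g, 300, silentFraction = 0,
                        promoterFactors = c(long_EF1a = 1, short_EF1a = 1,
                                            mPGK = 1, PGK = 1),
                        chromatinFactors = setNames(
                          rep(1, 11), choChromatinStates()$state),
                        activitySdlog = 0, seed = 42L)
  d <- tempfile()
  simulateLibraries(tr, g, d, errorRate = 0, seed = 43L)
  norm <- processLibrary(file.path(d, "normalization.fastq"),
                         readLayout("normalization"))
  expr <- processLibrary(file.path(d, "expression.fastq"),
                         readLayout("expression"))
  rec <- classifySilent(buildExpressionRecords(norm$table, expr$table)$records)
  rec <- rec[rec$norm_count >= 5, ]
  for (p in unique(rec$promoter)) {
    sub <- rec[rec$promoter == p & !rec$is_silent, ]
    if (nrow(sub) < 10) next
    expect_lt(abs(median(sub$normalized_expression) - 1), 0.1,
              label = paste("null median for", p))
  }
})
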