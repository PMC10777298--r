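lay <- readLayout("normalization")
bc18 <- strrep("ACGTAC", 3)

test_that("index and barcode are cut out at the expected offsets", {
  rd <- paste0(lay$constantPrefix, "TACAA", bc18)
  out <- extractIndexBarcode(rd, lay)
  expect_identical(out$index, "TACAA")
  expect_identical(out$barcode, bc18)
  expect_identical(out$reason, "ok")

  # one substitution inside the prefix is tolerated at anchorMismatch = 1
  mut <- rd
  substr(mut, 3, 3) <- if (substr(mut, 3, 3) == "A") "C" else "A"
  expect_identical(extractIndexBarcode(mut, lay, anchorMismatch = 1)$reason,
                   "ok")
  expect_identical(extractIndexBarcode(mut, lay, anchorMismatch = 0)$reason,
                   "anchor_not_found")

  # 17-nt barcode field: too short
  short <- paste0(lay$constantPrefix, "TACAA", substr(bc18, 1, 17))
  expect_identical(extractIndexBarcode(short, lay)$reason, "too_short")

  # N inside the barcode
  amb <- paste0(lay$constantPrefix, "TACAA", sub("A", "N", bc18))
  expect_identical(extractIndexBarcode(amb, lay)$reason,
                   "ambiguous_base_in_barcode")
})

test_that("demultiplexing assigns each index and its 1-neighbours uniquely", {
  expect_identical(demultiplexIndex("TACAA"), "short_EF1a")
  expect_identical(demultiplexIndex("TACGA"), "short_EF1a")
  expect_identical(demultiplexIndex("NNNNN"), "unassigned")
  # brute force: every 1-mismatch neighbour of every index must come back
  # to its own promoter (pairwise distances are >= 4)
  tab <- promoterIndexTable()
  for (r in seq_len(nrow(tab))) {
    idx <- tab$index[r]
    for (j in 1:5) for (b in c("A", "C", "G", "T")) {
      mut <- idx; substr(mut, j, j) <- b
      expect_identical(demultiplexIndex(mut), tab$promoter[r])
    }
  }
})

test_that("a table violating the separation invariant is a configuration error", {
  bad <- data.frame(index = c("AAAAA", "AAAAT"), promoter = c("p1", "p2"))
  expect_error(demultiplexIndex("AAAAA", bad, maxMismatch = 1),
               "Hamming distance")
  expect_silent(validateIndexTable(bad, maxMismatch = 0))
})

test_that("counting is exact and conserves every read", {
  tab <- countBarcodes("norm",
                       c("p1", "p1", "p1", "unassigned", "p2"),
                       c("B1", "B1", "B1", "B2", NA))
  cnt <- as.data.frame(tab$counts)
  expect_identical(cnt$count[cnt$barcode == "B1"], 3L)
  expect_identical(unname(tab$tallies),
                   c(5L, 3L, 1L, 1L))
  expect_identical(sum(tab$tallies[c("assigned", "unassigned", "malformed")]),
                   unname(tab$tallies["processed"]))

  empty <- countBarcodes("norm", character(0), character(0))
  expect_identical(nrow(empty$counts), 0L)
  expect_true(all(empty$tallies == 0))
})

test_that("read accounting on a simulated library matches an independent recount", {
  run <- defaultRun()
  f <- file.path(run$config$outdir, "sim", "normalization.fastq")
  lay <- readLayout("normalization")
  reads <- as.character(Biostrings::readDNAStringSet(f, format = "fastq"))
  ext <- extractIndexBarcode(reads, lay)
  prom <- rep("unassigned", nrow(ext))
  prom[!is.na(ext$index)] <- demultiplexIndex(ext$index[!is.na(ext$index)])
  tab <- countBarcodes("normalization", prom, ext$barcode)
  expect_identical(unname(tab$tallies["processed"]), length(reads))
  expect_identical(sum(as.data.frame(tab$counts)$count),
                   unname(tab$tallies[["assigned"]]))
  expect_identical(sum(tab$tallies[c("assigned", "unassigned", "malformed")]),
                   unname(tab$tallies["processed"]))
})

test_that("rare near-duplicates collapse and the boundary rules hold", {
  b1 <- strrep("A", 18)
  b2 <- paste0(strrep("A", 17), "T")                    # distance 1
  tab <- countTableFrom(setNames(c(1000L, 5L), c(b1, b2)))
  out <- collapseMutants(tab)
  cnt <- as.data.frame(out$table$counts)
  expect_identical(nrow(cnt), 1L)
  expect_identical(cnt$barcode, b1)
  expect_identical(cnt$count, 1005L)
  expect_identical(out$map$genuine[out$map$barcode == b2], b1)

  # far apart: both kept whatever the counts
  b3 <- paste0(strrep("C", 10), strrep("A", 8))          # distance 10 to b1
  tab2 <- countTableFrom(setNames(c(1000L, 900L), c(b1, b3)))
  expect_identical(nrow(as.data.frame(collapseMutants(tab2)$table$counts)), 2L)

  # ratio rule: 60 >= 0.1 * 100, so both kept even at distance 1
  tab3 <- countTableFrom(setNames(c(100L, 60L), c(b1, b2)))
  expect_identical(nrow(as.data.frame(collapseMutants(tab3)$table$counts)), 2L)
})

test_that("greedy collapse agrees with the brute-force oracle on random tables", {
  for (s in 1:20) {
    set.seed(s)
    m <- sample(5:50, 1)
    # a few genuine barcodes plus mutant clouds around them
    genuine <- sampleBarcodesForTest(max(2, m %/% 5), seed = s)
    bcs <- character(0); cnts <- integer(0)
    for (g in genuine) {
      bcs <- c(bcs, g); cnts <- c(cnts, sample(200:2000, 1))
    }
    while (length(bcs) < m) {
      src <- sample(genuine, 1)
      nmut <- sample(1:3, 1)
      mut <- src
      for (k in sample(1:18, nmut))
        substr(mut, k, k) <- sample(c("A", "C", "G", "T"), 1)
      if (!mut %in% bcs) { bcs <- c(bcs, mut); cnts <- c(cnts, sample(1:40, 1)) }
    }
    tab <- countTableFrom(setNames(cnts, bcs))
    got <- as.data.frame(collapseMutants(tab)$table$counts)
    want <- oracleCollapse(bcs, cnts)
    expect_setequal(got$barcode, want$barcode)
    expect_identical(got$count[order(got$barcode)],
                     as.integer(want$count[order(want$barcode)]))
  }
})

test_that("collapsing conserves reads and the map is idempotent", {
  run <- defaultRun()
  pl <- processLibrary(file.path(run$config$outdir, "sim",
                                 "normalization.fastq"),
                       readLayout("normalization"))
  expect_identical(sum(as.data.frame(pl$raw$counts)$count),
                   sum(as.data.frame(pl$table$counts)$count))
  # idempotence: genuine barcodes map to themselves
  m <- pl$map
  again <- m$genuine[match(m$genuine, m$barcode)]
  expect_identical(again, m$genuine)
  # genuine barcodes never map elsewhere
  expect_true(all(m$genuine[m$barcode %in% m$genuine] ==
                    m$barcode[m$barcode %in% m$genuine]))
})

test_that("collapse is the identity on an error-free library", {
  run <- errorFreeRun()
  pl <- processLibrary(file.path(run$config$outdir, "sim",
                                 "normalization.fastq"),
                       readLayout("normalization"))
  expect_identical(as.data.frame(pl$raw$counts),
                   as.data.frame(pl$table$counts))
  expect_true(all(pl$map$barcode == pl$map$genuine))
})

test_that("nearly all reads reach their true barcode after collapsing", {
  # substitution rate 0.005 with truth barcodes >= 5 apart
  g <- smallGenome()
  tr <- plantInsertions(g, 80, seed = 31L)
  d <- tempfile()
  sim <- simulateLibraries(tr, g, d, errorRate = 0.005, seed = 32L)
  pl <- processLibrary(file.path(d, "normalization.fastq"),
                       readLayout("normalization"))
  cnt <- as.data.frame(pl$table$counts)
  truthKey <- paste(tr$promoter_class, tr$barcode)
  tab <- promoterIndexTable()
  gotKey <- paste(cnt$promoter, cnt$barcode)
  assignedTrue <- sum(cnt$count[gotKey %in% truthKey])
  expect_gte(assignedTrue / sim$log$reads[["normalization"]], 0.99)
})
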