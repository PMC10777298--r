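# a small hand-built annotation: two genes on opposite strands
handGff <- function() {
  gr <- GenomicRanges::GRanges(
    c("chrT", "chrT", "chrT", "chrT", "chrT", "chrT", "chrT",
      "chrT", "chrT", "chrT"),
    IRanges::IRanges(
      start = c(5000, 5000, 5000, 6000, 5000, 5200, 6800,
                20000, 20000, 20000),
      end   = c(7000, 7000, 5500, 7000, 5150, 5500, 7000,
                24000, 24000, 24000)),
    strand = c("+", "+", "+", "+", "+", "+", "+", "-", "-", "-"),
    type = c("gene", "mRNA", "exon", "exon", "CDS", "CDS", "CDS",
             "gene", "mRNA", "exon"),
    ID = c("gA", "gA.t1", NA, NA, NA, NA, NA, "gB", "gB.t1", NA),
    Parent = c(NA, "gA", "gA.t1", "gA.t1", "gA.t1", "gA.t1", "gA.t1",
               NA, "gB", "gB.t1"))
  gr
}

test_that("the promoter window is -1000..+100 around the TSS, strand aware", {
  idx <- buildElementIndex(handGff())
  el <- idx$elements
  promA <- el[S4Vectors::mcols(el)$feature == "promoter" &
                S4Vectors::mcols(el)$gene_id == "gA"]
  expect_identical(BiocGenerics::start(promA), 4000L)
  expect_identical(BiocGenerics::end(promA), 5100L)
  expect_identical(BiocGenerics::width(promA), 1101L)
  # minus-strand gene: window upstream means larger coordinates
  promB <- el[S4Vectors::mcols(el)$feature == "promoter" &
                S4Vectors::mcols(el)$gene_id == "gB"]
  expect_identical(BiocGenerics::start(promB), 23900L)
  expect_identical(BiocGenerics::end(promB), 25000L)
})

test_that("a single-exon gene whose CDS spans the exon has no UTRs or introns", {
  gr <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(1000, 1000, 1000, 1000),
                             c(2000, 2000, 2000, 2000)),
    strand = "+",
    type = c("gene", "mRNA", "exon", "CDS"),
    ID = c("gS", "gS.t1", NA, NA),
    Parent = c(NA, "gS", "gS.t1", "gS.t1"))
  idx <- buildElementIndex(gr)
  feats <- S4Vectors::mcols(idx$elements)$feature
  expect_false(any(feats %in% c("utr5", "utr3", "intron")))
  expect_identical(sort(unique(feats)), c("exon", "promoter"))
})

test_that("element priority resolves overlaps: promoter beats intron", {
  # position inside gA's intron (5501..5999) and inside a promoter window
  # of a gene starting at 6200
  gr <- c(handGff(), GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(6200, 6200, 6200), c(9000, 9000, 9000)),
    strand = "+", type = c("gene", "mRNA", "exon"),
    ID = c("gC", "gC.t1", NA), Parent = c(NA, "gC", "gC.t1")))
  idx <- buildElementIndex(gr)
  got <- classifyElement("chrT", 5700L, idx)
  expect_identical(got$element, "promoter")
  expect_identical(got$gene_id, "gC")
})

test_that("positions far from genes are intergenic; TSS + 50 is promoter", {
  idx <- buildElementIndex(handGff())
  far <- classifyElement("chrT", 15000L, idx)
  expect_identical(far$element, "intergenic")
  expect_true(is.na(far$gene_id))
  expect_identical(classifyElement("chrT", 5050L, idx)$element, "promoter")
})

test_that("classification matches per-base brute-force labeling on random loci", {
  g <- smallGenome()
  files <- writeGenome(g, tempfile())
  idx <- buildElementIndex(files$gff3)
  set.seed(20)
  chroms <- names(genomeSequences(g))
  pos <- sample.int(30000L, 1000L, replace = TRUE)
  chr <- sample(chroms, 1000L, replace = TRUE)
  got <- classifyElement(chr, pos, idx)$element
  want <- vapply(seq_len(1000L), function(i)
    oracleClassify(pos[i], chr[i], idx), character(1))
  expect_identical(got, want)
})

test_that("element proportions over a cohort partition to 1", {
  run <- defaultRun()
  ann <- run$result$annotated
  enr <- run$result$report$enrichment
  el <- enr[enr$category_type == "element", ]
  expect_equal(sum(el$prop_all), 1)
  expect_equal(sum(el$prop_top), 1)
  ch <- enr[enr$category_type == "chromatin", ]
  expect_equal(sum(ch$prop_all), 1)
})

test_that("TSS/TTS distances equal a brute-force all-genes scan", {
  g <- smallGenome()
  files <- writeGenome(g, tempfile())
  idx <- buildElementIndex(files$gff3)
  expect_identical(
    nearestDistances("chrA", idx$genes$tss[idx$genes$chrom == "chrA"][1],
                     idx)$dist_tss, 0)
  set.seed(21)
  pos <- sample.int(30000L, 200L, replace = TRUE)
  d <- nearestDistances(rep("chrA", 200), pos, idx)
  gA <- idx$genes[idx$genes$chrom == "chrA", ]
  for (i in seq_len(200)) {
    expect_equal(d$dist_tss[i], min(abs(pos[i] - gA$tss)))
    expect_equal(d$dist_tts[i], min(abs(pos[i] - gA$tts)))
  }
})

test_that("distance to the nearer of two TSSs is picked", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "c",
                      strand = c("+", "+"),
                      tss = c(7000L, 18000L), tts = c(9000L, 20000L))
  d <- nearestDistances("c", 10000L, genes)
  expect_equal(d$dist_tss, 3000)
  expect_equal(d$dist_tts, 1000)
})

test_that("chromatin overlap honours BED conventions and gaps", {
  bedPath <- tempfile(fileext = ".bed")
  writeLines(c("chrQ\t0\t1000\tStrong transcription (H3K36me3)",
               "chrQ\t1000\t2000\tQuiescent/low"), bedPath)
  # 1-based position 1000 is the last base of the first (0-based
  # half-open) segment; 1001 starts the next
  expect_identical(chromatinOverlap("chrQ", 1000L, bedPath),
                   "Strong transcription (H3K36me3)")
  expect_identical(chromatinOverlap("chrQ", 1001L, bedPath),
                   "Quiescent/low")
  expect_identical(chromatinOverlap("chrZ", 100L, bedPath), "unassigned")
  expect_identical(chromatinOverlap("chrQ", 2500L, bedPath), "unassigned")

  seg <- GenomicRanges::GRanges(
    "c", IRanges::IRanges(c(1, 50), c(100, 160)), state = c("a", "b"))
  expect_error(chromatinOverlap("c", 60L, seg), "overlap")
})

test_that("chromatin assignment returns exactly one label per locus", {
  run <- defaultRun()
  ann <- run$result$annotated
  expect_true(all(!is.na(ann$chromatin_type)))
  expect_true(all(ann$chromatin_type %in%
                    c(choChromatinStates()$state, "unassigned")))
})

test_that("enrichment ratios are top-vs-all proportions", {
  ann <- data.frame(
    element = rep(c("intron", "promoter"), c(90, 10)),
    chromatin_type = "Quiescent/low",
    normalized_expression = c(rep(1, 84), rep(10, 16)),
    barcode = sprintf("B%03d", 1:100))
  # top decile (10 records) drawn from the high-activity tail, which is
  # 6 introns + 10 promoters; ties on activity resolved by barcode
  enr <- enrichmentReport(ann, topFraction = 0.10)
  pr <- enr[enr$category == "promoter", ]
  expect_equal(pr$prop_all, 0.10)
  got <- pr$prop_top / pr$prop_all
  expect_equal(got, pr$ratio)
  expect_error(enrichmentReport(ann[0, , drop = FALSE]), "no transgenes")
})

test_that("an activity-boosted chromatin state enriches among top transgenes", {
  run <- defaultRun()
  enr <- run$result$report$enrichment
  boosted <- enr[enr$category_type == "chromatin" &
                   enr$category == "Strong transcription (H3K36me3)", ]
  if (nrow(boosted) == 1 && boosted$prop_all > 0) {
    expect_gt(boosted$ratio, 1)
  } else {
    succeed("boosted state absent from this cohort")
  }
})

test_that("mirrored genomes give mirrored element classifications", {
  g <- smallGenome()
  files <- writeGenome(g, tempfile())
  idx <- buildElementIndex(files$gff3)
  # flip annotations to the reverse-complemented coordinate system
  gr <- rtracklayer::import(files$gff3, format = "gff3")
  L <- stats::setNames(Biostrings::width(genomeSequences(g)),
                       names(genomeSequences(g)))
  chr <- as.character(GenomicRanges::seqnames(gr))
  newStart <- L[chr] - BiocGenerics::end(gr) + 1L
  newEnd <- L[chr] - BiocGenerics::start(gr) + 1L
  flipped <- GenomicRanges::GRanges(
    chr, IRanges::IRanges(unname(newStart), unname(newEnd)),
    strand = ifelse(as.character(BiocGenerics::strand(gr)) == "+", "-", "+"),
    type = S4Vectors::mcols(gr)$type,
    ID = S4Vectors::mcols(gr)$ID,
    Parent = S4Vectors::mcols(gr)$Parent)
  idxM <- buildElementIndex(flipped)
  set.seed(31)
  pos <- sample.int(29000L, 300L) + 500L
  chrq <- sample(names(L), 300L, replace = TRUE)
  a <- classifyElement(chrq, pos, idx)
  b <- classifyElement(chrq, L[chrq] - pos + 1L, idxM)
  expect_identical(a$element, b$element)
})
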