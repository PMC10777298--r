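# Shared fixtures, built once per test run and cached.  All synthetic
# data is generated in code at fixed seeds; nothing is read from disk
# except files the fixtures themselves write.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small genome for unit tests
smallGenome <- function() {
  fixture("smallGenome", function() makeGenome(
    c(chrA = 30000L, chrB = 30000L), gc = 0.45, seed = 11L))
}

# the default study-scale run: 300 insertions on a 2 x 200 kb genome,
# 7:7:7:1 promoter mix, half the insertions silent, mean depths 50/50/20,
# substitution error rate 0.002
defaultRun <- function() {
  fixture("defaultRun", function() {
    cfg <- tripConfig(outdir = file.path(tempdir(), "tripkit_default_run"),
                      seed = 1L)
    res <- runPipeline(cfg)
    truth <- read.delim(file.path(cfg$outdir, "sim", "truth.tsv"),
                        stringsAsFactors = FALSE)
    list(config = cfg, result = res, truth = truth)
  })
}

# an error-free run used by the motif / round-trip checks
errorFreeRun <- function() {
  fixture("errorFreeRun", function() {
    cfg <- tripConfig(outdir = file.path(tempdir(), "tripkit_ef_run"),
                      seed = 5L,
                      chromSizes = c(chr1 = 100000L, chr2 = 100000L),
                      nInsertions = 150L,
                      depths = c(normalization = 30, expression = 30,
                                 mapping = 25),
                      errorRate = 0)
    res <- runPipeline(cfg)
    truth <- read.delim(file.path(cfg$outdir, "sim", "truth.tsv"),
                        stringsAsFactors = FALSE)
    list(config = cfg, result = res, truth = truth)
  })
}

# build a BarcodeCountTable directly from named counts (one stratum)
countTableFrom <- function(counts, promoter = "long_EF1a",
                           library = "normalization") {
  countBarcodes(library,
                rep(promoter, sum(counts)),
                rep(names(counts), counts))
}

# well-separated random barcodes for collapse tests
sampleBarcodesForTest <- function(n, seed) {
  set.seed(seed)
  tripkit:::sampleBarcodes(n)
}

# ---- independent oracles -------------------------------------------------

# brute-force greedy collapse reimplemented from the rule statement:
# full distance matrix first, then a sequential scan in (count desc,
# barcode asc) order merging into the earliest genuine barcode at
# distance <= maxDistance with count < ratio * its raw count
oracleCollapse <- function(barcodes, counts, maxDistance = 2L,
                           ratio = 0.1) {
  o <- order(-counts, barcodes)
  b <- barcodes[o]; cnt <- counts[o]
  m <- length(b)
  D <- outer(seq_len(m), seq_len(m), Vectorize(function(i, j)
    sum(utf8ToInt(b[i]) != utf8ToInt(b[j]))))
  genuine <- rep(TRUE, m); tgt <- seq_len(m)
  for (i in seq_len(m)[-1]) {
    for (j in seq_len(i - 1L)) {
      if (genuine[j] && D[i, j] <= maxDistance && cnt[i] < ratio * cnt[j]) {
        genuine[i] <- FALSE; tgt[i] <- j; break
      }
    }
  }
  total <- vapply(seq_len(m), function(i) sum(cnt[tgt == i]), numeric(1))
  data.frame(barcode = b[genuine], count = total[genuine],
             stringsAsFactors = FALSE)
}

# per-base brute-force element labeling of a single position
oracleClassify <- function(pos, chrom, idx,
                           priority = c("promoter", "utr5", "utr3",
                                        "exon", "intron")) {
  el <- idx$elements
  hit <- as.character(GenomicRanges::seqnames(el)) == chrom &
    BiocGenerics::start(el) <= pos & BiocGenerics::end(el) >= pos
  if (!any(hit)) return("intergenic")
  labs <- S4Vectors::mcols(el)$feature[hit]
  priority[min(match(labs, priority))]
}

# exact binomial tail by direct summation (n small)
oracleBinomLogOdds <- function(k, n, p) {
  if (k / n >= p) {
    -log10(sum(dbinom(k:n, n, p)))
  } else {
    log10(sum(dbinom(0:k, n, p)))
  }
}
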