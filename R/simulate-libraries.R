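# constant pad appended after the informative part of a simulated read,
# mimicking read-through into adapter sequence
.padSequence <- "CTGTCTCTTATACACATCTCCGAGCCCACGAGACGGCACTGAGGTTCAGAGTTC"

.padTo <- function(x, len) {
  pad <- strrep(.padSequence, ceiling(len / nchar(.padSequence)))
  out <- paste0(x, substring(pad, 1L, pmax(0L, len - nchar(x))))
  substring(out, 1L, len)
}

#' Genomic flank of an insertion, bounded by the first downstream GATC
#'
#' Returns the sequence an inverse-PCR mapping read would carry for one
#' insertion: starting at the first base past the TTAA target site and
#' read in the direction of the transgene's orientation (reverse-
#' complemented for minus-strand insertions), truncated at the first GATC
#' encountered; the 4 bases of the DpnII site are retained at the flank
#' end.  If no GATC occurs within `maxLen` bases (or before the
#' chromosome end), the untruncated stretch is returned.
#'
#' @param genome a [SyntheticGenome-class] (or a `DNAStringSet`).
#' @param chrom,position,strand insertion locus; `position` is the 1-based
#'   coordinate of the first T of the TTAA on the plus strand.
#' @param maxLen maximum flank length scanned for a GATC.
#' @return a single flank string (possibly empty at a chromosome edge).
#' @export
insertionFlank <- function(genome, chrom, position, strand, maxLen = 2000L) {
  seqs <- if (is(genome, "SyntheticGenome")) genome@sequences else genome
  L <- width(seqs[chrom])
  if (strand == "+") {
    from <- position + 4L
    if (from > L) return("")
    region <- as.character(subseq(seqs[[chrom]], from,
                                  min(L, from + maxLen - 1L)))
  } else {
    to <- position - 1L
    if (to < 1L) return("")
    region <- revcomp(as.character(subseq(seqs[[chrom]],
                                          max(1L, to - maxLen + 1L), to)))
  }
  hit <- regexpr("GATC", region, fixed = TRUE)
  if (hit > 0L) substr(region, 1L, hit + 3L) else region
}

# i.i.d. per-base substitution errors over a vector of equal-length reads
injectErrors <- function(reads, errorRate) {
  if (errorRate <= 0 || length(reads) == 0L) return(reads)
  L <- nchar(reads[1L])
  tot <- length(reads) * L
  err <- which(runif(tot) < errorRate)
  if (length(err) == 0L) return(reads)
  ri <- (err - 1L) %/% L + 1L
  pj <- (err - 1L) %% L + 1L
  bases <- c("A", "C", "G", "T")
  for (e in seq_along(err)) {
    cur <- substr(reads[ri[e]], pj[e], pj[e])
    substr(reads[ri[e]], pj[e], pj[e]) <- sample(setdiff(bases, cur), 1L)
  }
  reads
}

.writeFastq <- function(reads, ids, path) {
  if (length(reads) == 0L) {
    writeLines(character(0), path)
    return(path)
  }
  x <- DNAStringSet(reads)
  names(x) <- ids
  quals <- BStringSet(rep(strrep("I", nchar(reads[1L])), length(reads)))
  writeXStringSet(x, path, format = "fastq", qualities = quals)
  path
}

#' Simulate the three TRIP FASTQ libraries from ground-truth insertions
#'
#' Emits normalization, expression and mapping reads for a truth set:
#' per-insertion read counts are Poisson with mean proportional to clone
#' abundance (normalization, mapping) or clone abundance x true activity
#' (expression), scaled so the population mean matches the requested
#' depth.  Reads follow the [readLayout()] structures; mapping reads carry
#' the GATC-bounded genomic flank (paired: R1 = index + barcode side,
#' R2 = flank).  Substitution errors are applied i.i.d. per base; quality
#' strings are constant.  A truth TSV is written alongside, with a
#' `short_flank` flag for insertions whose flank is shorter than
#' `minFlank` (a GATC too close to the transposon end).
#'
#' @param truth data.frame from [plantInsertions()].
#' @param genome the [SyntheticGenome-class] the truth was planted in.
#' @param outdir output directory.
#' @param layouts list of [readLayout()]s per library kind.
#' @param depths named mean reads per insertion,
#'   `c(normalization=, expression=, mapping=)`.
#' @param errorRate per-base substitution probability (< 0.05).
#' @param minFlank flank length below which the truth record is flagged
#'   `short_flank` (default 20, the aligner seed length).
#' @param seed integer RNG seed; output is byte-identical for a fixed
#'   (truth, arguments, seed).
#' @return invisibly, a list: `files` (FASTQ/TSV paths), `truth` (with
#'   `flank`, `flank_length`, `short_flank` columns), `log` (reads
#'   emitted per library).
#' @export
simulateLibraries <- function(truth, genome, outdir,
                              layouts = defaultLayouts(),
                              depths = c(normalization = 50,
                                         expression = 50, mapping = 20),
                              errorRate = 0.002,
                              minFlank = 20L,
                              seed = 1L) {
  stopifnot(errorRate >= 0, errorRate < 0.05, all(depths > 0))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  n <- nrow(truth)

  truth$flank <- vapply(seq_len(n), function(i)
    insertionFlank(genome, truth$chrom[i], truth$position[i],
                   truth$strand[i]), character(1))
  truth$flank_length <- nchar(truth$flank)
  truth$short_flank <- truth$flank_length < minFlank

  ab <- truth$clone_abundance
  lamNorm <- depths[["normalization"]] * ab / mean(ab)
  w <- ab * truth$true_activity
  lamExpr <- if (mean(w) > 0) depths[["expression"]] * w / mean(w) else
    rep(0, n)
  lamMap <- depths[["mapping"]] * ab / mean(ab)

  cNorm <- rpois(n, lamNorm)
  cExpr <- rpois(n, lamExpr)
  cMap <- rpois(n, lamMap)

  mkCore <- function(layout, idx) {
    paste0(layout$constantPrefix, truth$promoter_index[idx],
           truth$barcode[idx])
  }
  files <- list()

  layN <- layouts$normalization
  iN <- rep(seq_len(n), cNorm)
  rN <- injectErrors(.padTo(mkCore(layN, iN), layN$readLength), errorRate)
  files$normalization <- .writeFastq(
    rN, sprintf("norm_%06d", seq_along(rN)),
    file.path(outdir, "normalization.fastq"))

  layE <- layouts$expression
  iE <- rep(seq_len(n), cExpr)
  rE <- injectErrors(.padTo(mkCore(layE, iE), layE$readLength), errorRate)
  files$expression <- .writeFastq(
    rE, sprintf("expr_%06d", seq_along(rE)),
    file.path(outdir, "expression.fastq"))

  layM <- layouts$mapping
  iM <- rep(seq_len(n), cMap)
  if (layM$paired) {
    r1 <- injectErrors(.padTo(mkCore(layM, iM), layM$readLength), errorRate)
    r2 <- injectErrors(.padTo(paste0(layM$transposonAnchor, truth$flank[iM]),
                              layM$readLength), errorRate)
    ids <- sprintf("map_%06d", seq_along(iM))
    files$mapping_R1 <- .writeFastq(r1, ids,
                                    file.path(outdir, "mapping_R1.fastq"))
    files$mapping_R2 <- .writeFastq(r2, ids,
                                    file.path(outdir, "mapping_R2.fastq"))
  } else {
    rM <- injectErrors(.padTo(paste0(mkCore(layM, iM), layM$transposonAnchor,
                                     truth$flank[iM]), layM$readLength),
                       errorRate)
    files$mapping <- .writeFastq(rM, sprintf("map_%06d", seq_along(iM)),
                                 file.path(outdir, "mapping.fastq"))
  }

  truthPath <- file.path(outdir, "truth.tsv")
  writeTsv(truth[, c("barcode", "promoter_class", "promoter_index", "chrom",
                     "position", "strand", "true_activity",
                     "clone_abundance", "short_flank")], truthPath)
  files$truth <- truthPath

  invisible(list(
    files = files,
    truth = truth,
    log = list(reads = c(normalization = length(rN),
                         expression = length(rE),
                         mapping = length(iM)))
  ))
}
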