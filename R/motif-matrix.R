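#' MotifMatrix: positional nucleotide composition around insertion sites
#'
#' Position x nucleotide counts, frequencies and binomial log-odds for
#' oriented sequence windows centred on the piggyBac TTAA target site.
#' Positions are numbered as in target-site logos: `-W .. -1` upstream,
#' `+1 .. +4` the duplicated TTAA, `+5 .. +(W+4)` downstream; there is no
#' position 0.
#'
#' The log-odds statistic is the pLogo-style binomial tail: with `n`
#' windows, `k` occurrences of a base at a position and background rate
#' `p`, enriched bases (`k/n >= p`) score `-log10 P(X >= k)` (positive)
#' and depleted bases score `log10 P(X <= k)` (negative), so the sign
#' always matches the direction of the deviation from background.
#'
#' @slot counts integer matrix, positions x `A,C,G,T`.
#' @slot frequencies column-stochastic-by-row frequency matrix (each row
#'   sums to 1).
#' @slot background named background nucleotide frequencies.
#' @slot logOdds binomial log-odds matrix.
#' @slot nSites number of windows tallied.
#' @slot W flank width.
#'
#' @aliases MotifMatrix
#' @exportClass MotifMatrix
setClass("MotifMatrix",
  representation(counts = "matrix", frequencies = "matrix",
                 background = "numeric", logOdds = "matrix",
                 nSites = "integer", W = "integer"))

setValidity("MotifMatrix", function(object) {
  msgs <- character(0)
  if (!identical(colnames(object@counts), c("A", "C", "G", "T")))
    msgs <- c(msgs, "count columns must be A, C, G, T")
  if (any(abs(rowSums(object@frequencies) - 1) > 1e-9))
    msgs <- c(msgs, "frequencies must sum to 1 at every position")
  if (any(rowSums(object@counts) != object@nSites))
    msgs <- c(msgs, "counts at every position must sum to nSites")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MotifMatrix", function(object) {
  cat(sprintf("MotifMatrix: %d site(s), window -%d..+%d (no position 0)\n",
              object@nSites, object@W, object@W + 4L))
  core <- object@frequencies[as.character(c("+1", "+2", "+3", "+4")), ,
                             drop = FALSE]
  cat("target-site (+1..+4) frequencies:\n")
  print(round(core, 3))
})

#' @rdname MotifMatrix-class
#' @param x a `MotifMatrix`.
#' @export
motifCounts <- function(x) x@counts

#' @rdname MotifMatrix-class
#' @export
motifFrequencies <- function(x) x@frequencies

#' @rdname MotifMatrix-class
#' @export
motifLogOdds <- function(x) x@logOdds

#' @rdname MotifMatrix-class
#' @export
motifBackground <- function(x) x@background

# position labels -W..-1, +1..+(W+4)
.motifPositions <- function(W) {
  c(as.character(-W:-1), paste0("+", 1:(W + 4L)))
}

#' Extract oriented sequence windows around insertion sites
#'
#' Returns, per insertion, `2W + 4` bases: `W` upstream, the 4-base TTAA
#' target site, `W` downstream, reverse-complemented for minus-strand
#' insertions so all windows share the transgene's orientation.  Sites
#' whose window would run off the chromosome are skipped and counted.
#'
#' @param insertions data.frame with `chrom`, `position`, `strand`.
#' @param genome [SyntheticGenome-class], `DNAStringSet` or FASTA path.
#' @param W flank width (default 10).
#' @return character vector of windows, with attribute `skipped` (number
#'   of out-of-bounds sites).
#' @export
extractWindows <- function(insertions, genome, W = 10L) {
  seqs <- if (is(genome, "SyntheticGenome")) genome@sequences
          else if (is(genome, "DNAStringSet")) genome
          else readDNAStringSet(genome)
  n <- nrow(insertions)
  out <- character(0); skipped <- 0L
  for (i in seq_len(n)) {
    s <- getSubseq(seqs, insertions$chrom[i],
                   insertions$position[i] - W,
                   insertions$position[i] + 3L + W)
    if (is.na(s)) { skipped <- skipped + 1L; next }
    if (insertions$strand[i] == "-") s <- revcomp(s)
    out <- c(out, s)
  }
  attr(out, "skipped") <- skipped
  out
}

# signed pLogo-style binomial tail statistic, log space throughout
binomialLogOdds <- function(k, n, p) {
  stopifnot(p > 0, p < 1)
  upper <- k / n >= p
  out <- numeric(length(k))
  # enrichment: -log10 P(X >= k)
  out[upper] <- -pbinom(k[upper] - 1L, n, p, lower.tail = FALSE,
                        log.p = TRUE) / log(10)
  # depletion: log10 P(X <= k)  (negative)
  out[!upper] <- pbinom(k[!upper], n, p, log.p = TRUE) / log(10)
  out
}

#' Tally windows into a positional motif matrix
#'
#' @param windows character vector from [extractWindows()] (equal-length,
#'   `2W + 4` nt).
#' @param background named nucleotide frequencies (`A`,`C`,`G`,`T`,
#'   positive, summing to 1); typically the genome-wide mononucleotide
#'   frequencies, see [genomeBackground()].
#' @return a [MotifMatrix-class].
#' @export
motifMatrix <- function(windows, background = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25)) {
  windows <- toupper(as.character(windows))
  n <- length(windows)
  if (n == 0L) stop("no windows to tally")
  wlen <- nchar(windows[1L])
  if (wlen %% 2L != 0L || wlen < 6L)
    stop("windows must have even length 2W + 4")
  W <- as.integer((wlen - 4L) / 2L)
  background <- background[c("A", "C", "G", "T")]
  if (any(is.na(background)) || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6)
    stop("background must be positive A/C/G/T frequencies summing to 1")

  counts <- matrix(0L, nrow = wlen, ncol = 4L,
                   dimnames = list(.motifPositions(W), c("A", "C", "G", "T")))
  for (j in seq_len(wlen)) {
    tab <- table(factor(substr(windows, j, j), levels = c("A", "C", "G", "T")))
    counts[j, ] <- as.integer(tab)
  }
  freqs <- counts / n
  lo <- matrix(0, nrow = wlen, ncol = 4L, dimnames = dimnames(counts))
  for (b in colnames(counts))
    lo[, b] <- binomialLogOdds(counts[, b], n, background[[b]])
  new("MotifMatrix", counts = counts, frequencies = freqs,
      background = setNames(as.numeric(background), names(background)),
      logOdds = lo, nSites = as.integer(n), W = W)
}

#' Genome-wide mononucleotide background frequencies
#'
#' @param genome [SyntheticGenome-class], `DNAStringSet` or FASTA path.
#' @return named frequencies of A, C, G, T over all chromosomes.
#' @export
genomeBackground <- function(genome) {
  seqs <- if (is(genome, "SyntheticGenome")) genome@sequences
          else if (is(genome, "DNAStringSet")) genome
          else readDNAStringSet(genome)
  af <- colSums(alphabetFrequency(seqs)[, c("A", "C", "G", "T"),
                                        drop = FALSE])
  af / sum(af)
}

#' Per-position A+T fraction of a motif matrix
#'
#' The AT-richness profile around the insertion site: at the duplicated
#' TTAA (+1..+4) it is 1 by construction; in the flanks it tracks the
#' local sequence composition relative to the genome background.
#'
#' @param matrix a [MotifMatrix-class].
#' @return named numeric vector, one A+T fraction per position.
#' @export
atContentProfile <- function(matrix) {
  f <- motifFrequencies(matrix)
  setNames(f[, "A"] + f[, "T"], rownames(f))
}

#' Serialize a motif matrix as a TSV
#'
#' One row per position: counts, frequencies and log-odds per base.
#'
#' @param matrix a [MotifMatrix-class].
#' @param path output TSV path.
#' @return invisibly the path.
#' @export
writeMotifTsv <- function(matrix, path) {
  cnt <- motifCounts(matrix); fr <- motifFrequencies(matrix)
  lo <- motifLogOdds(matrix)
  df <- data.frame(position = rownames(cnt), cnt,
                   setNames(as.data.frame(fr), paste0("freq_", colnames(fr))),
                   setNames(as.data.frame(lo), paste0("logodds_", colnames(lo))),
                   check.names = FALSE)
  writeTsv(df, path)
}
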