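#' KmerIndex: exact k-mer lookup over both strands of a genome
#'
#' Hash-style index mapping every k-mer of the reference (both strands)
#' to its genomic positions, used to seed flank alignment.  A minus-strand
#' entry at plus-window `[pos, pos+k-1]` stores the reverse complement of
#' that window, i.e. the sequence a read from the minus strand would
#' show.
#'
#' @slot genome the indexed [Biostrings::DNAStringSet].
#' @slot k k-mer width.
#' @slot table a keyed `data.table` (`kmer`, `chrom`, `pos`, `strand`).
#'
#' @aliases KmerIndex
#' @exportClass KmerIndex
setClass("KmerIndex",
  representation(genome = "DNAStringSet", k = "integer", table = "ANY"))

setValidity("KmerIndex", function(object) {
  if (object@k < 12L) return("k must be >= 12")
  TRUE
})

setMethod("show", "KmerIndex", function(object) {
  cat(sprintf("KmerIndex: k = %d, %d chromosome(s), %d indexed k-mers\n",
              object@k, length(object@genome), nrow(object@table)))
})

#' @rdname KmerIndex-class
#' @param x a `KmerIndex`.
#' @export
kmerWidth <- function(x) x@k

#' Build a k-mer index of a reference genome
#'
#' @param genome a [SyntheticGenome-class], `DNAStringSet` or FASTA path.
#' @param k k-mer width (>= 12, default 20).
#' @return a [KmerIndex-class].
#' @examples
#' g <- makeGenome(c(chrA = 20000L), seed = 1)
#' buildKmerIndex(g, k = 20)
#' @export
buildKmerIndex <- function(genome, k = 20L) {
  k <- as.integer(k)
  if (k < 12L) stop("k must be >= 12")
  seqs <- if (is(genome, "SyntheticGenome")) genome@sequences
          else if (is(genome, "DNAStringSet")) genome
          else readDNAStringSet(genome)
  parts <- list()
  for (chr in names(seqs)) {
    s <- as.character(seqs[[chr]])
    L <- nchar(s)
    if (L < k) next
    n <- L - k + 1L
    pos <- seq_len(n)
    plus <- substring(s, pos, pos + k - 1L)
    rc <- revcomp(s)
    # minus-strand k-mer over plus-window [p, p+k-1] = rc[L-p-k+2 .. L-p+1]
    minus <- substring(rc, L - pos - k + 2L, L - pos + 1L)
    parts[[paste0(chr, "+")]] <- data.table(kmer = plus, chrom = chr,
                                            pos = pos, strand = "+")
    parts[[paste0(chr, "-")]] <- data.table(kmer = minus, chrom = chr,
                                            pos = pos, strand = "-")
  }
  tab <- rbindlist(parts)
  setkey(tab, kmer)
  new("KmerIndex", genome = seqs, k = k, table = tab)
}

#' Look up a k-mer's genomic occurrences
#'
#' @param index a [KmerIndex-class].
#' @param kmer a single k-mer string.
#' @return data.frame (`chrom`, `pos`, `strand`), zero rows if absent.
#' @export
lookupKmer <- function(index, kmer) {
  stopifnot(nchar(kmer) == index@k)
  # the query must not be named like the key column, or the i-expression
  # would resolve to the column itself (a full self-join)
  qkmer <- toupper(kmer)
  hits <- index@table[list(qkmer), nomatch = 0L]
  as.data.frame(hits[, c("chrom", "pos", "strand")])
}

#' Align a genomic flank by seed-and-extend
#'
#' Seeds on the flank's first k-mer via the index, extends each hit over
#' the full flank allowing up to `maxMismatch` substitutions, and reports
#' all loci achieving the minimal mismatch count.  Hit coordinates are
#' converted to the insertion coordinate: the 1-based position of the
#' first T of the duplicated TTAA on the plus strand.  For a plus-strand
#' hit the flank starts 4 bases past the TTAA, so `position = pos - 4`;
#' for a minus-strand hit the flank reads leftwards from `position - 1`,
#' so `position = pos + k`.
#'
#' @param flank flank sequence (>= k nt).
#' @param index a [KmerIndex-class].
#' @param maxMismatch substitutions allowed over the full flank.
#' @return data.frame of candidates (`chrom`, `position`, `strand`,
#'   `mismatches`, `flank_length`); zero rows if unalignable.
#' @export
alignFlank <- function(flank, index, maxMismatch = 2L) {
  flank <- toupper(flank)
  k <- index@k
  len <- nchar(flank)
  empty <- data.frame(chrom = character(0), position = integer(0),
                      strand = character(0), mismatches = integer(0),
                      flank_length = integer(0))
  if (len < k) return(empty)
  seeds <- index@table[list(substr(flank, 1L, k)), nomatch = 0L]
  if (nrow(seeds) == 0L) return(empty)
  res <- list()
  for (i in seq_len(nrow(seeds))) {
    chr <- seeds$chrom[i]; pos <- seeds$pos[i]; strd <- seeds$strand[i]
    if (strd == "+") {
      ref <- getSubseq(index@genome, chr, pos, pos + len - 1L)
      insPos <- pos - 4L
    } else {
      ref <- getSubseq(index@genome, chr, pos + k - len, pos + k - 1L)
      if (!is.na(ref)) ref <- revcomp(ref)
      insPos <- pos + k
    }
    if (is.na(ref)) next
    mm <- hammingDist(flank, ref)
    if (mm <= maxMismatch && insPos >= 1L)
      res[[length(res) + 1L]] <- data.frame(
        chrom = chr, position = insPos, strand = strd,
        mismatches = mm, flank_length = len)
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  out <- out[out$mismatches == min(out$mismatches), , drop = FALSE]
  out <- out[order(out$chrom, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
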