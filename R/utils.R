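#' Hamming distance between equal-length strings
#'
#' Position-wise substitution count.  `hammingToRef()` compares a vector of
#' strings against one reference; `hammingMatrix()` returns the full
#' distance matrix between two sets.  All strings within a call must share
#' one length; this is the metric used for promoter-index demultiplexing
#' and barcode collapsing (substitution-only error model, no indels).
#'
#' @param x,y character vectors of equal-length strings.
#' @param ref a single reference string, same width as `x`.
#' @return `hammingToRef()`: integer vector; `hammingMatrix()`: integer
#'   matrix of dim `length(x)` x `length(y)`.
#' @examples
#' hammingToRef(c("TACAA", "TACGA"), "TACAA")
#' @export
hammingToRef <- function(x, ref) {
  w <- nchar(ref)
  if (length(x) == 0L) return(integer(0))
  if (any(nchar(x) != w)) stop("all strings must have the same width as 'ref'")
  d <- integer(length(x))
  for (j in seq_len(w)) {
    d <- d + (substr(x, j, j) != substr(ref, j, j))
  }
  d
}

#' @rdname hammingToRef
#' @export
hammingMatrix <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    return(matrix(0L, length(x), length(y)))
  w <- nchar(x[1L])
  if (any(nchar(c(x, y)) != w)) stop("all strings must share one width")
  xm <- matrix(unlist(strsplit(x, "", fixed = TRUE)), nrow = length(x), byrow = TRUE)
  ym <- matrix(unlist(strsplit(y, "", fixed = TRUE)), nrow = length(y), byrow = TRUE)
  d <- matrix(0L, length(x), length(y))
  for (j in seq_len(w)) d <- d + outer(xm[, j], ym[, j], "!=")
  d
}

# reverse-complement a plain character vector of DNA strings
revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

# fetch genome[chrom][from..to] as a character string (1-based inclusive);
# returns NA if the range falls outside the chromosome
getSubseq <- function(genomeSeqs, chrom, from, to) {
  if (!chrom %in% names(genomeSeqs)) return(NA_character_)
  L <- width(genomeSeqs[chrom])
  if (from < 1L || to > L || from > to) return(NA_character_)
  as.character(subseq(genomeSeqs[[chrom]], from, to))
}

# write a data.frame as a TSV with header, no quoting
writeTsv <- function(x, path) {
  fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname hammingToRef
#' @param a,b single strings of equal length.
#' @export
hammingDist <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("strings must have equal length")
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}
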