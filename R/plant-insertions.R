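#' Promoter-index lookup table
#'
#' The fixed 5-bp promoter indexes that sit immediately upstream of the
#' 18-bp barcode and identify which promoter drives a construct.  The four
#' default entries have pairwise Hamming distance >= 4, so demultiplexing
#' with one allowed mismatch is unambiguous.
#'
#' @return data.frame with columns `index` (uppercase 5-mer) and
#'   `promoter`.
#' @examples
#' promoterIndexTable()
#' @export
promoterIndexTable <- function() {
  data.frame(
    index = c("TACAA", "CCGAG", "CTAGT", "AGCTC"),
    promoter = c("short_EF1a", "long_EF1a", "mPGK", "PGK"),
    stringsAsFactors = FALSE
  )
}

# default per-promoter activity multipliers; long EF-1a is the strongest,
# the short variant roughly 10x weaker at the median
defaultPromoterFactors <- function() {
  c(long_EF1a = 10, short_EF1a = 1, mPGK = 0.5, PGK = 0.3)
}

# sample n barcodes of the given width with pairwise Hamming distance >=
# minDist; batch generation with greedy rejection (random 18-mers almost
# always qualify, so few batches are needed)
sampleBarcodes <- function(n, width = 18L, minDist = 5L) {
  out <- character(0)
  while (length(out) < n) {
    m <- max(16L, n - length(out))
    cand <- unique(vapply(seq_len(m), function(i)
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = ""), character(1)))
    for (i in seq_along(cand)) {
      if (length(out) >= n) break
      if (length(out) == 0L ||
          all(hammingToRef(out, cand[i]) >= minDist))
        out <- c(out, cand[i])
    }
  }
  out
}

#' Plant ground-truth transgene insertions at TTAA sites
#'
#' Draws `n` piggyBac insertion loci without replacement from the TTAA
#' occurrences of a synthetic genome, assigns each a unique 18-nt barcode
#' (pairwise Hamming distance >= 5), a promoter class drawn from the
#' library mixing weights, a clone abundance (log-normal polyclonal
#' drift), and a true transcriptional activity: exactly
#' `round(silentFraction * n)` insertions are fully silent (activity 0);
#' the rest draw a log-normal rate scaled by a per-promoter factor and by
#' the activity factor of the chromatin state at the locus.
#'
#' @param genome a [SyntheticGenome-class].
#' @param n number of insertions.
#' @param mix numeric weights for classes (long_EF1a, short_EF1a, mPGK,
#'   PGK); the default 7:7:7:1 mirrors a library mixed at that molar
#'   ratio.
#' @param silentFraction proportion of insertions forced silent.
#' @param promoterFactors named multiplier per promoter class.
#' @param chromatinFactors named multiplier per chromatin state; defaults
#'   to the `activity_factor` column of [choChromatinStates()] (states not
#'   listed get factor 1).
#' @param activityMeanlog,activitySdlog log-normal parameters of the base
#'   activity draw.
#' @param abundanceSdlog log-normal sigma of clone abundance.
#' @param seed integer RNG seed.
#' @return data.frame of ground truth: `barcode`, `promoter_class`,
#'   `promoter_index`, `chrom`, `position` (1-based first base of the
#'   TTAA), `strand`, `true_activity`, `clone_abundance`.
#' @examples
#' g <- makeGenome(c(chrA = 20000L), seed = 1)
#' head(plantInsertions(g, 10, seed = 2))
#' @export
plantInsertions <- function(genome, n,
                            mix = c(long_EF1a = 7, short_EF1a = 7,
                                    mPGK = 7, PGK = 1),
                            silentFraction = 0.5,
                            promoterFactors = defaultPromoterFactors(),
                            chromatinFactors = NULL,
                            activityMeanlog = 0,
                            activitySdlog = 1,
                            abundanceSdlog = 1,
                            seed = 1L) {
  stopifnot(n >= 1L, length(mix) == 4L, all(mix >= 0), sum(mix) > 0,
            silentFraction >= 0, silentFraction <= 1)
  if (is.null(names(mix)))
    names(mix) <- c("long_EF1a", "short_EF1a", "mPGK", "PGK")
  set.seed(seed)

  # all plus-strand TTAA occurrences (the motif is its own reverse
  # complement, so this enumerates both orientations' target sites)
  sites <- do.call(rbind, lapply(names(genome@sequences), function(chr) {
    m <- matchPattern("TTAA", genome@sequences[[chr]])
    if (length(m) == 0L) return(NULL)
    data.frame(chrom = chr, position = start(m))
  }))
  nSites <- if (is.null(sites)) 0L else nrow(sites)
  if (nSites < n)
    stop(sprintf("genome has only %d TTAA sites but %d insertions requested",
                 nSites, n))
  pick <- sites[sample.int(nSites, n), , drop = FALSE]

  idxTab <- promoterIndexTable()
  cls <- sample(names(mix), n, replace = TRUE, prob = mix / sum(mix))
  truth <- data.frame(
    barcode = sampleBarcodes(n),
    promoter_class = cls,
    promoter_index = idxTab$index[match(cls, idxTab$promoter)],
    chrom = pick$chrom,
    position = pick$position,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  if (is.null(chromatinFactors)) {
    st <- choChromatinStates()
    chromatinFactors <- setNames(st$activity_factor, st$state)
  }
  seg <- genome@chromatin
  hit <- findOverlaps(GRanges(truth$chrom, IRanges(truth$position,
                                                   truth$position)), seg)
  stateAt <- rep(NA_character_, n)
  stateAt[queryHits(hit)] <- mcols(seg)$state[subjectHits(hit)]
  cf <- ifelse(is.na(stateAt) | !stateAt %in% names(chromatinFactors),
               1, chromatinFactors[stateAt])

  act <- rlnorm(n, activityMeanlog, activitySdlog) *
    unname(promoterFactors[truth$promoter_class]) * cf
  silentIdx <- sample.int(n, round(silentFraction * n))
  act[silentIdx] <- 0
  truth$true_activity <- act
  truth$clone_abundance <- rlnorm(n, 0, abundanceSdlog)
  rownames(truth) <- NULL
  truth
}
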