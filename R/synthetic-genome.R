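#' SyntheticGenome: a toy genome with gene models and a chromatin segmentation
#'
#' Container for the simulated reference used by the test pipeline: raw
#' chromosome sequences, simple gene models (gene span, exons, CDS per
#' gene) and a chromatin-state segmentation that tiles every chromosome
#' exactly once.  It stands in for a real assembly plus GFF3 gene models
#' plus a ChromHMM-style BED segmentation; [writeGenome()] serializes it to
#' those three standard formats.
#'
#' Validity requirements: gene and segment intervals lie within chromosome
#' bounds; exons lie within their gene span; chromatin segments are
#' non-overlapping and cover each chromosome exactly; every chromosome
#' carries on average at least one TTAA per kb (piggyBac needs target
#' sites).
#'
#' @slot sequences a [Biostrings::DNAStringSet], one entry per chromosome.
#' @slot genes a [GenomicRanges::GRanges] of gene spans (TSS to TTS in
#'   plus-strand coordinates) with mcols `gene_id`.
#' @slot exons a `GRanges` of exons with mcols `gene_id`.
#' @slot cds a `GRanges` of coding regions with mcols `gene_id`.
#' @slot chromatin a `GRanges` tiling each chromosome, mcols `state`.
#'
#' @aliases SyntheticGenome
#' @exportClass SyntheticGenome
setClass("SyntheticGenome",
  representation(
    sequences = "DNAStringSet",
    genes     = "GRanges",
    exons     = "GRanges",
    cds       = "GRanges",
    chromatin = "GRanges"
  )
)

setValidity("SyntheticGenome", function(object) {
  msgs <- character(0)
  lens <- setNames(width(object@sequences), names(object@sequences))
  checkBounds <- function(gr, what) {
    if (length(gr) == 0L) return(character(0))
    bad <- as.character(seqnames(gr)) %in% names(lens) &
      (start(gr) < 1L | end(gr) > lens[as.character(seqnames(gr))])
    miss <- !as.character(seqnames(gr)) %in% names(lens)
    out <- character(0)
    if (any(miss)) out <- c(out, sprintf("%s on unknown chromosome", what))
    if (any(bad))  out <- c(out, sprintf("%s outside chromosome bounds", what))
    out
  }
  msgs <- c(msgs, checkBounds(object@genes, "gene"),
            checkBounds(object@exons, "exon"),
            checkBounds(object@chromatin, "chromatin segment"))
  # exons within gene spans
  if (length(object@exons) > 0L) {
    gid <- match(mcols(object@exons)$gene_id, mcols(object@genes)$gene_id)
    if (anyNA(gid)) {
      msgs <- c(msgs, "exon with unknown gene_id")
    } else if (any(start(object@exons) < start(object@genes)[gid] |
                   end(object@exons) > end(object@genes)[gid])) {
      msgs <- c(msgs, "exon outside its gene span")
    }
  }
  # chromatin tiles each chromosome exactly once
  for (chr in names(lens)) {
    seg <- object@chromatin[as.character(seqnames(object@chromatin)) == chr]
    if (length(seg) == 0L) { msgs <- c(msgs, sprintf("no chromatin segments on %s", chr)); next }
    seg <- seg[order(start(seg))]
    if (start(seg)[1L] != 1L || end(seg)[length(seg)] != lens[chr] ||
        (length(seg) > 1L && any(start(seg)[-1L] != end(seg)[-length(seg)] + 1L)))
      msgs <- c(msgs, sprintf("chromatin segments do not tile %s exactly", chr))
  }
  # TTAA density >= 1 per kb on average per chromosome
  for (chr in names(lens)) {
    nttaa <- vcountPattern("TTAA", object@sequences[chr])
    if (nttaa / (lens[chr] / 1000) < 1)
      msgs <- c(msgs, sprintf("fewer than 1 TTAA per kb on %s", chr))
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SyntheticGenome", function(object) {
  cat("SyntheticGenome with", length(object@sequences), "chromosome(s):\n")
  for (chr in names(object@sequences))
    cat(sprintf("  %s: %d bp\n", chr, width(object@sequences[chr])))
  cat(sprintf("  %d gene(s), %d exon(s), %d chromatin segment(s) (%d states)\n",
              length(object@genes), length(object@exons),
              length(object@chromatin),
              length(unique(mcols(object@chromatin)$state))))
})

#' @rdname SyntheticGenome-class
#' @param x a `SyntheticGenome`.
#' @export
genomeSequences <- function(x) x@sequences

#' @rdname SyntheticGenome-class
#' @export
geneModels <- function(x) list(genes = x@genes, exons = x@exons, cds = x@cds)

#' @rdname SyntheticGenome-class
#' @export
chromatinSegments <- function(x) x@chromatin

#' Chromatin-state palette for the simulator
#'
#' Eleven segmentation labels patterned on published ChromHMM-style
#' chromatin types of CHO-K1 cells, with the genome-fraction weights used
#' when tiling a synthetic chromosome and a multiplicative activity factor
#' applied to reporters landing in each state.  The three inactive states
#' (quiescent, H3K9me3- and H3K27me3-repressed) together cover ~88 % of
#' the genome, matching the real segmentations this stands in for; active
#' transcription and enhancer states boost reporter activity.
#'
#' @return a data.frame with columns `state`, `weight` (tiling
#'   probability, sums to 1) and `activity_factor`.
#' @examples
#' choChromatinStates()
#' @export
choChromatinStates <- function() {
  data.frame(
    state = c(
      "Quiescent/low",
      "Repressed heterochromatin (H3K9me3)",
      "Polycomb repressed regions (H3K27me3)",
      "Strong transcription (H3K36me3)",
      "Weak transcription",
      "Enhancer (H3K27ac high)",
      "Enhancer (H3K27ac low)",
      "Active TSS",
      "Flanking active TSS",
      "Bivalent TSS",
      "Repeat/ZNF"
    ),
    weight = c(0.70, 0.10, 0.08, 0.025, 0.02, 0.015, 0.015,
               0.01, 0.01, 0.0125, 0.0125),
    activity_factor = c(0.5, 0.4, 0.4, 5, 1.5, 3, 1.5, 3, 2, 1, 0.8),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic reference genome with gene models and chromatin states
#'
#' Draws i.i.d. chromosome sequences at a requested GC content, places
#' non-overlapping multi-exon gene models on random strands, and tiles each
#' chromosome with chromatin-state segments drawn from a label palette.
#' Deterministic for a fixed seed.
#'
#' @param chromSizes named integer vector of chromosome lengths (bp), each
#'   at least 10 kb.
#' @param gc target GC fraction of the simulated sequence.
#' @param geneDensity expected genes per bp (default one per 10 kb).
#' @param states a data.frame as returned by [choChromatinStates()] with
#'   columns `state` and `weight`; labels used for the segmentation.
#' @param meanSegmentLength mean chromatin segment length in bp.
#' @param seed integer RNG seed.
#' @return a [SyntheticGenome-class] object.
#' @examples
#' g <- makeGenome(c(chrA = 20000L), seed = 1)
#' g
#' @export
makeGenome <- function(chromSizes,
                       gc = 0.45,
                       geneDensity = 1 / 10000,
                       states = choChromatinStates(),
                       meanSegmentLength = 5000,
                       seed = 1L) {
  stopifnot(length(chromSizes) >= 1L, !is.null(names(chromSizes)),
            gc > 0, gc < 1, geneDensity >= 0)
  if (any(chromSizes < 10000L))
    stop("every chromosome must be at least 10 kb: ",
         paste(names(chromSizes)[chromSizes < 10000L], collapse = ", "))
  set.seed(seed)
  baseProb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

  seqs <- DNAStringSet(vapply(chromSizes, function(L) {
    paste(sample(names(baseProb), L, replace = TRUE, prob = baseProb),
          collapse = "")
  }, character(1)))
  names(seqs) <- names(chromSizes)

  ## gene models: carve each chromosome into slots, one candidate gene each
  geneRows <- list(); exonRows <- list(); cdsRows <- list()
  gi <- 0L
  for (chr in names(chromSizes)) {
    L <- chromSizes[[chr]]
    nGenes <- max(0L, round(geneDensity * L))
    if (geneDensity > 0 && nGenes >= 1L && L < 6000L)
      stop("chromosome too short to host a gene: ", chr)
    if (nGenes == 0L) next
    slot <- floor(L / nGenes)
    if (slot < 6000L) {
      nGenes <- max(1L, floor(L / 6000L))
      slot <- floor(L / nGenes)
    }
    for (s in seq_len(nGenes)) {
      gi <- gi + 1L
      id <- sprintf("gene%04d", gi)
      lo <- (s - 1L) * slot + 1L
      span <- sample(2000:min(5000L, slot - 1200L), 1L)
      gstart <- lo + sample.int(slot - span - 1100L, 1L) + 1050L
      gend <- gstart + span - 1L
      strand <- sample(c("+", "-"), 1L)
      nEx <- sample(1:5, 1L)
      # split the span into nEx exons separated by introns
      if (nEx == 1L) {
        exS <- gstart; exE <- gend
      } else {
        cuts <- sort(sample(seq(gstart + 200L, gend - 200L, by = 50L),
                            2L * (nEx - 1L)))
        exS <- c(gstart, cuts[seq(2, length(cuts), by = 2)] + 1L)
        exE <- c(cuts[seq(1, length(cuts), by = 2)], gend)
      }
      # CDS trimmed inside the first/last exon, leaving UTRs
      u5 <- min(100L, exE[1L] - exS[1L])
      u3 <- min(100L, exE[nEx] - exS[nEx])
      if (strand == "+") {
        cdsLo <- exS[1L] + u5; cdsHi <- exE[nEx] - u3
      } else {
        cdsLo <- exS[1L] + u3; cdsHi <- exE[nEx] - u5
      }
      keep <- exE >= cdsLo & exS <= cdsHi
      cS <- pmax(exS[keep], cdsLo); cE <- pmin(exE[keep], cdsHi)
      geneRows[[gi]] <- data.frame(chrom = chr, start = gstart, end = gend,
                                   strand = strand, gene_id = id)
      exonRows[[gi]] <- data.frame(chrom = chr, start = exS, end = exE,
                                   strand = strand, gene_id = id)
      cdsRows[[gi]] <- data.frame(chrom = chr, start = cS, end = cE,
                                  strand = strand, gene_id = id)
    }
  }
  df2gr <- function(rows) {
    if (length(rows) == 0L)
      return(GRanges(character(0), IRanges(integer(0), integer(0)),
                     gene_id = character(0)))
    df <- do.call(rbind, rows)
    GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
            gene_id = df$gene_id)
  }

  ## chromatin segmentation: exponential segment lengths, weighted labels
  segRows <- list()
  for (chr in names(chromSizes)) {
    L <- chromSizes[[chr]]
    pos <- 1L; starts <- integer(0); ends <- integer(0)
    while (pos <= L) {
      len <- max(500L, round(rexp(1L, 1 / meanSegmentLength)))
      ends <- c(ends, min(L, pos + len - 1L)); starts <- c(starts, pos)
      pos <- pos + len
    }
    lab <- sample(states$state, length(starts), replace = TRUE,
                  prob = states$weight)
    segRows[[chr]] <- data.frame(chrom = chr, start = starts, end = ends,
                                 state = lab)
  }
  segDf <- do.call(rbind, segRows)
  chromatin <- GRanges(segDf$chrom, IRanges(segDf$start, segDf$end),
                       state = segDf$state)

  new("SyntheticGenome", sequences = seqs, genes = df2gr(geneRows),
      exons = df2gr(exonRows), cds = df2gr(cdsRows), chromatin = chromatin)
}

#' Write a SyntheticGenome as FASTA + GFF3 + BED
#'
#' Serializes the genome to the standard formats the downstream stages
#' consume: `genome.fa` (chromosome sequences), `genes.gff3` (gene, mRNA,
#' exon and CDS features, 1-based), `chromatin.bed` (BED4 segmentation,
#' 0-based half-open).
#'
#' @param genome a [SyntheticGenome-class].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the three file paths.
#' @export
writeGenome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "genes.gff3")
  bed <- file.path(dir, "chromatin.bed")
  writeXStringSet(genome@sequences, fa)

  gn <- genome@genes; ex <- genome@exons; cd <- genome@cds
  feats <- c(
    { g <- gn; mcols(g) <- NULL
      mcols(g)$type <- "gene"
      mcols(g)$ID <- mcols(gn)$gene_id
      mcols(g)$Parent <- NA_character_
      mcols(g)$phase <- NA_integer_; g },
    { m <- gn; mcols(m) <- NULL
      mcols(m)$type <- "mRNA"
      mcols(m)$ID <- paste0(mcols(gn)$gene_id, ".t1")
      mcols(m)$Parent <- mcols(gn)$gene_id
      mcols(m)$phase <- NA_integer_; m },
    { e <- ex; mcols(e) <- NULL
      mcols(e)$type <- "exon"
      mcols(e)$ID <- NA_character_
      mcols(e)$Parent <- paste0(mcols(ex)$gene_id, ".t1")
      mcols(e)$phase <- NA_integer_; e },
    { cc <- cd; mcols(cc) <- NULL
      mcols(cc)$type <- "CDS"
      mcols(cc)$ID <- NA_character_
      mcols(cc)$Parent <- paste0(mcols(cd)$gene_id, ".t1")
      mcols(cc)$phase <- 0L; cc }
  )
  export(feats, gff, format = "gff3")

  seg <- genome@chromatin
  bedDf <- data.frame(chrom = as.character(seqnames(seg)),
                      start = start(seg) - 1L,   # BED is 0-based half-open
                      end = end(seg),
                      name = mcols(seg)$state)
  write.table(bedDf, bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(list(fasta = fa, gff3 = gff, bed = bed))
}
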