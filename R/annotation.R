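#' Build a labeled gene-element interval index from GFF3 gene models
#'
#' Derives, for every gene, the interval sets used to classify insertion
#' loci: the promoter window (-1000 to +100 bp around the distal
#' transcription start site, in transcription orientation), 5' and 3'
#' UTRs, exons and introns, as unions over the gene's transcripts.
#' Overlapping labels are permitted in the index; [classifyElement()]
#' resolves them by priority.
#'
#' @param gff a GFF3 path, or a `GRanges` with mcols `type`, `ID`,
#'   `Parent` (gene / mRNA / exon / CDS features).
#' @param promoterUp,promoterDown promoter window extent upstream /
#'   downstream of the TSS (defaults 1000 and 100; window length 1101).
#' @return a list of class `"ElementIndex"`: `elements` (`GRanges` with
#'   mcols `element`, `gene_id`) and `genes` (data.frame `gene_id`,
#'   `chrom`, `strand`, `tss`, `tts`).
#' @export
buildElementIndex <- function(gff, promoterUp = 1000L, promoterDown = 100L) {
  gr <- if (is(gff, "GRanges")) gff else import(gff, format = "gff3")
  typ <- as.character(mcols(gr)$type)
  firstParent <- function(x) {
    p <- mcols(x)$Parent
    if (is(p, "List") || is.list(p))
      vapply(p, function(v) if (length(v)) as.character(v[[1L]]) else
        NA_character_, character(1))
    else as.character(p)
  }
  genes <- gr[typ == "gene"]
  mrna <- gr[typ == "mRNA"]
  exons <- gr[typ == "exon"]
  cds <- gr[typ == "CDS"]
  if (length(genes) == 0L) stop("no gene features in the annotation")
  mrnaGene <- setNames(firstParent(mrna), as.character(mcols(mrna)$ID))
  exonGene <- unname(mrnaGene[firstParent(exons)])
  cdsGene <- unname(mrnaGene[firstParent(cds)])

  elemRows <- list()
  geneRows <- list()
  for (gi in seq_along(genes)) {
    id <- as.character(mcols(genes)$ID[gi])
    chr <- as.character(seqnames(genes))[gi]
    strd <- as.character(strand(genes))[gi]
    gEx <- exons[!is.na(exonGene) & exonGene == id]
    gCds <- cds[!is.na(cdsGene) & cdsGene == id]
    gs <- start(genes)[gi]; ge <- end(genes)[gi]
    tss <- if (strd == "-") ge else gs     # distal TSS
    tts <- if (strd == "-") gs else ge
    geneRows[[gi]] <- data.frame(gene_id = id, chrom = chr, strand = strd,
                                 tss = tss, tts = tts)
    add <- function(el, s, e) {
      keep <- s <= e
      if (!any(keep)) return()
      elemRows[[length(elemRows) + 1L]] <<- data.frame(
        chrom = chr, start = s[keep], end = e[keep], element = el,
        gene_id = id, stringsAsFactors = FALSE)
    }
    # promoter window, transcription-oriented
    if (strd == "-") add("promoter", tss - promoterDown, tss + promoterUp)
    else add("promoter", tss - promoterUp, tss + promoterDown)

    if (length(gEx) > 0L) {
      exMerged <- reduce(gEx)
      add("exon", start(exMerged), end(exMerged))
      if (length(exMerged) > 1L) {
        o <- order(start(exMerged))
        add("intron", end(exMerged)[o][-length(exMerged)] + 1L,
            start(exMerged)[o][-1L] - 1L)
      }
      if (length(gCds) > 0L) {
        cdsLo <- min(start(gCds)); cdsHi <- max(end(gCds))
        utrS <- integer(0); utrE <- integer(0)
        lab <- character(0)
        for (k in seq_along(exMerged)) {
          es <- start(exMerged)[k]; ee <- end(exMerged)[k]
          if (es < cdsLo) {
            utrS <- c(utrS, es); utrE <- c(utrE, min(ee, cdsLo - 1L))
            lab <- c(lab, if (strd == "-") "utr3" else "utr5")
          }
          if (ee > cdsHi) {
            utrS <- c(utrS, max(es, cdsHi + 1L)); utrE <- c(utrE, ee)
            lab <- c(lab, if (strd == "-") "utr5" else "utr3")
          }
        }
        for (el in unique(lab)) add(el, utrS[lab == el], utrE[lab == el])
        if (any(start(gCds) < min(start(gEx)) - 0L) ||
            any(end(gCds) > max(end(gEx))))
          stop("CDS outside exons for gene ", id)
        cdsOut <- vapply(seq_along(gCds), function(k)
          !any(start(gCds)[k] >= start(gEx) & end(gCds)[k] <= end(gEx)),
          logical(1))
        if (any(cdsOut)) stop("CDS outside exons for gene ", id)
      }
    }
  }
  elemDf <- rbindlist(elemRows)
  elements <- GRanges(elemDf$chrom,
                      IRanges(pmax(1L, elemDf$start), elemDf$end),
                      feature = elemDf$element, gene_id = elemDf$gene_id)
  structure(list(elements = elements,
                 genes = do.call(rbind, geneRows)),
            class = "ElementIndex")
}

#' @export
print.ElementIndex <- function(x, ...) {
  cat(sprintf("ElementIndex: %d labeled interval(s) over %d gene(s)\n",
              length(x$elements), nrow(x$genes)))
  print(table(mcols(x$elements)$feature))
  invisible(x)
}

# fixed priority making the element categories mutually exclusive,
# regulatory regions dominant
.elementPriority <- c("promoter", "utr5", "utr3", "exon", "intron")

#' Classify insertion loci into gene elements
#'
#' Assigns each query point (the TTAA start coordinate) the
#' highest-priority overlapping label -- promoter > 5'UTR > 3'UTR > exon
#' > intron -- or `intergenic` when nothing overlaps.  When two genes tie
#' at the winning priority, the gene whose TSS is nearest wins.
#'
#' @param chrom,position parallel vectors of query loci.
#' @param index an `"ElementIndex"` from [buildElementIndex()].
#' @param priority label order, strongest first.
#' @return data.frame (`element`, `gene_id`); `gene_id` is NA iff
#'   intergenic.
#' @export
classifyElement <- function(chrom, position, index,
                            priority = .elementPriority) {
  q <- GRanges(chrom, IRanges(position, position))
  ov <- findOverlaps(q, index$elements)
  element <- rep("intergenic", length(q))
  geneId <- rep(NA_character_, length(q))
  if (length(ov)) {
    hitEl <- mcols(index$elements)$feature[subjectHits(ov)]
    hitGene <- mcols(index$elements)$gene_id[subjectHits(ov)]
    pr <- match(hitEl, priority)
    for (i in unique(queryHits(ov))) {
      sel <- queryHits(ov) == i
      best <- min(pr[sel])
      cand <- which(sel & pr == best)
      if (length(cand) > 1L) {
        tss <- index$genes$tss[match(hitGene[cand], index$genes$gene_id)]
        cand <- cand[which.min(abs(position[i] - tss))]
      }
      element[i] <- priority[best]
      geneId[i] <- hitGene[cand[1L]]
    }
  }
  data.frame(element = element, gene_id = geneId, stringsAsFactors = FALSE)
}

#' Distances to the nearest TSS and TTS
#'
#' Unsigned base-pair distance from each locus to the nearest
#' transcription start site and, independently, the nearest termination
#' site, over all genes on the same chromosome.  Loci on chromosomes
#' without genes get NA.
#'
#' @param chrom,position query loci.
#' @param genes data.frame (`gene_id`, `chrom`, `strand`, `tss`, `tts`)
#'   as in an `"ElementIndex"`, or the index itself.
#' @return data.frame (`dist_tss`, `dist_tts`).
#' @export
nearestDistances <- function(chrom, position, genes) {
  if (inherits(genes, "ElementIndex")) genes <- genes$genes
  n <- length(position)
  dTss <- rep(NA_real_, n); dTts <- rep(NA_real_, n)
  for (chr in unique(chrom)) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    qi <- which(chrom == chr)
    if (nrow(g) == 0L) next
    for (i in qi) {
      dTss[i] <- min(abs(position[i] - g$tss))
      dTts[i] <- min(abs(position[i] - g$tts))
    }
  }
  data.frame(dist_tss = dTss, dist_tts = dTts)
}

#' Chromatin state overlapping each locus
#'
#' Returns the label of the unique segmentation interval containing the
#' TTAA start coordinate, or `"unassigned"` when the coordinate falls in
#' a gap or on a chromosome absent from the segmentation.  Overlapping
#' segments are a malformed segmentation and raise an error.
#'
#' @param chrom,position query loci.
#' @param segmentation a BED path or a `GRanges` whose first mcols column
#'   (or `state`) holds the label.
#' @return character vector of labels.
#' @export
chromatinOverlap <- function(chrom, position, segmentation) {
  seg <- if (is(segmentation, "GRanges")) segmentation
         else import(segmentation, format = "bed")
  labCol <- if ("state" %in% names(mcols(seg))) "state" else
    if ("name" %in% names(mcols(seg))) "name" else names(mcols(seg))[1L]
  self <- findOverlaps(seg, seg)
  if (length(self) > length(seg))
    stop("malformed segmentation: overlapping segments")
  q <- GRanges(chrom, IRanges(position, position))
  # chromosomes absent from the segmentation are legitimate queries and
  # simply come back unassigned
  ov <- suppressWarnings(findOverlaps(q, seg))
  out <- rep("unassigned", length(q))
  out[queryHits(ov)] <- as.character(mcols(seg)[[labCol]][subjectHits(ov)])
  out
}

#' Annotate transgenes with elements, distances and chromatin types
#'
#' Convenience wrapper joining [classifyElement()], [nearestDistances()]
#' and [chromatinOverlap()] onto a transgene table.
#'
#' @param transgenes data.frame with `chrom`, `position` columns.
#' @param gff GFF3 path / `GRanges` (see [buildElementIndex()]), or an
#'   `"ElementIndex"`.
#' @param segmentation optional BED path / `GRanges`; omitted =
#'   `chromatin_type` set to `"unassigned"`.
#' @return `transgenes` with columns `element`, `gene_id`, `dist_tss`,
#'   `dist_tts`, `chromatin_type` appended.
#' @export
annotateTransgenes <- function(transgenes, gff, segmentation = NULL) {
  idx <- if (inherits(gff, "ElementIndex")) gff else buildElementIndex(gff)
  cls <- classifyElement(transgenes$chrom, transgenes$position, idx)
  dst <- nearestDistances(transgenes$chrom, transgenes$position, idx)
  out <- cbind(transgenes, cls, dst)
  out$chromatin_type <- if (is.null(segmentation)) "unassigned" else
    chromatinOverlap(transgenes$chrom, transgenes$position, segmentation)
  out
}

#' Element / chromatin enrichment among the most active transgenes
#'
#' For every gene-element category and chromatin type, compares the
#' proportion among all transgenes with the proportion among the
#' `topFraction` most active filtered transgenes and reports their
#' ratio, the fold-enrichment form used to describe position effects.
#'
#' @param annotated annotated transgene table (needs `element`,
#'   `chromatin_type`, `normalized_expression`, `barcode`).
#' @param topFraction fraction defining the most-active set (top set
#'   size `ceiling(topFraction * n)`).
#' @return data.frame: `category_type` (element / chromatin), `category`,
#'   `prop_all`, `prop_top`, `ratio` (NA when the baseline is 0).
#' @export
enrichmentReport <- function(annotated, topFraction = 0.10) {
  n <- nrow(annotated)
  if (n == 0L) stop("no transgenes to report on")
  nTop <- ceiling(topFraction * n)
  if (nTop == 0L) stop("top set is empty; supply a larger cohort")
  ord <- order(-annotated$normalized_expression, annotated$barcode)
  top <- annotated[ord[seq_len(nTop)], , drop = FALSE]
  oneBlock <- function(col, type) {
    cats <- sort(unique(annotated[[col]]))
    pAll <- vapply(cats, function(cc) mean(annotated[[col]] == cc), 0)
    pTop <- vapply(cats, function(cc) mean(top[[col]] == cc), 0)
    data.frame(category_type = type, category = cats, prop_all = pAll,
               prop_top = pTop,
               ratio = ifelse(pAll > 0, pTop / pAll, NA_real_),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  rbind(oneBlock("element", "element"),
        oneBlock("chromatin_type", "chromatin"))
}
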