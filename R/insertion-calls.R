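#' Parse mapping-library reads into (barcode, flank) pairs
#'
#' Extracts the promoter index and barcode from the index side of each
#' mapping read ([extractIndexBarcode()]), then recovers the genomic
#' flank: the sequence following the transposon-end anchor, truncated at
#' the first GATC (the DpnII site bases are retained) or, failing that,
#' at the start of read-through adapter sequence.  Paired layouts take
#' the barcode from R1 and the flank from R2; single-end layouts take
#' both from one read.  Rejections are reported per read, not raised:
#' reasons `"too_short"`, `"anchor_not_found"`,
#' `"ambiguous_base_in_barcode"`, `"flank_anchor_not_found"`,
#' `"flank_too_short"`.
#'
#' @param r1 character vector (or `DNAStringSet`) of reads: the index +
#'   barcode side.
#' @param r2 the flank side for paired layouts; `NULL` for single-end.
#' @param layout the mapping [readLayout()].
#' @param anchorMismatch substitutions allowed in either anchor.
#' @param minFlank minimum usable flank length (defaults to the aligner
#'   seed length, 20).
#' @return data.frame: `index`, `barcode`, `flank`, `reason`.
#' @export
parseMappingReads <- function(r1, r2 = NULL, layout = readLayout("mapping"),
                              anchorMismatch = 1L, minFlank = 20L) {
  stopifnot(layout$kind == "mapping")
  r1 <- toupper(as.character(r1))
  ext <- extractIndexBarcode(r1, layout, anchorMismatch)
  if (layout$paired) {
    if (is.null(r2)) stop("paired layout requires r2")
    flankSide <- toupper(as.character(r2))
    flankOffset <- 1L
  } else {
    flankSide <- r1
    flankOffset <- nchar(layout$constantPrefix) + layout$indexLength +
      layout$barcodeLength + 1L
  }
  anchor <- layout$transposonAnchor
  aw <- nchar(anchor)
  n <- length(r1)
  flank <- rep(NA_character_, n)
  reason <- ext$reason
  for (i in seq_len(n)) {
    if (reason[i] != "ok") next
    fs <- flankSide[i]
    if (nchar(fs) < flankOffset + aw - 1L) {
      reason[i] <- "flank_anchor_not_found"; next
    }
    got <- substr(fs, flankOffset, flankOffset + aw - 1L)
    if (hammingToRef(got, anchor) > anchorMismatch) {
      reason[i] <- "flank_anchor_not_found"; next
    }
    fl <- substr(fs, flankOffset + aw, nchar(fs))
    # truncate at the first DpnII site, keeping its 4 bases
    hit <- regexpr("GATC", fl, fixed = TRUE)
    if (hit > 0L) {
      fl <- substr(fl, 1L, hit + 3L)
    } else {
      # no GATC in view: strip read-through pad if present
      pad <- regexpr(substr(.padSequence, 1L, 10L), fl, fixed = TRUE)
      if (pad > 0L) fl <- substr(fl, 1L, pad - 1L)
    }
    if (nchar(fl) < minFlank) { reason[i] <- "flank_too_short"; next }
    flank[i] <- fl
  }
  data.frame(index = ext$index, barcode = ext$barcode, flank = flank,
             reason = reason, stringsAsFactors = FALSE)
}

#' Call one insertion locus per barcode
#'
#' Groups per-read candidate alignments by barcode and calls the top
#' locus: the (chrom, position, strand) supported by the most reads, ties
#' broken lexicographically by chromosome, then coordinate, then strand.
#' `reads_r` is the total number of mapping reads carrying the barcode --
#' including unalignable ones -- so `freq1_r` (top-locus reads / reads_r)
#' penalizes chimeric or ambiguous products.  A call passes the mapping
#' filter iff `reads_r >= readsRMin` and `freq1_r > freq1Min` (strict).
#'
#' @param alignments data.frame with one row per (read, candidate locus):
#'   columns `barcode`, `read_id`, `chrom`, `position`, `strand`.
#' @param totalReads data.frame (`barcode`, `reads`): all mapping reads
#'   per barcode, aligned or not.  Defaults to the number of distinct
#'   read ids per barcode in `alignments`.
#' @param readsRMin,freq1Min reliability thresholds (defaults 10 and
#'   0.60).
#' @return data.frame, one row per barcode: `barcode`, `chrom`,
#'   `position`, `strand`, `reads_r`, `freq1_r`,
#'   `passes_mapping_filter`.
#' @export
callInsertions <- function(alignments, totalReads = NULL,
                           readsRMin = 10L, freq1Min = 0.60) {
  al <- as.data.table(alignments)
  if (is.null(totalReads)) {
    totalReads <- al[, list(reads = length(unique(read_id))), by = "barcode"]
  }
  tot <- as.data.table(totalReads)
  if (nrow(al) == 0L)
    return(data.frame(barcode = character(0), chrom = character(0),
                      position = integer(0), strand = character(0),
                      reads_r = integer(0), freq1_r = numeric(0),
                      passes_mapping_filter = logical(0)))
  # support = number of distinct reads backing each locus
  sup <- al[, list(support = length(unique(read_id))),
            by = c("barcode", "chrom", "position", "strand")]
  setorder(sup, barcode, -support, chrom, position, strand)
  top <- sup[, .SD[1L], by = "barcode"]
  out <- merge(top, tot, by = "barcode", all.x = TRUE)
  out$freq1_r <- out$support / out$reads
  res <- data.frame(barcode = out$barcode, chrom = out$chrom,
                    position = out$position, strand = out$strand,
                    reads_r = out$reads, freq1_r = out$freq1_r,
                    passes_mapping_filter =
                      out$reads >= readsRMin & out$freq1_r > freq1Min,
                    stringsAsFactors = FALSE)
  res[order(res$barcode), , drop = FALSE]
}

#' Map a whole TRIP mapping library to insertion calls
#'
#' End-to-end mapping stage: parse reads ([parseMappingReads()]),
#' demultiplex indexes, correct barcodes against the collapsed barcode
#' set of the library itself ([collapseMutants()]), align each distinct
#' flank ([alignFlank()]) and call one locus per (promoter, barcode)
#' ([callInsertions()]).  Barcodes whose flanks never align are reported
#' in the `residuals` component rather than called.
#'
#' @param r1,r2 FASTQ paths (r2 = `NULL` for single-end layouts).
#' @param genome reference ([SyntheticGenome-class], `DNAStringSet` or
#'   FASTA path).
#' @param layout mapping [readLayout()].
#' @param k seed k-mer width.
#' @param maxMismatch substitutions allowed over a flank.
#' @param indexTable promoter-index table.
#' @param anchorMismatch,maxIndexMismatch,maxDistance,ratioThreshold
#'   extraction / demultiplex / collapse parameters.
#' @param readsRMin,freq1Min call reliability thresholds.
#' @param index optionally a prebuilt [KmerIndex-class] (overrides
#'   `genome`/`k`).
#' @return list: `calls` (per-barcode data.frame with `promoter`
#'   prepended), `residuals` (barcodes with reads but no alignable
#'   flank), `tallies` (read-accounting vector), `parsed` (per-read
#'   parse table).
#' @export
mapInsertions <- function(r1, r2 = NULL, genome, layout = readLayout("mapping"),
                          k = 20L, maxMismatch = 2L,
                          indexTable = promoterIndexTable(),
                          anchorMismatch = 1L, maxIndexMismatch = 1L,
                          maxDistance = 2L, ratioThreshold = 0.1,
                          readsRMin = 10L, freq1Min = 0.60,
                          index = NULL) {
  reads1 <- unlist(lapply(r1, function(f)
    as.character(readDNAStringSet(f, format = "fastq"))))
  reads2 <- if (!is.null(r2)) unlist(lapply(r2, function(f)
    as.character(readDNAStringSet(f, format = "fastq")))) else NULL
  parsed <- parseMappingReads(reads1, reads2, layout, anchorMismatch,
                              minFlank = k)
  parsed$promoter <- "unassigned"
  okIdx <- !is.na(parsed$index)
  parsed$promoter[okIdx] <- demultiplexIndex(parsed$index[okIdx], indexTable,
                                             maxIndexMismatch)

  # error-correct barcodes: collapse the mapping library's own counts and
  # apply the mutant -> genuine map to every read
  hasBc <- !is.na(parsed$barcode) & parsed$promoter != "unassigned"
  raw <- countBarcodes("mapping", parsed$promoter, parsed$barcode)
  col <- collapseMutants(raw, maxDistance, ratioThreshold)
  key <- paste(parsed$promoter[hasBc], parsed$barcode[hasBc], sep = "\r")
  mapKey <- paste(col$map$promoter, col$map$barcode, sep = "\r")
  corrected <- col$map$genuine[match(key, mapKey)]
  parsed$genuine <- NA_character_
  parsed$genuine[hasBc] <- corrected

  # reads_r: every mapping read carrying the (corrected) barcode
  withBc <- parsed[!is.na(parsed$genuine), , drop = FALSE]
  withBc$read_id <- seq_len(nrow(withBc))
  totalReads <- as.data.table(withBc)[, list(reads = .N),
                                      by = c("promoter", "genuine")]

  # align each distinct usable flank once
  if (is.null(index)) index <- buildKmerIndex(genome, k)
  usable <- withBc[withBc$reason == "ok" & !is.na(withBc$flank), ,
                   drop = FALSE]
  uniqFlanks <- unique(usable$flank)
  alnPer <- lapply(uniqFlanks, alignFlank, index = index,
                   maxMismatch = maxMismatch)
  names(alnPer) <- uniqFlanks

  candTab <- rbindlist(lapply(seq_along(uniqFlanks), function(j) {
    cand <- alnPer[[j]]
    if (nrow(cand) == 0L) return(NULL)
    data.table(flank = uniqFlanks[j], cand)
  }))
  if (!is.null(candTab) && nrow(candTab)) {
    aln <- merge(as.data.table(usable[, c("promoter", "genuine", "read_id",
                                          "flank")]),
                 candTab, by = "flank", allow.cartesian = TRUE)
    aln <- as.data.frame(aln)
    names(aln)[names(aln) == "genuine"] <- "barcode"
  } else {
    aln <- data.frame(promoter = character(0), barcode = character(0),
                      read_id = integer(0), chrom = character(0),
                      position = integer(0), strand = character(0))
  }

  # call per (promoter, barcode); fold promoter into the barcode key so
  # identical barcodes under different indexes stay distinct
  aln$pb <- paste(aln$promoter, aln$barcode, sep = "\r")
  totalReads$pb <- paste(totalReads$promoter, totalReads$genuine, sep = "\r")
  calls <- callInsertions(
    data.frame(barcode = aln$pb, read_id = aln$read_id, chrom = aln$chrom,
               position = aln$position, strand = aln$strand,
               stringsAsFactors = FALSE),
    totalReads = data.frame(barcode = totalReads$pb,
                            reads = totalReads$reads),
    readsRMin = readsRMin, freq1Min = freq1Min)
  split2 <- strsplit(calls$barcode, "\r", fixed = TRUE)
  calls <- data.frame(promoter = vapply(split2, `[`, "", 1L),
                      barcode = vapply(split2, `[`, "", 2L),
                      calls[, -1L], stringsAsFactors = FALSE)

  calledKey <- paste(calls$promoter, calls$barcode, sep = "\r")
  totDf <- as.data.frame(totalReads)
  resid <- totDf[!totDf$pb %in% calledKey,
                 c("promoter", "genuine", "reads"), drop = FALSE]
  names(resid) <- c("promoter", "barcode", "reads_r")

  reasons <- table(parsed$reason)
  list(calls = calls, residuals = as.data.frame(resid),
       tallies = c(processed = nrow(parsed),
                   setNames(as.integer(reasons), names(reasons))),
       parsed = parsed)
}
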