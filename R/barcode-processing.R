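#' Validate a promoter-index table against a mismatch tolerance
#'
#' Demultiplexing with up to `maxMismatch` substitutions is unambiguous
#' only if all indexes are pairwise at Hamming distance
#' >= 2 * maxMismatch + 1.  Violations raise a configuration error.
#'
#' @param table data.frame with columns `index`, `promoter`.
#' @param maxMismatch allowed substitutions during demultiplexing.
#' @return invisibly `TRUE` on success.
#' @export
validateIndexTable <- function(table, maxMismatch = 1L) {
  idx <- toupper(table$index)
  if (length(unique(nchar(idx))) != 1L)
    stop("all promoter indexes must have the same length")
  need <- 2L * maxMismatch + 1L
  d <- hammingMatrix(idx, idx)
  diag(d) <- NA
  if (any(d < need, na.rm = TRUE)) {
    bad <- which(d < need, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "promoter indexes %s and %s are at Hamming distance %d (< %d needed for max_mismatch = %d)",
      idx[bad[1L]], idx[bad[2L]], d[bad[1L], bad[2L]], need, maxMismatch))
  }
  invisible(TRUE)
}

#' Extract promoter index and barcode from reads
#'
#' Locates the layout's constant prefix at the start of each read
#' (allowing up to `anchorMismatch` substitutions) and returns the
#' following `indexLength` bases as the promoter index and the next
#' `barcodeLength` bases as the barcode, both uppercased.  Rejections are
#' data, not errors: each read gets a reason of `"ok"`, `"too_short"`,
#' `"anchor_not_found"` or `"ambiguous_base_in_barcode"`.
#'
#' @param reads character vector of read sequences (or a `DNAStringSet`).
#' @param layout a [readLayout()].
#' @param anchorMismatch substitutions tolerated inside the prefix.
#' @return data.frame with columns `index`, `barcode` (NA when rejected)
#'   and `reason`.
#' @examples
#' lay <- readLayout("normalization")
#' rd <- paste0(lay$constantPrefix, "TACAA", strrep("ACGT", 5), "AC")
#' extractIndexBarcode(rd, lay)
#' @export
extractIndexBarcode <- function(reads, layout, anchorMismatch = 1L) {
  reads <- toupper(as.character(reads))
  pw <- nchar(layout$constantPrefix)
  need <- pw + layout$indexLength + layout$barcodeLength
  n <- length(reads)
  index <- rep(NA_character_, n)
  barcode <- rep(NA_character_, n)
  reason <- rep("ok", n)

  tooShort <- nchar(reads) < need
  reason[tooShort] <- "too_short"
  ok <- !tooShort
  if (any(ok)) {
    pref <- substr(reads[ok], 1L, pw)
    anchorBad <- hammingToRef(pref, layout$constantPrefix) > anchorMismatch
    reason[ok][anchorBad] <- "anchor_not_found"
    keep <- which(ok)[!anchorBad]
    idx <- substr(reads[keep], pw + 1L, pw + layout$indexLength)
    bc <- substr(reads[keep], pw + layout$indexLength + 1L, need)
    amb <- grepl("[^ACGT]", bc)
    reason[keep][amb] <- "ambiguous_base_in_barcode"
    good <- keep[!amb]
    index[good] <- idx[!amb]
    barcode[good] <- bc[!amb]
  }
  data.frame(index = index, barcode = barcode, reason = reason,
             stringsAsFactors = FALSE)
}

#' Assign promoter indexes to promoters
#'
#' Maps each observed 5-bp index to the unique table entry within Hamming
#' distance `maxMismatch`; returns `"unassigned"` when no entry qualifies
#' or two entries tie at the minimal distance.  The table must satisfy the
#' separation invariant (see [validateIndexTable()]).
#'
#' @param indexes character vector of observed indexes (NA allowed).
#' @param table promoter-index table ([promoterIndexTable()] by default).
#' @param maxMismatch allowed substitutions.
#' @return character vector of promoter names or `"unassigned"`.
#' @examples
#' demultiplexIndex(c("TACAA", "TACGA", "NNNNN"))
#' @export
demultiplexIndex <- function(indexes, table = promoterIndexTable(),
                             maxMismatch = 1L) {
  validateIndexTable(table, maxMismatch)
  ref <- toupper(table$index)
  out <- rep("unassigned", length(indexes))
  okIdx <- which(!is.na(indexes) & nchar(indexes) == nchar(ref[1L]))
  if (length(okIdx)) {
    d <- hammingMatrix(toupper(indexes[okIdx]), ref)
    best <- apply(d, 1L, min)
    uniq <- rowSums(d == best) == 1L
    hit <- best <= maxMismatch & uniq
    out[okIdx[hit]] <- table$promoter[apply(d[hit, , drop = FALSE],
                                            1L, which.min)]
  }
  out
}

#' Count barcodes per library and promoter
#'
#' Exact multiset counting of extracted reads.  Reads with a failed
#' extraction (NA barcode) are tallied as malformed; reads whose index
#' did not demultiplex are tallied as unassigned.  The conservation
#' invariant `assigned + unassigned + malformed = processed` always
#' holds.
#'
#' @param libraryKind single string naming the library.
#' @param promoter character vector of promoter assignments (including
#'   `"unassigned"`).
#' @param barcode character vector of barcodes (NA = malformed read).
#' @return a list of class `"BarcodeCountTable"`: `counts` (data.table
#'   `library`, `promoter`, `barcode`, `count`) and `tallies` (named
#'   vector `processed`, `assigned`, `unassigned`, `malformed`).
#' @export
countBarcodes <- function(libraryKind, promoter, barcode) {
  stopifnot(length(promoter) == length(barcode))
  malformed <- is.na(barcode)
  unassigned <- !malformed & promoter == "unassigned"
  keep <- !malformed & !unassigned
  counts <- if (any(keep)) {
    dt <- data.table(library = libraryKind, promoter = promoter[keep],
                     barcode = barcode[keep])
    dt[, list(count = .N), by = c("library", "promoter", "barcode")]
  } else {
    data.table(library = character(0), promoter = character(0),
               barcode = character(0), count = integer(0))
  }
  setorder(counts, promoter, -count, barcode)
  structure(list(
    counts = counts,
    tallies = c(processed = length(barcode), assigned = sum(keep),
                unassigned = sum(unassigned), malformed = sum(malformed))
  ), class = "BarcodeCountTable")
}

#' @export
print.BarcodeCountTable <- function(x, ...) {
  t <- x$tallies
  cat(sprintf(
    "BarcodeCountTable: %d reads (%d assigned, %d unassigned, %d malformed), %d distinct (promoter, barcode)\n",
    t[["processed"]], t[["assigned"]], t[["unassigned"]], t[["malformed"]],
    nrow(x$counts)))
  invisible(x)
}

#' Collapse sequencing-error mutant barcodes into genuine barcodes
#'
#' Greedy directional collapse, the standard scheme for barcode/UMI error
#' correction: within each (library, promoter) stratum, barcodes are
#' visited in deterministic order (count descending, then lexicographic);
#' a barcode is merged into the highest-count already-genuine barcode
#' within Hamming distance `maxDistance` whose raw count satisfies
#' `mutant count < ratioThreshold x genuine count`.  Merged counts are
#' added to the genuine barcode, so total reads are conserved per
#' stratum.  The resulting map is idempotent and genuine barcodes never
#' map elsewhere.
#'
#' @param table a `BarcodeCountTable` from [countBarcodes()].
#' @param maxDistance maximal Hamming distance merged (default 2).
#' @param ratioThreshold count-ratio rule (default 0.1): a mutant must be
#'   rarer than a tenth of its target.
#' @return list: `table` (collapsed `BarcodeCountTable`) and `map`
#'   (data.table `library`, `promoter`, `barcode`, `genuine`, `distance`,
#'   `ratio`; identity rows have distance 0, ratio NA).
#' @export
collapseMutants <- function(table, maxDistance = 2L, ratioThreshold = 0.1) {
  counts <- table$counts
  if (nrow(counts) == 0L)
    return(list(table = table,
                map = data.table(library = character(0),
                                 promoter = character(0),
                                 barcode = character(0),
                                 genuine = character(0),
                                 distance = integer(0), ratio = numeric(0))))
  strata <- split(counts, paste(counts$library, counts$promoter, sep = "\r"))
  outCounts <- list(); outMap <- list()
  for (s in names(strata)) {
    st <- strata[[s]]
    setorder(st, -count, barcode)
    bc <- st$barcode; cnt <- as.numeric(st$count)
    m <- length(bc)
    target <- seq_len(m)     # index of the genuine barcode each maps to
    genuine <- rep(TRUE, m)
    if (m > 1L) {
      D <- hammingMatrix(bc, bc)
      for (i in 2:m) {
        cand <- which(genuine[seq_len(i - 1L)] &
                        D[i, seq_len(i - 1L)] <= maxDistance &
                        cnt[i] < ratioThreshold * cnt[seq_len(i - 1L)])
        if (length(cand)) {
          target[i] <- cand[1L]   # earliest = highest count
          genuine[i] <- FALSE
        }
      }
    }
    newCnt <- vapply(seq_len(m), function(i)
      sum(cnt[target == i]), numeric(1))
    keep <- which(genuine)
    outCounts[[s]] <- data.table(library = st$library[keep],
                                 promoter = st$promoter[keep],
                                 barcode = bc[keep],
                                 count = as.integer(newCnt[keep]))
    outMap[[s]] <- data.table(
      library = st$library, promoter = st$promoter, barcode = bc,
      genuine = bc[target], distance = 0L, ratio = NA_real_)
    merged <- which(!genuine)
    if (length(merged)) {
      outMap[[s]]$distance[merged] <- vapply(merged, function(i)
        hammingDist(bc[i], bc[target[i]]), integer(1))
      outMap[[s]]$ratio[merged] <- cnt[merged] / cnt[target[merged]]
    }
  }
  newCounts <- rbindlist(outCounts)
  setorder(newCounts, promoter, -count, barcode)
  tal <- table$tallies
  list(table = structure(list(counts = newCounts, tallies = tal),
                         class = "BarcodeCountTable"),
       map = rbindlist(outMap))
}

#' Process one FASTQ library into a collapsed barcode count table
#'
#' Convenience wrapper chaining [extractIndexBarcode()],
#' [demultiplexIndex()], [countBarcodes()] and [collapseMutants()] for a
#' whole library.
#'
#' @param fastq path(s) to FASTQ file(s) (plain or gzip).
#' @param layout the library's [readLayout()].
#' @param libraryKind library label stored in the table.
#' @param indexTable promoter-index table.
#' @param anchorMismatch,maxMismatch,maxDistance,ratioThreshold stage
#'   parameters (see the underlying functions).
#' @return list: `table` (collapsed `BarcodeCountTable`), `raw` (pre-
#'   collapse table), `map` (collapse audit), `extracted` (per-read
#'   extraction data.frame).
#' @export
processLibrary <- function(fastq, layout, libraryKind = layout$kind,
                           indexTable = promoterIndexTable(),
                           anchorMismatch = 1L, maxMismatch = 1L,
                           maxDistance = 2L, ratioThreshold = 0.1) {
  reads <- unlist(lapply(fastq, function(f)
    as.character(readDNAStringSet(f, format = "fastq"))))
  ext <- extractIndexBarcode(reads, layout, anchorMismatch)
  ext$promoter <- "unassigned"
  okRows <- !is.na(ext$index)
  ext$promoter[okRows] <- demultiplexIndex(ext$index[okRows], indexTable,
                                           maxMismatch)
  raw <- countBarcodes(libraryKind, ext$promoter, ext$barcode)
  col <- collapseMutants(raw, maxDistance, ratioThreshold)
  list(table = col$table, raw = raw, map = col$map, extracted = ext)
}
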