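#' Normalized transcriptional activity of a barcode
#'
#' The TRIP activity statistic: the ratio of a barcode's abundance among
#' transcripts to its abundance in the cell population, each expressed as
#' within-library parts-per-million, i.e.
#' `(expr_count / total_expr) / (norm_count / total_norm)` in arbitrary
#' units.  Scale-invariant in both library totals; zero iff the barcode
#' has no expression reads.
#'
#' @param exprCount,normCount per-barcode collapsed read counts in the
#'   expression and normalization libraries (`normCount` must be >= 1).
#' @param totalExpr,totalNorm library totals.
#' @return numeric vector of activities (a.u.).
#' @examples
#' normalizedExpression(100, 1e6, 50, 1e6)
#' @export
normalizedExpression <- function(exprCount, totalExpr, normCount, totalNorm) {
  stopifnot(all(normCount >= 1), totalExpr >= max(0, exprCount, na.rm = TRUE),
            totalNorm >= max(normCount))
  te <- if (totalExpr > 0) totalExpr else 1  # all-silent library: 0/te = 0
  (exprCount / te) / (normCount / totalNorm)
}

#' Build per-barcode expression records from two count tables
#'
#' Joins the collapsed normalization and expression counts on
#' (promoter, barcode).  Barcodes absent from the expression library get
#' `expr_count = 0`; barcodes seen only in the expression library have no
#' DNA evidence and are excluded (returned separately with reason
#' `no_dna_evidence`).  Parts-per-million are computed within each
#' library over its assigned, collapsed reads.
#'
#' @param normTable,exprTable collapsed `BarcodeCountTable`s (from
#'   [processLibrary()] / [collapseMutants()]).
#' @return list: `records` data.frame (`promoter`, `barcode`,
#'   `norm_count`, `expr_count`, `norm_ppm`, `expr_ppm`,
#'   `normalized_expression`, `passes_norm_filter` at the default
#'   threshold 5) and `excluded` (expression-only barcodes).
#' @export
buildExpressionRecords <- function(normTable, exprTable) {
  nc <- as.data.frame(normTable$counts)
  ec <- as.data.frame(exprTable$counts)
  totalNorm <- sum(nc$count)
  totalExpr <- sum(ec$count)
  key <- function(d) paste(d$promoter, d$barcode, sep = "\r")
  m <- match(key(nc), key(ec))
  rec <- data.frame(promoter = nc$promoter, barcode = nc$barcode,
                    norm_count = nc$count,
                    expr_count = ifelse(is.na(m), 0L, ec$count[m]),
                    stringsAsFactors = FALSE)
  rec$norm_ppm <- rec$norm_count / totalNorm * 1e6
  rec$expr_ppm <- rec$expr_count / max(totalExpr, 1L) * 1e6
  rec$normalized_expression <- normalizedExpression(
    rec$expr_count, totalExpr, rec$norm_count, totalNorm)
  rec$passes_norm_filter <- rec$norm_count >= 5L
  excluded <- ec[!key(ec) %in% key(nc), , drop = FALSE]
  excluded$reason <- if (nrow(excluded)) "no_dna_evidence" else character(0)
  rec <- rec[order(rec$promoter, rec$barcode), , drop = FALSE]
  rownames(rec) <- NULL
  list(records = rec, excluded = excluded)
}

#' Flag silent transgenes
#'
#' A transgene is silent iff its normalized expression does not exceed
#' the threshold; the default threshold 0 reads "completely silent" as
#' zero expression reads.
#'
#' @param records data.frame with a `normalized_expression` column.
#' @param silenceThreshold activity (a.u.) at or below which a transgene
#'   is silent.
#' @return `records` with an `is_silent` logical column.
#' @export
classifySilent <- function(records, silenceThreshold = 0) {
  records$is_silent <- records$normalized_expression <= silenceThreshold
  records
}

#' Apply the TRIP reliability filters
#'
#' Retains records satisfying all three reliability criteria:
#' `norm_count >= normMin` (enough gDNA evidence), `reads_r >= readsRMin`
#' and `freq1_r > freq1Min` (strict) from the mapping calls.  Barcodes
#' lacking an insertion call are dropped with reason `unmapped`.  A
#' barcode with two calls is a hard error (upstream guarantees
#' uniqueness).
#'
#' @param records expression records (see [buildExpressionRecords()]).
#' @param calls insertion calls with `promoter`, `barcode`, `chrom`,
#'   `position`, `strand`, `reads_r`, `freq1_r`.
#' @param normMin,readsRMin,freq1Min thresholds (defaults 5, 10, 0.60).
#' @return list: `transgenes` (retained, joined, ordered by promoter then
#'   barcode), `dropped` (with a `drop_reason` column).
#' @export
applyTripFilters <- function(records, calls, normMin = 5L,
                             readsRMin = 10L, freq1Min = 0.60) {
  key <- function(d) paste(d$promoter, d$barcode, sep = "\r")
  ck <- key(calls)
  if (anyDuplicated(ck))
    stop("duplicate insertion call for barcode(s): ",
         paste(head(calls$barcode[duplicated(ck)]), collapse = ", "))
  m <- match(key(records), ck)
  joined <- cbind(records,
                  calls[m, c("chrom", "position", "strand", "reads_r",
                             "freq1_r"), drop = FALSE])
  rownames(joined) <- NULL
  unmapped <- is.na(m)
  pass <- !unmapped &
    joined$norm_count >= normMin &
    joined$reads_r >= readsRMin &
    joined$freq1_r > freq1Min
  dropped <- joined[!pass, , drop = FALSE]
  dropped$drop_reason <- ifelse(unmapped[!pass], "unmapped", "failed_filter")
  out <- joined[pass, , drop = FALSE]
  out <- out[order(out$promoter, out$barcode), , drop = FALSE]
  rownames(out) <- NULL
  list(transgenes = out, dropped = dropped)
}

#' Per-promoter activity summary
#'
#' Summarizes filtered transgenes per promoter: totals, silent and
#' expressed counts, median and mean activity of the expressed records,
#' the fold by which the long EF-1a (reference) median exceeds each
#' promoter's median, and
#' the promoter composition of the top `topFraction` most active
#' records (top set size = `ceiling(topFraction * n)`, sorted by
#' activity descending with ties broken by barcode).
#'
#' @param records filtered transgene records with `promoter`,
#'   `normalized_expression`, `is_silent`.
#' @param topFraction fraction defining the most-active set (default
#'   0.10).
#' @param reference promoter whose median anchors the fold-ratios.
#' @return data.frame, one row per promoter present: `promoter`, `n`,
#'   `n_silent`, `n_expressed`, `median_expr`, `mean_expr`,
#'   `fold_vs_reference`, `top_decile_share`.  Promoters with no
#'   expressed records get NA statistics.
#' @export
promoterSummary <- function(records, topFraction = 0.10,
                            reference = "long_EF1a") {
  if (!"is_silent" %in% names(records)) records <- classifySilent(records)
  proms <- sort(unique(records$promoter))
  ord <- order(-records$normalized_expression, records$barcode)
  nTop <- ceiling(topFraction * nrow(records))
  topSet <- records[ord[seq_len(nTop)], , drop = FALSE]

  rows <- lapply(proms, function(p) {
    sub <- records[records$promoter == p, , drop = FALSE]
    expr <- sub[!sub$is_silent, , drop = FALSE]
    data.frame(promoter = p, n = nrow(sub), n_silent = sum(sub$is_silent),
               n_expressed = nrow(expr),
               median_expr = if (nrow(expr)) median(expr$normalized_expression) else NA_real_,
               mean_expr = if (nrow(expr)) mean(expr$normalized_expression) else NA_real_,
               top_decile_share = if (nTop > 0)
                 sum(topSet$promoter == p) / nTop else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  refMed <- out$median_expr[match(reference, out$promoter)]
  out$fold_vs_reference <- if (!is.null(refMed) && length(refMed) &&
                               !is.na(refMed) && refMed > 0)
    refMed / out$median_expr else NA_real_
  out
}
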