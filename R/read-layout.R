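#' Amplicon read layouts for the three TRIP libraries
#'
#' Describes how a sequencing read of each library is structured.
#' Normalization (gDNA) and expression (cDNA) reads carry a constant
#' upstream anchor, then the 5-bp promoter index immediately followed by
#' the 18-bp barcode.  Mapping (inverse-PCR) reads additionally carry the
#' genomic flank of the insertion: the sequence from the transposon end to
#' the first downstream GATC (the DpnII site that bounded the self-ligated
#' circle; the 4 site bases are retained).  Primer tails of the real
#' amplicons are deliberately not modeled: downstream code must not depend
#' on them.
#'
#' @param kind one of `"normalization"`, `"expression"`, `"mapping"`.
#' @param constantPrefix fixed anchor sequence preceding the index
#'   (>= 8 nt).
#' @param indexLength,barcodeLength index and barcode widths (nt).
#' @param readLength sequencing read length (default 75, as on a 2 x 75 bp
#'   platform).
#' @param paired mapping library only: emit read pairs (R1 = index +
#'   barcode side, R2 = genomic flank) instead of one concatenated read.
#' @param transposonAnchor fixed transposon-end sequence that precedes the
#'   genomic flank in mapping reads.
#' @return a list of class `"ReadLayout"`.
#' @examples
#' readLayout("normalization")
#' @export
readLayout <- function(kind = c("normalization", "expression", "mapping"),
                       constantPrefix = "GTCCTGCTAACGCTTCAG",
                       indexLength = 5L,
                       barcodeLength = 18L,
                       readLength = 75L,
                       paired = TRUE,
                       transposonAnchor = "CCTAGAAAGATA") {
  kind <- match.arg(kind)
  stopifnot(nchar(constantPrefix) >= 8L,
            readLength >= nchar(constantPrefix) + indexLength + barcodeLength)
  structure(list(kind = kind,
                 constantPrefix = toupper(constantPrefix),
                 indexLength = as.integer(indexLength),
                 barcodeLength = as.integer(barcodeLength),
                 readLength = as.integer(readLength),
                 paired = isTRUE(paired) && kind == "mapping",
                 transposonAnchor = toupper(transposonAnchor)),
            class = "ReadLayout")
}

#' @rdname readLayout
#' @param readLength,paired passed to [readLayout()] for each library.
#' @export
defaultLayouts <- function(readLength = 75L, paired = TRUE) {
  list(normalization = readLayout("normalization", readLength = readLength),
       expression = readLayout("expression", readLength = readLength),
       mapping = readLayout("mapping", readLength = readLength,
                            paired = paired))
}
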