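#' Assemble a pipeline run configuration
#'
#' Collects every stage parameter with the assay's standard defaults:
#' reliability thresholds `normMin = 5`, `readsRMin = 10`,
#' `freq1Min = 0.60`, aligner seed `k = 20`, motif window `W = 10`,
#' top-activity fraction 0.10.  With `simulate = TRUE` the run starts by
#' generating a synthetic genome and the three libraries; otherwise the
#' `fastq*`, `genomeFasta`, `gff` and `chromatinBed` paths must point at
#' existing inputs.
#'
#' @param outdir output directory for all stage TSVs.
#' @param seed integer seed governing every stochastic stage.
#' @param simulate generate inputs with the synthetic-data module.
#' @param chromSizes,gc,geneDensity,nInsertions,mix,silentFraction,
#'   depths,errorRate simulator settings (see [makeGenome()],
#'   [plantInsertions()], [simulateLibraries()]).
#' @param fastqNorm,fastqExpr,fastqMapR1,fastqMapR2,genomeFasta,gff,
#'   chromatinBed external inputs when `simulate = FALSE`.
#' @param k,maxMismatch aligner parameters.
#' @param anchorMismatch,indexMismatch,collapseMaxDistance,collapseRatio
#'   extraction and collapse parameters.
#' @param normMin,readsRMin,freq1Min reliability thresholds.
#' @param silenceThreshold activity at or below which a transgene is
#'   silent.
#' @param W motif flank width.
#' @param topFraction most-active fraction used in summaries.
#' @param readLength,paired simulated read geometry.
#' @return a list of class `"TripConfig"`.
#' @export
tripConfig <- function(outdir = tempfile("trip_run_"),
                       seed = 1L,
                       simulate = TRUE,
                       chromSizes = c(chr1 = 200000L, chr2 = 200000L),
                       gc = 0.45,
                       geneDensity = 1 / 10000,
                       nInsertions = 300L,
                       mix = c(long_EF1a = 7, short_EF1a = 7, mPGK = 7,
                               PGK = 1),
                       silentFraction = 0.5,
                       depths = c(normalization = 50, expression = 50,
                                  mapping = 20),
                       errorRate = 0.002,
                       fastqNorm = NULL, fastqExpr = NULL,
                       fastqMapR1 = NULL, fastqMapR2 = NULL,
                       genomeFasta = NULL, gff = NULL, chromatinBed = NULL,
                       k = 20L, maxMismatch = 2L,
                       anchorMismatch = 1L, indexMismatch = 1L,
                       collapseMaxDistance = 2L, collapseRatio = 0.1,
                       normMin = 5L, readsRMin = 10L, freq1Min = 0.60,
                       silenceThreshold = 0,
                       W = 10L, topFraction = 0.10,
                       readLength = 75L, paired = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "TripConfig"
  cfg
}

#' Validate pipeline inputs and parameters
#'
#' Non-throwing checks returning machine-readable diagnostics: missing
#' or unparseable input files, promoter-index tables violating the
#' separation needed for the configured mismatch tolerance, overlapping
#' chromatin segments, and out-of-range thresholds.  An empty result
#' means the configuration is runnable.
#'
#' @param config a `"TripConfig"`.
#' @param indexTable promoter-index table to check.
#' @return data.frame (`check`, `message`), zero rows when valid.
#' @export
validateInputs <- function(config, indexTable = promoterIndexTable()) {
  diag <- list()
  note <- function(check, message)
    diag[[length(diag) + 1L]] <<- data.frame(check = check,
                                             message = message)
  sep <- try(validateIndexTable(indexTable, config$indexMismatch),
             silent = TRUE)
  if (inherits(sep, "try-error"))
    note("index_table", conditionMessage(attr(sep, "condition")))
  if (config$normMin < 0) note("thresholds", "normMin must be >= 0")
  if (config$readsRMin < 1) note("thresholds", "readsRMin must be >= 1")
  if (config$freq1Min < 0 || config$freq1Min >= 1)
    note("thresholds", "freq1Min must lie in [0, 1)")
  if (config$topFraction <= 0 || config$topFraction > 1)
    note("thresholds", "topFraction must lie in (0, 1]")
  if (config$errorRate < 0 || config$errorRate >= 0.05)
    note("simulator", "errorRate must lie in [0, 0.05)")

  if (!config$simulate) {
    needFile <- function(path, what, reader) {
      if (is.null(path) || !all(file.exists(path))) {
        note(what, sprintf("missing %s file", what))
      } else {
        ok <- try(reader(path), silent = TRUE)
        if (inherits(ok, "try-error"))
          note(what, sprintf("%s does not parse: %s", what,
                             conditionMessage(attr(ok, "condition"))))
        ok
      }
    }
    needFile(config$genomeFasta, "fasta", readDNAStringSet)
    needFile(config$gff, "gff3", function(p) import(p, format = "gff3"))
    for (fq in list(config$fastqNorm, config$fastqExpr, config$fastqMapR1))
      needFile(fq, "fastq", function(p)
        readDNAStringSet(p[1L], format = "fastq", nrec = 10L))
    if (!is.null(config$chromatinBed)) {
      seg <- needFile(config$chromatinBed, "bed",
                      function(p) import(p, format = "bed"))
      if (is(seg, "GRanges")) {
        self <- findOverlaps(seg, seg)
        if (length(self) > length(seg))
          note("bed", "overlapping chromatin segments")
      }
    }
  }
  if (length(diag)) do.call(rbind, diag) else
    data.frame(check = character(0), message = character(0))
}

#' Run the whole TRIP pipeline
#'
#' Executes the stages in order -- simulate (optional), extract,
#' map, quantify, annotate, motif -- writing every stage table as a TSV
#' under `config$outdir`, and returns a run report consolidating the
#' headline summaries: transgene counts per promoter, silent/expressed
#' counts and median activities per promoter, element and chromatin
#' proportions for all vs the most-active transgenes, and median TSS/TTS
#' distances for both cohorts.  Deterministic for a fixed configuration
#' and seed.
#'
#' @param config a `"TripConfig"` from [tripConfig()].
#' @return invisibly, a list: `report` (summary tables + `parameters`
#'   echo), `transgenes`, `calls`, `records`, `annotated`, `motif`
#'   (a [MotifMatrix-class]), `files`, `log`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "TripConfig"))
  diags <- validateInputs(config)
  if (nrow(diags))
    stop("invalid configuration: ",
         paste(diags$check, diags$message, sep = ": ", collapse = "; "))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  layouts <- defaultLayouts(config$readLength, config$paired)

  ## stage: simulate (or take external inputs)
  if (config$simulate) {
    genome <- makeGenome(config$chromSizes, gc = config$gc,
                         geneDensity = config$geneDensity,
                         seed = config$seed)
    truth <- plantInsertions(genome, config$nInsertions, mix = config$mix,
                             silentFraction = config$silentFraction,
                             seed = config$seed + 1L)
    sim <- simulateLibraries(truth, genome,
                             file.path(config$outdir, "sim"),
                             layouts = layouts, depths = config$depths,
                             errorRate = config$errorRate,
                             minFlank = config$k,
                             seed = config$seed + 2L)
    gfiles <- writeGenome(genome, file.path(config$outdir, "sim"))
    fastqNorm <- sim$files$normalization
    fastqExpr <- sim$files$expression
    fastqMapR1 <- if (config$paired) sim$files$mapping_R1 else
      sim$files$mapping
    fastqMapR2 <- if (config$paired) sim$files$mapping_R2 else NULL
    genomeSrc <- genome
    gffSrc <- gfiles$gff3
    bedSrc <- gfiles$bed
    log$simulate <- sim$log
  } else {
    fastqNorm <- config$fastqNorm; fastqExpr <- config$fastqExpr
    fastqMapR1 <- config$fastqMapR1; fastqMapR2 <- config$fastqMapR2
    genomeSrc <- config$genomeFasta
    gffSrc <- config$gff
    bedSrc <- config$chromatinBed
  }

  ## stage: extract + collapse the counting libraries
  norm <- processLibrary(fastqNorm, layouts$normalization,
                         anchorMismatch = config$anchorMismatch,
                         maxMismatch = config$indexMismatch,
                         maxDistance = config$collapseMaxDistance,
                         ratioThreshold = config$collapseRatio)
  expr <- processLibrary(fastqExpr, layouts$expression,
                         anchorMismatch = config$anchorMismatch,
                         maxMismatch = config$indexMismatch,
                         maxDistance = config$collapseMaxDistance,
                         ratioThreshold = config$collapseRatio)
  log$extract <- list(normalization = norm$table$tallies,
                      expression = expr$table$tallies)
  writeTsv(as.data.frame(norm$table$counts),
           file.path(config$outdir, "counts_normalization.tsv"))
  writeTsv(as.data.frame(expr$table$counts),
           file.path(config$outdir, "counts_expression.tsv"))

  ## stage: map
  mapped <- mapInsertions(fastqMapR1, fastqMapR2, genome = genomeSrc,
                          layout = layouts$mapping, k = config$k,
                          maxMismatch = config$maxMismatch,
                          anchorMismatch = config$anchorMismatch,
                          maxIndexMismatch = config$indexMismatch,
                          maxDistance = config$collapseMaxDistance,
                          ratioThreshold = config$collapseRatio,
                          readsRMin = config$readsRMin,
                          freq1Min = config$freq1Min)
  log$map <- mapped$tallies
  writeTsv(mapped$calls, file.path(config$outdir, "insertions.tsv"))
  writeTsv(mapped$residuals, file.path(config$outdir,
                                       "mapping_residuals.tsv"))

  ## stage: quantify
  recs <- buildExpressionRecords(norm$table, expr$table)
  records <- classifySilent(recs$records, config$silenceThreshold)
  filt <- applyTripFilters(records, mapped$calls,
                           normMin = config$normMin,
                           readsRMin = config$readsRMin,
                           freq1Min = config$freq1Min)
  transgenes <- filt$transgenes
  promSummary <- if (nrow(transgenes)) promoterSummary(
    transgenes, config$topFraction) else NULL
  writeTsv(records, file.path(config$outdir, "expression_records.tsv"))
  writeTsv(transgenes, file.path(config$outdir, "transgenes.tsv"))
  if (!is.null(promSummary))
    writeTsv(promSummary, file.path(config$outdir, "promoter_summary.tsv"))
  log$quantify <- c(records = nrow(records), retained = nrow(transgenes),
                    dropped = nrow(filt$dropped))

  ## stage: annotate
  annotated <- annotateTransgenes(transgenes, gffSrc, bedSrc)
  enrich <- if (nrow(annotated)) enrichmentReport(annotated,
                                                  config$topFraction) else NULL
  writeTsv(annotated, file.path(config$outdir, "transgenes_annotated.tsv"))
  if (!is.null(enrich))
    writeTsv(enrich, file.path(config$outdir, "enrichment.tsv"))

  ## stage: motif (all called insertions)
  windows <- extractWindows(mapped$calls, genomeSrc, W = config$W)
  motif <- if (length(windows)) motifMatrix(
    windows, genomeBackground(genomeSrc)) else NULL
  if (!is.null(motif))
    writeMotifTsv(motif, file.path(config$outdir, "motif.tsv"))

  ## run report
  nTop <- ceiling(config$topFraction * nrow(annotated))
  ordA <- order(-annotated$normalized_expression, annotated$barcode)
  topA <- annotated[ordA[seq_len(nTop)], , drop = FALSE]
  report <- list(
    parameters = config[setdiff(names(config), "outdir")],
    promoter_counts = as.data.frame(table(
      promoter = mapped$calls$promoter), stringsAsFactors = FALSE),
    promoter_summary = promSummary,
    enrichment = enrich,
    distance_medians = data.frame(
      cohort = c("all", "top"),
      median_dist_tss = c(median(annotated$dist_tss),
                          median(topA$dist_tss)),
      median_dist_tts = c(median(annotated$dist_tts),
                          median(topA$dist_tts))),
    log = log
  )
  invisible(list(report = report, transgenes = transgenes,
                 calls = mapped$calls, records = records,
                 annotated = annotated, motif = motif,
                 residuals = mapped$residuals,
                 files = list(outdir = config$outdir), log = log))
}
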