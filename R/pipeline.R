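#' Parse a structure key back into a DimerStructure
#'
#' Inverse of [structureKey()]: \code{"M1;M2|+-|3"} gives the structure with
#' motifs M1, M2, orientation (+,-) and spacing 3.
#'
#' @param key Character vector of structure keys.
#' @return List of [DimerStructure-class] objects.
#' @export
parseStructureKey <- function(key) {
  lapply(key, function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    if (length(parts) != 3L)
      stop("parseStructureKey(): malformed key '", k, "'")
    ids <- strsplit(parts[1], ";", fixed = TRUE)[[1]]
    ori <- strsplit(parts[2], "")[[1]]
    new("DimerStructure", pwmA = ids[1], pwmB = ids[2],
        orientation = ori, spacing = as.integer(parts[3]))
  })
}

#' Full dimer-discovery stage on in-memory objects
#'
#' Runs the open-chromatin dimer search end to end: per-replicate top-signal
#' peak selection, majority masking, replicate union per cell type, genome
#' scanning of every motif at its balanced threshold, hit masking,
#' enumeration of dimer instances for every unordered motif pair, and
#' cell-type-specific overrepresentation testing.
#'
#' @param pwms Named list of [PWM-class] objects.
#' @param genome Named character vector of chromosome sequences.
#' @param regions GRanges of open-chromatin peaks (\code{signalValue},
#'   \code{cellType}, \code{replicate} metadata).
#' @param mask Optional GRanges of masked intervals (exons, repeats).
#' @param regionCount Top peaks kept per replicate (default 50000).
#' @param maxGap Bound on |spacing| (default 50).
#' @param ratio Balanced-threshold FPR/FNR ratio (default 100).
#' @param binWidth Score discretisation (default 0.1 bits).
#' @param minTargetInstances Minimum target-count for testing (default 1).
#' @return List with \code{thresholds}, \code{hits}, \code{regions} (the
#'   merged per-cell-type region set), \code{instances}, \code{openBp},
#'   \code{enrichment}.
#' @export
discoverDimers <- function(pwms, genome, regions, mask = NULL,
                           regionCount = 50000, maxGap = 50, ratio = 100,
                           binWidth = 0.1, minTargetInstances = 1) {
  if (is.null(names(pwms)) || any(!nzchar(names(pwms))))
    names(pwms) <- vapply(pwms, pwmId, "")
  widths <- vapply(pwms, pwmWidth, 0L)
  sel <- selectTopRegions(regions, regionCount)
  if (!is.null(mask)) sel <- applyMasking(sel, mask)
  # replicates of one cell type merge by interval union
  merged <- do.call(c, unname(lapply(
    split(sel, sel$cellType), function(r) {
      u <- GenomicRanges::reduce(r)
      u$cellType <- r$cellType[1]
      u
    })))
  thresholds <- vapply(pwms, balancedThreshold, 0,
                       ratio = ratio, binWidth = binWidth)
  hits <- do.call(rbind, lapply(names(genome), function(chrom)
    scanWithPWMs(pwms, genome[[chrom]], thresholds = thresholds,
                 seqId = chrom)))
  if (!is.null(mask)) hits <- maskHits(hits, mask, widths)
  ids <- sort(names(pwms))
  pairIdx <- which(upper.tri(matrix(0, length(ids), length(ids)),
                             diag = TRUE), arr.ind = TRUE)
  instances <- do.call(rbind, lapply(seq_len(nrow(pairIdx)), function(i) {
    a <- ids[pairIdx[i, "row"]]; b <- ids[pairIdx[i, "col"]]
    findDimerInstances(hits[hits$pwmId == a, , drop = FALSE],
                       hits[hits$pwmId == b, , drop = FALSE],
                       merged, maxGap = maxGap, widths = widths)
  }))
  openBp <- openChromatinBp(merged)
  enrichment <- testOverrepresentation(instances, openBp,
                                       minTargetInstances)
  list(thresholds = thresholds, hits = hits, regions = merged,
       instances = instances, openBp = openBp, enrichment = enrichment)
}

#' Match enriched structures against the enhanceosome arrangement
#'
#' For each structure, finds enhanceosome hit pairs within the spacing
#' tolerance and classifies them into the four dimer types.
#'
#' @param structures List of [DimerStructure-class] (or character keys).
#' @param pwms Named list of [PWM-class] objects.
#' @param enhanceosome An [EnhanceosomeSequence-class]; default the built-in
#'   human sequence.
#' @param tolerance Spacing tolerance in bp (default 2).
#' @param layout Binding-site layout table (default [defaultLayout()]).
#' @param thresholds,ratio Passed to [mapEnhanceosomeHits()].
#' @return Data frame of arrangement matches with a \code{dimerType} column.
#' @export
matchEnhanceosome <- function(structures, pwms,
                              enhanceosome = builtinSequences()$human,
                              tolerance = 2, layout = defaultLayout(),
                              thresholds = NULL, ratio = 100) {
  if (is.character(structures)) structures <- parseStructureKey(structures)
  if (is.null(names(pwms)) || any(!nzchar(names(pwms))))
    names(pwms) <- vapply(pwms, pwmId, "")
  widths <- vapply(pwms, pwmWidth, 0L)
  enhHits <- mapEnhanceosomeHits(pwms, enhanceosome,
                                 thresholds = thresholds, ratio = ratio)
  out <- do.call(rbind, lapply(structures, function(s)
    matchStructure(s, enhHits, tolerance = tolerance, widths = widths)))
  if (is.null(out) || !nrow(out)) {
    out <- data.frame(startA = integer(0), startB = integer(0),
                      strandA = character(0), strandB = character(0),
                      pwmA = character(0), pwmB = character(0),
                      enhSpacing = integer(0), delta = integer(0),
                      structure = character(0), dimerType = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out$dimerType <- vapply(seq_len(nrow(out)), function(i)
    classifyDimerType(out[i, ], layout, widths), "")
  rownames(out) <- NULL
  out
}

#' @noRd
configHash <- function(config) {
  flat <- paste(names(unlist(config)), unlist(config), sep = "=",
                collapse = ";")
  h <- fnv1a(flat)   # double in [0, 2^32): format as hex in 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' @noRd
writeStamped <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# enhanceodimer config=%s seed=%s", hash,
                     format(seed)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
readStamped <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the enabled stages in order (scan, discover, match, context,
#' xspecies) from file inputs, writing one TSV per product into
#' \code{outDir}. Every output starts with a \code{#} header line carrying a
#' hash of the configuration and the seed, so identical configurations can
#' be recognised by identical files.
#'
#' Config fields (paths unless noted): \code{pwms} (TRANSFAC file),
#' \code{genome} (FASTA), \code{peaks} (data frame with \code{path},
#' \code{cellType}, \code{replicate}), \code{mask} (BED3, optional),
#' \code{genes} (gene TSV), \code{chromhmm} (BED4), \code{enhancers} (BED3,
#' optional), \code{orthologs}/\code{goH}/\code{goM}/\code{genesH}/
#' \code{genesM} (xspecies inputs), \code{enhanceosome} ("human", "mouse" or
#' a FASTA path; default "human"), and scalars \code{seed}, \code{stages}
#' (character vector), \code{ratio} (100), \code{tolerance} (2),
#' \code{regionCount} (50000), \code{maxGap} (50), \code{fdr} (0.01).
#'
#' @param config Named list as above, or a path to a JSON file with the
#'   same fields.
#' @param outDir Output directory (created if missing).
#' @return Named list of output file paths, invisibly.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("runPipeline(): jsonlite needed to read a JSON config")
    config <- jsonlite::fromJSON(config, simplifyDataFrame = TRUE)
  }
  stages <- config$stages %||% c("scan", "discover", "match", "context")
  if (!length(stages)) stop("runPipeline(): no stages enabled")
  known <- c("scan", "discover", "match", "context", "xspecies")
  if (!all(stages %in% known))
    stop("runPipeline(): unknown stage(s): ",
         paste(setdiff(stages, known), collapse = ", "))
  needs <- list(
    scan = c("pwms", "genome"), discover = c("pwms", "genome", "peaks"),
    match = c("pwms", "genome", "peaks"),
    context = c("pwms", "genome", "peaks", "genes", "chromhmm"),
    xspecies = c("orthologs", "goH", "goM", "genesH", "genesM"))
  missing <- setdiff(unique(unlist(needs[stages])), names(config))
  if (length(missing))
    stop("runPipeline(): missing config inputs: ",
         paste(missing, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  ratio <- config$ratio %||% 100
  tolerance <- config$tolerance %||% 2
  regionCount <- config$regionCount %||% 50000
  maxGap <- config$maxGap %||% 50
  fdr <- config$fdr %||% 0.01
  hash <- configHash(config)
  outputs <- list()
  emit <- function(df, name) {
    p <- file.path(outDir, name)
    writeStamped(df, p, hash, seed)
    outputs[[name]] <<- p
    p
  }

  pwms <- NULL; genome <- NULL
  if (any(stages %in% c("scan", "discover", "match", "context"))) {
    pwms <- readTransfac(config$pwms)
    names(pwms) <- vapply(pwms, pwmId, "")
    fa <- Biostrings::readDNAStringSet(config$genome)
    genome <- setNames(as.character(fa), names(fa))
  }
  mask <- if (!is.null(config$mask)) {
    bed <- read.table(config$mask, sep = "\t")
    GenomicRanges::GRanges(bed[[1]],
                           IRanges::IRanges(bed[[2]] + 1L, bed[[3]]))
  }

  disc <- NULL
  if ("scan" %in% stages) {
    thresholds <- vapply(pwms, balancedThreshold, 0, ratio = ratio)
    hits <- do.call(rbind, lapply(names(genome), function(chrom)
      scanWithPWMs(pwms, genome[[chrom]], thresholds = thresholds,
                   seqId = chrom)))
    emit(data.frame(pwmId = names(thresholds), threshold = thresholds),
         "thresholds.tsv")
    emit(hits, "hits.tsv")
  }
  if (any(stages %in% c("discover", "match", "context"))) {
    peaks <- config$peaks
    regions <- do.call(c, lapply(seq_len(nrow(peaks)), function(i)
      readNarrowPeak(peaks$path[i], peaks$cellType[i], peaks$replicate[i])))
    disc <- discoverDimers(pwms, genome, regions, mask = mask,
                           regionCount = regionCount, maxGap = maxGap,
                           ratio = ratio)
    emit(disc$instances, "instances.tsv")
    emit(disc$enrichment, "enrich.tsv")
  }
  if ("match" %in% stages) {
    sig <- disc$enrichment[disc$enrichment$q < fdr, , drop = FALSE]
    keys <- unique(sig$structure)
    enh <- config$enhanceosome %||% "human"
    enhSeq <- if (enh %in% c("human", "mouse")) builtinSequences()[[enh]]
    else as.character(Biostrings::readDNAStringSet(enh))[[1]]
    matches <- matchEnhanceosome(keys, pwms, enhanceosome = enhSeq,
                                 tolerance = tolerance, ratio = ratio)
    emit(matches, "matches.tsv")
    emit(spacingSummary(matches), "spacing_summary.tsv")
  }
  if ("context" %in% stages) {
    gm <- readGenesTsv(config$genes)
    segments <- readChromHmm(config$chromhmm)
    inst <- annotateNearestGene(disc$instances, gm$genes)
    inst$state <- assignState(inst, segments)
    emit(inst, "context.tsv")
    p0 <- gplusFraction(segments)
    gb <- gplusBinomial(inst$state, p0)
    summ <- data.frame(
      metric = c("withinGenePercent", "gplusK", "gplusN", "gplusP0",
                 "gplusPValue"),
      value = c(if (nrow(inst)) withinGeneFraction(inst) else NA,
                gb$k, gb$n, p0, gb$pValue))
    if (!is.null(config$enhancers)) {
      bed <- read.table(config$enhancers, sep = "\t")
      enh <- GenomicRanges::GRanges(bed[[1]],
                                    IRanges::IRanges(bed[[2]] + 1L,
                                                     bed[[3]]))
      eo <- enhancerOverlapFraction(inst, enh)
      summ <- rbind(summ, data.frame(
        metric = c("enhancerK", "enhancerN", "enhancerPercent"),
        value = c(eo$k, eo$n, eo$percent)))
    }
    emit(summ, "context_summary.tsv")
  }
  if ("xspecies" %in% stages) {
    rO <- readOrthologs(config$orthologs)
    annH <- readGoAnnotations(config$goH)
    annM <- readGoAnnotations(config$goM)
    gH <- readLines(config$genesH); gH <- gH[nzchar(gH)]
    gM <- readLines(config$genesM); gM <- gM[nzchar(gM)]
    uniH <- sort(unique(annH$gene)); uniM <- sort(unique(annM$gene))
    eH <- goEnrichment(intersect(gH, uniH), uniH, annH, fdr = fdr)
    eM <- goEnrichment(intersect(gM, uniM), uniM, annM, fdr = fdr)
    termUniverse <- sort(unique(c(annH$term, annM$term)))
    ts <- compareTermSets(termSetOf(eH), termSetOf(eM), termUniverse)
    gs <- compareGeneSets(intersect(gH, uniH), intersect(gM, uniM), rO,
                          uniH, uniM)
    emit(rbind(cbind(species = "human", eH), cbind(species = "mouse", eM)),
         "xspecies_terms.tsv")
    emit(data.frame(
      metric = c("termFisherP", "termFisherMinusLog10P", "geneFisherP",
                 "geneFisherMinusLog10P", "linkedBlocksH", "linkedBlocksM",
                 "universeBlocks"),
      value = c(ts$p, ts$minusLog10P, gs$p, gs$minusLog10P, gs$a,
                gs$aPrime, gs$N)), "xspecies_summary.tsv")
  }
  invisible(outputs)
}

#' Summarise a pipeline run directory
#'
#' Rebuilds the report tables from the TSVs of a [runPipeline()] run: the
#' structure-by-cell-type breakdown of significant dimers, the within-gene
#' fraction per structure, the spacing-difference-by-type contingency and
#' the chromatin-state-group histogram. Percentages recompute from the
#' stored counts. Missing products give empty tables, never an error.
#'
#' @param runDir Directory written by [runPipeline()].
#' @param fdr Significance cutoff on q for the breakdown (default 0.01).
#' @return Named list of data frames: \code{breakdown}, \code{withinGene},
#'   \code{spacing}, \code{states}.
#' @export
summarizeRun <- function(runDir, fdr = 0.01) {
  empty <- data.frame()
  out <- list(breakdown = empty, withinGene = empty, spacing = empty,
              states = empty)
  enrichPath <- file.path(runDir, "enrich.tsv")
  if (file.exists(enrichPath)) {
    enrich <- readStamped(enrichPath)
    sig <- enrich[!is.na(enrich$q) & enrich$q < fdr, , drop = FALSE]
    if (nrow(sig)) {
      tab <- table(sig$structure)
      out$breakdown <- data.frame(structure = names(tab),
                                  nCellTypes = as.integer(tab),
                                  stringsAsFactors = FALSE)
      out$breakdown <- out$breakdown[order(-out$breakdown$nCellTypes), ,
                                     drop = FALSE]
      rownames(out$breakdown) <- NULL
    }
  }
  ctxPath <- file.path(runDir, "context.tsv")
  if (file.exists(ctxPath)) {
    ctx <- readStamped(ctxPath)
    if (nrow(ctx)) {
      bySt <- split(ctx$withinGene, ctx$structure)
      out$withinGene <- data.frame(
        structure = names(bySt),
        withinGene = vapply(bySt, sum, 0L),
        total = vapply(bySt, length, 0L), stringsAsFactors = FALSE)
      out$withinGene$percent <- percentOf(out$withinGene$withinGene,
                                          out$withinGene$total)
      rownames(out$withinGene) <- NULL
      grp <- ifelse(ctx$state %in% gplusStates(), ctx$state, "G-minus")
      tab <- table(grp)
      out$states <- data.frame(stateGroup = names(tab),
                               count = as.integer(tab),
                               stringsAsFactors = FALSE)
    }
  }
  spPath <- file.path(runDir, "spacing_summary.tsv")
  if (file.exists(spPath)) out$spacing <- readStamped(spPath)
  out
}
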