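#' Read an ENCODE narrowPeak (BED6+4) file of open-chromatin peaks
#'
#' @param path Path to a narrowPeak file (10 whitespace-separated columns:
#'   chrom, start, end, name, score, strand, signalValue, pValue, qValue,
#'   peak; 0-based half-open coordinates).
#' @param cellType Cell-type label attached to every region.
#' @param replicate Replicate label attached to every region.
#' @return A [GenomicRanges::GRanges] with metadata columns
#'   \code{signalValue}, \code{cellType}, \code{replicate}. Coordinates are
#'   converted to the 1-based closed convention GRanges uses; widths are
#'   preserved.
#' @examples
#' f <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t200\t.\t0\t.\t5.5\t-1\t-1\t50", f)
#' readNarrowPeak(f, "K562", "rep1")
#' @export
readNarrowPeak <- function(path, cellType = "unknown", replicate = "rep1") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(GenomicRanges::GRanges(signalValue = numeric(0),
                                  cellType = character(0),
                                  replicate = character(0)))
  toks <- strsplit(lines, "[ \t]+")
  ncols <- lengths(toks)
  bad <- which(ncols < 10L)
  if (length(bad))
    stop(sprintf("readNarrowPeak(): line %d has %d columns (10 required)",
                 bad[1L], ncols[bad[1L]]))
  chrom <- vapply(toks, `[[`, "", 1L)
  start <- as.numeric(vapply(toks, `[[`, "", 2L))
  end <- as.numeric(vapply(toks, `[[`, "", 3L))
  signal <- as.numeric(vapply(toks, `[[`, "", 7L))
  if (anyNA(start) || anyNA(end) || anyNA(signal))
    stop("readNarrowPeak(): non-numeric coordinate or signalValue in ", path)
  badrec <- which(start >= end)
  if (length(badrec))
    stop(sprintf("readNarrowPeak(): line %d has start >= end", badrec[1L]))
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    signalValue = signal, cellType = cellType, replicate = replicate
  )
}

#' Keep the top-signal peaks of each replicate
#'
#' Per replicate, retains the \code{count} regions with highest
#' \code{signalValue} (all of them when fewer are present, hence "up to").
#' Ties are broken by (chrom, start) ascending, so the selection is stable
#' across runs and idempotent.
#'
#' @param regions GRanges from [readNarrowPeak()] (needs \code{signalValue}
#'   and \code{replicate} metadata columns).
#' @param count Maximum number of peaks to keep per replicate; default 50000.
#' @return The selected subset, original order within each replicate restored
#'   by genomic position.
#' @export
selectTopRegions <- function(regions, count = 50000) {
  stopifnot(count >= 1)
  if (!length(regions)) return(regions)
  key <- paste(regions$cellType, regions$replicate, sep = "\r")
  keep <- unlist(lapply(split(seq_along(regions), key), function(idx) {
    r <- regions[idx]
    o <- order(-r$signalValue, as.character(GenomicRanges::seqnames(r)),
               GenomicRanges::start(r))
    idx[head(o, count)]
  }), use.names = FALSE)
  out <- regions[sort(keep)]
  out
}

#' Drop peaks whose sequence is mostly masked
#'
#' A region is excluded iff strictly more than half of its bases fall in the
#' mask ("Majority" policy); surviving regions are returned unchanged, with
#' no trimming.
#'
#' @param regions GRanges of open-chromatin peaks.
#' @param mask GRanges of masked intervals (e.g. exons plus repeats), same
#'   assembly.
#' @param policy Only \code{"Majority"} is implemented.
#' @return The surviving subset of \code{regions}.
#' @export
applyMasking <- function(regions, mask, policy = "Majority") {
  policy <- match.arg(policy, "Majority")
  if (!length(regions) || !length(mask)) return(regions)
  maskR <- GenomicRanges::reduce(mask)
  ov <- GenomicRanges::findOverlaps(regions, maskR)
  coveredBp <- numeric(length(regions))
  if (length(ov)) {
    inter <- IRanges::pintersect(regions[S4Vectors::queryHits(ov)],
                                 maskR[S4Vectors::subjectHits(ov)])
    bp <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(ov), sum)
    coveredBp[as.integer(names(bp))] <- bp
  }
  regions[coveredBp <= GenomicRanges::width(regions) / 2]
}

#' Remove motif hits overlapping a masked interval set
#'
#' @param hits Motif-hit data frame (genomic coordinates in \code{seqId} /
#'   \code{start}, 0-based) as produced by [scanSequence()] on a chromosome.
#' @param mask GRanges of masked intervals.
#' @param widths Named vector of motif widths by pwmId.
#' @return The subset of hits not overlapping the mask.
#' @export
maskHits <- function(hits, mask, widths) {
  if (!nrow(hits) || !length(mask)) return(hits)
  gr <- GenomicRanges::GRanges(hits$seqId,
                               IRanges::IRanges(start = hits$start + 1L,
                                                width = widths[hits$pwmId]))
  keep <- !IRanges::overlapsAny(gr, mask)
  hits[keep, , drop = FALSE]
}

#' Enumerate dimer instances from two motif hit sets
#'
#' Pairs every a-hit with every b-hit lying inside the same open region with
#' gap at most \code{maxGap} in absolute value, reduces each pair to its
#' canonical [DimerStructure-class] form, and records the genomic interval
#' covering both hits. Spacing is end-to-start: the gap in bp between the
#' end of the upstream hit and the start of the downstream hit (negative =
#' overlap). For a homodimer (same PWM) pairs are unordered and a hit never
#' pairs with itself.
#'
#' @param hitsA,hitsB Motif-hit data frames (genomic: \code{seqId} is the
#'   chromosome, \code{start} 0-based).
#' @param regions GRanges of open regions; an instance must lie entirely
#'   within one region and carries that region's \code{cellType}.
#' @param maxGap Bound on |spacing| in bp (default 50).
#' @param widths Named vector of motif widths by pwmId.
#' @return Data frame of dimer instances: \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{pwmA}, \code{pwmB},
#'   \code{strandA}, \code{strandB}, \code{spacing}, \code{structure} (key
#'   string), \code{cellType}, \code{canonicalStrand}.
#' @export
findDimerInstances <- function(hitsA, hitsB, regions, maxGap = 50, widths) {
  emptyOut <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), pwmA = character(0),
                         pwmB = character(0), strandA = character(0),
                         strandB = character(0), spacing = integer(0),
                         structure = character(0), cellType = character(0),
                         canonicalStrand = character(0),
                         stringsAsFactors = FALSE)
  if (!nrow(hitsA) || !nrow(hitsB) || !length(regions)) return(emptyOut)
  homodimer <- identical(sort(unique(hitsA$pwmId)), sort(unique(hitsB$pwmId))) &&
    length(unique(c(hitsA$pwmId, hitsB$pwmId))) == 1L
  asGR <- function(h) GenomicRanges::GRanges(
    h$seqId, IRanges::IRanges(start = h$start + 1L, width = widths[h$pwmId]))
  grA <- asGR(hitsA); grB <- asGR(hitsB)
  ovA <- GenomicRanges::findOverlaps(grA, regions, type = "within")
  ovB <- GenomicRanges::findOverlaps(grB, regions, type = "within")
  if (!length(ovA) || !length(ovB)) return(emptyOut)
  rows <- list()
  byRegA <- split(S4Vectors::queryHits(ovA), S4Vectors::subjectHits(ovA))
  byRegB <- split(S4Vectors::queryHits(ovB), S4Vectors::subjectHits(ovB))
  for (reg in intersect(names(byRegA), names(byRegB))) {
    ia <- byRegA[[reg]]; ib <- byRegB[[reg]]
    grid <- expand.grid(a = ia, b = ib, KEEP.OUT.ATTRS = FALSE)
    if (homodimer) {
      # unordered pairs, no self-pairing: keep one orientation of each pair
      grid <- grid[hitsA$start[grid$a] < hitsB$start[grid$b] |
                     (hitsA$start[grid$a] == hitsB$start[grid$b] &
                        grid$a < grid$b), , drop = FALSE]
    }
    if (!nrow(grid)) next
    aStart <- hitsA$start[grid$a]; bStart <- hitsB$start[grid$b]
    aEnd <- aStart + widths[hitsA$pwmId[grid$a]]
    bEnd <- bStart + widths[hitsB$pwmId[grid$b]]
    aFirst <- aStart < bStart | (aStart == bStart & aEnd <= bEnd)
    upStart <- ifelse(aFirst, aStart, bStart)
    upEnd <- ifelse(aFirst, aEnd, bEnd)
    dnStart <- ifelse(aFirst, bStart, aStart)
    dnEnd <- ifelse(aFirst, bEnd, aEnd)
    spacing <- dnStart - upEnd
    keep <- abs(spacing) <= maxGap
    if (!any(keep)) next
    grid <- grid[keep, , drop = FALSE]
    aFirst <- aFirst[keep]; spacing <- spacing[keep]
    upStart <- upStart[keep]; upEnd <- upEnd[keep]
    dnStart <- dnStart[keep]; dnEnd <- dnEnd[keep]
    upPwm <- ifelse(aFirst, hitsA$pwmId[grid$a], hitsB$pwmId[grid$b])
    dnPwm <- ifelse(aFirst, hitsB$pwmId[grid$b], hitsA$pwmId[grid$a])
    upStr <- ifelse(aFirst, hitsA$strand[grid$a], hitsB$strand[grid$b])
    dnStr <- ifelse(aFirst, hitsB$strand[grid$b], hitsA$strand[grid$a])
    regIdx <- as.integer(reg)
    can <- canonicalStructure(upPwm, dnPwm, upStr, dnStr, spacing)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = hitsA$seqId[grid$a],
      start = upStart,
      end = pmax(upEnd, dnEnd),
      pwmA = can$pwmA, pwmB = can$pwmB,
      strandA = can$strandA, strandB = can$strandB,
      spacing = as.integer(can$spacing),
      structure = paste0(can$pwmA, ";", can$pwmB, "|",
                         paste0(can$strandA, can$strandB), "|", can$spacing),
      cellType = regions$cellType[regIdx],
      canonicalStrand = ifelse(can$flipped, "-", "+"),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(emptyOut)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$end, out$structure), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test dimer structures for cell-type-specific overrepresentation
#'
#' For each structure and target cell type, compares the instance rate per
#' open-chromatin bp in the target against the pooled background of all
#' other cell types, using an exact one-sided binomial test: with k_t target
#' and k_b background instances and open-chromatin totals bp_t, bp_b, the
#' p-value is P(X >= k_t) for X ~ Binomial(k_t + k_b, bp_t/(bp_t + bp_b)).
#' Benjamini-Hochberg q-values are computed across all structures tested
#' within each cell type. This enrichment statistic is this package's own,
#' documented substitute for the unpublished internal statistic of external
#' dimer-discovery tools with the same interface.
#'
#' @param instances Dimer-instance data frame from [findDimerInstances()]
#'   (or a concatenation across structure candidates), with \code{structure}
#'   and \code{cellType} columns.
#' @param openBp Named numeric vector: total open-chromatin bp per cell type
#'   (after top-region selection, replicate union and masking).
#' @param minTargetInstances Structures with fewer target instances are
#'   skipped (default 1, i.e. no lower bound beyond existence).
#' @return Data frame with one row per (structure, cellType): counts, bp
#'   totals, \code{p} and \code{q}, ordered by \code{q} then \code{p}.
#' @export
testOverrepresentation <- function(instances, openBp, minTargetInstances = 1) {
  if (any(openBp <= 0) || sum(openBp) <= 0)
    stop("testOverrepresentation(): open-chromatin bp totals must be positive")
  cellTypes <- names(openBp)
  counts <- table(factor(instances$structure),
                  factor(instances$cellType, levels = cellTypes))
  rows <- list()
  for (ct in cellTypes) {
    bpT <- openBp[[ct]]; bpB <- sum(openBp) - bpT
    if (bpB <= 0) stop("testOverrepresentation(): need >= 2 cell types")
    for (s in rownames(counts)) {
      kT <- counts[s, ct]; kB <- sum(counts[s, ]) - kT
      if (kT < minTargetInstances) next
      p0 <- bpT / (bpT + bpB)
      p <- stats::pbinom(kT - 1L, kT + kB, p0, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        structure = s, cellType = ct, targetCount = as.integer(kT),
        targetBp = bpT, backgroundCount = as.integer(kB), backgroundBp = bpB,
        p = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(structure = character(0), cellType = character(0),
                      targetCount = integer(0), targetBp = numeric(0),
                      backgroundCount = integer(0), backgroundBp = numeric(0),
                      p = numeric(0), q = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (ct in unique(out$cellType)) {
    i <- out$cellType == ct
    out$q[i] <- stats::p.adjust(out$p[i], method = "BH")
  }
  out <- out[order(out$q, out$p, out$structure), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Total open-chromatin bp per cell type
#'
#' Replicates of one cell type are merged by interval union after top-region
#' selection, then widths are summed.
#'
#' @param regions GRanges with \code{cellType} metadata.
#' @return Named numeric vector of bp totals.
#' @export
openChromatinBp <- function(regions) {
  vapply(split(regions, regions$cellType), function(r)
    sum(GenomicRanges::width(GenomicRanges::reduce(r))), numeric(1))
}

#' Write an enrichment table as TSV
#'
#' @param enrichment Data frame from [testOverrepresentation()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
writeEnrichmentTsv <- function(enrichment, path) {
  write.table(enrichment, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
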