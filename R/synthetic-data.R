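#' Generate a random genome sequence
#'
#' I.i.d. bases at a requested GC content. Each generator in this module
#' draws from its own RNG stream keyed by (seed, generator name), so adding
#' generators never perturbs existing outputs and identical seeds give
#' byte-identical results.
#'
#' @param length Genome length in bp (>= 1).
#' @param gc GC fraction in (0, 1); default 0.41, a typical mammalian value.
#' @param seed Integer seed.
#' @param name Chromosome name (default "chr1").
#' @return Named character vector of length 1: the sequence.
#' @export
generateGenome <- function(length, gc = 0.41, seed = 1, name = "chr1") {
  stopifnot(length >= 1, gc > 0, gc < 1)
  withLocalSeed(deriveSeed(seed, "genome"), {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seq <- paste(sample(DNA_BASES4, length, replace = TRUE, prob = p),
                 collapse = "")
    setNames(seq, name)
  })
}

#' Generate non-overlapping open-chromatin peaks for one cell type
#'
#' Emulates a DNase-seq narrowPeak track: the genome is divided into
#' \code{nPeaks} equal slots and one peak of random length is placed at a
#' random offset inside each slot, guaranteeing disjointness. signalValues
#' are strictly positive draws from an exponential law.
#'
#' @param genome Named character vector from [generateGenome()].
#' @param nPeaks Number of peaks.
#' @param peakLen Length-2 vector: min and max peak length in bp.
#' @param seed Integer seed.
#' @param cellType,replicate Labels attached to the peaks.
#' @return GRanges with \code{signalValue}, \code{cellType},
#'   \code{replicate} metadata, as from [readNarrowPeak()].
#' @export
generateCellType <- function(genome, nPeaks = 100, peakLen = c(150, 400),
                             seed = 1, cellType = "cellA",
                             replicate = "rep1") {
  L <- nchar(genome[[1]])
  slot <- floor(L / nPeaks)
  if (slot < max(peakLen) + 1)
    stop("generateCellType(): ", nPeaks, " peaks of up to ", max(peakLen),
         " bp do not fit in ", L, " bp")
  withLocalSeed(deriveSeed(seed, paste0("peaks:", cellType, ":", replicate)), {
    len <- sample(seq(peakLen[1], peakLen[2]), nPeaks, replace = TRUE)
    off <- vapply(seq_len(nPeaks), function(i)
      sample.int(slot - len[i], 1L), 0L)
    start0 <- (seq_len(nPeaks) - 1L) * slot + off   # 0-based
    GenomicRanges::GRanges(
      names(genome)[1],
      IRanges::IRanges(start = start0 + 1L, width = len),
      signalValue = round(rexp(nPeaks, rate = 0.2) + 0.01, 3),
      cellType = cellType, replicate = replicate)
  })
}

#' Plant dimer instances of a structure inside target peaks
#'
#' Writes sampled motif words (drawn per column from each PWM's smoothed
#' probabilities; minus-strand words are reverse complemented before
#' insertion) into the genome at the structure's exact spacing and
#' orientation, at random positions inside distinct target peaks. Sampling
#' from the PWM means a planted site can occasionally score below the
#' balanced threshold; recovery is high but not exact by construction.
#'
#' @param genome Named character vector.
#' @param structure A [DimerStructure-class] (canonical form).
#' @param pwms Named list of the two [PWM-class] objects (names = motif ids).
#' @param nCopies Number of instances to plant (0 leaves the genome
#'   untouched).
#' @param targetPeaks GRanges of peaks to plant into; needs at least
#'   \code{nCopies} peaks.
#' @param seed Integer seed.
#' @return List with \code{genome} (modified) and \code{truth}: data frame
#'   of planted instances (\code{chrom}, \code{start}, \code{end}, 0-based
#'   half-open, plus \code{structure}).
#' @export
plantDimer <- function(genome, structure, pwms, nCopies, targetPeaks,
                       seed = 1) {
  if (nCopies == 0)
    return(list(genome = genome,
                truth = data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0), structure = character(0),
                                   stringsAsFactors = FALSE)))
  if (length(targetPeaks) < nCopies)
    stop("plantDimer(): need at least ", nCopies, " target peaks")
  pwmA <- pwms[[structure@pwmA]]; pwmB <- pwms[[structure@pwmB]]
  wA <- pwmWidth(pwmA); wB <- pwmWidth(pwmB)
  span <- wA + structure@spacing + wB
  withLocalSeed(deriveSeed(seed, "plant"), {
    peakIdx <- sample(seq_along(targetPeaks), nCopies)
    seq <- genome[[1]]
    sampleWord <- function(pwm, strand) {
      p <- pwmProbs(pwm)
      word <- paste(vapply(seq_len(ncol(p)), function(j)
        sample(DNA_BASES4, 1L, prob = p[, j]), ""), collapse = "")
      if (strand == "-") revCompString(word) else word
    }
    rows <- vector("list", nCopies)
    for (i in seq_len(nCopies)) {
      pk <- targetPeaks[peakIdx[i]]
      pkStart0 <- GenomicRanges::start(pk) - 1L
      room <- GenomicRanges::width(pk) - span
      if (room < 0)
        stop("plantDimer(): peak ", peakIdx[i], " too short for the dimer")
      pos <- pkStart0 + sample.int(room + 1L, 1L) - 1L   # 0-based
      wordA <- sampleWord(pwmA, structure@orientation[1])
      wordB <- sampleWord(pwmB, structure@orientation[2])
      substr(seq, pos + 1L, pos + wA) <- wordA
      bPos <- pos + wA + structure@spacing
      substr(seq, bPos + 1L, bPos + wB) <- wordB
      rows[[i]] <- data.frame(chrom = names(genome)[1], start = pos,
                              end = pos + span,
                              structure = structureKey(structure),
                              stringsAsFactors = FALSE)
    }
    genome[[1]] <- seq
    truth <- do.call(rbind, rows)
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    list(genome = genome, truth = truth)
  })
}

#' Generate non-overlapping gene models with exons
#'
#' Genes are placed in equal slots (disjoint by construction) with random
#' strand; each gene receives 1-3 exons inside its body. The exon mask is
#' the union of all exons.
#'
#' @param genome Named character vector.
#' @param nGenes Number of genes.
#' @param geneLen Length-2 vector of min/max gene length in bp.
#' @param seed Integer seed.
#' @return List with \code{genes} (GRanges, \code{geneId} metadata, strand
#'   set), \code{exons} (GRanges with \code{geneId}) and \code{mask}
#'   (reduced exon GRanges).
#' @export
generateGenes <- function(genome, nGenes = 50, geneLen = c(2000, 8000),
                          seed = 1) {
  L <- nchar(genome[[1]])
  slot <- floor(L / nGenes)
  if (slot < max(geneLen) + 1)
    stop("generateGenes(): ", nGenes, " genes of up to ", max(geneLen),
         " bp do not fit in ", L, " bp")
  withLocalSeed(deriveSeed(seed, "genes"), {
    chrom <- names(genome)[1]
    len <- sample(seq(geneLen[1], geneLen[2]), nGenes, replace = TRUE)
    off <- vapply(seq_len(nGenes), function(i)
      sample.int(slot - len[i], 1L), 0L)
    start0 <- (seq_len(nGenes) - 1L) * slot + off
    strand <- sample(c("+", "-"), nGenes, replace = TRUE)
    geneId <- sprintf("G%04d", seq_len(nGenes))
    genes <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = start0 + 1L, width = len),
      strand = strand, geneId = geneId)
    exRows <- lapply(seq_len(nGenes), function(i) {
      nEx <- sample(1:3, 1L)
      subSlot <- floor(len[i] / nEx)     # one exon per sub-slot: disjoint
      exLen <- pmin(sample(100:300, nEx, replace = TRUE), subSlot - 1L)
      exOff <- vapply(seq_len(nEx), function(j)
        sample.int(subSlot - exLen[j], 1L), 0L)
      exStart <- (seq_len(nEx) - 1L) * subSlot + exOff
      data.frame(chrom = chrom, start = start0[i] + exStart,
                 end = start0[i] + exStart + exLen, geneId = geneId[i],
                 stringsAsFactors = FALSE)
    })
    ex <- do.call(rbind, exRows)
    exons <- GenomicRanges::GRanges(
      ex$chrom, IRanges::IRanges(start = ex$start + 1L, end = ex$end),
      geneId = ex$geneId)
    list(genes = genes, exons = exons,
         mask = GenomicRanges::reduce(exons))
  })
}

#' @noRd
CHROMHMM_STATES <- c(
  "Active_Promoter", "Weak_Promoter", "Poised_Promoter", "Strong_Enhancer",
  "Weak_Enhancer", "Insulator", "Txn_Transition", "Txn_Elongation",
  "Weak_Txn", "Repressed", "Heterochrom_lo", "Repetitive_CNV",
  "Repetitive_CNV_2", "Quiescent", "Artifact")

#' Generate a 15-state chromatin segmentation
#'
#' Tiles the genome with non-overlapping segments of random length and
#' assigns labels from a 15-state vocabulary so that the realized G-plus
#' base-pair fraction tracks the request closely: segments are visited in
#' random order and labelled G-plus until the requested bp share is
#' reached.
#'
#' @param genome Named character vector.
#' @param gPlusFraction Requested fraction of bp in G-plus states, in
#'   \code{[0, 1]}.
#' @param meanSegment Mean segment length in bp (default 1000).
#' @param seed Integer seed.
#' @param cellType Label attached to the segments.
#' @return GRanges tiling the genome with \code{state} and \code{cellType}
#'   metadata.
#' @export
generateChromHmm <- function(genome, gPlusFraction = 0.1, meanSegment = 1000,
                             seed = 1, cellType = "cellA") {
  stopifnot(gPlusFraction >= 0, gPlusFraction <= 1)
  L <- nchar(genome[[1]])
  withLocalSeed(deriveSeed(seed, paste0("chromhmm:", cellType)), {
    lens <- integer(0); tot <- 0
    while (tot < L) {
      l <- max(200L, as.integer(round(rexp(1, 1 / meanSegment))))
      lens <- c(lens, min(l, L - tot)); tot <- tot + l
    }
    start0 <- cumsum(c(0L, head(lens, -1L)))
    ord <- sample.int(length(lens))
    cum <- cumsum(lens[ord])
    nPlus <- sum(cum <= gPlusFraction * L + 1e-9)
    if (gPlusFraction == 1) nPlus <- length(lens)
    isPlus <- logical(length(lens)); isPlus[ord[seq_len(nPlus)]] <- TRUE
    gMinus <- setdiff(CHROMHMM_STATES, gplusStates())
    state <- ifelse(isPlus,
                    sample(gplusStates(), length(lens), replace = TRUE),
                    sample(gMinus, length(lens), replace = TRUE))
    GenomicRanges::GRanges(
      names(genome)[1],
      IRanges::IRanges(start = start0 + 1L, width = lens),
      state = state, cellType = cellType)
  })
}

#' Generate a block-structured many-to-many orthology relation
#'
#' Builds ortholog pairs whose bipartite connected components exactly match
#' a requested block-size spectrum; genes not used by any block remain
#' orthology-free singletons. Within a block, edges connect the first human
#' gene to every mouse gene and every human gene to the first mouse gene,
#' which keeps the component connected without making it complete.
#'
#' @param nH,nM Number of human and mouse genes (ids H0001.., M0001..).
#' @param spectrum Data frame with columns \code{hSize}, \code{mSize},
#'   \code{count}: how many blocks of each shape to create.
#' @param seed Integer seed.
#' @return List with \code{pairs} (data frame \code{human}, \code{mouse}),
#'   \code{genesH}, \code{genesM}, and \code{truth}: list of blocks, each
#'   with \code{h} and \code{m} gene-id vectors.
#' @export
generateOrthology <- function(nH, nM,
                              spectrum = data.frame(hSize = 1, mSize = 1,
                                                    count = 10),
                              seed = 1) {
  needH <- sum(spectrum$hSize * spectrum$count)
  needM <- sum(spectrum$mSize * spectrum$count)
  if (needH > nH || needM > nM)
    stop("generateOrthology(): spectrum needs ", needH, " human and ",
         needM, " mouse genes; only ", nH, "/", nM, " available")
  genesH <- sprintf("H%04d", seq_len(nH))
  genesM <- sprintf("M%04d", seq_len(nM))
  withLocalSeed(deriveSeed(seed, "orthology"), {
    poolH <- sample(genesH); poolM <- sample(genesM)
    blocks <- list(); pairs <- list()
    for (r in seq_len(nrow(spectrum))) {
      for (b in seq_len(spectrum$count[r])) {
        hs <- poolH[seq_len(spectrum$hSize[r])]
        poolH <- poolH[-seq_len(spectrum$hSize[r])]
        ms <- poolM[seq_len(spectrum$mSize[r])]
        poolM <- poolM[-seq_len(spectrum$mSize[r])]
        blocks[[length(blocks) + 1L]] <- list(h = sort(hs), m = sort(ms))
        e <- unique(rbind(
          data.frame(human = hs[1], mouse = ms, stringsAsFactors = FALSE),
          data.frame(human = hs, mouse = ms[1], stringsAsFactors = FALSE)))
        pairs[[length(pairs) + 1L]] <- e
      }
    }
    pairsDf <- if (length(pairs)) do.call(rbind, pairs)
    else data.frame(human = character(0), mouse = character(0),
                    stringsAsFactors = FALSE)
    rownames(pairsDf) <- NULL
    list(pairs = pairsDf, genesH = genesH, genesM = genesM, truth = blocks)
  })
}

#' Generate gene-to-GO annotations with planted enrichment
#'
#' Background terms annotate every gene independently at a uniform base
#' rate; each planted term annotates the genes of its subset at
#' \code{factor} times the base rate (capped at 1), creating a known
#' enrichment signal for calibration tests.
#'
#' @param genes Character vector of gene ids.
#' @param nTerms Number of background terms (ids T0001..).
#' @param planted Optional list of lists, each with \code{term} (id),
#'   \code{genes} (subset of \code{genes}) and \code{factor} (enrichment
#'   multiplier; 1 = null).
#' @param baseRate Per-gene annotation probability of each term (default
#'   0.02).
#' @param seed Integer seed.
#' @return Data frame \code{gene}, \code{term}.
#' @export
generateGo <- function(genes, nTerms = 100, planted = NULL, baseRate = 0.02,
                       seed = 1) {
  stopifnot(baseRate > 0, baseRate < 1)
  for (p in planted %||% list())
    if (!all(p$genes %in% genes))
      stop("generateGo(): planted subset must be drawn from 'genes'")
  withLocalSeed(deriveSeed(seed, "go"), {
    terms <- sprintf("T%04d", seq_len(nTerms))
    rows <- lapply(terms, function(t) {
      hit <- runif(length(genes)) < baseRate
      if (!any(hit)) return(NULL)
      data.frame(gene = genes[hit], term = t, stringsAsFactors = FALSE)
    })
    for (p in planted %||% list()) {
      rate <- min(1, p$factor * baseRate)
      inSub <- genes %in% p$genes
      hit <- runif(length(genes)) < ifelse(inSub, rate, baseRate)
      if (any(hit))
        rows[[length(rows) + 1L]] <- data.frame(
          gene = genes[hit], term = p$term, stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, TRUE)]
    out <- unique(do.call(rbind, rows))
    out <- out[order(out$term, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two sharply-defined synthetic motifs for simulation studies
#'
#' Deterministic 10-bp count matrices (97 counts on the consensus base, 1 on
#' each alternative) used by the end-to-end simulations: sharp enough that
#' words sampled from the motif model almost always clear the balanced
#' threshold, while chance hits stay rare (background false-positive rate
#' around 3.5e-3 per window at the ratio-100 threshold).
#'
#' @return Named list of two [PWM-class] objects, \code{SYNA} and
#'   \code{SYNB}.
#' @export
syntheticPWMs <- function() {
  fromConsensus <- function(word, id) {
    w <- nchar(word)
    counts <- matrix(1, nrow = 4, ncol = w,
                     dimnames = list(DNA_BASES4, NULL))
    idx <- match(strsplit(word, "")[[1]], DNA_BASES4)
    counts[cbind(idx, seq_len(w))] <- 97
    PWM(counts, id = id)
  }
  # consensus words chosen for low cross- and self-similarity (including
  # reverse complements), so planted composites create few shifted
  # near-matches
  list(SYNA = fromConsensus("GGAACGTCCA", "SYNA"),
       SYNB = fromConsensus("CACGATTGAG", "SYNB"))
}

#' Simulate a complete synthetic study with one planted dimer
#'
#' Generates the full input bundle the pipeline consumes: a genome, open
#' chromatin for several cell types, a dimer structure planted into the
#' peaks of one target cell type, gene models with an exon mask, and a
#' chromatin-state segmentation. Defaults follow the scale used by the
#' package's validation suite: a 1 Mb genome, 3 cell types with 100 peaks
#' each, 30 planted copies.
#'
#' @param seed Integer seed driving every generator stream.
#' @param genomeLength Genome length in bp.
#' @param nCellTypes Number of cell types (the first is the target).
#' @param nPeaks Peaks per cell type.
#' @param nCopies Planted instance count.
#' @param structure [DimerStructure-class] to plant; default SYNA/SYNB at
#'   spacing 3, orientation (+,+).
#' @param gPlusFraction G-plus fraction of the segmentation.
#' @param nGenes Number of genes.
#' @return List with \code{genome}, \code{pwms}, \code{structure},
#'   \code{regions} (all cell types combined), \code{truth},
#'   \code{genes}, \code{exons}, \code{mask}, \code{segments},
#'   \code{cellTypes}, \code{targetCellType}.
#' @export
simulateStudy <- function(seed = 1, genomeLength = 1e6, nCellTypes = 3,
                          nPeaks = 100, nCopies = 30,
                          structure = DimerStructure("SYNA", "SYNB",
                                                     c("+", "+"), 3L),
                          gPlusFraction = 0.1, nGenes = 50) {
  genome <- generateGenome(genomeLength, seed = seed)
  cellTypes <- paste0("cell", LETTERS[seq_len(nCellTypes)])
  regionsList <- lapply(cellTypes, function(ct)
    generateCellType(genome, nPeaks = nPeaks, seed = seed, cellType = ct))
  names(regionsList) <- cellTypes
  planted <- plantDimer(genome, structure, syntheticPWMs(), nCopies,
                        regionsList[[1]], seed = seed)
  # gene sizes scale down with the genome so small test worlds stay feasible
  maxGene <- min(8000, floor(genomeLength / nGenes) - 10)
  if (maxGene < 1000)
    stop("simulateStudy(): genome too short for ", nGenes, " genes")
  geneSet <- generateGenes(genome, nGenes = nGenes,
                           geneLen = c(min(2000, maxGene - 1), maxGene),
                           seed = seed)
  segments <- generateChromHmm(genome, gPlusFraction = gPlusFraction,
                               seed = seed, cellType = cellTypes[1])
  list(genome = planted$genome, pwms = syntheticPWMs(),
       structure = structure,
       regions = do.call(c, unname(regionsList)),
       truth = planted$truth,
       genes = geneSet$genes, exons = geneSet$exons, mask = geneSet$mask,
       segments = segments, cellTypes = cellTypes,
       targetCellType = cellTypes[1])
}

# ---- plain-text writers -------------------------------------------------

#' Write a genome as FASTA
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(unname(unlist(genome)))
  names(set) <- names(genome)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write peaks as a narrowPeak (BED6+4) file
#' @param regions GRanges with \code{signalValue} metadata.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeNarrowPeak <- function(regions, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,
    end = GenomicRanges::end(regions),
    name = ".", score = 0L, strand = ".",
    signalValue = regions$signalValue, pValue = -1, qValue = -1, peak = -1)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write intervals as BED3
#' @param gr GRanges.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeBed3 <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a chromatin-state segmentation as BED4
#' @param segments GRanges with \code{state} metadata.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeChromHmmBed <- function(segments, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(segments)),
                   start = GenomicRanges::start(segments) - 1L,
                   end = GenomicRanges::end(segments),
                   state = segments$state)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write gene models (with exon lists) as TSV
#' @param genes GRanges with \code{geneId} and strand.
#' @param exons GRanges with \code{geneId}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeGenesTsv <- function(genes, exons, path) {
  exStr <- vapply(genes$geneId, function(g) {
    e <- exons[exons$geneId == g]
    if (!length(e)) return("")
    paste(sprintf("%d-%d", GenomicRanges::start(e) - 1L,
                  GenomicRanges::end(e)), collapse = ",")
  }, "")
  df <- data.frame(gene_id = genes$geneId,
                   chrom = as.character(GenomicRanges::seqnames(genes)),
                   start = GenomicRanges::start(genes) - 1L,
                   end = GenomicRanges::end(genes),
                   strand = as.character(GenomicRanges::strand(genes)),
                   exons = exStr)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ortholog pairs as a two-column TSV
#' @param pairs Data frame \code{human}, \code{mouse}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeOrthologsTsv <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene-to-GO annotations as a two-column TSV
#' @param annotations Data frame \code{gene}, \code{term}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeGoTsv <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
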