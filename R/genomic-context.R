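#' G-plus regulatory chromatin-state labels
#'
#' The four 15-state ChromHMM labels treated as regulatory (promoter or
#' enhancer associated); the remaining labels form the G-minus group.
#'
#' @return Character vector of the four G-plus labels.
#' @export
gplusStates <- function() {
  c("Strong_Enhancer", "Active_Promoter", "Weak_Promoter", "Weak_Enhancer")
}

#' Distance thresholds of the Q1-Q6 gene-selection queries
#'
#' @return Named integer vector: Q1 = 100 through Q6 = 50000 bp. Q0 (the
#'   within-gene query) has no threshold.
#' @export
queryThresholds <- function() {
  c(Q1 = 100L, Q2 = 500L, Q3 = 1000L, Q4 = 5000L, Q5 = 10000L, Q6 = 50000L)
}

#' Midpoint of a dimer instance
#'
#' The single position used to represent an instance in all genomic-context
#' rules: floor of the average of its 0-based half-open bounds, so an
#' even-length interval takes the left-of-center base.
#'
#' @param start,end 0-based half-open bounds (vectors allowed).
#' @return 0-based midpoint position(s).
#' @examples
#' instanceMidpoint(100, 110)  # 105
#' instanceMidpoint(100, 111)  # 105
#' @export
instanceMidpoint <- function(start, end) {
  stopifnot(all(end > start))
  floor((start + end) / 2)
}

#' Nearest gene to a genomic position
#'
#' If the position falls inside a gene body the distance is 0 and the
#' within-gene flag is set (with exons masked upstream, such positions are
#' intronic). Otherwise the nearest boundary point of any same-chromosome
#' gene is used: the left edge (TSS side for a + gene) when the gene lies
#' downstream of the position, the right edge when it lies upstream. Ties
#' are broken by the lexicographically smaller gene id.
#'
#' @param chrom Chromosome of the position.
#' @param pos 0-based position (typically [instanceMidpoint()]).
#' @param genes GRanges of gene bodies with a \code{geneId} metadata column
#'   (1-based closed, as GRanges).
#' @return List with \code{geneId} (NA when no same-chromosome gene exists),
#'   \code{distance} (bp; Inf when no gene) and \code{withinGene}.
#' @export
nearestGene <- function(chrom, pos, genes) {
  g <- genes[as.character(GenomicRanges::seqnames(genes)) == chrom]
  if (!length(g))
    return(list(geneId = NA_character_, distance = Inf, withinGene = FALSE))
  s0 <- GenomicRanges::start(g) - 1L       # back to 0-based half-open
  e0 <- GenomicRanges::end(g)
  d <- ifelse(pos < s0, s0 - pos, ifelse(pos >= e0, pos - (e0 - 1L), 0L))
  dmin <- min(d)
  cand <- which(d == dmin)
  pick <- cand[order(g$geneId[cand])][1L]
  list(geneId = g$geneId[pick], distance = as.numeric(dmin),
       withinGene = dmin == 0)
}

#' Annotate instances with their nearest gene
#'
#' @param instances Dimer-instance data frame (needs \code{chrom},
#'   \code{start}, \code{end}).
#' @param genes GRanges of gene bodies with \code{geneId}.
#' @return The instances with added \code{midpoint}, \code{geneId},
#'   \code{distance}, \code{withinGene} columns.
#' @export
annotateNearestGene <- function(instances, genes) {
  if (!nrow(instances)) {
    instances$midpoint <- integer(0); instances$geneId <- character(0)
    instances$distance <- numeric(0); instances$withinGene <- logical(0)
    return(instances)
  }
  mids <- instanceMidpoint(instances$start, instances$end)
  ann <- lapply(seq_len(nrow(instances)), function(i)
    nearestGene(instances$chrom[i], mids[i], genes))
  instances$midpoint <- mids
  instances$geneId <- vapply(ann, `[[`, "", "geneId")
  instances$distance <- vapply(ann, `[[`, 0, "distance")
  instances$withinGene <- vapply(ann, `[[`, FALSE, "withinGene")
  instances
}

#' Genes selected by dimer instances under a Q0-Q6 query
#'
#' Each instance selects exactly one gene: its nearest. Q0 returns genes
#' containing at least one instance midpoint; Qi (i >= 1) returns nearest
#' genes at distance strictly below the Qi threshold (100, 500, 1000, 5000,
#' 10000, 50000 bp).
#'
#' @param instances Annotated instances from [annotateNearestGene()].
#' @param query One of \code{"Q0"}..\code{"Q6"}.
#' @return Character vector of selected gene ids (unique, sorted).
#' @export
selectGenes <- function(instances, query = "Q0") {
  stopifnot(query %in% c("Q0", paste0("Q", 1:6)))
  if (!nrow(instances)) return(character(0))
  if (query == "Q0") {
    ids <- instances$geneId[instances$withinGene]
  } else {
    thr <- queryThresholds()[[query]]
    ids <- instances$geneId[instances$distance < thr]
  }
  sort(unique(ids[!is.na(ids)]))
}

#' Percentage of instances lying within a gene
#'
#' @param instances Annotated instances from [annotateNearestGene()], or a
#'   logical \code{withinGene} vector.
#' @return Integer percent (nearest integer, halves away from zero).
#' @examples
#' # the largest human dimer row: 1105 of 2029 instances in-gene
#' percentOf(1105, 2029)  # 54
#' @export
withinGeneFraction <- function(instances) {
  flags <- if (is.data.frame(instances)) instances$withinGene else instances
  if (!length(flags)) stop("withinGeneFraction(): no instances")
  percentOf(sum(flags), length(flags))
}

#' Chromatin state at an instance midpoint
#'
#' An instance may straddle several segmentation states; the state of its
#' midpoint is taken as representative.
#'
#' @param instances Dimer-instance data frame (\code{chrom}, \code{start},
#'   \code{end}).
#' @param segments GRanges of ChromHMM segments with a \code{state}
#'   metadata column; segments of one cell type must not overlap.
#' @return Character vector of state labels; midpoints outside every
#'   segment get \code{"unannotated"}.
#' @export
assignState <- function(instances, segments) {
  if (!nrow(instances)) return(character(0))
  mids <- instanceMidpoint(instances$start, instances$end)
  mg <- GenomicRanges::GRanges(instances$chrom,
                               IRanges::IRanges(start = mids + 1L, width = 1L))
  ov <- GenomicRanges::findOverlaps(mg, segments)
  qh <- S4Vectors::queryHits(ov)
  if (anyDuplicated(qh))
    stop("assignState(): overlapping segments at an instance midpoint")
  out <- rep("unannotated", nrow(instances))
  out[qh] <- segments$state[S4Vectors::subjectHits(ov)]
  out
}

#' Binomial enrichment of instances in G-plus regulatory states
#'
#' With k of n instance midpoints assigned a G-plus state and a background
#' G-plus probability p0, the p-value is the exact upper binomial tail
#' P(X >= k), X ~ Binomial(n, p0). A natural p0 is the G-plus base-pair
#' fraction of the cell type's segmentation ([gplusFraction()]).
#'
#' @param labels Character vector of state labels (one per instance).
#' @param p0 Background G-plus probability, 0 < p0 < 1.
#' @return List with \code{k}, \code{n}, \code{pValue}.
#' @export
gplusBinomial <- function(labels, p0) {
  stopifnot(p0 > 0, p0 < 1)
  k <- sum(labels %in% gplusStates())
  n <- length(labels)
  list(k = k, n = n,
       pValue = stats::pbinom(k - 1L, n, p0, lower.tail = FALSE))
}

#' G-plus base-pair fraction of a segmentation
#'
#' @param segments GRanges with a \code{state} column.
#' @return Fraction of annotated bp carrying a G-plus label.
#' @export
gplusFraction <- function(segments) {
  w <- GenomicRanges::width(segments)
  sum(w[segments$state %in% gplusStates()]) / sum(w)
}

#' Genes with enough dimer instances near their TSS
#'
#' Selects genes having at least \code{minInstances} instance midpoints
#' strictly within \code{window} bp of their transcription start site (TSS:
#' gene start on +, gene end on -).
#'
#' @param instances Dimer-instance data frame.
#' @param genes GRanges of gene bodies with \code{geneId}; strand is taken
#'   from the GRanges strand.
#' @param window Half-width of the TSS window in bp (default 10000).
#' @param minInstances Minimum instance count (default 3).
#' @return Character vector of gene ids (sorted).
#' @export
tssWindowSelection <- function(instances, genes, window = 10000,
                               minInstances = 3) {
  if (!nrow(instances) || !length(genes)) return(character(0))
  mids <- instanceMidpoint(instances$start, instances$end)
  strand <- as.character(GenomicRanges::strand(genes))
  tss <- ifelse(strand == "-", GenomicRanges::end(genes) - 1L,
                GenomicRanges::start(genes) - 1L)  # 0-based
  hitsPerGene <- vapply(seq_along(genes), function(i) {
    onChrom <- instances$chrom ==
      as.character(GenomicRanges::seqnames(genes))[i]
    sum(onChrom & abs(mids - tss[i]) < window)
  }, 0L)
  sort(genes$geneId[hitsPerGene >= minInstances])
}

#' Fraction of instances falling inside predicted enhancers
#'
#' Membership is evaluated at the instance midpoint, mirroring the
#' chromatin-state rule. Enhancer intervals are consumed as input (the
#' enhancer predictor itself is external).
#'
#' @param instances Dimer-instance data frame.
#' @param enhancers GRanges of enhancer intervals.
#' @return List with \code{k} (instances inside), \code{n} (total) and
#'   \code{percent} (nearest integer).
#' @examples
#' # reporting arithmetic: 183 of 205 instances inside -> 89 percent
#' percentOf(183, 205)
#' @export
enhancerOverlapFraction <- function(instances, enhancers) {
  n <- nrow(instances)
  if (!n) stop("enhancerOverlapFraction(): no instances")
  mids <- instanceMidpoint(instances$start, instances$end)
  mg <- GenomicRanges::GRanges(instances$chrom,
                               IRanges::IRanges(start = mids + 1L, width = 1L))
  k <- sum(IRanges::overlapsAny(mg, enhancers))
  list(k = k, n = n, percent = percentOf(k, n))
}

#' Read a ChromHMM segmentation BED
#'
#' BED4: chrom, start, end, state label; 0-based half-open.
#'
#' @param path BED file path.
#' @param cellType Cell-type label attached to every segment.
#' @return GRanges with \code{state} and \code{cellType} metadata.
#' @export
readChromHmm <- function(path, cellType = "unknown") {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "state"),
                   colClasses = c("character", "numeric", "numeric",
                                  "character"))
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end),
                         state = df$state, cellType = cellType)
}

#' Read gene models from a tabular file
#'
#' Expects columns gene_id, chrom, start, end, strand, exons where start/end
#' are 0-based half-open and exons is a comma-separated list of
#' \code{start-end} pairs within the gene.
#'
#' @param path TSV file path.
#' @return List with \code{genes} (GRanges, \code{geneId} metadata) and
#'   \code{exons} (GRanges with \code{geneId}).
#' @export
readGenesTsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  genes <- GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand, geneId = df$gene_id)
  exRows <- lapply(seq_len(nrow(df)), function(i) {
    if (is.na(df$exons[i]) || !nzchar(df$exons[i])) return(NULL)
    parts <- strsplit(strsplit(df$exons[i], ",")[[1]], "-")
    data.frame(chrom = df$chrom[i],
               start = as.numeric(vapply(parts, `[[`, "", 1L)),
               end = as.numeric(vapply(parts, `[[`, "", 2L)),
               geneId = df$gene_id[i], stringsAsFactors = FALSE)
  })
  ex <- do.call(rbind, exRows)
  exons <- if (is.null(ex)) GenomicRanges::GRanges(geneId = character(0))
  else GenomicRanges::GRanges(ex$chrom,
                              IRanges::IRanges(start = ex$start + 1L,
                                               end = ex$end),
                              geneId = ex$geneId)
  list(genes = genes, exons = exons)
}
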