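#' @import methods
#' @importFrom stats p.adjust pbinom phyper rbinom rexp runif setNames
#' @importFrom utils head read.table write.table
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Position weight matrix with background model
#'
#' A position count matrix over \{A,C,G,T\} together with a pseudocount
#' fraction and a background base composition. Scores are log2 odds of the
#' pseudocount-smoothed position probabilities against the background.
#'
#' @slot id Motif identifier, e.g. \code{"M00750"}.
#' @slot counts 4 x width numeric matrix of nonnegative counts, rows named
#'   A, C, G, T. Columns are motif positions.
#' @slot pseudocount Fraction of each column total added as pseudocount mass,
#'   distributed across bases proportionally to the background. Default 0.01.
#' @slot background Probability vector over A, C, G, T summing to 1.
#'
#' @seealso [PWM()], [pwmProbs()], [logOddsMatrix()], [balancedThreshold()]
#' @export
setClass("PWM",
  representation(
    id = "character",
    counts = "matrix",
    pseudocount = "numeric",
    background = "numeric"
  ),
  prototype(pseudocount = 0.01,
            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
)

setValidity("PWM", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  cts <- object@counts
  if (nrow(cts) != 4L || is.null(rownames(cts)) ||
      !identical(rownames(cts), DNA_BASES4))
    msg <- c(msg, "counts must have 4 rows named A, C, G, T")
  if (ncol(cts) < 1L) msg <- c(msg, "width must be >= 1")
  if (any(cts < 0)) msg <- c(msg, "counts must be nonnegative")
  if (ncol(cts) >= 1L && any(colSums(cts) <= 0))
    msg <- c(msg, "every position needs at least one positive count")
  if (length(object@pseudocount) != 1L || object@pseudocount < 0)
    msg <- c(msg, "pseudocount must be a single nonnegative number")
  bg <- object@background
  if (length(bg) != 4L || abs(sum(bg) - 1) > 1e-9 || any(bg <= 0))
    msg <- c(msg, "background must be 4 positive probabilities summing to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PWM
#'
#' @param counts 4 x width matrix (rows A, C, G, T) or width x 4 matrix
#'   (columns A, C, G, T), of nonnegative counts. Probability rows are fine
#'   too: counts are only ever used through the smoothed column proportions.
#' @param id Motif identifier.
#' @param pseudocount Pseudocount fraction of each column total (default
#'   0.01); set 0 to score raw proportions.
#' @param background Background base probabilities, in A, C, G, T order;
#'   default uniform.
#' @return A [PWM-class] object.
#' @examples
#' m <- PWM(matrix(c(10, 0, 0, 0, 0, 10, 0, 0), nrow = 4,
#'                 dimnames = list(c("A", "C", "G", "T"), NULL)), id = "toy")
#' pwmWidth(m)
#' @export
PWM <- function(counts, id = "pwm", pseudocount = 0.01,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 4L && nrow(counts) != 4L) counts <- t(counts)
  if (nrow(counts) == 4L && is.null(rownames(counts)))
    rownames(counts) <- DNA_BASES4
  if (nrow(counts) == 4L && !identical(rownames(counts), DNA_BASES4))
    counts <- counts[DNA_BASES4, , drop = FALSE]
  background <- setNames(as.numeric(background), DNA_BASES4)
  new("PWM", id = id, counts = counts, pseudocount = pseudocount,
      background = background)
}

#' @describeIn PWM Motif identifier.
#' @param x,object A \code{PWM}.
#' @export
pwmId <- function(x) x@id

#' @describeIn PWM Number of motif positions.
#' @export
pwmWidth <- function(x) ncol(x@counts)

#' @describeIn PWM Raw count matrix (4 x width).
#' @export
pwmCounts <- function(x) x@counts

#' @describeIn PWM Background base probabilities.
#' @export
pwmBackground <- function(x) x@background

#' Smoothed position probability matrix
#'
#' Per column, the pseudocount mass (pseudocount fraction times the column
#' total) is split across bases proportionally to the background before
#' normalising, so zero counts never produce infinite log odds (unless
#' \code{pseudocount = 0} was requested).
#'
#' @param x A [PWM-class].
#' @return 4 x width matrix of probabilities; columns sum to 1.
#' @export
pwmProbs <- function(x) {
  cts <- x@counts
  tot <- colSums(cts)
  pc <- x@pseudocount * tot
  p <- sweep(cts, 2L, tot + pc, "/") +
    outer(x@background, pc / (tot + pc))
  p
}

#' Log2-odds scoring matrix
#'
#' @param x A [PWM-class].
#' @return 4 x width matrix \code{log2(p / background)} in bits.
#' @export
logOddsMatrix <- function(x) {
  log2(pwmProbs(x) / x@background)
}

#' @describeIn PWM Majority-base consensus string.
#' @export
pwmConsensus <- function(x) {
  paste(DNA_BASES4[apply(x@counts, 2L, which.max)], collapse = "")
}

setMethod("show", "PWM", function(object) {
  cat("PWM", object@id, "| width", pwmWidth(object),
      "| consensus", pwmConsensus(object),
      "| pseudocount", object@pseudocount, "\n")
  print(round(pwmProbs(object), 3))
  invisible(NULL)
})

#' Dimer structure: motif pair, orientation and spacing
#'
#' The unit of overrepresentation testing: an unordered motif pair with a
#' mutual orientation and a spacing, where spacing is the gap in bp between
#' the end of the upstream hit and the start of the downstream hit (negative
#' values encode overlap). Objects are stored in canonical form: of a
#' structure and its reverse-complement image, the lexicographically smaller
#' tuple (pwmA, pwmB, strandA, strandB) is kept, with "+" ordered before "-".
#'
#' @slot pwmA,pwmB Motif identifiers, upstream and downstream in the
#'   canonical reading.
#' @slot orientation Character vector of two strands, canonical reading.
#' @slot spacing Integer gap in bp (negative = overlapping hits).
#'
#' @seealso [DimerStructure()], [canonicalStructure()]
#' @export
setClass("DimerStructure",
  representation(
    pwmA = "character",
    pwmB = "character",
    orientation = "character",
    spacing = "integer"
  )
)

setValidity("DimerStructure", function(object) {
  msg <- character(0)
  if (length(object@orientation) != 2L ||
      !all(object@orientation %in% c("+", "-")))
    msg <- c(msg, "orientation must be two strands in {+,-}")
  if (length(object@spacing) != 1L) msg <- c(msg, "spacing must be scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a canonical dimer structure
#'
#' @param pwmA,pwmB Motif identifiers of the upstream and downstream hit.
#' @param orientation Two strands, e.g. \code{c("+", "-")}.
#' @param spacing Integer gap between the hits (bp; negative = overlap).
#' @return A [DimerStructure-class] in canonical form.
#' @examples
#' DimerStructure("M2", "M1", c("+", "-"), 3L)  # canonicalised to M1 first
#' @export
DimerStructure <- function(pwmA, pwmB, orientation, spacing) {
  can <- canonicalStructure(pwmA, pwmB, orientation[1], orientation[2],
                            as.integer(spacing))
  new("DimerStructure", pwmA = can$pwmA, pwmB = can$pwmB,
      orientation = c(can$strandA, can$strandB),
      spacing = as.integer(can$spacing))
}

#' Canonicalise a dimer arrangement
#'
#' A genomic dimer arrangement read on the minus strand is the same
#' structure: the motif order swaps and both strands flip, while the spacing
#' is unchanged. The canonical form is the lexicographically smaller of the
#' arrangement and its reverse-complement image, comparing
#' (pwmA, pwmB, strandA, strandB) with "+" before "-".
#'
#' @param pwmA,pwmB Motif ids in genomic (upstream, downstream) order.
#' @param strandA,strandB Hit strands.
#' @param spacing Gap in bp.
#' @return List with fields \code{pwmA}, \code{pwmB}, \code{strandA},
#'   \code{strandB}, \code{spacing} and \code{flipped} (TRUE when the
#'   reverse-complement image was chosen).
#' @export
canonicalStructure <- function(pwmA, pwmB, strandA, strandB, spacing) {
  key <- function(a, b, sa, sb) {
    paste(a, b, match(sa, c("+", "-")), match(sb, c("+", "-")), sep = "\r")
  }
  fwd <- key(pwmA, pwmB, strandA, strandB)
  rev <- key(pwmB, pwmA, flipStrand(strandB), flipStrand(strandA))
  flip <- rev < fwd
  list(pwmA = ifelse(flip, pwmB, pwmA),
       pwmB = ifelse(flip, pwmA, pwmB),
       strandA = ifelse(flip, flipStrand(strandB), strandA),
       strandB = ifelse(flip, flipStrand(strandA), strandB),
       spacing = spacing, flipped = flip)
}

#' @describeIn DimerStructure Single-string label
#'   \code{"pwmA;pwmB|++|3"} used as a grouping key in result tables.
#' @param x A \code{DimerStructure}.
#' @export
structureKey <- function(x) {
  paste0(x@pwmA, ";", x@pwmB, "|", paste(x@orientation, collapse = ""),
         "|", x@spacing)
}

setMethod("show", "DimerStructure", function(object) {
  cat("DimerStructure:", object@pwmA, object@orientation[1], "--[",
      object@spacing, "bp ]--", object@pwmB, object@orientation[2], "\n")
  invisible(NULL)
})

#' A 57-bp enhanceosome sequence with its genomic anchor
#'
#' @slot species "human" or "mouse".
#' @slot sequence The 57-bp DNA string.
#' @slot assembly Genome assembly of the anchor (e.g. "hg19").
#' @slot chrom Chromosome name.
#' @slot anchorStart,anchorEnd 1-based inclusive genomic positions, or NA
#'   when only the chromosome is known.
#' @slot upstreamOffset Distance in bp to the interferon-beta gene.
#' @seealso [builtinSequences()]
#' @export
setClass("EnhanceosomeSequence",
  representation(
    species = "character",
    sequence = "character",
    assembly = "character",
    chrom = "character",
    anchorStart = "numeric",
    anchorEnd = "numeric",
    upstreamOffset = "numeric"
  )
)

setValidity("EnhanceosomeSequence", function(object) {
  msg <- character(0)
  if (nchar(object@sequence) != 57L)
    msg <- c(msg, "sequence must be exactly 57 bp")
  if (!grepl("^[ACGT]+$", object@sequence))
    msg <- c(msg, "sequence alphabet must be {A,C,G,T}")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EnhanceosomeSequence", function(object) {
  cat(sprintf("EnhanceosomeSequence (%s, %s %s:%s-%s, %d bp upstream of IFNB1)\n",
              object@species, object@assembly, object@chrom,
              format(object@anchorStart), format(object@anchorEnd),
              object@upstreamOffset))
  cat(" ", object@sequence, "\n")
  invisible(NULL)
})

#' @describeIn EnhanceosomeSequence The DNA string.
#' @param x An \code{EnhanceosomeSequence}.
#' @export
enhSequence <- function(x) x@sequence

#' @describeIn EnhanceosomeSequence The species label.
#' @export
enhSpecies <- function(x) x@species

#' Block partition of two gene sets under many-to-many orthology
#'
#' Result of the iterative block-joining procedure: within each species,
#' blocks are disjoint and cover the input gene set, and at the fixed point
#' no two blocks of one species are linked to a common block of the other.
#'
#' @slot blocksH List of character vectors partitioning the human gene set.
#' @slot blocksM List of character vectors partitioning the mouse gene set.
#' @slot links Two-column integer matrix of (human block, mouse block)
#'   indices with at least one orthology pair between members.
#' @seealso [buildPartition()], [compareGeneSets()]
#' @export
setClass("OrthologyPartition",
  representation(
    blocksH = "list",
    blocksM = "list",
    links = "matrix"
  )
)

setValidity("OrthologyPartition", function(object) {
  msg <- character(0)
  hs <- unlist(object@blocksH)
  ms <- unlist(object@blocksM)
  if (anyDuplicated(hs)) msg <- c(msg, "human blocks must be disjoint")
  if (anyDuplicated(ms)) msg <- c(msg, "mouse blocks must be disjoint")
  if (nrow(object@links)) {
    if (anyDuplicated(object@links[, 1L]) || anyDuplicated(object@links[, 2L]))
      msg <- c(msg, "links must be one-to-one between blocks at fixed point")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "OrthologyPartition", function(object) {
  cat(sprintf("OrthologyPartition: %d human blocks, %d mouse blocks, %d links\n",
              length(object@blocksH), length(object@blocksM),
              nrow(object@links)))
  invisible(NULL)
})

#' @describeIn OrthologyPartition Human-side blocks.
#' @param x An \code{OrthologyPartition}.
#' @export
blocksH <- function(x) x@blocksH

#' @describeIn OrthologyPartition Mouse-side blocks.
#' @export
blocksM <- function(x) x@blocksM

#' @describeIn OrthologyPartition Block-level links (two-column matrix).
#' @export
blockLinks <- function(x) x@links
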