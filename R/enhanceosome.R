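#' The built-in human and mouse enhanceosome sequences
#'
#' The interferon-beta enhanceosome: a rigidly structured 57-bp enhancer
#' upstream of IFNB1, bound by NF-kB, ATF-2/c-Jun, IRF proteins and
#' HMG I(Y) architectural proteins. The human copy sits on hg19
#' chr9:21077989-21078045, 44 bp upstream of IFNB1; the homologous mouse
#' copy (mm9 chr4) lies 101 bp upstream of Ifnb1.
#'
#' @return Named list with \code{human} and \code{mouse}
#'   [EnhanceosomeSequence-class] objects.
#' @examples
#' nchar(enhSequence(builtinSequences()$human))  # 57
#' @export
builtinSequences <- function() {
  list(
    human = new("EnhanceosomeSequence",
      species = "human",
      sequence = "TAAATGACATAGGAAAACTGAAAGGGAGAAGTGAAAGTGGGAAATTCCTCTGAATAG",
      assembly = "hg19", chrom = "chr9",
      anchorStart = 21077989, anchorEnd = 21078045, upstreamOffset = 44),
    mouse = new("EnhanceosomeSequence",
      species = "mouse",
      sequence = "AAAATGACAGAGGAAAACTGAAAGGGAGAACTGAAAGTGGGAAATTCCTCTGAGGCA",
      assembly = "mm9", chrom = "chr4",
      anchorStart = NA_real_, anchorEnd = NA_real_, upstreamOffset = 101)
  )
}

#' Positionwise comparison of two equal-length sequences
#'
#' @param a,b DNA strings of equal length.
#' @return Ascending integer vector of 1-based mismatch positions (1-based
#'   to match the usual prose convention, "the first position").
#' @examples
#' s <- builtinSequences()
#' compareSequences(enhSequence(s$human), enhSequence(s$mouse))
#' @export
compareSequences <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("compareSequences(): sequences differ in length (",
         nchar(a), " vs ", nchar(b), ")")
  which(strsplit(toupper(a), "")[[1]] != strsplit(toupper(b), "")[[1]])
}

#' Default binding-site layout of the enhanceosome activators
#'
#' Offsets (0-based half-open) of the named activator binding sites within
#' the 57-bp sequence. The layout is a configurable table because the
#' published architecture is reported graphically; these defaults transcribe
#' the canonical arrangement: the ATF-2/c-Jun CRE-like site in PRD IV
#' flanked/overlapped by the two upstream HMG I sites (HMG-A, HMG-B), the
#' two IRF site regions (PRD III then PRD I), the NF-kB site
#' (GGGAAATTCC) in PRD II, and the third HMG I site over its AT-rich core.
#'
#' @return Data frame with columns \code{site}, \code{start}, \code{end}.
#' @export
defaultLayout <- function() {
  data.frame(
    site  = c("HMG-A", "ATF2", "HMG-B", "IRF-A", "IRF-B", "NFKB", "HMG-C"),
    start = c(0L, 4L, 12L, 17L, 29L, 38L, 41L),
    end   = c(5L, 12L, 18L, 30L, 40L, 48L, 50L),
    stringsAsFactors = FALSE
  )
}

#' Map motif hits onto an enhanceosome sequence
#'
#' Scans the 57-bp sequence with every motif on both strands at its
#' balanced threshold (unless per-motif thresholds are supplied), giving hit
#' positions relative to the enhanceosome.
#'
#' @param pwms List of [PWM-class] objects.
#' @param seq An [EnhanceosomeSequence-class] or a plain DNA string.
#' @param thresholds Optional named per-motif thresholds.
#' @param ratio,binWidth Passed to [balancedThreshold()].
#' @return Motif-hit data frame (see [scanSequence()]); \code{seqId} is the
#'   species when an [EnhanceosomeSequence-class] is given.
#' @export
mapEnhanceosomeHits <- function(pwms, seq, thresholds = NULL, ratio = 100,
                                binWidth = 0.1) {
  if (is(seq, "EnhanceosomeSequence")) {
    id <- enhSpecies(seq)
    s <- enhSequence(seq)
  } else {
    id <- "enhanceosome"
    s <- as.character(seq)
  }
  scanWithPWMs(pwms, s, thresholds = thresholds, ratio = ratio,
               binWidth = binWidth, seqId = id)
}

#' Match a dimer structure against enhanceosome motif hits
#'
#' Finds every pair of enhanceosome hits of the structure's two motifs whose
#' canonical orientation equals the structure's and whose spacing differs
#' from the structure's by at most \code{tolerance} bp. \code{delta} is
#' enhanceosome spacing minus structure spacing, so a positive delta means
#' the enhanceosome arrangement is wider than the genome-wide structure.
#'
#' @param structure A [DimerStructure-class].
#' @param enhHits Motif-hit data frame from [mapEnhanceosomeHits()].
#' @param tolerance Maximum |delta| in bp (default 2).
#' @param widths Named vector of motif widths by pwmId.
#' @return Data frame with one row per matching hit pair: hit coordinates
#'   and strands, \code{enhSpacing}, \code{delta}, \code{structure}.
#' @export
matchStructure <- function(structure, enhHits, tolerance = 2, widths) {
  empty <- data.frame(startA = integer(0), startB = integer(0),
                      strandA = character(0), strandB = character(0),
                      pwmA = character(0), pwmB = character(0),
                      enhSpacing = integer(0), delta = integer(0),
                      structure = character(0), stringsAsFactors = FALSE)
  ha <- enhHits[enhHits$pwmId == structure@pwmA, , drop = FALSE]
  hb <- enhHits[enhHits$pwmId == structure@pwmB, , drop = FALSE]
  if (!nrow(ha) || !nrow(hb)) return(empty)
  homodimer <- structure@pwmA == structure@pwmB
  grid <- expand.grid(a = seq_len(nrow(ha)), b = seq_len(nrow(hb)),
                      KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (k in seq_len(nrow(grid))) {
    A <- ha[grid$a[k], ]; B <- hb[grid$b[k], ]
    if (homodimer &&
        !(A$start < B$start ||
          (A$start == B$start && grid$a[k] < grid$b[k]))) next
    wA <- widths[[A$pwmId]]; wB <- widths[[B$pwmId]]
    aFirst <- A$start < B$start || (A$start == B$start && wA <= wB)
    up <- if (aFirst) A else B
    dn <- if (aFirst) B else A
    wUp <- if (aFirst) wA else wB
    sp <- dn$start - (up$start + wUp)
    can <- canonicalStructure(up$pwmId, dn$pwmId, up$strand, dn$strand, sp)
    if (can$pwmA != structure@pwmA || can$pwmB != structure@pwmB) next
    if (can$strandA != structure@orientation[1] ||
        can$strandB != structure@orientation[2]) next
    delta <- sp - structure@spacing
    if (abs(delta) > tolerance) next
    rows[[length(rows) + 1L]] <- data.frame(
      startA = up$start, startB = dn$start,
      strandA = up$strand, strandB = dn$strand,
      pwmA = up$pwmId, pwmB = dn$pwmId,
      enhSpacing = as.integer(sp), delta = as.integer(delta),
      structure = structureKey(structure), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$startA, out$startB), , drop = FALSE]
}

#' Classify an arrangement match into one of the four dimer types
#'
#' Each of the two hits is assigned to the layout site with the largest base
#' overlap (ties to the leftmost site); if the resulting site pair, read in
#' positional order, is one of the four enhanceosome dimer groups it is
#' returned, otherwise \code{"other"}.
#'
#' @param match One row of a [matchStructure()] result (data frame row with
#'   \code{startA}, \code{startB}, \code{pwmA}, \code{pwmB}).
#' @param layout Layout table, see [defaultLayout()].
#' @param widths Named vector of motif widths by pwmId.
#' @return One of \code{"HMG-A;ATF2"}, \code{"ATF2;HMG-B"},
#'   \code{"IRF-A;IRF-B"}, \code{"IRF-B;HMG-C"}, \code{"other"}.
#' @export
classifyDimerType <- function(match, layout = defaultLayout(), widths) {
  assignSite <- function(start, w) {
    ovl <- pmax(0, pmin(layout$end, start + w) - pmax(layout$start, start))
    if (max(ovl) <= 0) return(NA_character_)
    best <- which(ovl == max(ovl))
    layout$site[best[which.min(layout$start[best])]]  # leftmost wins ties
  }
  sA <- assignSite(match$startA, widths[[match$pwmA]])
  sB <- assignSite(match$startB, widths[[match$pwmB]])
  if (is.na(sA) || is.na(sB)) return("other")
  pair <- paste(sA, sB, sep = ";")
  groups <- c("HMG-A;ATF2", "ATF2;HMG-B", "IRF-A;IRF-B", "IRF-B;HMG-C")
  if (pair %in% groups) pair else "other"
}

#' Tabulate arrangement matches by spacing difference and dimer type
#'
#' @param matches Data frame of matches with \code{delta} and
#'   \code{dimerType} columns (e.g. [matchStructure()] output after
#'   [classifyDimerType()]).
#' @return Contingency data frame (delta x dimerType counts); totals equal
#'   the number of matches. Empty input gives a zero-row frame.
#' @export
spacingSummary <- function(matches) {
  if (!nrow(matches))
    return(data.frame(delta = integer(0), dimerType = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  if (is.null(matches$dimerType)) matches$dimerType <- "unclassified"
  tab <- as.data.frame(table(delta = matches$delta,
                             dimerType = matches$dimerType),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  out <- data.frame(delta = as.integer(tab$delta), dimerType = tab$dimerType,
                    count = as.integer(tab$Freq), stringsAsFactors = FALSE)
  out[order(out$delta, out$dimerType), , drop = FALSE]
}

#' Export the built-in enhanceosome sequences as FASTA
#'
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
writeEnhanceosomeFasta <- function(path) {
  seqs <- builtinSequences()
  set <- Biostrings::DNAStringSet(vapply(seqs, enhSequence, ""))
  names(set) <- vapply(seqs, enhSpecies, "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
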