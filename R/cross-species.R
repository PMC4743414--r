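#' Hypergeometric GO-term enrichment of a selected gene set
#'
#' Classical one-sided hypergeometric enrichment: for each term annotating
#' at least one selected gene, the p-value of drawing at least the observed
#' number of term-annotated genes when |selected| genes are drawn from the
#' universe without replacement; Benjamini-Hochberg q-values across the
#' tested terms; terms with q below the FDR cutoff are retained. No
#' ancestor propagation is applied unless a parent table is supplied.
#'
#' @param selected Character vector of selected gene ids; must be a subset
#'   of \code{universe}.
#' @param universe Character vector of all gene ids under consideration.
#' @param annotations Two-column data frame \code{gene}, \code{term}
#'   (multi-row per gene), or a named list gene -> character vector of terms.
#' @param fdr FDR cutoff on q (default 0.01).
#' @param parents Optional two-column data frame \code{child}, \code{parent}
#'   of term relations; when given, every gene's annotation is closed under
#'   ancestors before testing.
#' @return Data frame of retained terms with columns \code{term}, \code{k}
#'   (selected genes annotated), \code{m} (universe genes annotated),
#'   \code{p}, \code{q}, sorted by q then p. Attribute \code{"tested"}
#'   carries the full table before the FDR filter.
#' @examples
#' ann <- data.frame(gene = c("g1", "g2", "g3"), term = "GO:1")
#' goEnrichment(c("g1", "g2"), paste0("g", 1:50), ann, fdr = 0.05)
#' @export
goEnrichment <- function(selected, universe, annotations, fdr = 0.01,
                         parents = NULL) {
  if (!all(selected %in% universe))
    stop("goEnrichment(): selected genes must be a subset of the universe")
  ann <- normalizeAnnotations(annotations)
  if (!is.null(parents)) ann <- closeAncestors(ann, parents)
  ann <- ann[ann$gene %in% universe, , drop = FALSE]
  empty <- data.frame(term = character(0), k = integer(0), m = integer(0),
                      p = numeric(0), q = numeric(0), stringsAsFactors = FALSE)
  if (!length(selected) || !nrow(ann)) {
    attr(empty, "tested") <- empty
    return(empty)
  }
  N <- length(unique(universe))
  nSel <- length(unique(selected))
  byTerm <- split(ann$gene, ann$term)
  rows <- lapply(names(byTerm), function(t) {
    genes <- unique(byTerm[[t]])
    k <- sum(genes %in% selected)
    if (k == 0L) return(NULL)       # terms with no selected gene are skipped
    m <- length(genes)
    p <- stats::phyper(k - 1L, m, N - m, nSel, lower.tail = FALSE)
    data.frame(term = t, k = k, m = m, p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    attr(empty, "tested") <- empty
    return(empty)
  }
  tested <- do.call(rbind, rows)
  tested$q <- stats::p.adjust(tested$p, method = "BH")
  tested <- tested[order(tested$q, tested$p, tested$term), , drop = FALSE]
  rownames(tested) <- NULL
  out <- tested[tested$q < fdr, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tested") <- tested
  out
}

#' @noRd
normalizeAnnotations <- function(annotations) {
  if (is.data.frame(annotations)) {
    stopifnot(all(c("gene", "term") %in% names(annotations)))
    unique(annotations[, c("gene", "term")])
  } else {
    df <- data.frame(
      gene = rep(names(annotations), lengths(annotations)),
      term = unlist(annotations, use.names = FALSE),
      stringsAsFactors = FALSE)
    unique(df)
  }
}

# Close gene->term annotations under a child->parent term relation.
#' @noRd
closeAncestors <- function(ann, parents) {
  anc <- split(parents$parent, parents$child)
  ancestorsOf <- function(t) {
    seen <- character(0); frontier <- t
    while (length(frontier)) {
      nxt <- unique(unlist(anc[frontier], use.names = FALSE))
      nxt <- setdiff(nxt, c(seen, t))
      seen <- c(seen, nxt); frontier <- nxt
    }
    seen
  }
  extra <- lapply(unique(ann$term), ancestorsOf)
  names(extra) <- unique(ann$term)
  addRows <- lapply(seq_len(nrow(ann)), function(i) {
    up <- extra[[ann$term[i]]]
    if (!length(up)) return(NULL)
    data.frame(gene = ann$gene[i], term = up, stringsAsFactors = FALSE)
  })
  addRows <- addRows[!vapply(addRows, is.null, TRUE)]
  unique(rbind(ann, do.call(rbind, addRows)))
}

#' Strip an enrichment result to its term-id set
#'
#' @param enrichment A [goEnrichment()] result (or any data frame with a
#'   \code{term} column, or already a character vector).
#' @return Character vector of term ids (unique, sorted).
#' @export
termSetOf <- function(enrichment) {
  if (is.character(enrichment)) return(sort(unique(enrichment)))
  sort(unique(enrichment$term))
}

#' One-sided Fisher test for the overlap of two enriched-term sets
#'
#' Builds the 2x2 table of term-universe membership in the human vs mouse
#' enriched sets and evaluates the exact one-sided (enrichment)
#' hypergeometric p-value for the observed intersection.
#'
#' @param tH,tM Character vectors of enriched term ids, subsets of
#'   \code{universe}.
#' @param universe Character vector: all terms assignable to genes of either
#'   species.
#' @return List with the 2x2 \code{table}, \code{p} and \code{minusLog10P}.
#' @export
compareTermSets <- function(tH, tM, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("compareTermSets(): empty term universe")
  if (!all(tH %in% universe) || !all(tM %in% universe))
    stop("compareTermSets(): term sets must lie within the universe")
  tH <- unique(tH); tM <- unique(tM)
  a <- length(intersect(tH, tM))
  b <- length(tH) - a
  c <- length(tM) - a
  d <- length(universe) - a - b - c
  # exact upper tail: P(overlap >= a) drawing |tH| of the universe with
  # |tM| marked
  p <- stats::phyper(a - 1L, a + c, b + d, a + b, lower.tail = FALSE)
  list(table = matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                      dimnames = list(c("inH", "notH"), c("inM", "notM"))),
       p = p, minusLog10P = -log10(p))
}

#' Ortholog-block partition of two gene sets
#'
#' Implements the iterative block-joining procedure: initially every gene is
#' its own block and blocks are linked by the many-to-many orthology
#' relation; whenever two blocks of one species are linked to a common block
#' of the other species they are joined, until no join applies. At the
#' fixed point the human and mouse blocks over a connected set of genes are
#' linked one-to-one. Genes without any restricted orthology remain
#' singleton, unlinked blocks.
#'
#' @param gH,gM Character vectors: the human and mouse gene sets.
#' @param rO Two-column data frame \code{human}, \code{mouse} of ortholog
#'   pairs (many-to-many); pairs outside \code{gH}/\code{gM} are ignored.
#' @return An [OrthologyPartition-class].
#' @examples
#' buildPartition(c("h1", "h2"), "m1",
#'                data.frame(human = c("h1", "h2"), mouse = "m1"))
#' @export
buildPartition <- function(gH, gM, rO) {
  gH <- sort(unique(gH)); gM <- sort(unique(gM))
  rO <- unique(rO[rO$human %in% gH & rO$mouse %in% gM, , drop = FALSE])
  # block membership: index per gene, initially singletons
  bH <- seq_along(gH); names(bH) <- gH
  bM <- seq_along(gM); names(bM) <- gM
  repeat {
    changed <- FALSE
    if (nrow(rO)) {
      # join human blocks linked to a common mouse block
      linkH <- split(bH[rO$human], bM[rO$mouse])
      for (grp in linkH) {
        u <- unique(grp)
        if (length(u) > 1L) { bH[bH %in% u] <- u[1L]; changed <- TRUE }
      }
      # and mouse blocks linked to a common human block
      linkM <- split(bM[rO$mouse], bH[rO$human])
      for (grp in linkM) {
        u <- unique(grp)
        if (length(u) > 1L) { bM[bM %in% u] <- u[1L]; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  fH <- factor(bH, levels = sort(unique(bH)))
  fM <- factor(bM, levels = sort(unique(bM)))
  blocksH <- unname(split(gH, fH))
  blocksM <- unname(split(gM, fM))
  links <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("h", "m")))
  if (nrow(rO)) {
    hIdx <- as.integer(fH)[match(rO$human, gH)]
    mIdx <- as.integer(fM)[match(rO$mouse, gM)]
    links <- unique(cbind(h = hIdx, m = mIdx))
  }
  new("OrthologyPartition", blocksH = blocksH, blocksM = blocksM,
      links = links)
}

#' Fisher test for cross-species similarity of selected gene sets
#'
#' Selected human and mouse gene sets are first reduced to ortholog blocks
#' ([buildPartition()] on the selected sets); the "intersection" is the
#' number of human blocks linked to a mouse block by at least one orthology
#' pair. The universe size is the number of equivalence classes of the union
#' of both full universes under the complete orthology relation (a linked
#' human/mouse block pair counts once). The one-sided Fisher p-value of the
#' 2x2 table [[a, b], [c, N - a - b - c]] is reported, where a = linked
#' human blocks, b = unlinked human blocks, c = unlinked mouse blocks.
#'
#' @param gH,gM Selected human and mouse gene sets.
#' @param rO Ortholog-pair data frame (\code{human}, \code{mouse}).
#' @param universeH,universeM Full gene universes per species.
#' @return List with \code{a} (linked human blocks), \code{aPrime} (linked
#'   mouse blocks), \code{b}, \code{c}, \code{N}, \code{table}, \code{p},
#'   \code{minusLog10P}.
#' @export
compareGeneSets <- function(gH, gM, rO, universeH, universeM) {
  if (!all(gH %in% universeH) || !all(gM %in% universeM))
    stop("compareGeneSets(): selected genes must lie within their universe")
  part <- buildPartition(gH, gM, rO)
  a <- length(unique(blockLinks(part)[, "h"]))
  aPrime <- length(unique(blockLinks(part)[, "m"]))
  b <- length(blocksH(part)) - a
  c <- length(blocksM(part)) - aPrime
  full <- buildPartition(universeH, universeM, rO)
  # one class per linked block pair, plus unlinked blocks of either side
  N <- length(blocksH(full)) + length(blocksM(full)) - nrow(blockLinks(full))
  if (N < a + b + c)
    stop("compareGeneSets(): universe smaller than selected block counts")
  d <- N - a - b - c
  p <- stats::phyper(a - 1L, a + b, N - a - b, a + c, lower.tail = FALSE)
  list(a = a, aPrime = aPrime, b = b, c = c, N = N,
       table = matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                      dimnames = list(c("selH", "notH"), c("selM", "notM"))),
       p = p, minusLog10P = -log10(p))
}

#' Read a two-column ortholog-pair TSV
#'
#' @param path TSV with columns human, mouse (header optional: detected).
#' @return Data frame with \code{human}, \code{mouse} columns.
#' @export
readOrthologs <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("human", first, ignore.case = TRUE)
  df <- read.table(path, sep = "\t", header = hasHeader,
                   stringsAsFactors = FALSE)
  names(df)[1:2] <- c("human", "mouse")
  df[, c("human", "mouse")]
}

#' Read a two-column gene-to-GO-term TSV
#'
#' @param path TSV with columns gene, term (multi-row per gene; header
#'   optional, detected on the word "gene").
#' @return Data frame with \code{gene}, \code{term} columns.
#' @export
readGoAnnotations <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("gene", first, ignore.case = TRUE)
  df <- read.table(path, sep = "\t", header = hasHeader,
                   stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene", "term")
  df[, c("gene", "term")]
}
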