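#' Read PWMs from a TRANSFAC-format matrix file
#'
#' Parses the TRANSFAC matrix dialect: records delimited by \code{//} lines,
#' with \code{ID}/\code{AC} header lines, an optional \code{P0} column-header
#' line, and numbered rows \code{01..NN} carrying four count columns in
#' A, C, G, T order (an optional trailing consensus letter is ignored).
#'
#' @param path Path to the matrix file.
#' @param pseudocount,background Passed to [PWM()] for every record.
#' @return List of [PWM-class] objects, one per record. An empty file yields
#'   an empty list with a warning.
#' @examples
#' tf <- tempfile(fileext = ".transfac")
#' writeLines(c("ID toy", "P0 A C G T", "01 10 0 0 0", "02 0 10 0 0", "//"), tf)
#' readTransfac(tf)
#' @export
readTransfac <- function(path, pseudocount = 0.01,
                         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  lines <- readLines(path, warn = FALSE)
  pwms <- list()
  id <- ac <- NA_character_
  rows <- list()
  rowLabels <- character(0)
  flush <- function() {
    if (!length(rows)) return(NULL)
    counts <- do.call(cbind, rows)
    rownames(counts) <- DNA_BASES4
    mid <- if (!is.na(id)) id else if (!is.na(ac)) ac
           else paste0("record_", length(pwms) + 1L)
    PWM(counts, id = mid, pseudocount = pseudocount, background = background)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (ln == "//") {
      p <- flush()
      if (!is.null(p)) pwms[[length(pwms) + 1L]] <- p
      id <- ac <- NA_character_
      rows <- list(); rowLabels <- character(0)
      next
    }
    toks <- strsplit(ln, "[ \t]+")[[1]]
    tag <- toks[[1]]
    if (tag == "ID" && length(toks) > 1L) { id <- toks[[2]]; next }
    if (tag == "AC" && length(toks) > 1L) { ac <- toks[[2]]; next }
    if (grepl("^[0-9][0-9]$", tag)) {
      vals <- suppressWarnings(as.numeric(toks[-1L]))
      nNum <- length(vals) - sum(is.na(vals))
      # exactly 4 numeric count columns, optionally followed by a consensus
      # letter; anything else is malformed
      ok <- length(vals) >= 4L && !anyNA(vals[1:4]) &&
        (length(vals) == 4L ||
           (length(vals) == 5L && is.na(vals[5L]) && nNum == 4L))
      if (!ok)
        stop(sprintf("readTransfac(): malformed row %s at line %d: '%s'",
                     tag, i, lines[[i]]))
      rows[[length(rows) + 1L]] <- vals[1:4]
      rowLabels <- c(rowLabels, tag)
      next
    }
    # other TRANSFAC tags (P0, NA, DE, BF, XX, CC, ...) are skipped
  }
  p <- flush()
  if (!is.null(p)) pwms[[length(pwms) + 1L]] <- p
  if (!length(pwms)) warning("readTransfac(): no matrix records in ", path)
  pwms
}

#' Score one window of a sequence against a PWM
#'
#' Sum over positions of \code{log2(p(base)/background(base))} using the
#' pseudocount-smoothed probabilities. On strand \code{-} the reverse
#' complement of the window is scored. Any non-ACGT base in the window gives
#' \code{-Inf}: ambiguous windows are disqualified rather than averaged.
#'
#' @param pwm A [PWM-class].
#' @param seq DNA string over \{A,C,G,T,N\}.
#' @param start 0-based window offset.
#' @param strand \code{"+"} or \code{"-"}.
#' @return Log2-odds score in bits (scalar).
#' @examples
#' m <- PWM(matrix(c(0.97, 0.01, 0.01, 0.01, 0.01, 0.97, 0.01, 0.01),
#'                 nrow = 4), id = "ac", pseudocount = 0)
#' logOddsScore(m, "GGACGG", 2, "+")  # 2*log2(0.97/0.25)
#' @export
logOddsScore <- function(pwm, seq, start, strand = "+") {
  w <- pwmWidth(pwm)
  n <- nchar(seq)
  if (start < 0 || start + w > n)
    stop("logOddsScore(): window [", start, ",", start + w,
         ") out of bounds for sequence of length ", n)
  window <- substr(seq, start + 1L, start + w)
  if (strand == "-") window <- revCompString(window)
  codes <- dnaCodes(window)
  if (anyNA(codes)) return(-Inf)
  lom <- logOddsMatrix(pwm)
  sum(lom[cbind(codes, seq_len(w))])
}

# Per-column discretised log-odds values: bin index = round(score/binWidth).
# The discretised window score is the SUM of per-column bin indices times
# binWidth, which is what scoreDistribution(), balancedThreshold() and their
# enumeration oracles all share.
#' @noRd
binnedColumnScores <- function(pwm, binWidth) {
  round(logOddsMatrix(pwm) / binWidth)
}

#' Exact distribution of the discretised PWM score
#'
#' Computes, by column-wise convolution (exact dynamic programming, no
#' sampling), the distribution of the discretised log-odds score of a
#' width-w window whose columns are drawn i.i.d. from either the background
#' composition or the motif's own smoothed probabilities. Scores are
#' discretised per column to multiples of \code{binWidth} before summing.
#'
#' @param pwm A [PWM-class].
#' @param model \code{"background"} or \code{"motif"}: the generating model.
#' @param binWidth Positive bin width in bits (default 0.1).
#' @return List with \code{score} (numeric grid, ascending), \code{mass}
#'   (probabilities summing to 1 within 1e-6) and \code{binWidth}.
#' @seealso [balancedThreshold()]
#' @export
scoreDistribution <- function(pwm, model = c("background", "motif"),
                              binWidth = 0.1) {
  model <- match.arg(model)
  stopifnot(binWidth > 0)
  bins <- binnedColumnScores(pwm, binWidth)
  probs <- if (model == "background")
    matrix(pwmBackground(pwm), nrow = 4L, ncol = pwmWidth(pwm))
  else pwmProbs(pwm)
  # DP over columns on integer bin offsets
  lo <- sum(apply(bins, 2L, min)); hi <- sum(apply(bins, 2L, max))
  mass <- c(1)               # distribution over offsets, support starts at 0
  offset <- 0                # integer bin value of mass[1]
  for (j in seq_len(pwmWidth(pwm))) {
    bj <- bins[, j]; pj <- probs[, j]
    newLo <- offset + min(bj); newHi <- offset + length(mass) - 1L + max(bj)
    newMass <- numeric(newHi - newLo + 1L)
    for (b in 1:4) {
      if (pj[b] <= 0) next
      at <- (offset + bj[b] - newLo) + seq_along(mass)
      newMass[at] <- newMass[at] + mass * pj[b]
    }
    mass <- newMass; offset <- newLo
  }
  keep <- mass > 0
  idx <- (offset + seq_along(mass) - 1L)[keep]
  list(score = idx * binWidth, mass = mass[keep], binWidth = binWidth)
}

#' Balanced score threshold (false-positive / false-negative ratio)
#'
#' The motif score cutoff at which the false positive rate is at most
#' \code{ratio} times the false negative rate: FPR(t) = P(score >= t |
#' background model) and FNR(t) = P(score < t | motif model), both from the
#' exact discretised score distributions. Returns the smallest grid
#' threshold t with FPR(t) <= ratio * FNR(t); since FPR is nonincreasing and
#' FNR nondecreasing in t, the solution set is an upper interval of the grid.
#'
#' @param pwm A [PWM-class].
#' @param ratio Target FPR/FNR ratio (default 100).
#' @param binWidth Discretisation bin width in bits (default 0.1).
#' @return Threshold score in bits (a grid point). For a degenerate PWM
#'   where no grid point satisfies the condition, the maximum achievable
#'   score is returned with a warning.
#' @examples
#' m <- PWM(matrix(c(9, 1, 1, 1, 1, 9, 1, 1, 1, 1, 9, 1), nrow = 4), id = "x")
#' balancedThreshold(m, ratio = 100)
#' @export
balancedThreshold <- function(pwm, ratio = 100, binWidth = 0.1) {
  stopifnot(ratio > 0)
  bg <- scoreDistribution(pwm, "background", binWidth)
  mo <- scoreDistribution(pwm, "motif", binWidth)
  grid <- sort(unique(c(bg$score, mo$score)))
  # survival of bg at >= t, cdf of motif at < t, on the common grid
  fpr <- vapply(grid, function(t) sum(bg$mass[bg$score >= t - 1e-12]), 0)
  fnr <- vapply(grid, function(t) sum(mo$mass[mo$score < t - 1e-12]), 0)
  ok <- fpr <= ratio * fnr
  if (!any(ok)) {
    warning("balancedThreshold(): degenerate PWM '", pwmId(pwm),
            "'; returning max-score threshold")
    return(max(grid))
  }
  grid[which(ok)[1L]]
}

#' Scan a sequence with a PWM on both strands
#'
#' Reports all windows, on both strands, whose exact log-odds score is at
#' least \code{threshold}. Hits may overlap. Results are sorted by start
#' then strand (\code{+} before \code{-} at the same start).
#'
#' @param pwm A [PWM-class].
#' @param seq DNA string (case-insensitive; N allowed, N-containing windows
#'   never score above any finite threshold).
#' @param threshold Finite score cutoff in bits; typically
#'   [balancedThreshold()].
#' @param seqId Sequence identifier recorded in the hit table.
#' @return Motif-hit data frame with columns \code{seqId}, \code{start}
#'   (0-based), \code{strand}, \code{score}, \code{pwmId}. A sequence
#'   shorter than the motif yields zero rows.
#' @examples
#' m <- PWM(matrix(c(1, 0, 0, 0, 0, 0, 0, 1), nrow = 4), id = "AT",
#'          pseudocount = 0)
#' scanSequence(m, "GGATGG", threshold = 1)
#' @export
scanSequence <- function(pwm, seq, threshold, seqId = "seq") {
  stopifnot(is.finite(threshold))
  w <- pwmWidth(pwm)
  n <- nchar(seq)
  empty <- data.frame(seqId = character(0), start = integer(0),
                      strand = character(0), score = numeric(0),
                      pwmId = character(0), stringsAsFactors = FALSE)
  if (n < w) return(empty)
  codes <- dnaCodes(seq)
  lom <- logOddsMatrix(pwm)
  # strand "-": scoring the reverse complement of a window equals scoring
  # the window itself with the reverse-complemented matrix
  lomRC <- lom[4:1, w:1, drop = FALSE]
  starts <- 0:(n - w)
  scoreWith <- function(m) {
    s <- numeric(length(starts))
    for (j in seq_len(w)) {
      col <- m[, j][codes[starts + j]]
      col[is.na(col)] <- -Inf
      s <- s + col
    }
    s
  }
  sPlus <- scoreWith(lom)
  sMinus <- scoreWith(lomRC)
  hp <- which(sPlus >= threshold)
  hm <- which(sMinus >= threshold)
  out <- data.frame(
    seqId = seqId,
    start = c(starts[hp], starts[hm]),
    strand = c(rep("+", length(hp)), rep("-", length(hm))),
    score = c(sPlus[hp], sMinus[hm]),
    pwmId = pwmId(pwm),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan with several PWMs at their balanced thresholds
#'
#' Convenience wrapper: derives each motif's balanced threshold (unless
#' overridden) and concatenates [scanSequence()] results.
#'
#' @param pwms List of [PWM-class] objects.
#' @param seq DNA string to scan.
#' @param thresholds Optional named numeric vector of per-motif thresholds;
#'   motifs not named get the balanced threshold.
#' @param ratio,binWidth Passed to [balancedThreshold()].
#' @param seqId Sequence identifier for the hit table.
#' @return Combined motif-hit data frame (see [scanSequence()]).
#' @export
scanWithPWMs <- function(pwms, seq, thresholds = NULL, ratio = 100,
                         binWidth = 0.1, seqId = "seq") {
  empty <- data.frame(seqId = character(0), start = integer(0),
                      strand = character(0), score = numeric(0),
                      pwmId = character(0), stringsAsFactors = FALSE)
  if (!length(pwms)) return(empty)
  hits <- lapply(pwms, function(p) {
    t <- if (!is.null(thresholds) && pwmId(p) %in% names(thresholds))
      thresholds[[pwmId(p)]]
    else balancedThreshold(p, ratio = ratio, binWidth = binWidth)
    scanSequence(p, seq, t, seqId = seqId)
  })
  out <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  if (is.null(out)) empty else out
}
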