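# Shared fixtures and independent oracles. Oracles enumerate or sum
# directly and never call the code paths they check.

BASES <- c("A", "C", "G", "T")

# random count PWM of a given width
randomPWM <- function(width, seed, id = paste0("R", seed)) {
  set.seed(seed)
  PWM(matrix(runif(4 * width, 0.1, 10), nrow = 4,
             dimnames = list(BASES, NULL)), id = id)
}

# sharp consensus PWM (counts hi on the consensus base, rest shared)
consensusPWM <- function(word, id = word, hi = 97) {
  w <- nchar(word)
  counts <- matrix((100 - hi) / 3, nrow = 4, ncol = w,
                   dimnames = list(BASES, NULL))
  idx <- match(strsplit(word, "")[[1]], BASES)
  counts[cbind(idx, seq_len(w))] <- hi
  PWM(counts, id = id)
}

# --- enumeration oracle over all 4^w words -------------------------------
# per-word discretised scores plus background/motif weights
enumerateWords <- function(pwm, binWidth = 0.1) {
  w <- pwmWidth(pwm)
  bins <- round(log2(pwmProbs(pwm) / pwmBackground(pwm)) / binWidth)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  list(
    score = apply(words, 1, function(x) sum(bins[cbind(x, seq_len(w))])) *
      binWidth,
    wBg = apply(words, 1, function(x) prod(pwmBackground(pwm)[x])),
    wMotif = apply(words, 1, function(x)
      prod(pwmProbs(pwm)[cbind(x, seq_len(w))]))
  )
}

# brute-force balanced threshold from the word enumeration
bruteForceThreshold <- function(pwm, ratio = 100, binWidth = 0.1) {
  e <- enumerateWords(pwm, binWidth)
  grid <- sort(unique(e$score))
  fpr <- vapply(grid, function(t) sum(e$wBg[e$score >= t - 1e-12]), 0)
  fnr <- vapply(grid, function(t) sum(e$wMotif[e$score < t - 1e-12]), 0)
  ok <- which(fpr <= ratio * fnr)
  if (!length(ok)) return(max(grid))
  grid[ok[1]]
}

# exact binomial upper tail by direct log-space summation
binomTailSum <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# connected components of the bipartite orthology graph via union-find;
# independent of buildPartition's iterative joining
unionFindBlocks <- function(gH, gM, pairs) {
  nodes <- c(paste0("H|", sort(unique(gH))), paste0("M|", sort(unique(gM))))
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    a <- paste0("H|", pairs$human[r]); b <- paste0("M|", pairs$mouse[r])
    if (!(a %in% nodes) || !(b %in% nodes)) next
    ra <- find(which(nodes == a)); rb <- find(which(nodes == b))
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(seq_along(nodes), find, 0L)
  side <- substr(nodes, 1, 1)
  gene <- substr(nodes, 3, nchar(nodes))
  hBlocks <- split(gene[side == "H"], comp[side == "H"])
  mBlocks <- split(gene[side == "M"], comp[side == "M"])
  list(h = unname(lapply(hBlocks, sort)), m = unname(lapply(mBlocks, sort)))
}

# canonical string form of a set of blocks, for set-of-sets comparison
blockSignature <- function(blocks) {
  sort(vapply(blocks, function(b) paste(sort(b), collapse = ","), ""))
}

# write a TRANSFAC-format fixture file and return its path
writeTransfacFixture <- function(records, path = tempfile(fileext = ".txt")) {
  lines <- character(0)
  for (r in records) {
    lines <- c(lines, paste("ID", r$id), "P0 A C G T")
    for (i in seq_len(ncol(r$counts)))
      lines <- c(lines, paste(sprintf("%02d", i),
                              paste(r$counts[, i], collapse = " ")))
    lines <- c(lines, "//")
  }
  writeLines(lines, path)
  path
}

# small genomic hit table builder
mkHits <- function(chrom, start, strand, pwm, score = 10) {
  data.frame(seqId = chrom, start = as.integer(start), strand = strand,
             score = score, pwmId = pwm, stringsAsFactors = FALSE)
}

mkRegions <- function(chrom, start0, end0, cellType = "ct",
                      replicate = "rep1", signal = 1) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1L, end = end0),
                         signalValue = signal, cellType = cellType,
                         replicate = replicate)
}

mkGenes <- function(chrom, start0, end0, ids, strand = "+") {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1L, end = end0),
                         strand = strand, geneId = ids)
}
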