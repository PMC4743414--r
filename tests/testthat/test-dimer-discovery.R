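test_that("narrowPeak reading preserves coordinates and validates format", {
  f <- tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t200\t.\t0\t.\t5.5\t-1\t-1\t50",
               "chr1\t300\t500\t.\t0\t.\t2.0\t-1\t-1\t50",
               "chr2\t10\t60\t.\t0\t.\t9.9\t-1\t-1\t20"), f)
  r <- readNarrowPeak(f, "K562", "rep1")
  expect_length(r, 3L)
  expect_equal(GenomicRanges::start(r)[1], 101L)  # 0-based 100
  expect_equal(GenomicRanges::end(r)[1], 200L)
  expect_equal(r$signalValue, c(5.5, 2.0, 9.9))
  bad <- tempfile()
  writeLines(c("chr1\t1\t2\t.\t0\t.\t1\t-1\t-1\t5",
               "chr1\t1\t2\t.\t0\t.\t1\t-1\t-1"), bad)
  expect_error(readNarrowPeak(bad), "line 2 has 9 columns")
  rev <- tempfile()
  writeLines("chr1\t200\t100\t.\t0\t.\t1\t-1\t-1\t5", rev)
  expect_error(readNarrowPeak(rev), "start >= end")
})

test_that("top-region selection works per replicate and is idempotent", {
  r <- c(mkRegions("chr1", c(0, 100, 200, 300, 400),
                   c(50, 150, 250, 350, 450), signal = 1:5),
         mkRegions("chr1", c(600, 700, 800), c(650, 750, 850),
                   replicate = "rep2", signal = c(9, 8, 7)))
  # "up to": small count honoured per replicate
  sel <- selectTopRegions(r, count = 2)
  expect_length(sel, 4L)
  expect_setequal(sel$signalValue, c(5, 4, 9, 8))
  # all kept when count exceeds availability
  expect_length(selectTopRegions(r, count = 50000), 8L)
  # idempotence
  expect_identical(selectTopRegions(sel, count = 2), sel)
})

test_that("majority masking uses a strict-majority rule without trimming", {
  r <- mkRegions("chr1", 0, 100)            # length 100
  m51 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 51))
  m50 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50))
  expect_length(applyMasking(r, m51), 0L)   # 51 masked -> excluded
  kept <- applyMasking(r, m50)              # 50 masked -> kept
  expect_length(kept, 1L)
  expect_equal(GenomicRanges::width(kept), 100L)
  expect_identical(applyMasking(r, GenomicRanges::GRanges()), r)
})

test_that("dimer instances: spacing arithmetic, region confinement, homodimers", {
  widths <- c(A = 8L, B = 8L)
  reg <- mkRegions("chr1", 0, 100)
  hA <- mkHits("chr1", 10, "+", "A")
  hB <- mkHits("chr1", 20, "+", "B")
  inst <- findDimerInstances(hA, hB, reg, maxGap = 50, widths = widths)
  expect_equal(nrow(inst), 1L)
  expect_equal(inst$spacing, 2L)            # [10,18) then [20,28)
  expect_equal(inst$start, 10L)
  expect_equal(inst$end, 28L)
  expect_equal(inst$end - inst$start, 8L + 8L + 2L)
  # different regions: no instance
  reg2 <- c(mkRegions("chr1", 0, 15), mkRegions("chr1", 18, 100))
  expect_equal(nrow(findDimerInstances(hA, hB, reg2, 50, widths)), 0L)
  # homodimer counted once, no self-pairing
  hh <- mkHits("chr1", c(10, 20), "+", "A")
  instH <- findDimerInstances(hh, hh, reg, 50, widths)
  expect_equal(nrow(instH), 1L)
  # maxGap bound respected
  far <- mkHits("chr1", 80, "+", "B")
  expect_equal(nrow(findDimerInstances(hA, far, reg, 50, widths)), 0L)
})

test_that("canonicalization is idempotent and reverse-complement stable", {
  set.seed(7)
  for (i in 1:50) {
    ids <- sample(c("M1", "M2", "M3"), 2, replace = TRUE)
    s <- sample(c("+", "-"), 2, replace = TRUE)
    sp <- sample(-5:20, 1)
    c1 <- canonicalStructure(ids[1], ids[2], s[1], s[2], sp)
    c2 <- canonicalStructure(c1$pwmA, c1$pwmB, c1$strandA, c1$strandB,
                             c1$spacing)
    expect_false(c2$flipped)                 # idempotent
    # the reverse-complement image canonicalises to the same form
    rc <- canonicalStructure(ids[2], ids[1],
                             ifelse(s[2] == "+", "-", "+"),
                             ifelse(s[1] == "+", "-", "+"), sp)
    expect_equal(rc[c("pwmA", "pwmB", "strandA", "strandB", "spacing")],
                 c1[c("pwmA", "pwmB", "strandA", "strandB", "spacing")])
  }
  # preference at equal ids: (+,+) beats (-,-), (+,-) is its own image
  expect_equal(canonicalStructure("M", "M", "-", "-", 3)$strandA, "+")
  expect_false(canonicalStructure("M", "M", "+", "-", 3)$flipped)
})

test_that("instance counts are invariant under genome reverse complement", {
  sim <- simulateStudy(seed = 21, genomeLength = 2e5, nPeaks = 30,
                       nCopies = 10)
  widths <- vapply(sim$pwms, pwmWidth, 0L)
  thr <- vapply(sim$pwms, balancedThreshold, 0)
  hits <- scanWithPWMs(sim$pwms, sim$genome[[1]], thresholds = thr,
                       seqId = "chr1")
  inst <- findDimerInstances(hits[hits$pwmId == "SYNA", ],
                             hits[hits$pwmId == "SYNB", ],
                             sim$regions, 50, widths)
  # mirror everything
  L <- nchar(sim$genome[[1]])
  rcGenome <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sim$genome[[1]])))
  rcRegions <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = L - GenomicRanges::end(sim$regions) + 1L,
                     end = L - GenomicRanges::start(sim$regions) + 1L),
    signalValue = sim$regions$signalValue,
    cellType = sim$regions$cellType, replicate = sim$regions$replicate)
  rcHits <- scanWithPWMs(sim$pwms, rcGenome, thresholds = thr,
                         seqId = "chr1")
  rcInst <- findDimerInstances(rcHits[rcHits$pwmId == "SYNA", ],
                               rcHits[rcHits$pwmId == "SYNB", ],
                               rcRegions, 50, widths)
  expect_equal(nrow(rcInst), nrow(inst))
  expect_equal(sort(table(rcInst$structure)), sort(table(inst$structure)))
})

test_that("overrepresentation p-values come from the exact binomial tail", {
  # equal rates: p >= 0.5
  inst <- data.frame(
    structure = "S", cellType = rep(c("t", "b"), c(10, 10)),
    stringsAsFactors = FALSE)
  resEq <- testOverrepresentation(inst, c(t = 1e5, b = 1e5))
  expect_gte(resEq$p[resEq$cellType == "t"], 0.5)
  # strong enrichment: 20/1e4 vs 20/1e6, exact tail via independent summation
  inst2 <- data.frame(structure = "S",
                      cellType = rep(c("t", "b"), c(20, 20)),
                      stringsAsFactors = FALSE)
  res <- testOverrepresentation(inst2, c(t = 1e4, b = 1e6))
  pT <- res$p[res$cellType == "t"]
  expect_lt(pT, 1e-6)
  expect_equal(pT, binomTailSum(20, 40, 1e4 / (1e4 + 1e6)),
               tolerance = 1e-12)
  # zero bp errors
  expect_error(testOverrepresentation(inst, c(t = 0, b = 1)), "positive")
})

test_that("BH q-values dominate p-values and respect their ordering", {
  set.seed(5)
  inst <- data.frame(
    structure = rep(paste0("S", 1:6), times = c(9, 7, 5, 3, 2, 1)),
    cellType = "t", stringsAsFactors = FALSE)
  instB <- data.frame(structure = rep(paste0("S", 1:6), each = 3),
                      cellType = "b", stringsAsFactors = FALSE)
  res <- testOverrepresentation(rbind(inst, instB), c(t = 1e4, b = 1e6))
  expect_true(all(res$q >= res$p))
  for (ct in unique(res$cellType)) {
    sub <- res[res$cellType == ct, ]
    o <- order(sub$p)
    expect_false(is.unsorted(sub$q[o]))     # monotone transform of p
    expect_equal(sub$q, stats::p.adjust(sub$p, "BH"), tolerance = 1e-12)
  }
})
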