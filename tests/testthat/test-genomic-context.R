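test_that("instance midpoints take the floor of the interval average", {
  expect_equal(instanceMidpoint(100, 110), 105)
  expect_equal(instanceMidpoint(100, 111), 105)
  expect_equal(instanceMidpoint(0, 2), 1)
  expect_error(instanceMidpoint(5, 5))
})

test_that("nearest-gene lookup handles containment, distance and ties", {
  genes <- mkGenes("chr1", c(100, 400), c(200, 500), c("gB", "gA"))
  # inside a gene: distance 0, flagged
  r <- nearestGene("chr1", 150, genes)
  expect_true(r$withinGene)
  expect_equal(r$distance, 0)
  expect_equal(r$geneId, "gB")
  # between: closer boundary wins (50 left of gA start beats 100 right of gB)
  r2 <- nearestGene("chr1", 350, genes)
  expect_equal(r2$geneId, "gA")
  expect_equal(r2$distance, 50)
  expect_false(r2$withinGene)
  # equidistant: lexicographically smaller id
  r3 <- nearestGene("chr1", 300, genes)  # 100 right of gB end-1? compute both
  dB <- 300 - (200 - 1); dA <- 400 - 300
  expect_equal(r3$distance, min(dA, dB))
  genesTie <- mkGenes("chr1", c(0, 210), c(100, 300), c("gZ", "gY"))
  rT <- nearestGene("chr1", 154, genesTie)  # 55 from gZ end-1, 56 from gY
  expect_equal(rT$geneId, "gZ")
  genesTie2 <- mkGenes("chr1", c(0, 209), c(100, 300), c("gZ", "gY"))
  rT2 <- nearestGene("chr1", 154, genesTie2)  # both 55 away
  expect_equal(rT2$geneId, "gY")              # "gY" < "gZ"
  # no gene on the chromosome
  rN <- nearestGene("chr2", 10, genes)
  expect_true(is.na(rN$geneId))
  expect_equal(rN$distance, Inf)
})

test_that("Q0-Q6 gene selection nests and uses strict thresholds", {
  genes <- mkGenes("chr1", c(1000, 5000), c(2000, 6000), c("g1", "g2"))
  inst <- data.frame(chrom = "chr1",
                     start = c(1500, 2195, 2995, 10995, 54995),
                     end = c(1510, 2205, 3005, 11005, 55005),
                     stringsAsFactors = FALSE)
  ann <- annotateNearestGene(inst, genes)
  expect_equal(selectGenes(ann, "Q0"), "g1")
  # midpoint 2200 is 201 bp from g1 end-1 (1999): outside Q1/Q2, inside Q3
  expect_equal(ann$distance[2], 2200 - 1999)
  expect_false("g1" %in% selectGenes(ann, "Q2") &&
                 ann$distance[2] >= 500)
  qs <- lapply(paste0("Q", 1:6), selectGenes, instances = ann)
  for (i in 2:6) expect_true(all(qs[[i - 1]] %in% qs[[i]]))  # nesting
  # strict <: a midpoint exactly at the threshold is excluded
  instEdge <- data.frame(chrom = "chr1", start = 2094, end = 2104,
                         stringsAsFactors = FALSE)   # midpoint 2099, d = 100
  annEdge <- annotateNearestGene(instEdge, genes)
  expect_equal(annEdge$distance, 100)
  expect_length(selectGenes(annEdge, "Q1"), 0L)
  expect_equal(selectGenes(annEdge, "Q2"), "g1")
})

test_that("within-gene fraction reproduces reported percentages", {
  expect_equal(withinGeneFraction(rep(c(TRUE, FALSE), c(1105, 2029 - 1105))),
               54L)
  expect_equal(withinGeneFraction(rep(FALSE, 10)), 0L)
  expect_equal(withinGeneFraction(rep(TRUE, 10)), 100L)
  expect_error(withinGeneFraction(logical(0)), "no instances")
  # invariant under permutation
  set.seed(3)
  flags <- sample(c(TRUE, FALSE), 101, replace = TRUE)
  expect_equal(withinGeneFraction(flags), withinGeneFraction(sample(flags)))
})

test_that("state assignment uses the midpoint and flags gaps/overlaps", {
  seg <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1, 101), c(100, 200)),
                                state = c("Strong_Enhancer", "Repressed"))
  inst <- data.frame(chrom = "chr1", start = c(10, 90, 300),
                     end = c(20, 120, 310), stringsAsFactors = FALSE)
  st <- assignState(inst, seg)
  expect_equal(st[1], "Strong_Enhancer")
  # straddling instance: midpoint 105 falls in the second segment
  expect_equal(st[2], "Repressed")
  expect_equal(st[3], "unannotated")
  segBad <- c(seg, GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 50),
                                          state = "Weak_Txn"))
  expect_error(assignState(inst, segBad), "overlapping")
})

test_that("G-plus binomial equals direct tail summation up to n = 1000", {
  # closed form at k = n
  r <- gplusBinomial(rep("Active_Promoter", 10), 0.5)
  expect_equal(r$pValue, 2^-10, tolerance = 1e-12)
  # k = 0 gives p = 1
  expect_equal(gplusBinomial(rep("Repressed", 5), 0.3)$pValue, 1)
  # oracle equivalence across sizes
  set.seed(11)
  for (n in c(10, 25, 100, 1000)) {
    p0 <- runif(1, 0.05, 0.6)
    k <- rbinom(1, n, min(0.9, p0 * 2))
    labels <- c(rep("Weak_Enhancer", k), rep("Heterochrom_lo", n - k))
    got <- gplusBinomial(labels, p0)
    expect_equal(got$k, k)
    expect_equal(got$pValue, binomTailSum(k, n, p0), tolerance = 1e-9)
  }
})

test_that("TSS-window selection counts midpoints strictly inside the window", {
  genes <- mkGenes("chr1", c(50000, 200000), c(60000, 210000),
                   c("g1", "g2"), strand = c("+", "-"))
  # g1 TSS at 50000 (+); g2 TSS at 209999 (-)
  mk <- function(mids) data.frame(chrom = "chr1", start = mids - 5,
                                  end = mids + 5, stringsAsFactors = FALSE)
  sel <- tssWindowSelection(mk(c(51000, 52000, 59000)), genes)
  expect_equal(sel, "g1")
  expect_length(tssWindowSelection(mk(c(51000, 52000)), genes), 0L)
  # boundary: exactly at TSS + 10000 is outside
  expect_length(tssWindowSelection(mk(c(51000, 52000, 60000)), genes), 0L)
  expect_equal(tssWindowSelection(mk(c(51000, 52000, 59999)), genes), "g1")
  # minus-strand TSS respected
  sel2 <- tssWindowSelection(mk(c(201000, 205000, 209000)), genes)
  expect_equal(sel2, "g2")
})

test_that("enhancer overlap fractions use midpoints and round to percent", {
  enh <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  inst <- data.frame(chrom = "chr1",
                     start = c(seq(10, 910, by = 100), 5000),
                     end = c(seq(20, 920, by = 100), 5010),
                     stringsAsFactors = FALSE)
  r <- enhancerOverlapFraction(inst, enh)
  expect_equal(r$k, 10L)
  expect_equal(r$n, 11L)
  expect_equal(r$percent, 91L)
  allIn <- enhancerOverlapFraction(inst[1:10, ], enh)
  expect_equal(allIn$percent, 100L)
  expect_equal(enhancerOverlapFraction(inst[11, , drop = FALSE],
                                       enh)$percent, 0L)
  expect_error(enhancerOverlapFraction(inst[0, ], enh), "no instances")
})

test_that("within-gene instances avoid the exon mask when discovery masked", {
  sim <- simulateStudy(seed = 33, genomeLength = 2e5, nPeaks = 30,
                       nCopies = 10)
  disc <- discoverDimers(sim$pwms, sim$genome, sim$regions, mask = sim$mask)
  if (nrow(disc$instances)) {
    ann <- annotateNearestGene(disc$instances, sim$genes)
    mids <- ann$midpoint[ann$withinGene]
    if (length(mids)) {
      mg <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(mids + 1L, width = 1L))
      expect_false(any(IRanges::overlapsAny(mg, sim$mask)))
    }
  }
  expect_true(TRUE)
})
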