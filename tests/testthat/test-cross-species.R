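test_that("GO enrichment matches closed-form hypergeometric extremes", {
  universe <- sprintf("g%04d", 1:1000)
  selected <- universe[1:10]
  ann <- data.frame(gene = selected, term = "GO:X",
                    stringsAsFactors = FALSE)
  res <- goEnrichment(selected, universe, ann, fdr = 0.01)
  expect_equal(nrow(res), 1L)
  expect_equal(res$p, 1 / choose(1000, 10), tolerance = 1e-9)
  # empty selection gives an empty result
  expect_equal(nrow(goEnrichment(character(0), universe, ann)), 0L)
  # selected outside the universe is an error
  expect_error(goEnrichment("nope", universe, ann), "subset")
  # terms annotated to no selected gene are skipped entirely
  ann2 <- rbind(ann, data.frame(gene = universe[900:950], term = "GO:Y"))
  res2 <- goEnrichment(selected, universe, ann2, fdr = 1)
  expect_false("GO:Y" %in% attr(res2, "tested")$term)
})

test_that("proportionally represented terms are rarely retained at FDR 0.01", {
  set.seed(77)
  universe <- sprintf("g%04d", 1:1000)
  hits <- 0
  for (i in 1:200) {
    term <- sample(universe, 100)          # 10% of the universe
    selected <- sample(universe, 20)       # proportional draw
    ann <- data.frame(gene = term, term = "GO:N", stringsAsFactors = FALSE)
    res <- goEnrichment(selected, universe, ann, fdr = 0.01)
    hits <- hits + (nrow(res) > 0)
  }
  expect_lte(hits / 200, 0.05)
})

test_that("term-set Fisher comparison is exact and handles degenerate margins", {
  universe <- sprintf("T%05d", 1:10000)
  shared <- universe[1:50]
  r <- compareTermSets(shared, shared, universe)
  expect_equal(r$p, 1 / choose(10000, 50), tolerance = 1e-9)
  expect_gt(r$minusLog10P, 100)
  # independent oracle: base fisher.test on the same table
  tH <- universe[1:40]; tM <- universe[c(30:60)]
  got <- compareTermSets(tH, tM, universe)
  ft <- stats::fisher.test(got$table, alternative = "greater")
  expect_equal(got$p, ft$p.value, tolerance = 1e-9)
  # disjoint small sets: p ~ 1
  expect_gt(compareTermSets(universe[1:5], universe[101:105], universe)$p,
            0.9)
  # t_h = universe forces the overlap
  expect_equal(compareTermSets(universe, universe[1:10], universe)$p, 1)
  expect_error(compareTermSets("a", "a", character(0)), "empty")
})

test_that("partition building follows the block-join rule", {
  # two human genes orthologous to one mouse gene fuse into one block
  p <- buildPartition(c("h1", "h2"), "m1",
                      data.frame(human = c("h1", "h2"), mouse = "m1",
                                 stringsAsFactors = FALSE))
  expect_length(blocksH(p), 1L)
  expect_setequal(blocksH(p)[[1]], c("h1", "h2"))
  expect_equal(nrow(blockLinks(p)), 1L)
  # perfect 1-1 orthology: all singletons, one link per pair
  n <- 20
  ro <- data.frame(human = sprintf("h%02d", 1:n),
                   mouse = sprintf("m%02d", 1:n), stringsAsFactors = FALSE)
  p2 <- buildPartition(ro$human, ro$mouse, ro)
  expect_length(blocksH(p2), n)
  expect_length(blocksM(p2), n)
  expect_equal(nrow(blockLinks(p2)), n)
  # genes without orthology stay singletons, unlinked
  p3 <- buildPartition(c("h1", "h9"), c("m1", "m9"),
                       data.frame(human = "h1", mouse = "m1",
                                  stringsAsFactors = FALSE))
  expect_length(blocksH(p3), 2L)
  expect_equal(nrow(blockLinks(p3)), 1L)
})

test_that("partition equals union-find connected components on random graphs", {
  for (seed in 1:50) {
    set.seed(1000 + seed)
    nH <- sample(5:100, 1); nM <- sample(5:100, 1)
    gH <- sprintf("h%03d", 1:nH); gM <- sprintf("m%03d", 1:nM)
    nE <- sample(0:150, 1)
    ro <- unique(data.frame(human = sample(gH, nE, replace = TRUE),
                            mouse = sample(gM, nE, replace = TRUE),
                            stringsAsFactors = FALSE))
    p <- buildPartition(gH, gM, ro)
    oracle <- unionFindBlocks(gH, gM, ro)
    expect_equal(blockSignature(blocksH(p)), blockSignature(oracle$h))
    expect_equal(blockSignature(blocksM(p)), blockSignature(oracle$m))
    # fixed point: re-deriving the partition from its own blocks changes
    # nothing; input order and duplicated pairs do not matter
    ro2 <- ro[sample(nrow(ro)), , drop = FALSE]
    p2 <- buildPartition(rev(gH), sample(gM), rbind(ro2, ro2))
    expect_equal(blockSignature(blocksH(p2)), blockSignature(blocksH(p)))
  }
})

test_that("adding orthology edges never increases the block count", {
  set.seed(4)
  gH <- sprintf("h%02d", 1:30); gM <- sprintf("m%02d", 1:30)
  all <- expand.grid(human = gH, mouse = gM, stringsAsFactors = FALSE)
  edges <- all[sample(nrow(all), 60), ]
  prev <- Inf
  for (k in c(0, 10, 25, 40, 60)) {
    p <- buildPartition(gH, gM, edges[seq_len(k), , drop = FALSE])
    total <- length(blocksH(p)) + length(blocksM(p))
    expect_lte(total, prev)
    prev <- total
  }
})

test_that("gene-set Fisher reduces to the classical test under 1-1 orthology", {
  for (seed in 1:20) {
    set.seed(500 + seed)
    n <- 200
    ro <- data.frame(human = sprintf("h%03d", 1:n),
                     mouse = sprintf("m%03d", 1:n), stringsAsFactors = FALSE)
    gH <- sample(ro$human, 40)
    gM <- sample(ro$mouse, 30)
    got <- compareGeneSets(gH, gM, ro, ro$human, ro$mouse)
    # classical gene-level test after mapping mouse genes to human orthologs
    mapped <- ro$human[match(gM, ro$mouse)]
    a <- length(intersect(gH, mapped))
    oracle <- stats::phyper(a - 1, length(gH), n - length(gH), length(gM),
                            lower.tail = FALSE)
    expect_equal(got$a, a)
    expect_equal(got$N, n)
    expect_equal(got$p, oracle, tolerance = 1e-12)
  }
})

test_that("gene-set Fisher extremes behave: identity and disjoint links", {
  n <- 5000
  ro <- data.frame(human = sprintf("h%04d", 1:n),
                   mouse = sprintf("m%04d", 1:n), stringsAsFactors = FALSE)
  same <- compareGeneSets(ro$human[1:50], ro$mouse[1:50], ro,
                          ro$human, ro$mouse)
  expect_equal(same$a, 50)
  expect_gt(same$minusLog10P, 50)
  none <- compareGeneSets(ro$human[1:20], ro$mouse[100:120], ro,
                          ro$human, ro$mouse)
  expect_equal(none$a, 0)
  expect_gte(none$p, 0.5)
})

test_that("term-set wrappers strip statistics and are idempotent", {
  df <- data.frame(term = c("b", "a", "a"), p = c(0.1, 0.2, 0.2),
                   stringsAsFactors = FALSE)
  expect_equal(termSetOf(df), c("a", "b"))
  expect_equal(termSetOf(termSetOf(df)), c("a", "b"))
  expect_length(termSetOf(df[0, , drop = FALSE]), 0L)
})

test_that("synthetic orthology recovers its requested block spectrum", {
  spec <- data.frame(hSize = c(1, 3, 2), mSize = c(1, 2, 2),
                     count = c(10, 2, 3))
  o <- generateOrthology(40, 40, spec, seed = 5)
  p <- buildPartition(o$genesH, o$genesM, o$pairs)
  sizes <- table(vapply(o$truth, function(b)
    paste(length(b$h), length(b$m)), ""))
  # every truth block is reproduced exactly as a linked block pair
  for (b in o$truth) {
    hIdx <- which(vapply(blocksH(p), function(x) setequal(x, b$h), TRUE))
    mIdx <- which(vapply(blocksM(p), function(x) setequal(x, b$m), TRUE))
    expect_length(hIdx, 1L)
    expect_length(mIdx, 1L)
    expect_true(any(blockLinks(p)[, "h"] == hIdx &
                      blockLinks(p)[, "m"] == mIdx))
  }
  expect_equal(sum(spec$count), nrow(blockLinks(p)))
  expect_equal(unname(sizes[["1 1"]]), 10L)
})
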