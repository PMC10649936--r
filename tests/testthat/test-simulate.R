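# The synthetic-data generator: planted architectures, determinism,
# genome layouts, Ct tables.

test_that("planted architectures scan back to their subclass definition", {
  set.seed(1)
  a <- makeRBGProtein("IVa", 0.45)
  expect_equal(nrow(callRRMs(a)), 1)
  expect_equal(nrow(scanCCHC(a)), 0)
  gm <- glycineMetrics(a, callRRMs(a))
  expect_equal(gm$gly_fraction_cterm, 0.45, tolerance = 0.08)

  d <- makeRBGProtein("IVd", 0.45)
  expect_equal(nrow(callRRMs(d)), 2)

  b <- makeRBGProtein("IVb", 0.45)
  expect_equal(nrow(callRRMs(b)), 1)
  expect_equal(nrow(scanCCHC(b)), 1)

  c_ <- makeRBGProtein("IVc", 0.45)
  expect_equal(nrow(callRRMs(c_)), 0)
  expect_gte(nrow(scanCCHC(c_)), 2)

  expect_error(makeRBGProtein("IVa", 0.15), "unrecoverable")
})

test_that("proteome generation honors counts and is byte-deterministic", {
  cfg <- simulationConfig(seed = 7)
  p1 <- makeProteome(cfg)
  expect_length(p1$proteome, 63)                     # 5+3+2+3 planted + 50 bg
  expect_equal(nrow(truthMembers(p1$truth)), 11)     # IVc decoys are not members

  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  writeProteome(p1$proteome, f1)
  writeProteome(makeProteome(cfg)$proteome, f2)
  expect_equal(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])

  p0 <- makeProteome(simulationConfig(seed = 2, nBackground = 0))
  expect_equal(nrow(p0$truth@members), length(p0$proteome))
  expect_true(all(p0$truth@members$subclass != "background"))
})

test_that("background proteins contain no RNP-1 instance", {
  p <- makeProteome(simulationConfig(seed = 9))
  bg <- p$truth@members$id[p$truth@members$subclass == "background"]
  hits <- vapply(bg, function(id)
    nrow(scanRNP1(as.character(p$proteome[[id]]))), integer(1))
  expect_true(all(hits == 0))
})

test_that("config validation refuses self-contradictory settings", {
  expect_error(simulationConfig(glyMembers = 0.1), "unrecoverable")
  expect_error(simulationConfig(rearrangementRate = 1.5), "fraction")
  expect_error(simulationConfig(
    tandemArrays = list(list(chrom = 1, size = 3, spacing = 150000))),
    "tandem definition")
  expect_error(simulationConfig(nBackground = -1), "negative")
})

test_that("genome pairs plant mutually tandem arrays and record truth", {
  cfg <- simulationConfig(seed = 13, rearrangementRate = 0)
  gp <- makeGenomePair(cfg)
  # every truth id exists in the emitted annotation and proteome
  expect_setequal(gp$truth@members$id, gp$lociA$gene_id)
  expect_true(all(gp$truth@members$id %in% names(gp$proteomeA)))
  # one 3-gene array -> 3 mutually tandem pairs
  expect_equal(nrow(gp$truth@tandemPairs), 3)
  tanGenes <- unique(unlist(gp$truth@tandemPairs))
  expect_length(tanGenes, 3)
  st <- GenomicRanges::start(gp$lociA[tanGenes])
  expect_equal(diff(sort(st)), c(30000, 30000))
  # ortholog truth covers every gene once
  expect_equal(nrow(gp$truth@orthologPairs), length(gp$lociA))
})

test_that("rearrangement_rate = 0 preserves within-block flanking order", {
  gp <- makeGenomePair(simulationConfig(seed = 17, rearrangementRate = 0))
  op <- gp$truth@orthologPairs
  mapB <- setNames(op$gene_b, op$gene_a)
  rkA <- setNames(gp$lociA$rank, gp$lociA$gene_id)
  rkB <- setNames(gp$lociB$rank, gp$lociB$gene_id)
  chA <- setNames(as.character(GenomicRanges::seqnames(gp$lociA)),
                  gp$lociA$gene_id)
  chB <- setNames(as.character(GenomicRanges::seqnames(gp$lociB)),
                  gp$lociB$gene_id)
  # genes adjacent in A and inside the same collinear block stay adjacent in B
  ordA <- gp$lociA$gene_id[order(chA, rkA)]
  sameBlock <- 0L; adjacentB <- 0L
  for (i in seq_len(length(ordA) - 1)) {
    a1 <- ordA[i]; a2 <- ordA[i + 1]
    if (chA[a1] != chA[a2]) next
    b1 <- mapB[a1]; b2 <- mapB[a2]
    if (chB[b1] != chB[b2] || abs(rkB[b1] - rkB[b2]) != 1) next
    adjacentB <- adjacentB + 1L
    sameBlock <- sameBlock + 1L
  }
  # blocks of 20 genes: at least ~ (1 - 1/20) of adjacencies must survive
  expect_gt(adjacentB / (length(ordA) - 1), 0.85)
})

test_that("synteny collinearity support degrades with the rearrangement rate", {
  recalls <- vapply(c(0, 0.5, 1), function(rate) {
    gp <- makeGenomePair(simulationConfig(seed = 23, rearrangementRate = rate,
                                          nBackground = 0))
    bh <- bestHits(gp$proteomeA, gp$proteomeB)
    syn <- syntenicOrthologs(bh, gp$lociA, gp$lociB)
    op <- gp$truth@orthologPairs
    mean(paste(op$gene_a, op$gene_b) %in% paste(syn$gene_a, syn$gene_b))
  }, numeric(1))
  expect_true(all(diff(recalls) <= 0))   # monotone non-increasing
  expect_equal(recalls[1], 1)
  # at full rearrangement only chance collinearity remains, well below 1
  expect_lt(recalls[3], 0.9)
})

test_that("Ct datasets obey the closed-form recovery identities", {
  # noise 0: recovered log2 fold-change equals the planted value exactly
  fc <- matrix(c(0, 0, 2, -1.5, 0.25, 3), nrow = 2, byrow = FALSE,
               dimnames = list(c("g1", "g2"), c("ctl", "t1", "t2")))
  cfg <- simulationConfig(seed = 3, ctNoiseSd = 0, plantedLog2fc = fc)
  ctd <- makeCtDataset(cfg)
  m <- log2FoldChanges(deltaDeltaCt(ctd$ct, ctd$calibrator))
  expect_equal(m[rownames(fc), colnames(fc)], fc, tolerance = 1e-12)

  # planted 0 everywhere: all recovered values 0
  fc0 <- fc; fc0[] <- 0
  ctd0 <- makeCtDataset(simulationConfig(seed = 3, ctNoiseSd = 0,
                                         plantedLog2fc = fc0))
  m0 <- log2FoldChanges(deltaDeltaCt(ctd0$ct, ctd0$calibrator))
  expect_equal(max(abs(m0)), 0, tolerance = 1e-12)
})

test_that("replicate-noise recovery error follows the propagation oracle", {
  # sd of a recovered cell = sd(mean of 3 replicate dCt differences of two
  # samples) = noise * sqrt(2 * 2 / 3); 3-sigma bound should hold for >= 99%
  noise <- 0.2
  genes <- sprintf("g%03d", 1:100)
  fc <- matrix(stats::rnorm(200), 100, 2, dimnames = list(genes, c("ctl", "t1")))
  fc[, 1] <- 0
  ctd <- makeCtDataset(simulationConfig(seed = 29, ctNoiseSd = noise,
                                        plantedLog2fc = fc))
  m <- log2FoldChanges(deltaDeltaCt(ctd$ct, ctd$calibrator))
  err <- abs(m[genes, "t1"] - fc[genes, "t1"])
  bound <- 3 * noise * sqrt(2) * sqrt(2 / 3)
  expect_gte(mean(err <= bound), 0.99)
})
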