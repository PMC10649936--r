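# Tandem-duplication rule, best hits, syntenic orthologs, duplication labels.

mkLoci <- function(chrom, start, ids = sprintf("g%02d", seq_along(start))) {
  ord <- order(chrom, start)
  rk <- unlist(lapply(split(seq_along(start)[ord], chrom[ord]),
                      function(i) seq_along(i) - 1L), use.names = FALSE)
  gr <- GenomicRanges::GRanges(chrom[ord],
                               IRanges::IRanges(start[ord], start[ord] + 999))
  gr$gene_id <- ids[ord]
  gr$rank <- rk
  names(gr) <- gr$gene_id
  gr
}

test_that("the tandem rule applies both inclusive thresholds", {
  # adjacent ranks, 150 kb apart: a pair
  loci <- mkLoci(rep("c1", 2), c(100000, 250000))
  td <- findTandem(loci, loci$gene_id)
  expect_equal(nrow(td), 1)
  expect_equal(td$intervening, 0L)
  expect_equal(td$distance_bp, 150000)
  # 250 kb apart: too far
  far <- mkLoci(rep("c1", 2), c(100000, 350000))
  expect_equal(nrow(findTandem(far, far$gene_id)), 0)
  # 11 intervening genes within 50 kb: too many genes
  start <- seq(1000, by = 4000, length.out = 13)
  many <- mkLoci(rep("c1", 13), start)
  members <- c("g01", "g13")   # ranks 0 and 12 -> 11 intervening
  expect_equal(nrow(findTandem(many, members)), 0)
  # exactly 10 intervening and exactly 200 kb: both boundaries inclusive
  edge <- mkLoci(rep("c1", 12), c(seq(1000, by = 10000, length.out = 11),
                                  201000))
  expect_equal(nrow(findTandem(edge, c("g01", "g12"))), 1)
})

test_that("findTandem equals the brute-force all-pairs oracle", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    chrom <- sample(paste0("c", 1:3), n, replace = TRUE)
    start <- sample.int(5e6, n)
    loci <- mkLoci(chrom, start, sprintf("g%03d", sample.int(999, n)))
    members <- sample(loci$gene_id, sample(2:n, 1))
    expect_equal(pairKey(findTandem(loci, members)),
                 bruteForceTandem(loci, members))
  }
})

test_that("tandem output is invariant under input gene-order shuffling", {
  set.seed(72)
  chrom <- sample(paste0("c", 1:2), 20, replace = TRUE)
  start <- sample.int(1e6, 20)
  ids <- sprintf("g%03d", 1:20)
  loci <- mkLoci(chrom, start, ids)
  perm <- sample(20)
  lociShuf <- mkLoci(chrom[perm], start[perm], ids[perm])
  members <- ids[1:12]
  expect_equal(pairKey(findTandem(loci, members)),
               pairKey(findTandem(lociShuf, members)))
})

test_that("twin proteomes reciprocally best-hit their twins; ties break by id", {
  set.seed(73)
  A <- setNames(vapply(1:6, function(i) randomProtein(60), character(1)),
                sprintf("a%d", 1:6))
  B <- setNames(A, sprintf("b%d", 1:6))
  bh <- bestHits(A, B)
  expect_equal(nrow(bh$reciprocal), 6)
  expect_equal(sub("a", "b", bh$reciprocal$gene_a), bh$reciprocal$gene_b)

  # a mutated twin still pairs with its partner
  Bm <- B
  mut <- strsplit(Bm[["b3"]], "")[[1]]
  flip <- seq(1, 60, by = 2)
  mut[flip] <- vapply(mut[flip], function(ch)
    sample(setdiff(c("A", "G", "K", "P"), ch), 1), character(1))
  Bm[["b3"]] <- paste(mut, collapse = "")
  bh2 <- bestHits(A, Bm)
  expect_true(any(bh2$reciprocal$gene_a == "a3" &
                  bh2$reciprocal$gene_b == "b3"))

  # two identical B paralogs: lexicographically smaller id wins
  Bt <- c(B, b0dup = unname(B[["b1"]]))
  bh3 <- bestHits(A["a1"], Bt)
  expect_equal(bh3$ab$hit, "b0dup")
})

test_that("exhaustive mode agrees with the k-mer prescreen", {
  set.seed(74)
  A <- setNames(vapply(1:5, function(i) randomProtein(50), character(1)),
                sprintf("a%d", 1:5))
  B <- setNames(vapply(1:5, function(i) randomProtein(50), character(1)),
                sprintf("b%d", 1:5))
  bh1 <- bestHits(A, B, exhaustive = TRUE)
  bh2 <- bestHits(A, B, exhaustive = FALSE)
  expect_equal(bh1$ab, bh2$ab)
  expect_equal(bh1$ba, bh2$ba)
})

test_that("synteny recovers planted orthologs exactly without rearrangement", {
  gp <- makeGenomePair(simulationConfig(seed = 3, rearrangementRate = 0))
  fam <- classifyProteome(gp$proteomeA, properties = FALSE)
  members <- familyMembers(fam)
  bh <- bestHits(gp$proteomeA, gp$proteomeB)
  syn <- syntenicOrthologs(bh, gp$lociA, gp$lociB)
  synM <- syn[syn$gene_a %in% members, ]
  truthM <- subset(gp$truth@orthologPairs, member & !relocated)
  expect_setequal(paste(synM$gene_a, synM$gene_b),
                  paste(truthM$gene_a, truthM$gene_b))

  # min_support = 0 degenerates to reciprocal best hits
  syn0 <- syntenicOrthologs(bh, gp$lociA, gp$lociB, minSupport = 0)
  expect_equal(nrow(syn0), nrow(bh$reciprocal))

  # duplication labels: array genes tandem, collinear singletons retained
  tandem <- findTandem(gp$lociA, members)
  dup <- classifyDuplication(members, tandem, synM)
  lab <- setNames(dup$duplication, dup$gene_id)
  arrayGenes <- unique(unlist(gp$truth@tandemPairs))
  expect_true(all(lab[arrayGenes] == "tandem"))
  expect_true(all(lab[setdiff(members, arrayGenes)] == "syntenic_retained"))
})

test_that("a relocated member is rejected despite its reciprocal best hit", {
  gp <- makeGenomePair(simulationConfig(seed = 11, rearrangementRate = 0,
                                        relocatedMembers = 1))
  bh <- bestHits(gp$proteomeA, gp$proteomeB)
  rel <- subset(gp$truth@orthologPairs, relocated)
  expect_equal(nrow(rel), 1)
  # still a reciprocal best hit on sequence alone...
  expect_true(paste(rel$gene_a, rel$gene_b) %in%
              paste(bh$reciprocal$gene_a, bh$reciprocal$gene_b))
  # ...but rejected for lack of collinear flanks
  syn <- syntenicOrthologs(bh, gp$lociA, gp$lociB)
  expect_false(paste(rel$gene_a, rel$gene_b) %in%
               paste(syn$gene_a, syn$gene_b))
  # the remaining members are still recovered
  truthOk <- subset(gp$truth@orthologPairs, member & !relocated)
  expect_true(all(paste(truthOk$gene_a, truthOk$gene_b) %in%
                  paste(syn$gene_a, syn$gene_b)))
  dup <- classifyDuplication(rel$gene_a, findTandem(gp$lociA, rel$gene_a),
                             syn[syn$gene_a == rel$gene_a, ])
  expect_equal(dup$duplication, "dispersed")
})
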