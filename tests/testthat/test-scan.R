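# Consensus scanners, RRM pairing, glycine metrics, domain-table filter.

test_that("RNP-1 scanning matches the 8-residue consensus", {
  expect_equal(scanRNP1("KGFGFVTF")[, c("start", "end")],
               data.frame(start = 1L, end = 8L))
  expect_equal(nrow(scanRNP1("AGFGFVTF")), 0)        # pos 1 must be K/R
  two <- scanRNP1("KGFGFVTFKGYAFVQY")
  expect_equal(two$start, c(1L, 9L))
  expect_equal(two$match, c("KGFGFVTF", "KGYAFVQY"))
})

test_that("RNP-2 and CCHC scanning match their patterns", {
  expect_equal(scanRNP2("LFVGGL")$match, "LFVGGL")
  expect_equal(nrow(scanRNP2("LFVGGA")), 0)          # must end in L
  expect_equal(nrow(scanRNP2("")), 0)

  expect_equal(scanCCHC("CAACAAAAHAAAAC")$end, 14L)
  expect_equal(nrow(scanCCHC("CAACAAAAHAAAA")), 0)   # 13 aa: too short
  expect_equal(nrow(scanCCHC("CAACAAAAKAAAAC")), 0)  # H replaced by K
})

test_that("'X' matches only the RNP-1 wildcard position", {
  expect_equal(nrow(scanRNP1("KGFGFVXF")), 1)  # X at wildcard pos 7
  expect_equal(nrow(scanRNP1("XGFGFVTF")), 0)  # X at constrained pos 1
  expect_equal(nrow(scanRNP2("XFVGGL")), 0)
})

test_that("scanner hits shift by exactly the prepended length", {
  set.seed(21)
  for (rep in 1:20) {
    core <- paste0(randomProtein(sample(0:30, 1)), "KGFGFVTF",
                   randomProtein(sample(0:30, 1)), "LFVGGL")
    pre <- strrep("P", sample(1:15, 1))   # P never appears in either pattern
    post <- strrep("P", sample(1:15, 1))
    base1 <- scanRNP1(core); base2 <- scanRNP2(core)
    shif1 <- scanRNP1(paste0(pre, core, post))
    shif2 <- scanRNP2(paste0(pre, core, post))
    expect_equal(shif1$start, base1$start + nchar(pre))
    expect_equal(shif2$start, base2$start + nchar(pre))
  }
})

test_that("RRM pairing respects the gap window", {
  # RNP2 at [1,6], RNP1 after a 24-residue spacer: gap 24, inside [10,60]
  s1 <- paste0("LFVGGL", strrep("A", 24), "KGFGFVTF")
  expect_equal(nrow(callRRMs(s1)), 1)
  expect_equal(callRRMs(s1)$gap, 24L)
  # gap 94: outside the window
  s2 <- paste0("LFVGGL", strrep("A", 94), "KGFGFVTF")
  expect_equal(nrow(callRRMs(s2)), 0)
  # two tandem (RNP2, RNP1) pairs
  s3 <- paste0(s1, strrep("A", 20), s1)
  expect_equal(nrow(callRRMs(s3)), 2)
})

test_that("greedy RRM pairing equals the exhaustive matching oracle", {
  set.seed(22)
  for (rep in 1:200) {
    # random layouts with up to 4 hits of each kind
    parts <- character()
    for (k in seq_len(sample(2:6, 1))) {
      parts <- c(parts, strrep("A", sample(c(1:40, 60:80), 1)),
                 if (runif(1) < 0.5) "LFVGGL" else "KGFGFVTF")
    }
    seq <- paste(parts, collapse = "")
    h2 <- scanRNP2(seq); h1 <- scanRNP1(seq)
    if (nrow(h2) > 4 || nrow(h1) > 4) next
    expect_equal(nrow(callRRMs(seq)), oracleMaxRRMPairs(h2, h1))
  }
})

test_that("glycine metrics use the post-RRM C-terminal region", {
  expect_equal(glycineMetrics("GGAGG", callRRMs("GGAGG"))$gly_fraction_cterm, 0.8)
  expect_equal(glycineMetrics("AAAAA", callRRMs("AAAAA"))$gly_fraction_cterm, 0)
  # RRM span ends at 38; 12 G among the trailing 40 residues
  tail40 <- paste0(strrep("G", 12), strrep("A", 28))
  s <- paste0("LFVGGL", strrep("A", 24), "KGFGFVTF", tail40)
  gm <- glycineMetrics(s, callRRMs(s))
  expect_equal(gm$cterm_start, 39L)
  expect_equal(gm$gly_fraction_cterm, 12 / 40)
  # zero-length region
  s2 <- paste0("LFVGGL", strrep("A", 24), "KGFGFVTF")
  expect_warning(gm2 <- glycineMetrics(s2, callRRMs(s2)), "zero-length")
  expect_equal(gm2$gly_fraction_cterm, 0)
})

test_that("domain-table filter applies inclusive coverage and E-value cutoffs", {
  grid <- expand.grid(cov = c(0.59, 0.60, 0.70), e = c(1e-6, 1e-5, 1e-4))
  rows <- data.frame(protein_id = sprintf("p%d", seq_len(nrow(grid))),
                     model_name = "RRM_1", model_length = 100,
                     ali_from = 1, ali_to = grid$cov * 100,
                     e_value = grid$e)
  flt <- filterDomainTable(rows)
  kept <- rows$protein_id %in% flt$rows$protein_id
  expect_equal(kept, grid$cov >= 0.60 & grid$e <= 1e-5)

  expect_error(filterDomainTable(transform(rows, model_length = 0)),
               "model_length")
})

test_that("planted RRM counts are recovered for 1000 seeded draws", {
  set.seed(1234)
  wrong <- 0L
  for (rep in 1:1000) {
    sc <- sample(c("IVa", "IVd"), 1)
    seq <- makeRBGProtein(sc, glyFraction = 0.45)
    if (nrow(callRRMs(seq)) != if (sc == "IVa") 1L else 2L) wrong <- wrong + 1L
  }
  expect_equal(wrong, 0L)
})

test_that("the external-table evidence path drives RRM counts and CSD flags", {
  prot <- c(p1 = makeRBGProtein("IVa"), p2 = makeRBGProtein("IVc"))
  tab <- data.frame(protein_id = c("p1", "p2"), model_name = c("RRM_1", "CSP"),
                    model_length = c(70, 65), ali_from = c(1, 1),
                    ali_to = c(70, 65), e_value = c(1e-10, 1e-10))
  prof <- profilesFromDomainTable(prot, tab)
  expect_equal(prof$n_rrm[prof$protein_id == "p1"], 1L)
  expect_equal(prof$n_rrm[prof$protein_id == "p2"], 0L)
  expect_true(prof$csd[prof$protein_id == "p2"])
})
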