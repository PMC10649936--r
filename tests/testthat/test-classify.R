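# Subclass grammar, naming, molecular weight, isoelectric point.

profRow <- function(id = "p", rrm = 0, cchc = 0, csd = FALSE, gly = 0.45) {
  data.frame(protein_id = id, n_rrm = rrm, n_cchc = cchc, csd = csd,
             cterm_start = 1, gly_fraction_cterm = gly,
             gly_fraction_total = gly)
}

test_that("the subclass grammar follows the rule order", {
  cases <- list(
    list(profRow(rrm = 1, gly = 0.45),             "IVa",          TRUE),
    list(profRow(rrm = 2, gly = 0.45),             "IVd",          TRUE),
    list(profRow(rrm = 1, cchc = 1, gly = 0.45),   "IVb",          TRUE),
    list(profRow(rrm = 0, cchc = 2, csd = TRUE),   "IVc_excluded", FALSE),
    list(profRow(rrm = 1, cchc = 2, csd = TRUE),   "IVc_excluded", FALSE),
    list(profRow(rrm = 1, gly = 0.20),             "none",         FALSE),
    list(profRow(rrm = 0, gly = 0.45),             "none",         FALSE),
    # CSD with a single knuckle is not IVc; grammar continues normally
    list(profRow(rrm = 1, cchc = 1, csd = TRUE),   "IVb",          TRUE))
  for (cs in cases) {
    call <- assignSubclasses(cs[[1]])
    expect_equal(call$subclass, cs[[2]])
    expect_equal(call$is_member, cs[[3]])
  }
  # IVc exclusion outranks the glycine filter: a low-glycine CSD decoy is
  # still reported as IVc_excluded, not 'none'
  low <- assignSubclasses(profRow(cchc = 2, csd = TRUE, gly = 0.05))
  expect_equal(low$subclass, "IVc_excluded")
})

test_that("member naming is chromosome-ordered, prefixed and shuffle-stable", {
  loci <- GenomicRanges::GRanges(c("chr2", "chr1"),
                                 IRanges::IRanges(c(50, 100), c(60, 120)))
  loci$gene_id <- c("pB", "pA")
  names(loci) <- loci$gene_id
  prof <- rbind(profRow("pA", rrm = 1), profRow("pB", rrm = 1),
                profRow("pC", rrm = 2))
  # pC has no locus on purpose: it must be appended after placed members
  calls <- suppressWarnings(nameMembers(assignSubclasses(prof), loci = loci))
  nm <- setNames(calls$assigned_name, calls$protein_id)
  expect_equal(nm[["pA"]], "RBGA1")   # chr1:100 before chr2:50
  expect_equal(nm[["pB"]], "RBGA2")
  expect_equal(nm[["pC"]], "RBGD1")

  shuf <- suppressWarnings(
    nameMembers(assignSubclasses(prof[c(3, 1, 2), ]), loci = loci))
  expect_equal(setNames(shuf$assigned_name, shuf$protein_id)[names(nm)], nm)

  noloc <- rbind(profRow("pA", rrm = 1), profRow("pZ", rrm = 1))
  locA <- loci[loci$gene_id == "pA"]
  expect_warning(out <- nameMembers(assignSubclasses(noloc), loci = locA),
                 "without a gene locus")
  expect_equal(setNames(out$assigned_name, out$protein_id)[["pZ"]], "RBGA2")
})

test_that("molecular weight follows the average-mass table and additivity", {
  expect_equal(molWeight("G"), 0.0750672, tolerance = 1e-7)
  expect_equal(molWeight("GG"), 0.1321191, tolerance = 1e-7)
  set.seed(41)
  for (rep in 1:20) {
    a <- randomProtein(sample(1:50, 1))
    b <- randomProtein(sample(1:50, 1))
    expect_equal(molWeight(paste0(a, b)),
                 molWeight(a) + molWeight(b) - 0.0180153, tolerance = 1e-12)
  }
})

test_that("pI honors closed forms, monotonicity and the grid-scan oracle", {
  pka <- pkaTableBjellqvist()
  # only the two termini ionize: pI is the midpoint of their pKas
  expect_equal(isoelectricPoint("GG"),
               (pka$nterm_default + pka$cterm) / 2, tolerance = 2e-3)
  expect_gt(isoelectricPoint("KKKKK"), 7)
  expect_lt(isoelectricPoint("DDDDD"), 7)
  # net charge is strictly decreasing in pH
  set.seed(43)
  s <- randomProtein(60)
  ph <- seq(0.5, 13.5, by = 0.25)
  expect_true(all(diff(netCharge(s, ph)) < 0))
  # bisection vs 0.001-step grid scan
  for (rep in 1:25) {
    s <- randomProtein(sample(20:150, 1))
    expect_equal(isoelectricPoint(s), gridScanPI(s), tolerance = 2e-3)
  }
})

test_that("undefined residues are excluded from charge but reported", {
  expect_message(pi1 <- isoelectricPoint("GGXGG"), "undefined")
  expect_equal(pi1, suppressMessages(isoelectricPoint("GGGG")), tolerance = 2e-3)
  expect_equal(molWeight("X"), (mean(c(
    71.0788, 156.1875, 114.1038, 115.0886, 103.1388, 129.1155, 128.1307,
    57.0519, 137.1411, 113.1594, 113.1594, 128.1741, 131.1926, 147.1766,
    97.1167, 87.0782, 101.1051, 186.2132, 163.1760, 99.1326)) + 18.0153) / 1000,
    tolerance = 1e-9)
})

test_that("classification recovers planted memberships across seeds", {
  set.seed(0)
  for (seed in sample.int(10000, 5)) {
    p <- makeProteome(simulationConfig(seed = seed))
    fam <- classifyProteome(p$proteome, properties = FALSE)
    calls <- familyCalls(fam)
    truth <- p$truth@members
    m <- merge(calls, truth, by.x = "protein_id", by.y = "id",
               suffixes = c("_called", "_true"))
    expect_true(all(m$is_member ==
                    (m$subclass_true %in% c("IVa", "IVb", "IVd"))))
    expect_equal(m$subclass_called[m$is_member], m$subclass_true[m$is_member])
    # IVc decoys never slip through
    expect_true(all(!m$is_member[m$subclass_true == "IVc"]))
  }
})

test_that("an RBGFamily reports consistent member counts and properties", {
  p <- makeProteome(simulationConfig(seed = 4))
  fam <- classifyProteome(p$proteome)
  cnt <- subclassCounts(fam)
  expect_equal(sum(cnt), length(familyMembers(fam)))
  expect_equal(unname(cnt), c(5L, 3L, 3L))
  props <- proteinProperties(fam)
  expect_true(all(props$mw_kda > 0))
  expect_true(all(props$pi > 0 & props$pi < 14))
  members <- familyMembers(fam)
  expect_true(all(props$gly_percent[props$protein_id %in% members] > 20))
})
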