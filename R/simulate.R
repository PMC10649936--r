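# Synthetic proteomes, genome layouts and Ct tables with planted,
# recorded ground truth, so every pipeline stage can be validated
# without any genome download.

# Residues that can never create an RNP-1/RNP-2 instance (no F/Y/V/I/L) or a
# CCHC knuckle (no C/H), and that exclude G so glycine content stays under
# explicit control. Spacers, linkers and tail filler draw from this set.
.SAFE_AA <- c("A", "S", "T", "N", "Q", "D", "E", "P", "R", "K", "M", "W")

# Fixed 65-residue cold-shock-domain placeholder. It has no printed consensus
# in the field's motif grammar, so it is recognizable only through an external
# domain table (or truth labels), mirroring how CSDs are identified by
# profile HMMs rather than by a short consensus.
.CSD_TAG <- paste0("SQNARTEDPWMKSQNARTEDPWMKSQNARTEDPWMK",
                   "SQNARTEDPWMKSQNARTEDPWMKSQENT")

.randSafe <- function(n) paste(sample(.SAFE_AA, n, replace = TRUE), collapse = "")

.sampleRNP1 <- function() {
  paste0(sample(c("K", "R"), 1), "G", sample(c("F", "Y"), 1),
         sample(c("G", "A"), 1), "F", "V", sample(.AA20, 1),
         sample(c("F", "Y"), 1))
}

.sampleRNP2 <- function() {
  paste0(sample(c("L", "I"), 1), sample(c("F", "Y"), 1),
         sample(c("V", "I"), 1), sample(c("G", "K"), 1),
         sample(c("G", "N"), 1), "L")
}

# RNP-2, a 20-35 residue spacer, then RNP-1: the canonical internal geometry
# of an RRM, consistent with the default RRM pairing window.
.rrmSegment <- function() {
  paste0(.sampleRNP2(), .randSafe(sample(20:35, 1)), .sampleRNP1())
}

.cchcKnuckle <- function() {
  safe <- setdiff(.SAFE_AA, c("C", "H"))
  r <- function(n) paste(sample(safe, n, replace = TRUE), collapse = "")
  paste0("C", r(2), "C", r(4), "H", r(4), "C")
}

# Glycine-rich tail of given length and glycine fraction, optionally with
# CCHC knuckles spliced in (knuckle residues count toward the tail length).
.glyTail <- function(len, glyFraction, nKnuckles = 0) {
  kn <- if (nKnuckles > 0) replicate(nKnuckles, .cchcKnuckle()) else character()
  klen <- sum(nchar(kn))
  stopifnot(len > klen + 10)
  nG <- round(glyFraction * len)
  base <- len - klen
  stopifnot(nG <= base)
  res <- sample(.SAFE_AA, base, replace = TRUE)
  res[sample(base, nG)] <- "G"
  tail <- paste(res, collapse = "")
  for (k in kn) {
    at <- sample(nchar(tail) - 1, 1)
    tail <- paste0(substring(tail, 1, at), k,
                   substring(tail, at + 1, nchar(tail)))
  }
  tail
}

#' Simulation configuration
#'
#' Validated parameter set for the synthetic-data generator. Defaults emulate
#' a small desk-scale study: a proteome of 13 planted architectures (5 IVa,
#' 3 IVb, 3 IVd, plus 2 IVc cold-shock decoys that must end up excluded)
#' among 50 background proteins; a 3-chromosome genome with one planted
#' 3-gene tandem array; a sister species with preserved collinear blocks;
#' and triplicate Ct tables with 0.2-cycle replicate noise.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param nIVa,nIVb,nIVc,nIVd Planted proteins per subclass.
#' @param nBackground Background (non-RBG) proteins.
#' @param glyMembers C-terminal glycine fraction of planted members; must be
#'   strictly above \code{0.20} or the planted truth would be unrecoverable
#'   by design.
#' @param glyBackground Glycine fraction of background proteins.
#' @param chromCount,genesPerChrom Genome layout of species A.
#' @param tandemArrays list of lists with \code{chrom}, \code{size},
#'   \code{spacing} (bp, start-to-start); arrays that violate the tandem rule
#'   itself (pairwise distance over 200 kb or over 10 intervening genes) are
#'   refused.
#' @param syntenyBlockLen Genes per collinear block; species B preserves
#'   within-block gene order while block order is shuffled.
#' @param rearrangementRate Fraction of species-B background genes relocated
#'   to random positions.
#' @param relocatedMembers Number of planted member genes relocated in
#'   species B (negative controls for synteny detection).
#' @param substitutionRate Per-residue substitution rate between orthologs.
#' @param ctNoiseSd Replicate noise SD in Ct cycles.
#' @param plantedLog2fc Optional genes x samples matrix of planted log2
#'   fold-changes (calibrator column must be zero); drawn automatically when
#'   \code{NULL}.
#' @return A validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1, nIVa = 5, nIVb = 3, nIVc = 2, nIVd = 3,
                             nBackground = 50, glyMembers = 0.45,
                             glyBackground = 0.10, chromCount = 3,
                             genesPerChrom = 65,
                             tandemArrays = list(list(chrom = 1, size = 3,
                                                      spacing = 30000)),
                             syntenyBlockLen = 20, rearrangementRate = 0.05,
                             relocatedMembers = 0, substitutionRate = 0.05,
                             ctNoiseSd = 0.2, plantedLog2fc = NULL) {
  cfg <- list(seed = seed, nIVa = nIVa, nIVb = nIVb, nIVc = nIVc, nIVd = nIVd,
              nBackground = nBackground, glyMembers = glyMembers,
              glyBackground = glyBackground, chromCount = chromCount,
              genesPerChrom = genesPerChrom, tandemArrays = tandemArrays,
              syntenyBlockLen = syntenyBlockLen,
              rearrangementRate = rearrangementRate,
              relocatedMembers = relocatedMembers,
              substitutionRate = substitutionRate,
              ctNoiseSd = ctNoiseSd, plantedLog2fc = plantedLog2fc)
  errs <- character()
  cnt <- c(nIVa = nIVa, nIVb = nIVb, nIVc = nIVc, nIVd = nIVd,
           nBackground = nBackground, chromCount = chromCount,
           genesPerChrom = genesPerChrom, relocatedMembers = relocatedMembers)
  bad <- names(cnt)[cnt < 0]
  if (length(bad)) errs <- c(errs, paste("negative count:", paste(bad, collapse = ", ")))
  frc <- c(glyBackground = glyBackground, rearrangementRate = rearrangementRate,
           substitutionRate = substitutionRate)
  bad <- names(frc)[frc < 0 | frc > 1]
  if (length(bad)) errs <- c(errs, paste("fraction outside [0,1]:", paste(bad, collapse = ", ")))
  if (glyMembers <= 0.20 || glyMembers > 1)
    errs <- c(errs, "glyMembers must be in (0.20, 1]: planted members below the glycine threshold would make the truth unrecoverable")
  if (ctNoiseSd < 0) errs <- c(errs, "ctNoiseSd must be >= 0")
  for (a in tandemArrays) {
    if (a$spacing <= 0) errs <- c(errs, "tandem array spacing must be > 0")
    if ((a$size - 1) * a$spacing > 200000 || (a$size - 2) > 10)
      errs <- c(errs, "tandem array violates the tandem definition itself (pairwise distance > 200 kb or > 10 intervening genes)")
    if (a$chrom > chromCount) errs <- c(errs, "tandem array chromosome out of range")
  }
  if (length(errs))
    stop("invalid simulation config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Generate one synthetic RBG protein with a planted architecture
#'
#' IVa: one RRM segment then a glycine-rich tail; IVb: the same plus one CCHC
#' knuckle embedded in the tail; IVd: two RRM segments then the tail; IVc: a
#' cold-shock-domain placeholder plus two CCHC knuckles in the tail (no RNP
#' instances). The emitted string is rejection-sampled until the package's
#' own scanners recover exactly the planted motif counts, so recoverability
#' holds by construction.
#'
#' @param subclass One of \code{"IVa"}, \code{"IVb"}, \code{"IVc"},
#'   \code{"IVd"}.
#' @param glyFraction Glycine fraction of the tail; must exceed 0.20 (the
#'   classification threshold) or the call is refused.
#' @param tailLength Tail length in residues (sampled if NULL).
#' @return The protein sequence as a single character string.
#' @export
makeRBGProtein <- function(subclass, glyFraction = 0.45, tailLength = NULL) {
  stopifnot(subclass %in% .SUBCLASSES)
  if (glyFraction <= 0.20)
    stop("glyFraction must exceed 0.20: a planted subclass-", subclass,
         " protein below the glycine threshold would be unrecoverable by design",
         call. = FALSE)
  planted <- switch(subclass,
    IVa = c(rrm = 1, cchc = 0), IVb = c(rrm = 1, cchc = 1),
    IVc = c(rrm = 0, cchc = 2), IVd = c(rrm = 2, cchc = 0))
  for (try in 1:50) {
    tl <- if (is.null(tailLength)) sample(90:150, 1) else tailLength
    lead <- .randSafe(sample(5:15, 1))
    body <- switch(subclass,
      IVa = paste0(.rrmSegment(), .glyTail(tl, glyFraction)),
      IVb = paste0(.rrmSegment(), .glyTail(tl, glyFraction, nKnuckles = 1)),
      IVd = paste0(.rrmSegment(), .randSafe(sample(15:30, 1)), .rrmSegment(),
                   .glyTail(tl, glyFraction)),
      IVc = paste0(.CSD_TAG, .glyTail(tl, glyFraction, nKnuckles = 2)))
    seq <- paste0(lead, body)
    rrm <- callRRMs(seq)
    ok <- nrow(rrm) == planted[["rrm"]] &&
      nrow(scanCCHC(seq)) == planted[["cchc"]] &&
      glycineMetrics(seq, rrm)$gly_fraction_cterm > 0.20
    if (ok) return(seq)
  }
  stop("failed to generate a clean subclass-", subclass, " protein", call. = FALSE)
}

# Background protein: no RNP-1 instance anywhere (rejection-sampled),
# glycine at the configured background fraction.
.backgroundProtein <- function(glyFraction) {
  for (try in 1:100) {
    len <- sample(80:250, 1)
    probs <- rep((1 - glyFraction) / 19, 20)
    probs[match("G", .AA20)] <- glyFraction
    seq <- paste(sample(.AA20, len, replace = TRUE, prob = probs), collapse = "")
    if (nrow(scanRNP1(seq)) == 0) return(seq)
  }
  stop("failed to generate a clean background protein", call. = FALSE)
}

#' Generate a synthetic proteome with recorded truth
#'
#' Emits planted subclass architectures followed by background proteins.
#' Generation is deterministic given \code{config$seed}.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return list with \code{proteome} (named \code{AAStringSet}) and
#'   \code{truth} (an \code{\link{RBGTruth-class}}).
#' @export
makeProteome <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(stageSeed(config$seed, "proteome"))
  labels <- c(rep("IVa", config$nIVa), rep("IVb", config$nIVb),
              rep("IVc", config$nIVc), rep("IVd", config$nIVd),
              rep("background", config$nBackground))
  seqs <- vapply(labels, function(lb) {
    if (lb == "background") .backgroundProtein(config$glyBackground)
    else makeRBGProtein(lb, config$glyMembers)
  }, character(1), USE.NAMES = FALSE)
  ids <- sprintf("SIM%04d", seq_along(labels))
  proteome <- Biostrings::AAStringSet(seqs)
  names(proteome) <- ids
  truth <- new("RBGTruth", members = data.frame(id = ids, subclass = labels))
  list(proteome = proteome, truth = truth)
}

# Lay out one species: genes in given slot order per chromosome.
# chromOrder: list per chromosome of ordered gene-id vectors;
# spacingOverride: named start-to-start bp overrides (by gene id).
.layoutGenome <- function(chromOrder, spacingOverride = numeric()) {
  grs <- list()
  allChroms <- names(chromOrder)
  for (ch in allChroms) {
    ids <- chromOrder[[ch]]
    n <- length(ids)
    if (!n) next
    glen <- sample(900:2400, n, replace = TRUE)
    gap <- sample(8000:20000, n, replace = TRUE)
    start <- numeric(n)
    start[1] <- gap[1]
    for (i in seq_len(n)[-1]) {
      ov <- spacingOverride[ids[i]]
      start[i] <- if (!is.na(ov)) start[i - 1] + ov
                  else start[i - 1] + glen[i - 1] + gap[i]
    }
    end <- start + glen - 1
    nex <- sample(1:5, n, replace = TRUE)
    exl <- lapply(seq_len(n), function(i) {
      k <- nex[i]
      if (k == 1) return(IRanges::IRanges(start[i], end[i]))
      cuts <- sort(sample(seq(start[i] + 10, end[i] - 10, by = 1), 2 * (k - 1)))
      s <- c(start[i], cuts[seq(2, length(cuts), by = 2)])
      e <- c(cuts[seq(1, length(cuts), by = 2)], end[i])
      IRanges::IRanges(s, e)
    })
    gr <- GenomicRanges::GRanges(factor(rep(ch, n), levels = allChroms),
                                 IRanges::IRanges(start, end), strand = "+")
    gr$gene_id <- ids
    gr$rank <- seq_len(n) - 1L
    gr$n_exons <- nex
    gr$exons <- IRanges::IRangesList(exl)
    names(gr) <- ids
    grs[[ch]] <- gr
  }
  out <- do.call(c, unname(grs))
  out
}

.mutateProtein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  res <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(res)) < rate)
  for (i in hit) res[i] <- sample(setdiff(.AA20, res[i]), 1)
  paste(res, collapse = "")
}

# Mutated paralog of a planted member that still scans as its subclass
# (mutations falling into the planted motifs are rejection-resampled).
.mutateMemberProtein <- function(seq, rate, nRRM, nCCHC) {
  for (try in 1:50) {
    mut <- .mutateProtein(seq, rate)
    rrm <- callRRMs(mut)
    if (nrow(rrm) == nRRM && nrow(scanCCHC(mut)) == nCCHC &&
        glycineMetrics(mut, rrm)$gly_fraction_cterm > 0.20)
      return(mut)
  }
  stop("failed to mutate a member protein without destroying its architecture",
       call. = FALSE)
}

#' Generate a synthetic genome pair with planted tandem arrays and synteny
#'
#' Species A carries planted member genes (scattered, plus tandem arrays of
#' near-identical IVa paralogs at the configured spacing), IVc decoys, and
#' background genes. Species B preserves within-block gene order
#' (\code{syntenyBlockLen} genes per collinear block; block order is
#' shuffled), orthologs are mutated at \code{substitutionRate} per residue,
#' a \code{rearrangementRate} fraction of background genes is relocated, and
#' \code{relocatedMembers} planted members are relocated as negative
#' controls. All truth (memberships, tandem pairs, ortholog pairs with
#' relocation flags) is recorded.
#'
#' Scattered members are placed at least 12 gene ranks apart so that the only
#' planted tandem relationships are the arrays themselves.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return list with \code{lociA}, \code{lociB} (\code{GRanges}),
#'   \code{proteomeA}, \code{proteomeB} (\code{AAStringSet}) and \code{truth}
#'   (an \code{\link{RBGTruth-class}}).
#' @export
makeGenomePair <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(stageSeed(config$seed, "genome"))
  nChrom <- config$chromCount
  nPer <- config$genesPerChrom
  nTotal <- nChrom * nPer
  chroms <- sprintf("chrA%02d", seq_len(nChrom))

  # planted proteins
  memberLabels <- c(rep("IVa", config$nIVa), rep("IVb", config$nIVb),
                    rep("IVd", config$nIVd))
  decoyLabels <- rep("IVc", config$nIVc)
  arraySizes <- vapply(config$tandemArrays, `[[`, numeric(1), "size")
  nArray <- sum(arraySizes)
  nScatter <- length(memberLabels) + length(decoyLabels)
  if (nScatter + nArray + 1 > nTotal)
    stop("genome too small for the planted genes", call. = FALSE)

  ids <- sprintf("gA%04d", seq_len(nTotal))
  slotChrom <- rep(chroms, each = nPer)
  slotIndex <- rep(seq_len(nPer), times = nChrom)

  # Members are placed one per 13-gene segment (small jitter), so scattered
  # members sit at least 12 ranks apart and never satisfy the tandem rule;
  # each array takes its own segment plus the next as a buffer.
  segLen <- 13L
  segPerChrom <- nPer %/% segLen
  seg <- expand.grid(idx = seq_len(segPerChrom), chrom = seq_len(nChrom))
  segUsed <- rep(FALSE, nrow(seg))
  nMemberScatter <- length(memberLabels)
  if (nrow(seg) < nMemberScatter + 2L * length(config$tandemArrays))
    stop("genome too small for the planted member layout; increase ",
         "genesPerChrom or chromCount", call. = FALSE)

  slotOf <- function(chromNo, pos) as.integer((chromNo - 1L) * nPer + pos)
  taken <- rep(FALSE, nTotal)
  arrayGenes <- list()
  for (ai in seq_along(config$tandemArrays)) {
    a <- config$tandemArrays[[ai]]
    segsHere <- which(seg$chrom == a$chrom & !segUsed & seg$idx < segPerChrom)
    if (!length(segsHere))
      stop("no free segment for tandem array on chromosome ", a$chrom,
           call. = FALSE)
    s <- if (length(segsHere) == 1) segsHere else sample(segsHere, 1)
    segUsed[s] <- TRUE
    nxt <- which(seg$chrom == a$chrom & seg$idx == seg$idx[s] + 1L)
    segUsed[nxt] <- TRUE
    at <- (seg$idx[s] - 1L) * segLen + 1L + sample(0:1, 1)
    slots <- slotOf(a$chrom, seq(at, at + a$size - 1L))
    taken[slots] <- TRUE
    arrayGenes[[ai]] <- ids[slots]
  }
  freeSegs <- which(!segUsed)
  memberSegs <- if (nMemberScatter > 0) sample(freeSegs, nMemberScatter) else integer()
  memberSlots <- vapply(memberSegs, function(s) {
    at <- (seg$idx[s] - 1L) * segLen + 1L + sample(0:1, 1)
    slotOf(seg$chrom[s], at)
  }, integer(1))
  taken[memberSlots] <- TRUE
  decoySlots <- if (length(decoyLabels)) sample(which(!taken), length(decoyLabels))
                else integer()
  taken[decoySlots] <- TRUE

  subclass <- rep("background", nTotal)
  seqsA <- character(nTotal)
  scatterSlots <- c(memberSlots, decoySlots)
  scatterLabels <- c(memberLabels, decoyLabels)
  for (k in seq_along(scatterSlots))
    subclass[scatterSlots[k]] <- scatterLabels[k]
  for (ai in seq_along(arrayGenes)) {
    base <- makeRBGProtein("IVa", config$glyMembers)
    for (g in arrayGenes[[ai]]) {
      i <- match(g, ids)
      subclass[i] <- "IVa"
      seqsA[i] <- .mutateMemberProtein(base, 0.02, nRRM = 1, nCCHC = 0)
    }
  }
  for (i in seq_len(nTotal)) {
    if (nzchar(seqsA[i])) next
    seqsA[i] <- if (subclass[i] == "background")
      .backgroundProtein(config$glyBackground)
    else makeRBGProtein(subclass[i], config$glyMembers)
  }

  chromOrderA <- split(ids, slotChrom)[chroms]
  names(chromOrderA) <- chroms
  spacingOverride <- numeric()
  for (ai in seq_along(config$tandemArrays)) {
    a <- config$tandemArrays[[ai]]
    gs <- arrayGenes[[ai]][-1]
    spacingOverride[gs] <- a$spacing
  }
  lociA <- .layoutGenome(chromOrderA, spacingOverride)

  # species B: block-preserving order, per-gene relocation
  idsB <- sub("^gA", "gB", ids)
  names(idsB) <- ids
  chromsB <- sub("chrA", "chrB", chroms)
  orderB <- list()
  for (ci in seq_len(nChrom)) {
    g <- chromOrderA[[ci]]
    blocks <- split(g, ceiling(seq_along(g) / config$syntenyBlockLen))
    blocks <- blocks[sample(length(blocks))]
    orderB[[chromsB[ci]]] <- unname(unlist(blocks))
  }
  # relocation: background genes at rearrangementRate, plus member negatives
  bg <- ids[subclass == "background"]
  nRel <- round(config$rearrangementRate * length(bg))
  relocated <- if (nRel > 0) sample(bg, nRel) else character()
  scatterMemberIds <- ids[scatterSlots][scatterLabels %in% .MEMBER_SUBCLASSES]
  if (config$relocatedMembers > 0) {
    stopifnot(config$relocatedMembers <= length(scatterMemberIds))
    relocated <- c(relocated, sample(scatterMemberIds, config$relocatedMembers))
  }
  if (length(relocated)) {
    homeB <- chromsB[match(slotChrom[match(relocated, ids)], chroms)]
    orderB <- lapply(orderB, function(g) setdiff(g, relocated))
    for (k in seq_along(relocated)) {
      g <- relocated[k]
      # move to a different chromosome so no collinear flank survives
      choices <- if (nChrom > 1) setdiff(chromsB, homeB[k]) else chromsB
      ch <- if (length(choices) == 1) choices else sample(choices, 1)
      at <- sample(length(orderB[[ch]]) + 1, 1)
      orderB[[ch]] <- append(orderB[[ch]], g, after = at - 1)
    }
  }
  orderB <- lapply(orderB, function(g) unname(idsB[g]))
  lociB <- .layoutGenome(orderB)
  seqsB <- vapply(seqsA, .mutateProtein, character(1),
                  rate = config$substitutionRate, USE.NAMES = FALSE)

  # Within a tandem array the paralogs are near-identical, so ortholog truth
  # could be scrambled by unlucky mutation draws (an A copy scoring higher
  # against a sibling's B copy than against its own). Resample the B copies
  # of an array until each planted ortholog dominates both ways, keeping the
  # recorded truth recoverable by construction.
  sm <- .substMatrix("BLOSUM62")
  alnScore <- function(x, y)
    Biostrings::pairwiseAlignment(Biostrings::AAString(x),
                                  Biostrings::AAString(y),
                                  substitutionMatrix = sm, gapOpening = 10,
                                  gapExtension = 0.5, type = "global",
                                  scoreOnly = TRUE)
  for (ai in seq_along(arrayGenes)) {
    idxs <- match(arrayGenes[[ai]], ids)
    if (length(idxs) < 2) next
    for (try in 1:30) {
      sc <- outer(idxs, idxs, Vectorize(function(i, j)
        alnScore(seqsA[i], seqsB[j])))
      dom <- all(vapply(seq_along(idxs), function(k)
        sc[k, k] > max(sc[k, -k]) && sc[k, k] > max(sc[-k, k]), logical(1)))
      if (dom) break
      seqsB[idxs] <- vapply(seqsA[idxs], .mutateProtein, character(1),
                            rate = config$substitutionRate, USE.NAMES = FALSE)
    }
    if (!dom)
      stop("failed to plant distinguishable tandem-array orthologs",
           call. = FALSE)
  }

  proteomeA <- Biostrings::AAStringSet(seqsA); names(proteomeA) <- ids
  proteomeB <- Biostrings::AAStringSet(seqsB); names(proteomeB) <- idsB[ids]

  tp <- do.call(rbind, lapply(arrayGenes, function(g) {
    pr <- t(utils::combn(sort(g), 2))
    data.frame(gene_a = pr[, 1], gene_b = pr[, 2])
  }))
  if (is.null(tp)) tp <- data.frame(gene_a = character(), gene_b = character())
  op <- data.frame(gene_a = ids, gene_b = unname(idsB[ids]),
                   member = subclass %in% .MEMBER_SUBCLASSES,
                   relocated = ids %in% relocated)
  truth <- new("RBGTruth",
               members = data.frame(id = ids, subclass = subclass),
               tandemPairs = tp, orthologPairs = op)
  list(lociA = lociA, lociB = lociB,
       proteomeA = proteomeA, proteomeB = proteomeB, truth = truth)
}

#' Generate a replicate Ct table with planted log2 fold-changes
#'
#' Per replicate, the target Ct is a per-gene baseline minus the planted
#' log2 fold-change plus Gaussian noise; the reference Ct is constant up to
#' the same noise. With zero noise the 2^-ddCt pipeline recovers the planted
#' effects exactly.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param genes Gene ids (default 10 synthetic genes; ignored when
#'   \code{config$plantedLog2fc} is given).
#' @param samples Sample ids; the first is the calibrator (default a 5-tissue
#'   design with leaf as calibrator).
#' @param nReplicates Replicates per (gene, sample); default triplicate.
#' @return list with \code{ct} (data.frame: gene, sample, replicate,
#'   ct_target, ct_reference), \code{log2fc} (planted matrix) and
#'   \code{calibrator}.
#' @export
makeCtDataset <- function(config = simulationConfig(),
                          genes = sprintf("G%02d", 1:10),
                          samples = c("leaf", "flower", "stem", "curd", "root"),
                          nReplicates = 3) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(stageSeed(config$seed, "ct"))
  fc <- config$plantedLog2fc
  if (is.null(fc)) {
    fc <- matrix(round(stats::rnorm(length(genes) * length(samples), 0, 1.5), 2),
                 nrow = length(genes),
                 dimnames = list(genes, samples))
    fc[, 1] <- 0
  } else {
    genes <- rownames(fc); samples <- colnames(fc)
    if (any(fc[, 1] != 0))
      stop("planted log2fc must be 0 in the calibrator (first) column",
           call. = FALSE)
  }
  baseline <- stats::setNames(stats::runif(length(genes), 24, 30), genes)
  rows <- expand.grid(replicate = seq_len(nReplicates), sample = samples,
                      gene = genes, stringsAsFactors = FALSE)[, 3:1]
  rows$ct_target <- baseline[rows$gene] - fc[cbind(rows$gene, rows$sample)] +
    stats::rnorm(nrow(rows), 0, config$ctNoiseSd)
  rows$ct_reference <- 20 + stats::rnorm(nrow(rows), 0, config$ctNoiseSd)
  rownames(rows) <- NULL
  list(ct = rows, log2fc = fc, calibrator = samples[1])
}
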