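# Tandem-duplicate detection by the gene-order/distance rule and
# syntenic-ortholog detection via reciprocal best hits plus
# flanking-gene collinearity.

.lociFrame <- function(loci) {
  data.frame(gene_id = loci$gene_id,
             chrom = as.character(GenomicRanges::seqnames(loci)),
             start = GenomicRanges::start(loci),
             rank = loci$rank, row.names = loci$gene_id)
}

#' Detect tandem duplications among family members
#'
#' Two member genes form a tandem pair when they lie on the same chromosome,
#' are separated by at most \code{maxIntervening} annotated genes (of any
#' kind), and their starts are within \code{maxBp} of each other. Both
#' thresholds are inclusive. Distance is measured start-to-start (the anchor
#' point is configurable only through the coordinates supplied).
#'
#' @param loci \code{GRanges} from \code{\link{readGeneLoci}} (rank-annotated).
#' @param memberIds Gene ids of the family members to test.
#' @param maxIntervening Maximum intervening gene count (default 10).
#' @param maxBp Maximum start-to-start distance in bp (default 200000).
#' @return data.frame with columns \code{gene_a}, \code{gene_b} (sorted by
#'   position), \code{intervening}, \code{distance_bp}.
#' @export
findTandem <- function(loci, memberIds, maxIntervening = 10, maxBp = 200000) {
  lf <- .lociFrame(loci)
  miss <- setdiff(memberIds, lf$gene_id)
  if (length(miss))
    stop("member id(s) without a locus: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lf <- lf[lf$gene_id %in% memberIds, , drop = FALSE]
  out <- data.frame(gene_a = character(), gene_b = character(),
                    intervening = integer(), distance_bp = numeric())
  for (ch in unique(lf$chrom)) {
    sub <- lf[lf$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    n <- nrow(sub)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        interv <- sub$rank[j] - sub$rank[i] - 1L
        if (interv > maxIntervening) break  # ranks ascending: later j only worse
        dist <- abs(sub$start[j] - sub$start[i])
        if (dist <= maxBp)
          out <- rbind(out, data.frame(gene_a = sub$gene_id[i],
                                       gene_b = sub$gene_id[j],
                                       intervening = interv,
                                       distance_bp = dist))
      }
    }
  }
  rownames(out) <- NULL
  out
}

.kmerIndex <- function(seqs, k) {
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (id in names(seqs)) {
    s <- seqs[[id]]
    if (nchar(s) < k) next
    kms <- unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
    for (km in kms) assign(km, c(get0(km, envir = idx), id), envir = idx)
  }
  idx
}

#' Directed and reciprocal best hits between two proteomes
#'
#' For each protein of A the best-scoring partner in B under affine global
#' alignment, restricted (for speed) to candidates sharing at least one
#' \code{prescreenKmer}-mer; when no candidate shares a k-mer, all of B is
#' scored. Ties are broken by the lexicographically smaller id. The
#' \code{exhaustive} flag disables the prescreen entirely.
#'
#' @param proteomeA,proteomeB Named \code{AAStringSet}s or character vectors.
#' @param prescreenKmer k-mer length for the candidate prescreen.
#' @param exhaustive Score every pair (oracle mode).
#' @inheritParams globalAlign
#' @return list with data.frames \code{ab} and \code{ba} (columns
#'   \code{query}, \code{hit}, \code{score}) and \code{reciprocal}
#'   (columns \code{gene_a}, \code{gene_b}, \code{score}).
#' @export
bestHits <- function(proteomeA, proteomeB, prescreenKmer = 4,
                     exhaustive = FALSE, matrix = "BLOSUM62",
                     gapOpening = 10, gapExtension = 0.5) {
  A <- .asCharacterSeqs(proteomeA)
  B <- .asCharacterSeqs(proteomeB)
  stopifnot(length(A) > 0, length(B) > 0,
            !is.null(names(A)), !is.null(names(B)))
  sm <- .substMatrix(matrix)

  directed <- function(Q, S) {
    sset <- Biostrings::AAStringSet(S)
    idx <- if (!exhaustive) .kmerIndex(S, prescreenKmer) else NULL
    res <- lapply(names(Q), function(qid) {
      q <- Q[[qid]]
      cand <- if (exhaustive) names(S) else {
        kms <- if (nchar(q) >= prescreenKmer)
          unique(substring(q, 1:(nchar(q) - prescreenKmer + 1),
                           prescreenKmer:nchar(q))) else character()
        hits <- unique(unlist(lapply(kms, get0, envir = idx)))
        if (length(hits)) hits else names(S)
      }
      cand <- sort(cand)
      sc <- Biostrings::pairwiseAlignment(
        sset[cand], Biostrings::AAString(q), substitutionMatrix = sm,
        gapOpening = gapOpening, gapExtension = gapExtension,
        type = "global", scoreOnly = TRUE)
      best <- which(sc == max(sc))[1]  # candidates sorted: lexicographic tie-break
      data.frame(query = qid, hit = cand[best], score = sc[best])
    })
    do.call(rbind, res)
  }
  ab <- directed(A, B)
  ba <- directed(B, A)
  baHit <- stats::setNames(ba$hit, ba$query)
  recip <- ab[baHit[ab$hit] == ab$query, , drop = FALSE]
  reciprocal <- data.frame(gene_a = recip$query, gene_b = recip$hit,
                           score = recip$score, row.names = NULL)
  list(ab = ab, ba = ba, reciprocal = reciprocal)
}

#' Syntenic orthologs from best hits and flanking-gene collinearity
#'
#' A reciprocal best-hit pair (a, b) is called syntenic when, among the
#' \code{flankK} genes on each side of a, at least \code{minSupport} have
#' (directed) best hits landing within \code{flankK} ranks of b on b's
#' chromosome. Flanks are truncated at chromosome ends without lowering the
#' support threshold; \code{minSupport = 0} degenerates to reciprocal best
#' hits.
#'
#' @param bh Result of \code{\link{bestHits}}.
#' @param lociA,lociB Rank-annotated \code{GRanges} for the two species.
#' @param flankK Flank window size in genes (default 10).
#' @param minSupport Minimum corroborating flank pairs (default 2).
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{hit_score}, \code{flank_support}.
#' @export
syntenicOrthologs <- function(bh, lociA, lociB, flankK = 10, minSupport = 2) {
  la <- .lociFrame(lociA)
  lb <- .lociFrame(lociB)
  abHit <- stats::setNames(bh$ab$hit, bh$ab$query)
  out <- data.frame(gene_a = character(), gene_b = character(),
                    hit_score = numeric(), flank_support = integer())
  for (i in seq_len(nrow(bh$reciprocal))) {
    a <- bh$reciprocal$gene_a[i]
    b <- bh$reciprocal$gene_b[i]
    if (!a %in% la$gene_id || !b %in% lb$gene_id) next
    ra <- la[a, "rank"]; cha <- la[a, "chrom"]
    rb <- lb[b, "rank"]; chb <- lb[b, "chrom"]
    flank <- la$gene_id[la$chrom == cha & la$gene_id != a &
                        abs(la$rank - ra) <= flankK]
    support <- 0L
    for (f in flank) {
      bf <- abHit[f]
      if (is.na(bf) || !bf %in% lb$gene_id) next
      if (lb[bf, "chrom"] == chb && abs(lb[bf, "rank"] - rb) <= flankK)
        support <- support + 1L
    }
    if (support >= minSupport)
      out <- rbind(out, data.frame(gene_a = a, gene_b = b,
                                   hit_score = bh$reciprocal$score[i],
                                   flank_support = support))
  }
  rownames(out) <- NULL
  out
}

#' Classify the duplication status of member genes
#'
#' A member is \code{tandem} when it appears in any tandem pair, otherwise
#' \code{syntenic_retained} when it has a syntenic ortholog, otherwise
#' \code{dispersed}.
#'
#' @param memberIds Gene ids of the family members.
#' @param tandemPairs data.frame from \code{\link{findTandem}}.
#' @param syntenyPairs data.frame from \code{\link{syntenicOrthologs}}.
#' @return data.frame with columns \code{gene_id}, \code{duplication}.
#' @export
classifyDuplication <- function(memberIds, tandemPairs, syntenyPairs) {
  inTandem <- memberIds %in% c(tandemPairs$gene_a, tandemPairs$gene_b)
  inSynt <- memberIds %in% c(syntenyPairs$gene_a, syntenyPairs$gene_b)
  data.frame(gene_id = memberIds,
             duplication = ifelse(inTandem, "tandem",
                           ifelse(inSynt, "syntenic_retained", "dispersed")),
             row.names = NULL)
}
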