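# Pairwise affine-gap global alignment (needle-style identity/similarity),
# identity/similarity matrices, a naive center-star progressive MSA,
# and low-occupancy column masking.

.substMatrix <- function(matrix) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    get(matrix, envir = e)
  } else matrix
}

.cleanForMatrix <- function(seq, sm) {
  known <- rownames(sm)
  res <- strsplit(seq, "")[[1]]
  bad <- !(res %in% known)
  if (any(bad)) {
    warning("residue(s) absent from the substitution matrix treated as 'X': ",
            paste(unique(res[bad]), collapse = ", "))
    res[bad] <- "X"
    seq <- paste(res, collapse = "")
  }
  seq
}

#' Affine-gap global alignment with identity and similarity
#'
#' Needleman-Wunsch global alignment with affine gaps (a gap of length L
#' costs \code{gapOpening + L * gapExtension}), in the spirit of the EMBOSS
#' needle tool. Identity is matches over full alignment length (gap columns
#' included); similarity additionally counts mismatch columns with a positive
#' substitution score.
#'
#' @param a,b Amino-acid strings.
#' @param matrix Substitution matrix name (a Biostrings data set, default
#'   \code{"BLOSUM62"}) or a numeric matrix.
#' @param gapOpening,gapExtension Gap penalties (positive costs).
#' @return list with \code{aligned_a}, \code{aligned_b}, \code{score},
#'   \code{identity_pct}, \code{similarity_pct}.
#' @export
globalAlign <- function(a, b, matrix = "BLOSUM62",
                        gapOpening = 10, gapExtension = 0.5) {
  stopifnot(nzchar(a), nzchar(b))
  sm <- .substMatrix(matrix)
  a <- .cleanForMatrix(a, sm)
  b <- .cleanForMatrix(b, sm)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = sm, gapOpening = gapOpening,
    gapExtension = gapExtension, type = "global")
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  .alignmentStats(ga, gb, sm, score = Biostrings::score(aln))
}

.alignmentStats <- function(ga, gb, sm, score = NA_real_) {
  ra <- strsplit(ga, "")[[1]]
  rb <- strsplit(gb, "")[[1]]
  stopifnot(length(ra) == length(rb))
  len <- length(ra)
  nongap <- ra != "-" & rb != "-"
  matches <- sum(nongap & ra == rb)
  mism <- which(nongap & ra != rb)
  positive <- if (length(mism)) sum(sm[cbind(ra[mism], rb[mism])] > 0) else 0L
  list(aligned_a = ga, aligned_b = gb, score = score,
       identity_pct = 100 * matches / len,
       similarity_pct = 100 * (matches + positive) / len)
}

#' Pairwise identity and similarity matrices
#'
#' Aligns every unordered pair once; matrices are symmetric by construction
#' with a diagonal of 100.
#'
#' @param seqs Named \code{AAStringSet} or character vector (>= 2 sequences).
#' @inheritParams globalAlign
#' @return list of two symmetric percentage matrices, \code{identity} and
#'   \code{similarity}.
#' @export
identitySimilarityMatrix <- function(seqs, matrix = "BLOSUM62",
                                     gapOpening = 10, gapExtension = 0.5) {
  seqs <- .asCharacterSeqs(seqs)
  n <- length(seqs)
  stopifnot(n >= 2, !is.null(names(seqs)))
  idm <- simm <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- globalAlign(seqs[[i]], seqs[[j]], matrix, gapOpening, gapExtension)
    idm[i, j] <- idm[j, i] <- r$identity_pct
    simm[i, j] <- simm[j, i] <- r$similarity_pct
  }
  list(identity = idm, similarity = simm)
}

#' Naive center-star progressive multiple alignment
#'
#' A deliberately simple built-in aligner for self-contained analyses: the
#' center sequence (highest summed pairwise identity) is aligned pairwise to
#' every other sequence, and the pairwise alignments are merged on the center
#' coordinate frame (insertions relative to the center are left-aligned and
#' gap-padded to the maximum insertion length). An externally computed
#' aligned FASTA can be used anywhere an MSA is expected instead.
#'
#' @param seqs Named \code{AAStringSet} or character vector.
#' @inheritParams globalAlign
#' @return \code{AAStringSet} of equal-width gapped sequences, in input order.
#' @export
centerStarMSA <- function(seqs, matrix = "BLOSUM62",
                          gapOpening = 10, gapExtension = 0.5) {
  seqs <- .asCharacterSeqs(seqs)
  n <- length(seqs)
  stopifnot(n >= 1, !is.null(names(seqs)))
  if (n == 1) {
    out <- Biostrings::AAStringSet(seqs)
    return(out)
  }
  idm <- identitySimilarityMatrix(seqs, matrix, gapOpening, gapExtension)$identity
  center <- which.max(colSums(idm))
  cseq <- seqs[[center]]
  L <- nchar(cseq)
  others <- setdiff(seq_len(n), center)
  alns <- lapply(others, function(i)
    globalAlign(cseq, seqs[[i]], matrix, gapOpening, gapExtension))

  # ins[[k]][j] = gaps in the gapped center before center residue j (j = 1..L+1)
  insOf <- function(gc) {
    res <- strsplit(gc, "")[[1]]
    ins <- integer(L + 1)
    j <- 1L
    run <- 0L
    for (ch in res) {
      if (ch == "-") run <- run + 1L
      else { ins[j] <- run; run <- 0L; j <- j + 1L }
    }
    ins[L + 1L] <- run
    ins
  }
  insList <- lapply(alns, function(a) insOf(a$aligned_a))
  maxIns <- Reduce(pmax, insList, accumulate = FALSE)

  pad <- function(s, width) paste0(s, strrep("-", width - nchar(s)))
  expandRow <- function(go, ins) {
    res <- strsplit(go, "")[[1]]
    out <- character(0)
    p <- 1L
    for (j in seq_len(L)) {
      chunk <- if (ins[j] > 0) paste(res[p:(p + ins[j] - 1L)], collapse = "") else ""
      p <- p + ins[j]
      out <- c(out, pad(chunk, maxIns[j]), res[p])
      p <- p + 1L
    }
    chunk <- if (ins[L + 1L] > 0) paste(res[p:(p + ins[L + 1L] - 1L)], collapse = "") else ""
    out <- c(out, pad(chunk, maxIns[L + 1L]))
    paste(out, collapse = "")
  }
  rows <- character(n)
  cres <- strsplit(cseq, "")[[1]]
  rows[center] <- paste0(paste0(vapply(seq_len(L), function(j)
    paste0(strrep("-", maxIns[j]), cres[j]), character(1)), collapse = ""),
    strrep("-", maxIns[L + 1L]))
  for (k in seq_along(others))
    rows[others[k]] <- expandRow(alns[[k]]$aligned_b, insList[[k]])
  out <- Biostrings::AAStringSet(rows)
  names(out) <- names(seqs)
  out
}

#' Mask low-occupancy alignment columns
#'
#' Drops columns whose fraction of non-gap symbols is below
#' \code{minOccupancy}; a column at exactly the boundary is kept.
#'
#' @param msa \code{AAStringSet} of equal-width gapped sequences (or named
#'   character vector).
#' @param minOccupancy Minimum non-gap fraction (default 0.70).
#' @return Masked \code{AAStringSet}.
#' @export
maskLowCoverageColumns <- function(msa, minOccupancy = 0.70) {
  seqs <- .asCharacterSeqs(msa)
  m <- do.call(rbind, strsplit(seqs, ""))
  stopifnot(!is.null(m), all(nchar(seqs) == nchar(seqs[1])))
  occ <- colMeans(m != "-")
  keep <- occ >= minOccupancy
  if (!any(keep))
    stop("all alignment columns fall below the occupancy cutoff", call. = FALSE)
  out <- Biostrings::AAStringSet(apply(m[, keep, drop = FALSE], 1, paste,
                                       collapse = ""))
  names(out) <- names(seqs)
  out
}
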