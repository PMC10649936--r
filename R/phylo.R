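# Evolutionary distances from a masked MSA, a Saitou-Nei neighbor-joining
# implementation with deterministic tie-breaking, and column-resampling
# bootstrap support.

.msaMatrix <- function(msa) {
  seqs <- .asCharacterSeqs(msa)
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)))
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

#' Pairwise evolutionary distances from a masked alignment
#'
#' The p-distance is the mismatch fraction over mutually non-gap sites; the
#' Poisson-corrected distance is \code{-ln(1 - p)}. Jones-Taylor-Thornton
#' maximum-likelihood distances are not implemented; the Poisson correction
#' is the default stand-in (a stated deviation from MEGA's JTT option), and
#' the raw p-distance is selectable.
#'
#' @param msa \code{AAStringSet} (or named character vector) of equal-width
#'   gapped sequences, or a character matrix.
#' @param model \code{"poisson"} (default) or \code{"p"}.
#' @param ceiling Distance assigned (with a warning) when p >= 1 makes the
#'   Poisson correction undefined.
#' @return Symmetric numeric matrix of distances with a zero diagonal.
#' @export
pairwiseDistances <- function(msa, model = c("poisson", "p"), ceiling = 10) {
  model <- match.arg(model)
  m <- if (is.matrix(msa)) msa else .msaMatrix(msa)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok))
      stop("no mutually non-gap sites between ", rownames(m)[i], " and ",
           rownames(m)[j], call. = FALSE)
    p <- mean(m[i, ok] != m[j, ok])
    d <- if (model == "p") p
         else if (p >= 1) { warning("p >= 1; Poisson distance set to ceiling"); ceiling }
         else -log(1 - p)
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration with the standard Q-criterion. Ties in Q are
#' broken by the lexicographically smallest (label, label) pair so the result
#' is a pure function of the matrix. Negative branch lengths are clamped to
#' zero with the deficit moved to the sibling edge, keeping the joined pair's
#' distance intact.
#'
#' @param D Symmetric distance matrix with labels (n >= 3; n = 2 returns a
#'   trivial two-leaf tree with a warning).
#' @return An unrooted \code{ape::phylo} tree.
#' @export
neighborJoining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D),
            !is.null(rownames(D)), isTRUE(all.equal(D, t(D))))
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 3) {
    warning("fewer than 3 taxa: returning trivial tree")
    if (n == 1) return(ape::read.tree(text = paste0("(", labels[1], ":0);")))
    d <- D[1, 2] / 2
    return(ape::read.tree(text = sprintf("(%s:%.15g,%s:%.15g);",
                                         labels[1], d, labels[2], d)))
  }
  node <- labels                    # newick fragment per active node
  key <- labels                     # tie-break key: smallest leaf label inside
  while (length(node) > 3) {
    k <- nrow(D)
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pairKey <- apply(cand, 1, function(ij) {
      ks <- sort(c(key[ij[1]], key[ij[2]]))
      paste(ks, collapse = "\r")
    })
    pick <- cand[order(pairKey)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- D[i, j]; li <- 0 }
    if (lj < 0) { li <- D[i, j]; lj <- 0 }
    merged <- sprintf("(%s:%.15g,%s:%.15g)", node[i], li, node[j], lj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    node <- c(node[keep], merged)
    key <- c(key[keep], min(key[c(i, j)]))
    rownames(D2) <- colnames(D2) <- node
    D <- D2
  }
  # terminal trifurcation via the three-point formulas
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- max(0, (d12 + d13 - d23) / 2)
  l2 <- max(0, (d12 + d23 - d13) / 2)
  l3 <- max(0, (d13 + d23 - d12) / 2)
  txt <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 node[1], l1, node[2], l2, node[3], l3)
  ape::read.tree(text = txt)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, recomputes distances and the
#' NJ tree per replicate, and scores each internal edge of the full-data tree
#' by the fraction of replicates containing its bipartition (stored in
#' \code{node.label}). Deterministic given \code{seed}.
#'
#' @param msa Masked \code{AAStringSet} or character matrix.
#' @param nReps Number of bootstrap replicates (0 returns the tree without
#'   supports).
#' @param seed Integer seed for the resampling.
#' @param model Distance model passed to \code{\link{pairwiseDistances}}.
#' @return An \code{ape::phylo} with supports in \code{node.label} (root
#'   entry empty).
#' @export
bootstrapSupport <- function(msa, nReps = 1000, seed = 1,
                             model = c("poisson", "p")) {
  model <- match.arg(model)
  m <- if (is.matrix(msa)) msa else .msaMatrix(msa)
  tree <- neighborJoining(pairwiseDistances(m, model))
  if (nReps == 0) return(tree)
  set.seed(seed)
  boots <- vector("list", nReps)
  for (b in seq_len(nReps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    boots[[b]] <- neighborJoining(pairwiseDistances(m[, cols, drop = FALSE],
                                                    model))
  }
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- counts / nReps
  support[1] <- NA  # root "bipartition" of an unrooted tree is not an edge
  tree$node.label <- ifelse(is.na(support), "", format(support, trim = TRUE))
  attr(tree, "support") <- support
  tree
}
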