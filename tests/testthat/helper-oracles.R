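# Independent oracles and small fixture builders used across the suite.

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Exhaustive affine-gap global alignment score: direct DP over gap lengths
# (a gap of length L costs open + L * ext), with no three-state decomposition.
oracleAlignScore <- function(a, b, sm = .blosum62, open = 10, ext = 0.5) {
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  n <- length(ra); m <- length(rb)
  S <- matrix(-Inf, n + 1, m + 1)
  S[1, 1] <- 0
  for (i in 0:n) for (j in 0:m) {
    if (i == 0 && j == 0) next
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, S[i, j] + sm[ra[i], rb[j]])
    if (i > 0) for (k in 1:i)
      best <- max(best, S[i - k + 1, j + 1] - (open + ext * k))
    if (j > 0) for (k in 1:j)
      best <- max(best, S[i + 1, j - k + 1] - (open + ext * k))
    S[i + 1, j + 1] <- best
  }
  S[n + 1, m + 1]
}

# All-pairs tandem scan: the O(n^2) definition applied literally.
bruteForceTandem <- function(loci, memberIds, maxIntervening = 10,
                             maxBp = 200000) {
  chrom <- as.character(GenomicRanges::seqnames(loci))
  start <- GenomicRanges::start(loci)
  rank <- loci$rank
  ids <- loci$gene_id
  keep <- ids %in% memberIds
  out <- list()
  idx <- which(keep)
  for (i in idx) for (j in idx) {
    if (ids[i] >= ids[j]) next
    if (chrom[i] != chrom[j]) next
    interv <- abs(rank[i] - rank[j]) - 1L
    dist <- abs(start[i] - start[j])
    if (interv <= maxIntervening && dist <= maxBp)
      out[[length(out) + 1L]] <- sort(c(ids[i], ids[j]))
  }
  if (!length(out)) return(character())
  sort(vapply(out, paste, character(1), collapse = "|"))
}

pairKey <- function(df, a = "gene_a", b = "gene_b") {
  if (!nrow(df)) return(character())
  sort(apply(df[, c(a, b)], 1, function(r) paste(sort(r), collapse = "|")))
}

# Maximum RNP2/RNP1 matching by exhaustive enumeration over all pairings
# (feasible for <= 4 hits of a kind): the optimality oracle for the greedy
# pairing in callRRMs.
oracleMaxRRMPairs <- function(h2, h1, window = c(10, 60)) {
  n2 <- nrow(h2); n1 <- nrow(h1)
  if (!n2 || !n1) return(0L)
  feasible <- function(i, j) {
    gap <- h1$start[j] - h2$end[i] - 1L
    gap >= window[1] && gap <= window[2]
  }
  best <- 0L
  recurse <- function(i, used) {
    if (i > n2) {
      best <<- max(best, sum(used))
      return()
    }
    recurse(i + 1L, used)              # leave this RNP2 unpaired
    for (j in seq_len(n1)) {
      if (!used[j] && feasible(i, j)) {
        used[j] <- TRUE
        recurse(i + 1L, used)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, n1))
  best
}

# Grid-scan pI oracle: the pH on a 0.001 grid minimizing |net charge|.
gridScanPI <- function(seq, step = 0.001) {
  grid <- seq(0, 14, by = step)
  ch <- netCharge(seq, grid)
  grid[which.min(abs(ch))]
}

randomProtein <- function(len, letters = c("A", "C", "D", "E", "F", "G", "H",
                                           "I", "K", "L", "M", "N", "P", "Q",
                                           "R", "S", "T", "V", "W", "Y")) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# A small two-clade alignment: two blocks of identical core sequence that
# differ at a fixed diagnostic segment, plus a few private substitutions.
makeTwoCladeMSA <- function(seed = 4, perClade = 4, len = 60, diag = 20) {
  set.seed(seed)
  base <- strsplit(randomProtein(len, c("A", "C", "D", "E", "G")), "")[[1]]
  mk <- function(block) {
    s <- base
    s[seq_len(diag)] <- block
    s[sample(len, 3)] <- "W"
    paste(s, collapse = "")
  }
  seqs <- c(vapply(seq_len(perClade), function(i) mk("K"), character(1)),
            vapply(seq_len(perClade), function(i) mk("P"), character(1)))
  names(seqs) <- c(paste0("a", seq_len(perClade)), paste0("b", seq_len(perClade)))
  Biostrings::AAStringSet(seqs)
}

# Support of the bipartition splitting `tips` from the rest, looked up from
# a bootstrapSupport() tree.
bipartitionSupport <- function(tree, tips) {
  supp <- attr(tree, "support")
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  all <- seq_along(labs)
  target <- sort(match(tips, labs))
  comp <- sort(setdiff(all, target))
  for (k in seq_along(parts)) {
    p <- sort(parts[[k]])
    if (identical(p, target) || identical(p, comp)) return(supp[k])
  }
  NA_real_
}

writeTempLines <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
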