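# RNP-1/RNP-2 consensus scanning, CCHC zinc-knuckle detection, RRM calling,
# glycine metrics, and the external-domain-evidence filter.
#
# Motif hit coordinates are 1-based inclusive residue positions.

# Degenerate consensus patterns. 'X' in a sequence matches only the wildcard
# (pos 7) of RNP-1: character classes never list X, and '.' admits it.
.RNP1_REGEX <- "[KR]G[FY][GA]FV.[FY]"
.RNP2_REGEX <- "[LI][FY][VI][GK][GN]L"
.CCHC_REGEX <- "C..C....H....C"

.scanMotif <- function(seq, regex, kind) {
  if (!nzchar(seq))
    return(data.frame(kind = character(), start = integer(), end = integer(),
                      match = character()))
  m <- gregexpr(regex, seq)[[1]]
  if (m[1] == -1L)
    return(data.frame(kind = character(), start = integer(), end = integer(),
                      match = character()))
  st <- as.integer(m)
  len <- attr(m, "match.length")
  data.frame(kind = kind, start = st, end = st + len - 1L,
             match = substring(seq, st, st + len - 1L), row.names = NULL)
}

#' Scan for RNP-1 / RNP-2 / CCHC consensus motifs
#'
#' \code{scanRNP1} matches the 8-residue ribonucleoprotein-1 consensus
#' (K/R)-G-(F/Y)-(G/A)-F-V-x-(F/Y); \code{scanRNP2} the 6-residue RNP-2
#' consensus (L/I)-(F/Y)-(V/I)-(G/K)-(G/N)-L; \code{scanCCHC} the canonical
#' zinc-knuckle C-x2-C-x4-H-x4-C (14 residues). Matches are non-overlapping,
#' scanned left to right.
#'
#' @param seq Amino-acid string (20 letters + X).
#' @return data.frame with columns \code{kind}, \code{start}, \code{end}
#'   (1-based inclusive), \code{match}. Empty when nothing matches.
#' @export
scanRNP1 <- function(seq) {
  .assertAAString(seq)
  .scanMotif(seq, .RNP1_REGEX, "RNP1")
}

#' @rdname scanRNP1
#' @export
scanRNP2 <- function(seq) {
  .assertAAString(seq)
  .scanMotif(seq, .RNP2_REGEX, "RNP2")
}

#' @rdname scanRNP1
#' @export
scanCCHC <- function(seq) {
  .assertAAString(seq)
  .scanMotif(seq, .CCHC_REGEX, "CCHC")
}

#' Pair RNP-2 and RNP-1 hits into RRM calls
#'
#' Within a canonical ~80-residue RRM the RNP-2 submotif lies upstream of
#' RNP-1. Hits are paired greedily left to right: each RNP-2 takes the nearest
#' unused downstream RNP-1 whose inter-motif gap (residues strictly between
#' the two hits) lies in \code{pairingWindow}; each hit is used at most once.
#'
#' @param seq Amino-acid string.
#' @param pairingWindow Length-2 numeric, inclusive bounds on the gap.
#' @return data.frame with one row per RRM call: \code{rnp2_start},
#'   \code{rnp2_end}, \code{rnp1_start}, \code{rnp1_end}, \code{gap},
#'   \code{span_start}, \code{span_end}.
#' @export
callRRMs <- function(seq, pairingWindow = c(10, 60)) {
  stopifnot(length(pairingWindow) == 2L, pairingWindow[1] <= pairingWindow[2])
  h2 <- scanRNP2(seq)
  h1 <- scanRNP1(seq)
  out <- data.frame(rnp2_start = integer(), rnp2_end = integer(),
                    rnp1_start = integer(), rnp1_end = integer(),
                    gap = integer(), span_start = integer(), span_end = integer())
  if (!nrow(h1) || !nrow(h2)) return(out)
  used <- rep(FALSE, nrow(h1))
  for (i in seq_len(nrow(h2))) {
    gaps <- h1$start - h2$end[i] - 1L
    ok <- which(!used & gaps >= pairingWindow[1] & gaps <= pairingWindow[2])
    if (!length(ok)) next
    j <- ok[which.min(h1$start[ok])]
    used[j] <- TRUE
    out <- rbind(out, data.frame(
      rnp2_start = h2$start[i], rnp2_end = h2$end[i],
      rnp1_start = h1$start[j], rnp1_end = h1$end[j],
      gap = gaps[j], span_start = h2$start[i], span_end = h1$end[j]))
  }
  out
}

#' Glycine-content metrics of the C-terminal region
#'
#' The C-terminal region runs from just after the last RRM span to the end of
#' the sequence; with no RRM call the whole sequence is used. A zero-length
#' region yields fraction 0 with a warning.
#'
#' @param seq Amino-acid string.
#' @param rrmCalls data.frame from \code{\link{callRRMs}}.
#' @return list with \code{cterm_start}, \code{cterm_end},
#'   \code{gly_fraction_cterm}, \code{gly_fraction_total}.
#' @export
glycineMetrics <- function(seq, rrmCalls) {
  .assertAAString(seq)
  n <- nchar(seq)
  cstart <- if (nrow(rrmCalls)) max(rrmCalls$span_end) + 1L else 1L
  total <- .countChar(seq, "G") / n
  if (cstart > n) {
    warning("zero-length C-terminal region; glycine fraction set to 0")
    return(list(cterm_start = cstart, cterm_end = n,
                gly_fraction_cterm = 0, gly_fraction_total = total))
  }
  region <- substring(seq, cstart, n)
  list(cterm_start = cstart, cterm_end = n,
       gly_fraction_cterm = .countChar(region, "G") / nchar(region),
       gly_fraction_total = total)
}

#' Build per-protein domain profiles with the built-in consensus scanner
#'
#' The self-contained evidence path: RRMs from RNP-2/RNP-1 consensus pairing,
#' CCHC knuckles from the zinc-knuckle pattern, glycine metrics from the
#' post-RRM C-terminal region. Cold-shock domains have no printed consensus
#' and can only be flagged via \code{csdIds} (e.g. from an external domain
#' table, see \code{\link{profilesFromDomainTable}}).
#'
#' @param proteome \code{AAStringSet} or named character vector.
#' @param pairingWindow Inclusive gap window for RNP pairing.
#' @param csdIds Protein ids to flag as carrying a cold-shock domain.
#' @return data.frame with one row per protein: \code{protein_id},
#'   \code{n_rrm}, \code{n_cchc}, \code{csd}, \code{cterm_start},
#'   \code{gly_fraction_cterm}, \code{gly_fraction_total}.
#' @export
scanProteome <- function(proteome, pairingWindow = c(10, 60),
                         csdIds = character()) {
  seqs <- .asCharacterSeqs(proteome)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("proteome must have unique names", call. = FALSE)
  rows <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    rrm <- callRRMs(s, pairingWindow)
    gm <- glycineMetrics(s, rrm)
    data.frame(protein_id = id,
               n_rrm = nrow(rrm),
               n_cchc = nrow(scanCCHC(s)),
               csd = id %in% csdIds,
               cterm_start = gm$cterm_start,
               gly_fraction_cterm = gm$gly_fraction_cterm,
               gly_fraction_total = gm$gly_fraction_total)
  })
  do.call(rbind, rows)
}

#' Filter an external domain-hit table by model coverage and E-value
#'
#' Keeps rows with model coverage \code{(ali_to - ali_from + 1)/model_length}
#' of at least \code{minCoverage} and E-value at most \code{maxEvalue} (both
#' boundaries inclusive), then counts surviving RRM-model hits per protein.
#'
#' @param rows data.frame from \code{\link{readDomainTable}}.
#' @param minCoverage Minimum model coverage (default 0.60).
#' @param maxEvalue Maximum E-value (default 1e-5).
#' @param rrmModels Character vector of model names counted as RRM profiles;
#'   by default any model whose name contains "RRM".
#' @return list with \code{rows} (surviving rows, with a \code{coverage}
#'   column) and \code{rrm_counts} (data.frame \code{protein_id},
#'   \code{n_rrm}).
#' @export
filterDomainTable <- function(rows, minCoverage = 0.60, maxEvalue = 1e-5,
                              rrmModels = NULL) {
  if (any(rows$model_length == 0))
    stop("model_length of 0 in domain table", call. = FALSE)
  cov <- (rows$ali_to - rows$ali_from + 1) / rows$model_length
  keep <- cov >= minCoverage & rows$e_value <= maxEvalue
  out <- rows[keep, , drop = FALSE]
  out$coverage <- cov[keep]
  isrrm <- if (is.null(rrmModels)) grepl("RRM", out$model_name, ignore.case = TRUE)
           else out$model_name %in% rrmModels
  cnt <- table(factor(out$protein_id[isrrm], levels = unique(rows$protein_id)))
  list(rows = out,
       rrm_counts = data.frame(protein_id = names(cnt),
                               n_rrm = as.integer(cnt), row.names = NULL))
}

#' Build domain profiles from an external domain table
#'
#' The alternative evidence path: RRM counts (and cold-shock-domain flags)
#' come from a filtered profile-HMM hit table, while CCHC knuckles and
#' glycine metrics still come from the built-in scanner (the C-terminal
#' region is anchored on the scanner's RRM spans, since the external table
#' carries model, not protein, coordinates).
#'
#' @inheritParams scanProteome
#' @inheritParams filterDomainTable
#' @param table data.frame from \code{\link{readDomainTable}}.
#' @param csdModels Model names treated as cold-shock-domain profiles.
#' @return As \code{\link{scanProteome}}.
#' @export
profilesFromDomainTable <- function(proteome, table, minCoverage = 0.60,
                                    maxEvalue = 1e-5, rrmModels = NULL,
                                    csdModels = c("CSD", "CSP")) {
  prof <- scanProteome(proteome)
  flt <- filterDomainTable(table, minCoverage, maxEvalue, rrmModels)
  counts <- structure(flt$rrm_counts$n_rrm, names = flt$rrm_counts$protein_id)
  prof$n_rrm <- ifelse(prof$protein_id %in% names(counts),
                       counts[prof$protein_id], 0L)
  csdhit <- unique(flt$rows$protein_id[flt$rows$model_name %in% csdModels])
  prof$csd <- prof$csd | prof$protein_id %in% csdhit
  prof
}
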