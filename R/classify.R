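# Family membership filter, subclass grammar, member naming,
# and physicochemical properties (MW, pI, glycine content).

#' Apply the RBG subclass grammar to domain profiles
#'
#' Rules, in order of precedence: (i) cold-shock domain plus two or more CCHC
#' knuckles is subclass IVc, which is excluded from the family; (ii) proteins
#' whose C-terminal glycine fraction is not strictly above
#' \code{glyThreshold} are rejected; (iii) two or more RRMs is IVd; (iv) one
#' RRM plus at least one CCHC knuckle is IVb; (v) one RRM is IVa; (vi)
#' anything else is not a member. Evaluating the IVc exclusion before the
#' glycine filter keeps cold-shock decoys from leaking in as IVb.
#'
#' @param profiles data.frame from \code{\link{scanProteome}} or
#'   \code{\link{profilesFromDomainTable}}.
#' @param glyThreshold Strict lower bound on the C-terminal glycine fraction
#'   (default 0.20; a fraction of exactly 0.20 fails).
#' @return data.frame with columns \code{protein_id}, \code{is_member},
#'   \code{subclass} (IVa/IVb/IVd/IVc_excluded/none), \code{assigned_name}
#'   (NA until \code{\link{nameMembers}}), \code{reason}.
#' @export
assignSubclasses <- function(profiles, glyThreshold = 0.20) {
  n <- nrow(profiles)
  subclass <- character(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    p <- profiles[i, ]
    if (p$csd && p$n_cchc >= 2) {
      subclass[i] <- "IVc_excluded"
      reason[i] <- "CSD with >=2 CCHC knuckles: subclass IVc, excluded from family"
    } else if (p$gly_fraction_cterm <= glyThreshold) {
      subclass[i] <- "none"
      reason[i] <- sprintf("C-terminal glycine fraction %.3f not > %.2f",
                           p$gly_fraction_cterm, glyThreshold)
    } else if (p$n_rrm >= 2) {
      subclass[i] <- "IVd"
      reason[i] <- "two or more RRMs with glycine-rich C-terminal"
    } else if (p$n_rrm == 1 && p$n_cchc >= 1) {
      subclass[i] <- "IVb"
      reason[i] <- "one RRM plus CCHC knuckle with glycine-rich C-terminal"
    } else if (p$n_rrm == 1) {
      subclass[i] <- "IVa"
      reason[i] <- "one RRM with glycine-rich C-terminal"
    } else {
      subclass[i] <- "none"
      reason[i] <- "no RRM"
    }
  }
  data.frame(protein_id = profiles$protein_id,
             is_member = subclass %in% .MEMBER_SUBCLASSES,
             subclass = subclass,
             assigned_name = NA_character_,
             reason = reason, row.names = NULL)
}

#' Assign systematic member names (RBGA1, RBGB1, RBGD1, ...)
#'
#' Within each subclass, members are numbered 1..k in chromosome order
#' (chromosome name, then start coordinate) using the supplied gene loci;
#' members without a locus are appended after placed members, ordered by
#' protein id, with a warning.
#'
#' @param calls data.frame from \code{\link{assignSubclasses}}.
#' @param loci Optional \code{GRanges} from \code{\link{readGeneLoci}}; gene
#'   ids must match protein ids.
#' @param prefix Named character vector mapping subclass to name prefix.
#' @return \code{calls} with \code{assigned_name} filled in for members.
#' @export
nameMembers <- function(calls, loci = NULL,
                        prefix = c(IVa = "RBGA", IVb = "RBGB", IVd = "RBGD")) {
  for (sc in .MEMBER_SUBCLASSES) {
    idx <- which(calls$is_member & calls$subclass == sc)
    if (!length(idx)) next
    ids <- calls$protein_id[idx]
    if (!is.null(loci)) {
      m <- match(ids, loci$gene_id)
      if (anyNA(m))
        warning("member(s) without a gene locus named after placed members: ",
                paste(ids[is.na(m)], collapse = ", "))
      chrom <- ifelse(is.na(m), "~", as.character(GenomicRanges::seqnames(loci))[m])
      start <- ifelse(is.na(m), Inf, GenomicRanges::start(loci)[m])
      ord <- order(chrom, start, ids)
    } else {
      ord <- order(ids)
    }
    calls$assigned_name[idx[ord]] <- paste0(prefix[[sc]], seq_along(idx))
  }
  calls
}

# Average residue masses (Da) and one water; the standard average-isotopic
# table used by ExPASy-style MW tools.
.AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.0153

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water. Undefined residues ('X')
#' contribute the mean of the 20 standard residue masses.
#'
#' @param seq Amino-acid string (vectorized over a character vector).
#' @return Molecular weight in kDa.
#' @export
molWeight <- function(seq) {
  masses <- c(.AA_MASS, X = mean(.AA_MASS))
  vapply(seq, function(s) {
    .assertAAString(s)
    (sum(masses[strsplit(s, "")[[1]]]) + .WATER_MASS) / 1000
  }, numeric(1), USE.NAMES = FALSE)
}

#' Bjellqvist-style pKa table used for pI computation
#'
#' N-terminal pKa depends on the first residue (ExPASy convention);
#' side-chain values cover D, E, C, Y, H, K, R.
#'
#' @return list with \code{cterm}, \code{nterm_default}, \code{nterm}
#'   (residue-specific overrides) and \code{sidechain} components.
#' @export
pkaTableBjellqvist <- function() {
  list(cterm = 3.55,
       nterm_default = 7.50,
       nterm = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
                 V = 7.44, E = 7.70),
       sidechain = c(C = 9.00, D = 4.05, E = 4.45, H = 5.98,
                     K = 10.00, R = 12.00, Y = 10.00))
}

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch sum over the termini and the ionizable side chains
#' (D, E, C, Y negative; H, K, R positive). Undefined residues ('X') carry no
#' charge. Vectorized over \code{pH}.
#'
#' @param seq Amino-acid string.
#' @param pH Numeric vector of pH values.
#' @param pka pKa table, see \code{\link{pkaTableBjellqvist}}.
#' @return Net charge at each pH.
#' @export
netCharge <- function(seq, pH, pka = pkaTableBjellqvist()) {
  .assertAAString(seq)
  res <- strsplit(seq, "")[[1]]
  first <- res[res != "X"][1]
  ntermPka <- if (!is.na(first) && first %in% names(pka$nterm))
    pka$nterm[[first]] else pka$nterm_default
  pos <- function(pk) 1 / (1 + 10^(pH - pk))    # protonated basic group
  neg <- function(pk) -1 / (1 + 10^(pk - pH))   # deprotonated acidic group
  charge <- pos(ntermPka) + neg(pka$cterm)
  counts <- table(res)
  for (aa in c("D", "E", "C", "Y"))
    if (!is.na(counts[aa]))
      charge <- charge + as.numeric(counts[aa]) * neg(pka$sidechain[[aa]])
  for (aa in c("H", "K", "R"))
    if (!is.na(counts[aa]))
      charge <- charge + as.numeric(counts[aa]) * pos(pka$sidechain[[aa]])
  charge
}

#' Theoretical isoelectric point by bisection
#'
#' The net charge is strictly decreasing in pH, so the root of
#' \code{\link{netCharge}} on [0, 14] is unique; it is found by bisection to
#' a tolerance of 1e-3 pH units. The presence of undefined residues ('X') is
#' reported via a message (they are skipped in the charge sum).
#'
#' @inheritParams netCharge
#' @param tol Bisection tolerance in pH units.
#' @return The isoelectric point (pH units), vectorized over a character
#'   vector of sequences.
#' @export
isoelectricPoint <- function(seq, pka = pkaTableBjellqvist(), tol = 1e-3) {
  vapply(seq, function(s) {
    .assertAAString(s)
    nx <- .countChar(s, "X")
    if (nx > 0)
      message("pI of a sequence with ", nx,
              " undefined residue(s); they are excluded from the charge sum")
    lo <- 0; hi <- 14
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (netCharge(s, mid, pka) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1), USE.NAMES = FALSE)
}

#' Physicochemical properties of a proteome
#'
#' @param x \code{AAStringSet}, named character vector, or \code{RBGFamily}.
#' @param ... passed on (unused).
#' @return data.frame with \code{protein_id}, \code{length} (residues),
#'   \code{mw_kda}, \code{pi}, \code{gly_percent}.
#' @rdname proteinProperties
#' @export
setMethod("proteinProperties", "ANY", function(x, ...) {
  seqs <- .asCharacterSeqs(x)
  data.frame(protein_id = names(seqs),
             length = nchar(seqs),
             mw_kda = molWeight(seqs),
             pi = isoelectricPoint(seqs),
             gly_percent = 100 * .countChar(seqs, "G") / nchar(seqs),
             row.names = NULL)
})

#' Classify a proteome into an RBG family
#'
#' End-to-end identification: domain profiles (built-in scanner, or the
#' external-domain-table path when \code{domainTable} is given), subclass
#' grammar, member naming and protein properties, bundled in an
#' \code{RBGFamily}.
#'
#' @param proteome \code{AAStringSet} or named character vector.
#' @param loci Optional \code{GRanges} for chromosome-order naming.
#' @param domainTable Optional data.frame from \code{\link{readDomainTable}}.
#' @param glyThreshold Strict lower bound on C-terminal glycine fraction.
#' @param pairingWindow RNP pairing gap window.
#' @param minCoverage,maxEvalue Domain-table filter thresholds.
#' @param properties Compute physicochemical properties (default TRUE).
#' @return An \code{\link{RBGFamily-class}} object.
#' @export
classifyProteome <- function(proteome, loci = NULL, domainTable = NULL,
                             glyThreshold = 0.20, pairingWindow = c(10, 60),
                             minCoverage = 0.60, maxEvalue = 1e-5,
                             properties = TRUE) {
  if (is.character(proteome)) proteome <- Biostrings::AAStringSet(proteome)
  profiles <- if (is.null(domainTable))
    scanProteome(proteome, pairingWindow)
  else
    profilesFromDomainTable(proteome, domainTable, minCoverage, maxEvalue)
  calls <- nameMembers(assignSubclasses(profiles, glyThreshold), loci)
  props <- if (properties) suppressMessages(proteinProperties(proteome))
           else data.frame(protein_id = character())
  new("RBGFamily", proteome = proteome, profiles = profiles,
      calls = calls, properties = props)
}
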