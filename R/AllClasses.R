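#' @import methods
#' @importFrom S4Vectors metadata
#' @importClassesFrom Biostrings AAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames
NULL

.SUBCLASSES <- c("IVa", "IVb", "IVc", "IVd")
.MEMBER_SUBCLASSES <- c("IVa", "IVb", "IVd")

#' Planted ground truth from the synthetic-data generator
#'
#' Records what the generator planted: family membership with subclass labels,
#' tandem-duplicate pairs, cross-species ortholog pairs, and expression
#' log2 fold-changes. Used by the test-suite and by recovery summaries;
#' the analysis functions themselves never look at it.
#'
#' @slot members data.frame with columns \code{id}, \code{subclass}
#'   (one of IVa/IVb/IVc/IVd/background).
#' @slot tandemPairs data.frame with columns \code{gene_a}, \code{gene_b}.
#' @slot orthologPairs data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{member}, \code{relocated}.
#' @slot log2fc numeric matrix (genes x samples) of planted effects, or a
#'   0 x 0 matrix when no expression data were generated.
#' @export
setClass("RBGTruth",
  representation(members = "data.frame",
                 tandemPairs = "data.frame",
                 orthologPairs = "data.frame",
                 log2fc = "matrix"),
  prototype(members = data.frame(id = character(), subclass = character()),
            tandemPairs = data.frame(gene_a = character(), gene_b = character()),
            orthologPairs = data.frame(gene_a = character(), gene_b = character(),
                                       member = logical(), relocated = logical()),
            log2fc = matrix(numeric(), 0, 0)))

setValidity("RBGTruth", function(object) {
  msg <- character()
  m <- object@members
  if (!all(c("id", "subclass") %in% names(m)))
    msg <- c(msg, "members needs columns 'id' and 'subclass'")
  else {
    if (anyDuplicated(m$id)) msg <- c(msg, "duplicated ids in members")
    bad <- setdiff(unique(m$subclass), c(.SUBCLASSES, "background"))
    if (length(bad))
      msg <- c(msg, paste("invalid subclass labels:", paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' A classified RBG gene family
#'
#' Container tying together the proteome that was scanned, the per-protein
#' domain profiles, the family calls (membership, subclass, assigned name)
#' and physicochemical properties.
#'
#' @slot proteome \code{AAStringSet} of the scanned proteins.
#' @slot profiles data.frame of per-protein domain evidence
#'   (see \code{\link{scanProteome}}).
#' @slot calls data.frame of family calls (see \code{\link{assignSubclasses}}).
#' @slot properties data.frame of protein properties
#'   (see \code{\link{proteinProperties}}).
#' @export
setClass("RBGFamily",
  representation(proteome = "AAStringSet",
                 profiles = "data.frame",
                 calls = "data.frame",
                 properties = "data.frame"))

setValidity("RBGFamily", function(object) {
  msg <- character()
  ids <- names(object@proteome)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "proteome must have unique names")
  for (sl in c("profiles", "calls", "properties")) {
    df <- slot(object, sl)
    if (nrow(df) && !setequal(df$protein_id, ids))
      msg <- c(msg, paste0(sl, " ids do not match the proteome"))
  }
  cl <- object@calls
  if (nrow(cl)) {
    bad <- cl$is_member & !cl$subclass %in% .MEMBER_SUBCLASSES
    if (any(bad))
      msg <- c(msg, "members must carry subclass IVa, IVb or IVd")
    nm <- cl$assigned_name[!is.na(cl$assigned_name)]
    if (anyDuplicated(nm)) msg <- c(msg, "assigned names must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Relative-expression matrix from the 2^-ddCt method
#'
#' A \code{SummarizedExperiment} with assays \code{log2fc} (log2-transformed
#' relative expression, i.e. -ddCt) and \code{sd} (replicate SD of dCt).
#' The calibrator sample id is kept in \code{metadata(x)$calibrator}; its
#' column is identically zero by construction.
#'
#' @export
setClass("DdCtExperiment", contains = "SummarizedExperiment")

setValidity("DdCtExperiment", function(object) {
  msg <- character()
  if (!all(c("log2fc", "sd") %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays 'log2fc' and 'sd' are required")
  cal <- S4Vectors::metadata(object)$calibrator
  if (is.null(cal)) {
    msg <- c(msg, "metadata(x)$calibrator is required")
  } else if (!cal %in% colnames(object)) {
    msg <- c(msg, "calibrator sample is not a column")
  } else {
    v <- SummarizedExperiment::assay(object, "log2fc")[, cal]
    if (length(v) && max(abs(v)) > 1e-9)
      msg <- c(msg, "calibrator column must be identically zero")
  }
  if (length(msg)) msg else TRUE
})
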