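# Accessors and show methods for the S4 containers.

#' @rdname RBGFamily-class
#' @export
setMethod("domainProfiles", "RBGFamily", function(x) x@profiles)

#' @rdname RBGFamily-class
#' @export
setMethod("familyCalls", "RBGFamily", function(x) x@calls)

#' @rdname RBGFamily-class
#' @export
setMethod("familyMembers", "RBGFamily", function(x) {
  cl <- x@calls
  cl$protein_id[cl$is_member]
})

#' @rdname RBGFamily-class
#' @export
setMethod("subclassCounts", "RBGFamily", function(x) {
  cl <- x@calls[x@calls$is_member, ]
  out <- table(factor(cl$subclass, levels = .MEMBER_SUBCLASSES))
  c(out)
})

#' @rdname RBGFamily-class
#' @param ... unused for the accessor method.
#' @export
setMethod("proteinProperties", "RBGFamily", function(x, ...) x@properties)

setMethod("show", "RBGFamily", function(object) {
  n <- length(object@proteome)
  cnt <- subclassCounts(object)
  cat("RBGFamily with", n, "scanned proteins\n")
  cat("  members:", sum(cnt),
      sprintf("(IVa = %d, IVb = %d, IVd = %d)", cnt["IVa"], cnt["IVb"], cnt["IVd"]),
      "\n")
  exc <- sum(object@calls$subclass == "IVc_excluded")
  if (exc) cat("  IVc (cold-shock domain) proteins excluded:", exc, "\n")
  invisible(object)
})

#' @rdname RBGTruth-class
#' @export
setMethod("truthMembers", "RBGTruth", function(x) {
  m <- x@members
  m[m$subclass %in% .MEMBER_SUBCLASSES, , drop = FALSE]
})

setMethod("show", "RBGTruth", function(object) {
  m <- object@members
  cat("RBGTruth:", nrow(m), "labelled proteins;",
      nrow(truthMembers(object)), "planted family members\n")
  if (nrow(object@tandemPairs))
    cat("  tandem pairs:", nrow(object@tandemPairs), "\n")
  if (nrow(object@orthologPairs))
    cat("  ortholog pairs:", nrow(object@orthologPairs), "\n")
  invisible(object)
})

#' @rdname DdCtExperiment-class
#' @export
setMethod("calibratorSample", "DdCtExperiment", function(x)
  S4Vectors::metadata(x)$calibrator)

#' Extract the log2 relative-expression matrix
#'
#' @param x A \code{DdCtExperiment}.
#' @return Numeric matrix of log2(2^-ddCt) values, genes x samples.
#' @export
log2FoldChanges <- function(x) {
  stopifnot(is(x, "DdCtExperiment"))
  SummarizedExperiment::assay(x, "log2fc")
}
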