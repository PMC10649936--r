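#' @rdname RBGFamily-class
#' @param x An \code{RBGFamily} (or for \code{calibratorSample}, a
#'   \code{DdCtExperiment}).
#' @export
setGeneric("domainProfiles", function(x) standardGeneric("domainProfiles"))

#' @rdname RBGFamily-class
#' @export
setGeneric("familyCalls", function(x) standardGeneric("familyCalls"))

#' @rdname RBGFamily-class
#' @export
setGeneric("familyMembers", function(x) standardGeneric("familyMembers"))

#' @rdname RBGFamily-class
#' @export
setGeneric("subclassCounts", function(x) standardGeneric("subclassCounts"))

#' @rdname RBGFamily-class
#' @export
setGeneric("proteinProperties", function(x, ...) standardGeneric("proteinProperties"))

#' @rdname DdCtExperiment-class
#' @param x A \code{DdCtExperiment}.
#' @export
setGeneric("calibratorSample", function(x) standardGeneric("calibratorSample"))

#' @rdname RBGTruth-class
#' @param x An \code{RBGTruth}.
#' @export
setGeneric("truthMembers", function(x) standardGeneric("truthMembers"))
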