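#' @rdname ResponseExperiment-class
#' @param object a PharmacoMut object.
#' @export
setGeneric("gi50", function(object) standardGeneric("gi50"))

#' @rdname ResponseExperiment-class
#' @export
setGeneric("testedMask", function(object) standardGeneric("testedMask"))

#' @rdname NormalizedResponse-class
#' @param object a `NormalizedResponse`.
#' @export
setGeneric("log2NormIC50", function(object) standardGeneric("log2NormIC50"))

#' @rdname ResponseCalls-class
#' @param object a `ResponseCalls`.
#' @export
setGeneric("callMatrix", function(object) standardGeneric("callMatrix"))

#' @rdname ResponseExperiment-class
#' @export
setGeneric("compoundIds", function(object) standardGeneric("compoundIds"))

#' @rdname ResponseExperiment-class
#' @export
setGeneric("cellLineIds", function(object) standardGeneric("cellLineIds"))

#' @rdname MutationTable-class
#' @param object a `MutationTable`.
#' @export
setGeneric("mutationRecords", function(object) standardGeneric("mutationRecords"))

#' @rdname MutationTable-class
#' @export
setGeneric("cellLineUniverse", function(object) standardGeneric("cellLineUniverse"))

#' @rdname CaseControlSplit-class
#' @param object a `CaseControlSplit`.
#' @export
setGeneric("caseLines", function(object) standardGeneric("caseLines"))

#' @rdname CaseControlSplit-class
#' @export
setGeneric("controlLines", function(object) standardGeneric("controlLines"))
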