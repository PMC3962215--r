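#' @include AllClasses.R
NULL

#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))
#' @export
setGeneric("nPeaks", function(x) standardGeneric("nPeaks"))
#' @export
setGeneric("zStats", function(x) standardGeneric("zStats"))
#' @export
setGeneric("sourceIds", function(x) standardGeneric("sourceIds"))
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @export
setGeneric("referenceId", function(x) standardGeneric("referenceId"))
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))
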