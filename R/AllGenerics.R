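#' @rdname MixedMatrix-accessors
#' @export
setGeneric("values", function(x, ...) standardGeneric("values"))

#' @rdname MixedMatrix-accessors
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))

#' @rdname MixedMatrix-accessors
#' @export
setGeneric("naValue", function(x) standardGeneric("naValue"))

#' @rdname MixedMatrix-accessors
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname MixedMatrix-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname MixedMatrix-accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname MixedMatrix-accessors
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname isMissing
#' @export
setGeneric("isMissing", function(x, ...) standardGeneric("isMissing"))

#' @rdname ResultBundle-accessors
#' @export
setGeneric("resultNames", function(x) standardGeneric("resultNames"))
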