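#' @rdname SpectrumSet-accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname SpectrumSet-accessors
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))

#' @rdname SpectrumSet-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SpectrumSet-accessors
#' @export
setGeneric("targetValues", function(x) standardGeneric("targetValues"))

#' @rdname SpectrumSet-accessors
#' @export
setGeneric("targetValues<-", function(x, value) standardGeneric("targetValues<-"))

#' @rdname trimEdges
#' @export
setGeneric("trimEdges", function(x, low = 400, high = 2399)
  standardGeneric("trimEdges"))

#' @rdname FeatureBlock-accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname FeatureBlock-accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname SplitResult-class
#' @export
setGeneric("calibrationIdx", function(x) standardGeneric("calibrationIdx"))

#' @rdname SplitResult-class
#' @export
setGeneric("validationIdx", function(x) standardGeneric("validationIdx"))

#' @rdname IrivResult-class
#' @export
setGeneric("finalBands", function(x) standardGeneric("finalBands"))
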