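#' @rdname FeatureMatrix-class
#' @param object,x a `FeatureMatrix`
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureSchema", function(x) standardGeneric("featureSchema"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureLabels", function(x) standardGeneric("featureLabels"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Selected feature names of a selection result
#' @param x a [CVFSResult-class] or [HFEResult-class]
#' @return character vector of feature names.
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' Per-feature scores of a selection result
#' @param x an [HFEResult-class]
#' @return named numeric vector.
#' @export
setGeneric("featureScores", function(x) standardGeneric("featureScores"))
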