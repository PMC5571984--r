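# Accessor generics. Slot access stays internal; user code goes through
# these.

#' @rdname ViewMatrix-class
#' @param object,x a tdfe S4 object
#' @export
setGeneric("viewValues", function(object) standardGeneric("viewValues"))

#' @rdname ViewMatrix-class
#' @export
setGeneric("viewName", function(object) standardGeneric("viewName"))

#' @rdname ViewMatrix-class
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))

#' @rdname ViewMatrix-class
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname MultiViewSet-class
#' @export
setGeneric("views", function(object) standardGeneric("views"))

#' @rdname MultiViewSet-class
#' @export
setGeneric("viewCase", function(object) standardGeneric("viewCase"))

#' @rdname MultiwayArray-class
#' @export
setGeneric("tensorValues", function(object) standardGeneric("tensorValues"))

#' @rdname MultiwayArray-class
#' @export
setGeneric("tensorType", function(object) standardGeneric("tensorType"))

#' @rdname MultiwayArray-class
#' @export
setGeneric("modeLabels", function(object) standardGeneric("modeLabels"))

#' @rdname HOSVDResult-class
#' @export
setGeneric("coreTensor", function(object) standardGeneric("coreTensor"))

#' @rdname HOSVDResult-class
#' @export
setGeneric("factorMatrices", function(object) standardGeneric("factorMatrices"))

#' @rdname HOSVDResult-class
#' @export
setGeneric("factorRanks", function(object) standardGeneric("factorRanks"))

#' @rdname ProjectedVectors-class
#' @export
setGeneric("projectedVectors", function(object) standardGeneric("projectedVectors"))

#' @rdname SelectionResult-class
#' @export
setGeneric("selectionTable", function(object) standardGeneric("selectionTable"))

#' @rdname SelectionResult-class
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))

#' @rdname PCAResult-class
#' @export
setGeneric("pcaScores", function(object) standardGeneric("pcaScores"))

#' @rdname PCAResult-class
#' @export
setGeneric("pcaLoadings", function(object) standardGeneric("pcaLoadings"))

#' @rdname PCAResult-class
#' @export
setGeneric("pcaEigenvalues", function(object) standardGeneric("pcaEigenvalues"))

#' @rdname SyntheticDataset-class
#' @export
setGeneric("signalFeatures", function(object) standardGeneric("signalFeatures"))

#' @rdname SyntheticDataset-class
#' @export
setGeneric("baseCurves", function(object) standardGeneric("baseCurves"))
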