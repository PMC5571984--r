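#' @rdname ViewMatrix-class
setMethod("viewValues", "ViewMatrix", function(object) object@values)

#' @rdname ViewMatrix-class
setMethod("viewName", "ViewMatrix", function(object) object@name)

#' @rdname ViewMatrix-class
setMethod("featureIds", "ViewMatrix", function(object) rownames(object@values))

#' @rdname ViewMatrix-class
setMethod("sampleIds", "ViewMatrix", function(object) colnames(object@values))

#' @rdname ViewMatrix-class
setMethod("dim", "ViewMatrix", function(x) dim(x@values))

#' @rdname MultiViewSet-class
setMethod("views", "MultiViewSet", function(object) {
  v <- object@views
  names(v) <- vapply(v, viewName, character(1))
  v
})

#' @rdname MultiViewSet-class
setMethod("viewCase", "MultiViewSet", function(object) object@case)

#' @rdname MultiViewSet-class
setMethod("length", "MultiViewSet", function(x) length(x@views))

#' @rdname MultiViewSet-class
#' @param i view index or name
setMethod("[[", "MultiViewSet", function(x, i) views(x)[[i]])

#' @rdname MultiwayArray-class
setMethod("tensorValues", "MultiwayArray", function(object) object@data)

#' @rdname MultiwayArray-class
setMethod("tensorType", "MultiwayArray", function(object) object@tensorType)

#' @rdname MultiwayArray-class
setMethod("modeLabels", "MultiwayArray", function(object) object@modeLabels)

#' @rdname MultiwayArray-class
setMethod("dim", "MultiwayArray", function(x) dim(x@data))

#' @rdname MultiwayArray-class
setMethod("viewCase", "MultiwayArray", function(object) object@case)

#' @rdname HOSVDResult-class
setMethod("coreTensor", "HOSVDResult", function(object) object@core)

#' @rdname HOSVDResult-class
setMethod("factorMatrices", "HOSVDResult", function(object) {
  f <- object@factors
  names(f) <- object@modeLabels
  f
})

#' @rdname HOSVDResult-class
setMethod("factorRanks", "HOSVDResult", function(object) {
  r <- object@ranks
  names(r) <- object@modeLabels
  r
})

#' @rdname HOSVDResult-class
setMethod("modeLabels", "HOSVDResult", function(object) object@modeLabels)

#' @rdname HOSVDResult-class
setMethod("tensorType", "HOSVDResult", function(object) object@tensorType)

#' @rdname ProjectedVectors-class
setMethod("projectedVectors", "ProjectedVectors", function(object) object@vectors)

#' @rdname SelectionResult-class
setMethod("selectionTable", "SelectionResult", function(object) object@table)

#' @rdname SelectionResult-class
setMethod("selectedFeatures", "SelectionResult", function(object)
  object@table$feature_id[object@table$selected])

#' @rdname PCAResult-class
setMethod("pcaScores", "PCAResult", function(object) object@scores)

#' @rdname PCAResult-class
setMethod("pcaLoadings", "PCAResult", function(object) object@loadings)

#' @rdname PCAResult-class
setMethod("pcaEigenvalues", "PCAResult", function(object) object@eigenvalues)

#' @rdname SyntheticDataset-class
setMethod("views", "SyntheticDataset", function(object) views(object@views))

#' @rdname SyntheticDataset-class
setMethod("signalFeatures", "SyntheticDataset", function(object) object@signalIndex)

#' @rdname SyntheticDataset-class
setMethod("baseCurves", "SyntheticDataset", function(object) object@baseCurves)

## show() methods ------------------------------------------------------

setMethod("show", "ViewMatrix", function(object) {
  cat("ViewMatrix \"", object@name, "\": ", nrow(object@values),
      " features x ", ncol(object@values), " samples\n", sep = "")
})

setMethod("show", "MultiViewSet", function(object) {
  cat("MultiViewSet (",
      if (object@case == "shared_samples") "Case I, shared samples"
      else "Case II, shared features",
      "), ", length(object@views), " views\n", sep = "")
  for (v in object@views)
    cat("  - ", v@name, ": ", nrow(v@values), " x ", ncol(v@values), "\n",
        sep = "")
})

setMethod("show", "MultiwayArray", function(object) {
  cat("MultiwayArray (", object@tensorType, ", ",
      if (object@case == "shared_samples") "Case I" else "Case II",
      "): ", paste(dim(object@data), collapse = " x "),
      "\n  modes: ", paste(object@modeLabels, collapse = ", "), "\n",
      sep = "")
})

setMethod("show", "HOSVDResult", function(object) {
  cat("HOSVDResult: core ", paste(dim(object@core), collapse = " x "),
      "\n  modes: ", paste(object@modeLabels, collapse = ", "),
      "\n  factors: ",
      paste(vapply(object@factors, function(U)
        paste(dim(U), collapse = "x"), character(1)), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "ProjectedVectors", function(object) {
  cat("ProjectedVectors over the ",
      if (object@case == "shared_samples") "sample" else "feature",
      " mode (", object@derivation, ")\n", sep = "")
  for (nm in names(object@vectors))
    cat("  - ", nm, ": ", nrow(object@vectors[[nm]]), " components x ",
        ncol(object@vectors[[nm]]), "\n", sep = "")
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult: ", sum(object@table$selected), " of ",
      nrow(object@table), " features selected (BH-adjusted P < ",
      object@alpha, ")\n  components: ",
      if (length(object@components)) paste(object@components, collapse = ", ")
      else "none (screen removed all components)",
      "\n", sep = "")
})

setMethod("show", "PCAResult", function(object) {
  cat("PCAResult: ", ncol(object@scores), " components, ",
      nrow(object@scores), " features, ", nrow(object@loadings),
      " samples\n", sep = "")
})

setMethod("show", "SyntheticDataset", function(object) {
  cfg <- object@config
  cat("SyntheticDataset: two views, N = ", cfg$N, ", N0 = ", cfg$N0,
      ", M = ", cfg$M, ", c = ", cfg$c, ", seed = ", cfg$seed, "\n",
      sep = "")
})
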